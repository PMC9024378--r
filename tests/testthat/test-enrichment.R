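small_ann <- function() {
  phase_annotation(data.frame(
    gene = c("G1", "G2", "G3", "G4", "G5", "G6"),
    phase = c("S", "S", "NO_DATA", "G1", "M/G1", "G2/M")
  ))
}

test_that("phase fractions are over CCR genes; NO_DATA stays in the ccr denominator", {
  ann <- small_ann()
  d <- phase_distribution(c("G1", "G2", "G3"), ann)
  expect_equal(attr(d, "ccr_fraction"), 2 / 3)
  expect_equal(d$fraction[d$phase == "S"], 1.0)
  expect_equal(d$n[d$phase == "NO_DATA"], 1)
  expect_equal(sum(d$n[d$phase != "NO_DATA"]), attr(d, "n_ccr"))
  # phase fractions over the 8 phases sum to 1
  expect_equal(sum(d$fraction[d$phase != "NO_DATA"]), 1, tolerance = 1e-12)

  gd <- group_distribution(d)
  expect_equal(sum(gd$n), attr(d, "n_ccr"))
  expect_equal(sum(gd$fraction), 1, tolerance = 1e-12)
})

test_that("genes missing from the annotation count as NO_DATA", {
  d <- phase_distribution(c("G1", "UNKNOWN1", "UNKNOWN2"), small_ann())
  expect_equal(attr(d, "ccr_fraction"), 1 / 3)
  expect_equal(d$n[d$phase == "NO_DATA"], 2)
})

test_that("an all-NO_DATA set has undefined phase fractions", {
  d <- phase_distribution(c("G3", "UNKNOWN"), small_ann())
  expect_equal(attr(d, "ccr_fraction"), 0)
  expect_true(all(is.na(d$fraction)))
})

test_that("enrichment reports signed differences that sum to zero", {
  ann <- small_ann()
  target <- phase_distribution(c("G1", "G2", "G4"), ann)           # S-heavy
  baseline <- phase_distribution(c("G1", "G4", "G5", "G6"), ann)
  enr <- phase_enrichment(target, baseline)
  expect_equal(enr$difference, enr$target_fraction - enr$baseline_fraction)
  ph <- enr[enr$level_type == "phase", ]
  expect_equal(sum(ph$difference), 0, tolerance = 1e-12)
  gr <- enr[enr$level_type == "group", ]
  expect_equal(sum(gr$difference), 0, tolerance = 1e-12)
  expect_gt(ph$difference[ph$level == "S"], 0)  # S overrepresented in target
  # baseline fraction 0 with nonzero target -> ratio undefined, difference kept
  zero_base <- ph[ph$level == "G2/M", ]
  expect_equal(zero_base$baseline_fraction, 0.25)
  m_row <- ph[ph$level == "M", ]
  expect_true(is.na(m_row$ratio))

  identical_enr <- phase_enrichment(target, target)
  expect_true(all(identical_enr$difference == 0))
})

test_that("enrichment refuses mismatched phase vocabularies", {
  ann1 <- small_ann()
  ann2 <- phase_annotation(data.frame(gene = "G1", phase = "S"),
                           grouping = phase_grouping(
                             early = c("G1(P)", "G1"),
                             mid = c("G1/S", "S"),
                             late = c("G2", "G2/M", "M", "M/G1")))
  d1 <- phase_distribution("G1", ann1)
  d2 <- phase_distribution("G1", ann2)
  expect_error(phase_enrichment(d1, d2), "different phase vocabularies")
})

test_that("shared targets are a sorted, commutative, idempotent intersection", {
  a <- c("G3", "G1", "G2")
  b <- c("G2", "G4", "G3")
  expect_equal(shared_targets(a, b), c("G2", "G3"))
  expect_equal(shared_targets(a, b), shared_targets(b, a))
  expect_equal(shared_targets(a, a), sort(a))
  expect_equal(shared_targets(a, character(0)), character(0))
  expect_equal(shared_targets(c("G1"), c("G1", "G9")), "G1")
})

test_that("functional tallies count multi-label genes once per label", {
  ann <- annotation_table(terms = data.frame(
    gene = c("G1", "G2", "G2"),
    term = c("Metabolism", "Metabolism", "Cell cycle")
  ))
  tl <- functional_tally(c("G1", "G2"), ann)
  expect_equal(tl$n[tl$term == "Metabolism"], 2)
  expect_equal(tl$n[tl$term == "Cell cycle"], 1)
  expect_equal(tl$fraction[tl$term == "Metabolism"], 1.0)

  with_un <- functional_tally(c("G1", "G9"), ann)
  expect_equal(with_un$n[with_un$term == "UNANNOTATED"], 1)
  expect_equal(nrow(functional_tally(character(0), ann)), 0)
})

test_that("network export restricts edges to the node set and orders by phase", {
  ann <- annotation_table(edges = data.frame(
    source = c("FKH1", "FKH1", "G9"),
    target = c("G1", "G9", "G1"),
    type = c("regulatory", "regulatory", "physical")
  ))
  net <- export_network("G1", ann, phase_ann = small_ann())
  expect_setequal(net$nodes$gene, c("FKH1", "FKH2", "G1"))
  expect_equal(nrow(net$edges), 1)  # edges touching G9 are excluded
  expect_equal(net$edges$target, "G1")

  # phase ordering groups CCR nodes before NO_DATA ones
  net2 <- export_network(c("G5", "G1", "G3"), ann, phase_ann = small_ann())
  expect_equal(net2$nodes$gene[1], "G1")            # G1 phase (early)
  expect_equal(net2$nodes$gene[nrow(net2$nodes)], "G3")  # NO_DATA last? FKH nodes also NO_DATA
  expect_true(all(which(net2$nodes$phase != "NO_DATA") <
                    min(which(net2$nodes$phase == "NO_DATA"))))
})
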