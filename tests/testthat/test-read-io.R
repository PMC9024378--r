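write_tmp_tsv <- function(df, name = "tab.tsv") {
  path <- withr::local_tempfile(fileext = ".tsv", .local_envir = parent.frame())
  readr::write_tsv(df, path, progress = FALSE)
  path
}

test_that("threshold rules filter study rows; duplicates collapse by any-pass", {
  tab <- data.frame(gene = c("g1", "g2"), score = c(3.0, 0.5))
  st <- study_dataset(tab, "a", "FKH1",
                      threshold_rule = list(column = "score", comparator = ">=",
                                            cutoff = 1.0))
  expect_equal(st$targets, "G1")

  dup <- data.frame(gene = c("g1", "g1"), score = c(3.0, 0.1))
  st2 <- study_dataset(dup, "a", "FKH1",
                       threshold_rule = list(column = "score", comparator = ">=",
                                             cutoff = 1.0))
  expect_equal(st2$targets, "G1")

  st3 <- study_dataset(data.frame(gene = c("g1", "g2", "g2")), "a", "FKH1")
  expect_equal(st3$targets, c("G1", "G2"))

  # <= comparator for studies whose scores rank the other way
  st4 <- study_dataset(tab, "a", "FKH1",
                       threshold_rule = list(column = "score", comparator = "<=",
                                             cutoff = 1.0))
  expect_equal(st4$targets, "G2")
})

test_that("a cutoff below every score keeps every distinct gene", {
  tab <- data.frame(gene = c("g1", "g2", "g3", "g1"), score = c(-5, 0, 2, 1))
  st <- study_dataset(tab, "a", "FKH1",
                      threshold_rule = list(column = "score", comparator = ">=",
                                            cutoff = -Inf))
  expect_equal(st$targets, c("G1", "G2", "G3"))
})

test_that("study table format errors are caught, bad score rows are skipped", {
  tab <- data.frame(gene = "g1", score = 1)
  expect_error(
    study_dataset(tab, "a", "FKH1",
                  threshold_rule = list(column = "zscore", comparator = ">=",
                                        cutoff = 1)),
    "missing score column"
  )
  expect_error(study_dataset(data.frame(x = 1), "a", "FKH1"), "no 'gene' column")
  mixed <- data.frame(gene = c("g1", "g2"), score = c("oops", "2.5"))
  expect_warning(
    st <- study_dataset(mixed, "a", "FKH1",
                        threshold_rule = list(column = "score", comparator = ">=",
                                              cutoff = 1)),
    "unparsable score"
  )
  expect_equal(st$targets, "G2")
  expect_warning(study_dataset(data.frame(gene = character()), "a", "FKH1"),
                 "empty target set")
})

test_that("study targets round-trip through TSV", {
  st <- make_study(c("G5", "G1", "G3"), "a")
  path <- write_tmp_tsv(data.frame(gene = st$targets))
  write_study_targets(st, path)
  again <- read_study_targets(path, "a", "FKH1")
  expect_identical(again$targets, st$targets)
})

test_that("comment lines are skipped in the TSV dialect", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("# provenance comment", "gene\tscore", "g1\t2", "g2\t0"), path)
  st <- read_study_targets(path, "a", "FKH1",
                           threshold_rule = list(column = "score",
                                                 comparator = ">=", cutoff = 1))
  expect_equal(st$targets, "G1")
})

test_that("validation tables enforce cutoffs and rectangular time courses", {
  vt <- validation_tables(
    deletion = data.frame(gene = "g1", score = -1.5),
    overexpression = data.frame(gene = "g1", t1 = 0.1, t2 = -1.2),
    cutoffs = c(deletion = 1, overexpression = 1)
  )
  expect_equal(vt$deletion$score, -1.5)
  expect_equal(ncol(vt$overexpression), 3)

  ragged <- data.frame(gene = c("g1", "g2"), t1 = c(1, 2), t2 = c(3, NA))
  expect_error(validation_tables(overexpression = ragged), "ragged")
  expect_error(
    validation_tables(cutoffs = c(deletion = -1, overexpression = 1)),
    ">= 0"
  )
  empty <- validation_tables()
  expect_equal(nrow(empty$deletion), 0)
  expect_equal(nrow(empty$overexpression), 0)
})

test_that("phase annotations reject unknown phases and apply the default grouping", {
  ann <- phase_annotation(data.frame(gene = c("g1", "g2", "g3"),
                                     phase = c("S", "G1/S", "M/G1")))
  expect_equal(ann$group, c("MID", "EARLY", "LATE"))
  expect_error(
    phase_annotation(data.frame(gene = "g1", phase = "interphase")),
    "unknown cell-cycle phase"
  )
  nd <- phase_annotation(data.frame(gene = c("g1", "g2"),
                                    phase = c("No data", NA)))
  expect_equal(nd$phase, c("NO_DATA", "NO_DATA"))
})

test_that("custom phase groupings must cover the eight phases exactly once", {
  expect_error(phase_grouping(early = c("G1", "G1/S")), "exactly once")
  g <- phase_grouping(early = c("G1(P)", "G1"), mid = c("G1/S", "S"),
                      late = c("G2", "G2/M", "M", "M/G1"))
  expect_equal(unname(g[["G1/S"]]), "MID")
})

test_that("annotation tables validate edge types and deduplicate triples", {
  edges <- data.frame(
    source = c("FKH1", "FKH1", "g1"),
    target = c("g1", "g1", "g2"),
    type = c("regulatory", "regulatory", "physical")
  )
  ann <- annotation_table(edges = edges)
  expect_equal(nrow(ann$edges), 2)
  expect_error(
    annotation_table(edges = data.frame(source = "a", target = "b",
                                        type = "genetic")),
    "unknown edge type"
  )
})
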