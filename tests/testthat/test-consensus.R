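test_that("target matrices are built over the universe or the union", {
  uni <- gene_universe(c("G1", "G2"))
  m <- build_target_matrix(list(make_study("G1", "a")), uni, mode = "genome")
  expect_equal(m$gene, c("G1", "G2"))
  expect_equal(m$a, c(TRUE, FALSE))

  m2 <- build_target_matrix(make_studies(list(a = "G1", b = "G2")),
                            mode = "union")
  expect_setequal(m2$gene, c("G1", "G2"))

  expect_warning(
    m3 <- build_target_matrix(list(make_study(c("G1", "G9"), "a")), uni),
    "appended"
  )
  expect_true("G9" %in% m3$gene)

  expect_error(build_target_matrix(list()), "non-empty list")
  expect_error(
    build_target_matrix(list(make_study("G1", "a", "FKH1"),
                             make_study("G1", "b", "FKH2"))),
    "multiple factors"
  )
})

test_that("Hamming similarity counts both-true and both-false agreement", {
  uni <- gene_universe(paste0("G", 1:5))
  sim <- hamming_similarity(build_target_matrix(
    make_studies(list(a = c("G1", "G2"), b = c("G2", "G3"))), uni))
  # agree on G2 (both true), G4, G5 (both false) -> 3/5
  expect_equal(sim$similarity[sim$study1 == "a" & sim$study2 == "b"], 0.6)

  m_id <- build_target_matrix(make_studies(list(a = "G1", b = "G1")), uni)
  s_id <- as.matrix(hamming_similarity(m_id))
  expect_equal(s_id["a", "b"], 1.0)

  m_comp <- build_target_matrix(
    make_studies(list(a = character(0), b = paste0("G", 1:5))), uni)
  expect_equal(as.matrix(hamming_similarity(m_comp))["a", "b"], 0.0)
})

test_that("Hamming similarity is symmetric with unit diagonal and in [0, 1]", {
  set.seed(42)
  uni <- gene_universe(sprintf("G%02d", 1:12))
  for (rep in 1:5) {
    sets <- random_sets(4, uni$genes)
    sim <- as.matrix(hamming_similarity(build_target_matrix(make_studies(sets), uni)))
    expect_equal(sim, t(sim))
    expect_equal(unname(diag(sim)), rep(1, 4))
    expect_true(all(sim >= 0 & sim <= 1))
  }
})

test_that("hand-enumerated exclusive intersections and conservation identity", {
  m <- build_target_matrix(make_studies(list(A = c("g1", "g2"), B = c("g2", "g3"))),
                           mode = "union")
  it <- exclusive_intersections(m)
  expect_setequal(it$studies, c("A", "B", "A&B"))
  expect_equal(it$n_genes[match(c("A", "B", "A&B"), it$studies)], c(1, 1, 1))
  expect_equal(it$genes[[match("A&B", it$studies)]], "G2")
  expect_equal(sum(it$n_genes), 3)

  single <- exclusive_intersections(
    build_target_matrix(list(make_study(paste0("G", 1:7), "only")), mode = "union"))
  expect_equal(nrow(single), 1)
  expect_equal(single$n_genes, 7)
})

test_that("brute-force oracle reproduces intersections and consensus exactly", {
  set.seed(7)
  uni <- gene_universe(sprintf("G%02d", 1:10))
  for (n_studies in 2:4) {
    for (rep in 1:10) {
      sets <- random_sets(n_studies, uni$genes)
      m <- build_target_matrix(make_studies(sets), uni, mode = "genome")
      it <- exclusive_intersections(m)
      oracle <- oracle_exclusive(sets)
      expect_setequal(it$studies, names(oracle))
      for (key in it$studies) {
        expect_identical(it$genes[[match(key, it$studies)]],
                         sort(oracle[[key]]))
      }
      expect_equal(sum(it$n_genes), length(unique(unlist(sets))))
      for (k in seq_len(n_studies)) {
        expect_identical(k_of_n_consensus(m, k), oracle_k_of_n(sets, k))
      }
    }
  }
})

test_that("consensus is monotone in k, with union and intersection boundaries", {
  set.seed(11)
  uni <- gene_universe(sprintf("G%02d", 1:15))
  sets <- random_sets(5, uni$genes, p = 0.5)
  m <- build_target_matrix(make_studies(sets), uni)
  cons <- lapply(1:5, function(k) k_of_n_consensus(m, k))
  for (k in 2:5) expect_true(all(cons[[k]] %in% cons[[k - 1]]))
  expect_identical(cons[[1]], sort(unique(unlist(sets))))
  expect_identical(cons[[5]], sort(Reduce(intersect, sets)))
  expect_error(k_of_n_consensus(m, 0), "between 1 and")
  expect_error(k_of_n_consensus(m, 6), "between 1 and")
})

test_that("padding the universe with untargeted genes changes only similarity, upward", {
  sets <- list(a = c("G1", "G2"), b = c("G2", "G3"))
  small <- gene_universe(paste0("G", 1:4))
  big <- gene_universe(paste0("G", 1:50))
  m_small <- build_target_matrix(make_studies(sets), small)
  m_big <- build_target_matrix(make_studies(sets), big)

  it_small <- exclusive_intersections(m_small)
  it_big <- exclusive_intersections(m_big)
  expect_identical(tibble::as_tibble(it_small), tibble::as_tibble(it_big))
  expect_identical(k_of_n_consensus(m_small, 2), k_of_n_consensus(m_big, 2))

  s_small <- as.matrix(hamming_similarity(m_small))["a", "b"]
  s_big <- as.matrix(hamming_similarity(m_big))["a", "b"]
  expect_gt(s_big, s_small)
  expect_lt(s_big, 1)
})

test_that("similarity is invariant to gene-row and study-column permutation", {
  set.seed(13)
  uni <- gene_universe(sprintf("G%02d", 1:10))
  sets <- random_sets(3, uni$genes)
  m <- build_target_matrix(make_studies(sets), uni)
  sim <- as.matrix(hamming_similarity(m))

  perm_uni <- gene_universe(sample(uni$genes))
  perm_sets <- rev(sets)
  m_perm <- build_target_matrix(make_studies(perm_sets), perm_uni)
  sim_perm <- as.matrix(hamming_similarity(m_perm))
  expect_equal(sim_perm[rownames(sim), colnames(sim)], sim)
})

test_that("tidy and glance views agree with the matrix", {
  uni <- gene_universe(c("G1", "G2", "G3"))
  m <- build_target_matrix(make_studies(list(a = c("G1", "G2"), b = "G2")), uni)
  long <- tidy(m)
  expect_equal(nrow(long), 6)
  expect_equal(sum(long$target), 3)
  g <- glance(m)
  expect_equal(g$n_union, 2)
  expect_equal(study_totals(m)$n_targets, c(2, 1))
})
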