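test_that("generator configs validate probabilities and feasibility", {
  expect_s3_class(generator_config(), "generator_config")
  expect_error(generator_config(sens = 1.2), "\\[0, 1\\]")
  expect_error(generator_config(n_genes = 50, n_true = 100), "n_true")
  expect_error(generator_config(oe_points = 1), "oe_points")
  expect_error(
    generator_config(n_genes = 100, n_true = c(90, 90), shared_frac = 0),
    "infeasible"
  )
  expect_error(
    generator_config(phase_probs_target = c(S = 1)),
    "8 phases"
  )
})

test_that("truth sets honour the configured overlap exactly", {
  cfg0 <- generator_config(n_genes = 200, n_true = 20, shared_frac = 0, seed = 2)
  tr0 <- simulate_truth(cfg0)
  expect_length(intersect(tr0$truth[[1]], tr0$truth[[2]]), 0)

  cfg1 <- generator_config(n_genes = 200, n_true = 20, shared_frac = 1, seed = 2)
  tr1 <- simulate_truth(cfg1)
  expect_identical(tr1$truth[[1]], tr1$truth[[2]])

  cfg <- generator_config(n_genes = 500, n_true = c(60, 40),
                          shared_frac = 0.55, seed = 3)
  tr <- simulate_truth(cfg)
  expect_length(tr$truth$FKH1, 60)
  expect_length(tr$truth$FKH2, 40)
  expect_length(intersect(tr$truth$FKH1, tr$truth$FKH2), ceiling(0.55 * 40))
})

test_that("study simulation hits its boundary cases and binomial expectation", {
  cfg <- generator_config(n_genes = 1000, n_true = 100, seed = 5)
  tr <- simulate_truth(cfg)
  truth <- tr$truth$FKH1

  perfect <- simulate_study(truth, tr$universe, sens = 1, fpr = 0, seed = 6)
  expect_identical(perfect$targets, sort(truth))
  silent <- suppressWarnings(
    simulate_study(truth, tr$universe, sens = 0, fpr = 0, seed = 6))
  expect_length(silent$targets, 0)

  # E|targets| = 100*0.9 + 900*0.01 = 99, sigma ~ 4.2; check within 3 sigma
  sizes <- vapply(1:10, function(s) {
    length(simulate_study(truth, tr$universe, 0.9, 0.01, seed = 100 + s)$targets)
  }, numeric(1))
  sigma <- sqrt(100 * 0.9 * 0.1 + 900 * 0.01 * 0.99)
  expect_true(all(abs(sizes - 99) <= 3 * sigma))
  expect_lt(abs(mean(sizes) - 99), 3 * sigma / sqrt(10))
})

test_that("validation boundaries close the loop with response classification", {
  cfg <- generator_config(n_genes = 300, n_true = 30, p_del = 1, p_oe = 1,
                          q_del_up = 1, q_oe_down = 1, bg_del = 0, bg_oe = 0,
                          seed = 8)
  tr <- simulate_truth(cfg)
  vt <- simulate_validation(tr$truth$FKH1, tr$universe, cfg, seed = 9)
  vc <- validation_categories(sort(tr$truth$FKH1), vt)
  expect_true(all(vc$category == "BOTH"))
  expect_true(all(vc$deletion_direction == "UP"))
  expect_true(all(vc$oe_final_direction == "DOWN"))
  # non-targets never respond with zero background rates
  others <- setdiff(tr$universe$genes, tr$truth$FKH1)
  vc_bg <- validation_categories(others, vt)
  expect_true(all(vc_bg$category == "NEITHER"))

  cfg_del <- generator_config(n_genes = 300, n_true = 30, p_del = 1, p_oe = 0,
                              bg_del = 0, bg_oe = 0, seed = 8)
  vt_del <- simulate_validation(tr$truth$FKH1, tr$universe, cfg_del, seed = 9)
  vc_del <- validation_categories(sort(tr$truth$FKH1), vt_del)
  expect_true(all(vc_del$category == "DELETION_ONLY"))
})

test_that("the fraction classified BOTH converges to p_del * p_oe", {
  cfg <- generator_config(n_genes = 12000, n_true = c(10000, 100), seed = 3)
  tr <- simulate_truth(cfg)
  vt <- simulate_validation(tr$truth$FKH1, tr$universe, cfg, seed = 4)
  vc <- validation_categories(sort(tr$truth$FKH1), vt)
  expect_equal(mean(vc$category == "BOTH"), cfg$p_del * cfg$p_oe,
               tolerance = 0.02)
})

test_that("bundles are reproducible byte-for-byte under a fixed seed", {
  cfg <- generator_config(n_genes = 150, n_true = c(20, 10), seed = 21)
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  simulate_bundle(cfg, d1)
  simulate_bundle(cfg, d2)
  files <- list.files(d1)
  expect_true(length(files) > 10)
  for (f in files) {
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)),
                     label = paste("file", f))
  }
})

test_that("consensus recovery is high at good error rates and degrades at bad ones", {
  run_recovery <- function(sens, fpr, seeds) {
    vapply(seeds, function(s) {
      cfg <- generator_config(n_genes = 1000, n_true = 100, n_studies = 6,
                              sens = sens, fpr = fpr, seed = s)
      tr <- simulate_truth(cfg)
      studies <- lapply(1:6, function(j) {
        simulate_study(tr$truth$FKH1, tr$universe, sens, fpr,
                       study_id = paste0("s", j))
      })
      m <- build_target_matrix(studies, tr$universe)
      jaccard(k_of_n_consensus(m, 4), tr$truth$FKH1)
    }, numeric(1))
  }
  good <- run_recovery(0.9, 0.01, 1:20)
  poor <- run_recovery(0.5, 0.20, 1:5)
  expect_gte(mean(good), 0.9)
  expect_lt(mean(poor), mean(good) - 0.3)
})
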