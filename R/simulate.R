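#' Configuration for the synthetic-data generator
#'
#' Defines the generative model for a two-factor, multi-study benchmark:
#' a latent true-target set per factor, per-study Boolean calls made with
#' a given sensitivity and false-positive rate, conditional deletion and
#' overexpression responses, and multinomial phase-of-peak-expression
#' assignments. Every random draw flows from the single `seed`.
#'
#' Defaults emulate a genome of 6000 genes probed by six binding studies
#' for two paralogous factors with asymmetric regulons (350 and 90 true
#' targets) that share over half of the smaller factor's regulon; most
#' true responders go up upon deletion and end below baseline after an
#' overexpression time course; true targets are strongly enriched for
#' cell cycle-regulated genes relative to a genome where fewer than 15%
#' of genes have an assigned phase.
#'
#' @param n_genes Universe size.
#' @param n_true True-target set size per factor; length 1 (both) or 2.
#' @param n_studies Number of binding studies per factor.
#' @param sens Per-study probability of calling a true target; length 1
#'   or `n_studies`.
#' @param fpr Per-study probability of calling a non-target; length 1 or
#'   `n_studies`.
#' @param p_del,p_oe Probability that a true target responds to deletion /
#'   overexpression.
#' @param q_del_up Probability that a responding deletion score is
#'   positive (upregulated upon deletion).
#' @param q_oe_down Probability that a responding overexpression course
#'   ends below `-cutoff`.
#' @param bg_del,bg_oe Background response probabilities for non-targets
#'   (direction 50/50).
#' @param oe_points Time-course length (>= 2).
#' @param del_cutoff,oe_cutoff Response thresholds (>= 0); echoed into the
#'   generated tables' threshold configuration.
#' @param phase_probs_target,phase_probs_genome Named probability vectors
#'   over the 8 phases plus `NO_DATA`, summing to 1, for true targets and
#'   for the rest of the genome.
#' @param shared_frac Fraction of the second factor's true targets shared
#'   with the first factor's.
#' @param tfs Length-2 character vector of factor labels.
#' @param study_ids Study labels; default six labels matching the six
#'   published binding studies the defaults emulate.
#' @param seed Integer RNG seed.
#' @return Validated list of class `generator_config`.
#' @export
generator_config <- function(n_genes = 6000,
                             n_true = c(350, 90),
                             n_studies = 6,
                             sens = 0.8,
                             fpr = 0.02,
                             p_del = 0.35,
                             p_oe = 0.35,
                             q_del_up = 0.8,
                             q_oe_down = 0.9,
                             bg_del = 0.02,
                             bg_oe = 0.02,
                             oe_points = 5,
                             del_cutoff = 1,
                             oe_cutoff = 1,
                             phase_probs_target = c(
                               "G1(P)" = 0.03, "G1" = 0.05, "G1/S" = 0.04,
                               "S" = 0.12, "G2" = 0.06, "G2/M" = 0.10,
                               "M" = 0.10, "M/G1" = 0.05, NO_DATA = 0.45
                             ),
                             phase_probs_genome = c(
                               "G1(P)" = 0.01, "G1" = 0.02, "G1/S" = 0.02,
                               "S" = 0.02, "G2" = 0.01, "G2/M" = 0.01,
                               "M" = 0.01, "M/G1" = 0.01, NO_DATA = 0.89
                             ),
                             shared_frac = 0.55,
                             tfs = c("FKH1", "FKH2"),
                             study_ids = c("ostrow2014", "macisaac2006",
                                           "venters2011", "mondeel2019",
                                           "rossi2021", "lupo2021"),
                             seed = 1L) {
  n_true <- rep_len(as.integer(n_true), 2)
  sens <- rep_len(sens, n_studies)
  fpr <- rep_len(fpr, n_studies)
  study_ids <- rep_len(as.character(study_ids), n_studies)
  if (anyDuplicated(study_ids)) stop("study_ids must be distinct", call. = FALSE)

  probs <- c(sens, fpr, p_del, p_oe, q_del_up, q_oe_down, bg_del, bg_oe,
             shared_frac)
  if (any(probs < 0 | probs > 1)) {
    stop("all probabilities must lie in [0, 1]", call. = FALSE)
  }
  if (any(n_true > n_genes)) stop("n_true cannot exceed n_genes", call. = FALSE)
  if (oe_points < 2) stop("oe_points must be >= 2", call. = FALSE)
  if (del_cutoff < 0 || oe_cutoff < 0) stop("cutoffs must be >= 0", call. = FALSE)

  check_probs <- function(p, what) {
    if (!setequal(names(p), c(cc_phases(), NO_DATA))) {
      stop(what, " must be named over the 8 phases plus NO_DATA", call. = FALSE)
    }
    if (abs(sum(p) - 1) > 1e-12) stop(what, " must sum to 1", call. = FALSE)
    p[c(cc_phases(), NO_DATA)]
  }
  phase_probs_target <- check_probs(phase_probs_target, "phase_probs_target")
  phase_probs_genome <- check_probs(phase_probs_genome, "phase_probs_genome")

  n_shared <- ceiling(shared_frac * n_true[2])
  if (n_true[1] + n_true[2] - n_shared > n_genes) {
    stop("infeasible shared_frac: the two truth sets need more genes than n_genes",
         call. = FALSE)
  }
  structure(
    list(n_genes = as.integer(n_genes), n_true = n_true,
         n_studies = as.integer(n_studies), sens = sens, fpr = fpr,
         p_del = p_del, p_oe = p_oe, q_del_up = q_del_up,
         q_oe_down = q_oe_down, bg_del = bg_del, bg_oe = bg_oe,
         oe_points = as.integer(oe_points),
         del_cutoff = del_cutoff, oe_cutoff = oe_cutoff,
         phase_probs_target = phase_probs_target,
         phase_probs_genome = phase_probs_genome,
         shared_frac = shared_frac, tfs = toupper(tfs),
         study_ids = study_ids, seed = as.integer(seed)),
    class = "generator_config"
  )
}

#' Draw the latent truth: universe and true-target sets
#'
#' Creates synthetic gene names `G000001..` and samples one true-target
#' set per factor. The second factor's set is constructed to share exactly
#' `ceiling(shared_frac * n_true[2])` genes with the first factor's set,
#' the remainder drawn from outside it, so the overlap is controlled
#' exactly rather than in expectation.
#'
#' @param cfg A [generator_config()].
#' @param seed Optional seed; defaults to `cfg$seed`. Pass `NULL` to use
#'   the current RNG state (as [simulate_bundle()] does for its
#'   sub-draws).
#' @return List with elements `universe` (a [gene_universe()]) and
#'   `truth` (named list of sorted gene vectors, one per factor).
#' @export
simulate_truth <- function(cfg, seed = cfg$seed) {
  stopifnot(inherits(cfg, "generator_config"))
  if (!is.null(seed)) set.seed(seed)
  genes <- sprintf("G%06d", seq_len(cfg$n_genes))
  truth1 <- sample(genes, cfg$n_true[1])
  n_shared <- ceiling(cfg$shared_frac * cfg$n_true[2])
  n_shared <- min(n_shared, cfg$n_true[1], cfg$n_true[2])
  shared <- if (n_shared > 0) sample(truth1, n_shared) else character(0)
  rest <- sample(setdiff(genes, truth1), cfg$n_true[2] - n_shared)
  truth2 <- c(shared, rest)
  truth <- stats::setNames(list(sort(truth1), sort(truth2)), cfg$tfs)
  list(universe = gene_universe(genes), truth = truth)
}

#' Simulate one binding study's target calls
#'
#' Each true target is called with probability `sens`, each other gene
#' with probability `fpr`, independently across genes — the simplest null
#' consistent with treating studies as Boolean vectors. The expected
#' target count is `m * sens + (N - m) * fpr` for `m` true targets in a
#' universe of `N`.
#'
#' @param truth Character vector of true-target genes.
#' @param universe A [gene_universe()].
#' @param sens,fpr Detection and false-positive probabilities.
#' @param study_id,tf Labels for the resulting dataset.
#' @param seed Optional seed; `NULL` (default) uses the current RNG state.
#' @return A [study_dataset()] with `threshold_rule = "precalled"`.
#' @export
simulate_study <- function(truth, universe, sens, fpr,
                           study_id = "sim", tf = "FKH1", seed = NULL) {
  stopifnot(inherits(universe, "gene_universe"),
            sens >= 0, sens <= 1, fpr >= 0, fpr <= 1)
  if (!is.null(seed)) set.seed(seed)
  genes <- universe$genes
  is_true <- genes %in% truth
  p <- ifelse(is_true, sens, fpr)
  called <- stats::runif(length(genes)) < p
  suppressWarnings(
    study_dataset(tibble::tibble(gene = genes[called]),
                  study_id = study_id, tf = tf, universe = universe)
  )
}

#' Simulate deletion and overexpression validation tables for one factor
#'
#' True targets respond to deletion with probability `p_del` (score sign
#' up with probability `q_del_up`) and to overexpression with probability
#' `p_oe` (final time point down with probability `q_oe_down`); background
#' genes respond at `bg_del` / `bg_oe` with random sign. Responding scores
#' are drawn as `cutoff + |N(1, 0.5^2)|` beyond the threshold and
#' non-responding scores as sub-threshold noise `N(0, (cutoff/4)^2)`;
#' earlier time-course points of responders are sub-threshold noise too,
#' so the generated courses are flat-then-move by construction. Every
#' gene gets a row in both tables, emulating genome-wide expression
#' profiling.
#'
#' @param truth Character vector of true-target genes for this factor.
#' @param universe A [gene_universe()].
#' @param cfg A [generator_config()].
#' @param seed Optional seed; `NULL` uses the current RNG state.
#' @return A [validation_tables()] with the config's cutoffs.
#' @export
simulate_validation <- function(truth, universe, cfg, seed = NULL) {
  stopifnot(inherits(cfg, "generator_config"), inherits(universe, "gene_universe"))
  if (!is.null(seed)) set.seed(seed)
  genes <- universe$genes
  n <- length(genes)
  is_true <- genes %in% truth

  noise <- function(k, cutoff) stats::rnorm(k, 0, cutoff / 4)

  # deletion: one signed score per gene
  p_resp <- ifelse(is_true, cfg$p_del, cfg$bg_del)
  responds <- stats::runif(n) < p_resp
  p_up <- ifelse(is_true, cfg$q_del_up, 0.5)
  up <- stats::runif(n) < p_up
  del_score <- noise(n, cfg$del_cutoff)
  mag <- cfg$del_cutoff + abs(stats::rnorm(n, 1, 0.5))
  del_score[responds] <- (ifelse(up, 1, -1) * mag)[responds]

  # overexpression: time course per gene, final point carries the response
  p_resp_oe <- ifelse(is_true, cfg$p_oe, cfg$bg_oe)
  responds_oe <- stats::runif(n) < p_resp_oe
  p_down <- ifelse(is_true, cfg$q_oe_down, 0.5)
  down <- stats::runif(n) < p_down
  course <- matrix(noise(n * cfg$oe_points, cfg$oe_cutoff), nrow = n)
  final <- noise(n, cfg$oe_cutoff)
  mag_oe <- cfg$oe_cutoff + abs(stats::rnorm(n, 1, 0.5))
  final[responds_oe] <- (ifelse(down, -1, 1) * mag_oe)[responds_oe]
  course[, cfg$oe_points] <- final

  oe <- tibble::as_tibble(course, .name_repair = ~ paste0("t", seq_len(cfg$oe_points)))
  oe <- tibble::add_column(oe, gene = genes, .before = 1)
  validation_tables(
    deletion = tibble::tibble(gene = genes, score = del_score),
    overexpression = oe,
    cutoffs = c(deletion = cfg$del_cutoff, overexpression = cfg$oe_cutoff),
    universe = universe
  )
}

#' Simulate a phase annotation
#'
#' True targets (of either factor) draw their phase from
#' `phase_probs_target`, all other genes from `phase_probs_genome`.
#'
#' @param truths Named list of true-target gene vectors.
#' @param universe A [gene_universe()].
#' @param cfg A [generator_config()].
#' @param seed Optional seed; `NULL` uses the current RNG state.
#' @return A [phase_annotation()].
#' @export
simulate_phases <- function(truths, universe, cfg, seed = NULL) {
  stopifnot(inherits(cfg, "generator_config"))
  if (!is.null(seed)) set.seed(seed)
  genes <- universe$genes
  is_true <- genes %in% unlist(truths)
  levels <- c(cc_phases(), NO_DATA)
  ph <- character(length(genes))
  ph[is_true] <- sample(levels, sum(is_true), replace = TRUE,
                        prob = cfg$phase_probs_target)
  ph[!is_true] <- sample(levels, sum(!is_true), replace = TRUE,
                         prob = cfg$phase_probs_genome)
  phase_annotation(tibble::tibble(gene = genes, phase = ph))
}

#' Simulate a functional-annotation table
#'
#' Assigns each gene one or two top-level functional labels, with true
#' targets biased toward cell-cycle/cell-division labels, and builds a
#' regulatory edge from each factor to each of its true targets plus a
#' sprinkling of physical edges among targets.
#'
#' @inheritParams simulate_phases
#' @return An [annotation_table()].
#' @export
simulate_annotation <- function(truths, universe, cfg, seed = NULL) {
  stopifnot(inherits(cfg, "generator_config"))
  if (!is.null(seed)) set.seed(seed)
  genes <- universe$genes
  is_true <- genes %in% unlist(truths)
  labels <- c("Cell cycle", "Cell division", "Metabolism",
              "Signal transduction", "Transport", "Other")
  p_target <- c(0.25, 0.15, 0.20, 0.10, 0.10, 0.20)
  p_bg <- c(0.05, 0.05, 0.25, 0.10, 0.15, 0.40)
  term <- character(length(genes))
  term[is_true] <- sample(labels, sum(is_true), replace = TRUE, prob = p_target)
  term[!is_true] <- sample(labels, sum(!is_true), replace = TRUE, prob = p_bg)
  terms <- tibble::tibble(gene = genes, term = term, scheme = "GO_term_1")

  reg <- purrr::imap_dfr(truths, function(tg, tf) {
    tibble::tibble(source = tf, target = tg, type = "regulatory",
                   evidence = "simulated")
  })
  all_true <- sort(unique(unlist(truths)))
  n_phys <- min(length(all_true) %/% 2, 200)
  phys <- if (n_phys >= 1 && length(all_true) >= 2) {
    tibble::tibble(
      source = sample(all_true, n_phys, replace = TRUE),
      target = sample(all_true, n_phys, replace = TRUE),
      type = "physical", evidence = "simulated"
    )
  } else NULL
  if (!is.null(phys)) phys <- phys[phys$source != phys$target, ]
  annotation_table(terms, dplyr::bind_rows(reg, phys))
}

#' Generate a complete synthetic input bundle on disk
#'
#' Draws the latent truth, the per-study target calls for both factors,
#' the validation tables, the phase annotation, an alias table and the
#' functional/edge annotation, and writes them all in the pipeline's TSV
#' dialect together with a ready-to-run `config.yaml` and a
#' `manifest.json` echoing the configuration and seed. All draws flow
#' from `cfg$seed` in a fixed documented order (truth, then studies in
#' factor-major order, then validation per factor, phases, annotation),
#' so regeneration with the same seed is byte-identical.
#'
#' @param cfg A [generator_config()].
#' @param dir Output directory (created if missing).
#' @return Invisibly, a list with the in-memory objects (`universe`,
#'   `truth`, `studies`, `validation`, `phases`, `annotation`) and
#'   `config_path`.
#' @export
simulate_bundle <- function(cfg = generator_config(), dir) {
  stopifnot(inherits(cfg, "generator_config"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  set.seed(cfg$seed)

  latent <- simulate_truth(cfg, seed = NULL)
  universe <- latent$universe
  truth <- latent$truth

  studies <- list()
  for (tf in cfg$tfs) {
    for (j in seq_len(cfg$n_studies)) {
      sid <- cfg$study_ids[j]
      studies[[paste(tf, sid, sep = ".")]] <- simulate_study(
        truth[[tf]], universe, cfg$sens[j], cfg$fpr[j],
        study_id = sid, tf = tf, seed = NULL
      )
    }
  }
  validation <- lapply(stats::setNames(cfg$tfs, cfg$tfs), function(tf) {
    simulate_validation(truth[[tf]], universe, cfg, seed = NULL)
  })
  phases <- simulate_phases(truth, universe, cfg, seed = NULL)
  annotation <- simulate_annotation(truth, universe, cfg, seed = NULL)

  # --- write the bundle ---------------------------------------------------
  w <- function(x, name) {
    path <- file.path(dir, name)
    readr::write_tsv(x, path, progress = FALSE)
    path
  }
  w(tibble::tibble(gene = universe$genes), "universe.tsv")
  w(tibble::tibble(standard = paste0("SYN", seq_len(20)),
                   systematic = universe$genes[seq_len(20)]), "aliases.tsv")
  for (tf in cfg$tfs) {
    w(tibble::tibble(gene = truth[[tf]]), paste0("truth_", tolower(tf), ".tsv"))
    for (sid in cfg$study_ids) {
      st <- studies[[paste(tf, sid, sep = ".")]]
      w(tibble::tibble(gene = st$targets),
        paste0("targets_", tolower(tf), "_", sid, ".tsv"))
    }
    w(validation[[tf]]$deletion, paste0("deletion_", tolower(tf), ".tsv"))
    w(validation[[tf]]$overexpression, paste0("overexpression_", tolower(tf), ".tsv"))
  }
  w(tibble::as_tibble(phases)[c("gene", "phase")], "phases.tsv")
  w(annotation$terms, "go_terms.tsv")
  w(annotation$edges, "edges.tsv")

  config <- list(
    universe = list(genes = "universe.tsv", aliases = "aliases.tsv"),
    k = 4L,
    universe_mode = "genome",
    factors = lapply(stats::setNames(cfg$tfs, cfg$tfs), function(tf) {
      list(
        studies = lapply(cfg$study_ids, function(sid) {
          list(study_id = sid,
               path = paste0("targets_", tolower(tf), "_", sid, ".tsv"),
               threshold_rule = "precalled")
        }),
        deletion = paste0("deletion_", tolower(tf), ".tsv"),
        overexpression = paste0("overexpression_", tolower(tf), ".tsv")
      )
    }),
    cutoffs = list(deletion = cfg$del_cutoff, overexpression = cfg$oe_cutoff),
    oe_rule = "final",
    phases = "phases.tsv",
    annotation = list(terms = "go_terms.tsv", edges = "edges.tsv")
  )
  config_path <- file.path(dir, "config.yaml")
  yaml::write_yaml(config, config_path)

  manifest <- c(unclass(cfg)[setdiff(names(unclass(cfg)), NULL)],
                list(generated = "synthetic bundle",
                     score_model = paste(
                       "responders: sign * (cutoff + |N(1, 0.25)|);",
                       "non-responders and earlier time points: N(0, (cutoff/4)^2)")))
  manifest$phase_probs_target <- as.list(manifest$phase_probs_target)
  manifest$phase_probs_genome <- as.list(manifest$phase_probs_genome)
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)

  invisible(list(universe = universe, truth = truth, studies = studies,
                 validation = validation, phases = phases,
                 annotation = annotation, config_path = config_path))
}
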