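#' Validate a pipeline configuration
#'
#' Reads a YAML configuration (or takes an equivalent list), fills in
#' defaults, and checks the schema before anything is loaded: unknown
#' top-level keys are rejected, each factor needs at least one study with
#' a distinct `study_id`, and the consensus threshold `k` must not exceed
#' the study count. Relative paths are resolved against the config file's
#' directory.
#'
#' Recognized top-level keys: `universe` (`genes`, optional `aliases`),
#' `k` (default 4), `universe_mode` (`"genome"`/`"union"`), `factors`
#' (named list: per factor `studies` — each with `study_id`, `path`,
#' `threshold_rule` — plus `deletion` and `overexpression` paths),
#' `cutoffs` (`deletion`, `overexpression`), `oe_rule`
#' (`"final"`/`"any"`), `phases`, `annotation` (`terms`, `edges`),
#' `out_dir`.
#'
#' @param config Path to a YAML file, or a list with the same structure.
#' @return Object of class `pipeline_config`.
#' @export
validate_config <- function(config) {
  base_dir <- "."
  if (is.character(config) && length(config) == 1) {
    if (!file.exists(config)) stop("config file not found: ", config, call. = FALSE)
    base_dir <- dirname(config)
    config <- yaml::read_yaml(config)
  }
  if (!is.list(config)) stop("config must be a YAML file path or a list", call. = FALSE)

  known <- c("universe", "k", "universe_mode", "factors", "cutoffs",
             "oe_rule", "phases", "annotation", "out_dir")
  unknown <- setdiff(names(config), known)
  if (length(unknown) > 0) {
    stop("unknown config key(s): ", paste(unknown, collapse = ", "), call. = FALSE)
  }

  resolve <- function(p) {
    if (is.null(p)) return(NULL)
    ifelse(grepl("^(/|[A-Za-z]:)", p), p, file.path(base_dir, p))
  }

  if (is.null(config$factors) || length(config$factors) == 0 ||
      is.null(names(config$factors))) {
    stop("config needs a named 'factors' section", call. = FALSE)
  }
  k <- if (is.null(config$k)) 4L else as.integer(config$k)
  if (is.na(k) || k < 1) stop("k must be an integer >= 1", call. = FALSE)
  universe_mode <- if (is.null(config$universe_mode)) "genome" else config$universe_mode
  if (!universe_mode %in% c("genome", "union")) {
    stop("universe_mode must be 'genome' or 'union'", call. = FALSE)
  }
  if (universe_mode == "genome" &&
      (is.null(config$universe) || is.null(config$universe$genes))) {
    stop("genome mode requires universe$genes", call. = FALSE)
  }
  oe_rule <- if (is.null(config$oe_rule)) "final" else config$oe_rule
  if (!oe_rule %in% c("final", "any")) {
    stop("oe_rule must be 'final' or 'any'", call. = FALSE)
  }
  cutoffs <- config$cutoffs
  cutoffs <- c(
    deletion = if (is.null(cutoffs$deletion)) 1 else as.numeric(cutoffs$deletion),
    overexpression = if (is.null(cutoffs$overexpression)) 1 else as.numeric(cutoffs$overexpression)
  )
  if (any(is.na(cutoffs)) || any(cutoffs < 0)) {
    stop("validation cutoffs must be numeric and >= 0", call. = FALSE)
  }

  factors <- lapply(names(config$factors), function(tf) {
    fc <- config$factors[[tf]]
    if (is.null(fc$studies) || length(fc$studies) == 0) {
      stop("factor '", tf, "' has no studies", call. = FALSE)
    }
    ids <- vapply(fc$studies, function(s) as.character(s$study_id %||% ""), character(1))
    if (any(ids == "")) stop("every study needs a study_id (factor '", tf, "')", call. = FALSE)
    if (anyDuplicated(ids)) {
      stop("duplicate study_id(s) for factor '", tf, "': ",
           paste(unique(ids[duplicated(ids)]), collapse = ", "), call. = FALSE)
    }
    if (k > length(ids)) {
      stop("k = ", k, " exceeds the number of studies (", length(ids),
           ") for factor '", tf, "'", call. = FALSE)
    }
    studies <- lapply(fc$studies, function(s) {
      rule <- s$threshold_rule %||% "precalled"
      if (!identical(rule, "precalled")) {
        if (!is.list(rule) || !all(c("column", "comparator", "cutoff") %in% names(rule))) {
          stop("bad threshold_rule for study '", s$study_id, "'", call. = FALSE)
        }
        rule$cutoff <- as.numeric(rule$cutoff)
      }
      list(study_id = as.character(s$study_id), path = resolve(s$path),
           threshold_rule = rule)
    })
    list(tf = toupper(tf), studies = studies,
         deletion = resolve(fc$deletion), overexpression = resolve(fc$overexpression))
  })
  names(factors) <- toupper(names(config$factors))

  structure(
    list(
      universe = list(genes = resolve(config$universe$genes),
                      aliases = resolve(config$universe$aliases)),
      k = k, universe_mode = universe_mode, factors = factors,
      cutoffs = cutoffs, oe_rule = oe_rule,
      phases = resolve(config$phases),
      annotation = list(terms = resolve(config$annotation$terms),
                        edges = resolve(config$annotation$edges)),
      out_dir = config$out_dir
    ),
    class = "pipeline_config"
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Run the full consensus analysis pipeline
#'
#' Executes, per factor: load study target tables, build the gene-by-study
#' Boolean matrix, compute Hamming similarities, exclusive intersections
#' and the k-of-n consensus, classify the consensus against the deletion /
#' overexpression validation tables, and summarize cell-cycle-phase
#' distribution and enrichment (baseline: all CCR genes genome-wide) and
#' functional annotation of the (partially) validated targets. Across
#' factors it intersects the (partially) validated sets and exports the
#' node/edge network tables for the union of fully validated targets.
#'
#' When `out_dir` is set, all tables are written as TSV plus a
#' `report.json` with run metadata; writing is staged through a temporary
#' directory so a failed run leaves no partial outputs. Internal
#' consistency (every reported count re-derivable from the reported gene
#' lists) is asserted before anything is written.
#'
#' @param config A [validate_config()] result, a path to a YAML config, or
#'   a config list.
#' @param out_dir Output directory; overrides `config$out_dir`. `NULL`
#'   skips writing.
#' @return Object of class `consensus_report` (see [glance.consensus_report()]).
#' @export
run_pipeline <- function(config, out_dir = NULL) {
  if (!inherits(config, "pipeline_config")) config <- validate_config(config)
  out_dir <- out_dir %||% config$out_dir

  stage <- function(label, expr) {
    tryCatch(expr, error = function(e) {
      stop("[", label, "] ", conditionMessage(e), call. = FALSE)
    })
  }

  universe <- stage("universe", {
    if (!is.null(config$universe$genes)) {
      read_gene_universe(config$universe$genes, config$universe$aliases)
    } else NULL
  })
  phases <- stage("phases", {
    if (!is.null(config$phases)) read_phase_annotation(config$phases, universe = universe)
    else NULL
  })
  annotation <- stage("annotation", {
    if (!is.null(config$annotation$terms) || !is.null(config$annotation$edges)) {
      read_annotation(config$annotation$terms, config$annotation$edges,
                      universe = universe)
    } else NULL
  })
  baseline_dist <- if (!is.null(phases) && !is.null(universe)) {
    ccr_genes <- phases$gene[phases$phase != NO_DATA]
    phase_distribution(ccr_genes, phases)
  } else NULL

  per_factor <- lapply(config$factors, function(fc) {
    tf <- fc$tf
    studies <- stage(paste0(tf, "/load"), {
      lapply(fc$studies, function(s) {
        read_study_targets(s$path, study_id = s$study_id, tf = tf,
                           threshold_rule = s$threshold_rule, universe = universe)
      })
    })
    matrix <- stage(paste0(tf, "/matrix"), {
      build_target_matrix(studies, universe = universe, mode = config$universe_mode)
    })
    similarity <- stage(paste0(tf, "/similarity"), hamming_similarity(matrix))
    intersections <- stage(paste0(tf, "/intersections"), exclusive_intersections(matrix))
    consensus <- stage(paste0(tf, "/consensus"), k_of_n_consensus(matrix, config$k))

    tables <- stage(paste0(tf, "/validation"), {
      if (!is.null(fc$deletion) || !is.null(fc$overexpression)) {
        read_validation_tables(fc$deletion, fc$overexpression,
                               cutoffs = config$cutoffs, universe = universe)
      } else validation_tables(cutoffs = config$cutoffs)
    })
    categories <- stage(paste0(tf, "/categories"), {
      suppressWarnings(validation_categories(consensus, tables, oe_rule = config$oe_rule))
    })
    directions <- direction_summary(categories)
    partial <- partially_validated(categories)
    full <- fully_validated(categories)

    dist <- if (!is.null(phases)) phase_distribution(partial, phases) else NULL
    enr <- if (!is.null(dist) && !is.null(baseline_dist)) {
      phase_enrichment(dist, baseline_dist)
    } else NULL
    tally <- if (!is.null(annotation)) functional_tally(partial, annotation) else NULL

    list(tf = tf, studies = studies, matrix = matrix, similarity = similarity,
         intersections = intersections, consensus = consensus,
         categories = categories, directions = directions,
         partially_validated = partial, fully_validated = full,
         phase_distribution = dist, enrichment = enr, functional_tally = tally)
  })

  shared <- if (length(per_factor) >= 2) {
    shared_targets(per_factor[[1]]$partially_validated,
                   per_factor[[2]]$partially_validated)
  } else character(0)
  network <- if (!is.null(annotation)) {
    all_full <- sort(unique(unlist(lapply(per_factor, `[[`, "fully_validated"))))
    export_network(all_full, annotation, phase_ann = phases,
                   factors = names(per_factor))
  } else NULL

  report <- structure(
    list(factors = per_factor, shared_targets = shared, network = network,
         baseline_distribution = baseline_dist, config = config),
    class = "consensus_report"
  )
  check_report(report)
  if (!is.null(out_dir)) write_report(report, out_dir)
  report
}

#' Assert a report's internal consistency
#'
#' Re-derives every headline count from the report's own gene lists:
#' category counts partition the consensus, exclusive intersection counts
#' sum to the union of study targets, the fully validated list matches
#' the `BOTH` category, phase counts sum to the CCR total, and the shared
#' set equals the intersection of the per-factor (partially) validated
#' sets. Called automatically by [run_pipeline()]; exposed for re-checking
#' a report (or a report directory written by it).
#'
#' @param report A `consensus_report`.
#' @return `TRUE` invisibly; stops with a message on any inconsistency.
#' @export
check_report <- function(report) {
  stopifnot(inherits(report, "consensus_report"))
  fail <- function(...) stop("report inconsistency: ", ..., call. = FALSE)
  for (fr in report$factors) {
    cnt <- category_counts(fr$categories)
    if (sum(cnt$n) != length(fr$consensus)) {
      fail(fr$tf, ": category counts do not partition the consensus")
    }
    if (!setequal(fr$fully_validated, fr$categories$gene[fr$categories$category == "BOTH"])) {
      fail(fr$tf, ": fully validated list does not match the BOTH category")
    }
    m <- fr$matrix
    union_n <- sum(rowSums(as.matrix(m[setdiff(names(m), "gene")])) > 0)
    if (sum(fr$intersections$n_genes) != union_n) {
      fail(fr$tf, ": exclusive intersection counts do not sum to the union")
    }
    if (!all(lengths(fr$intersections$genes) == fr$intersections$n_genes)) {
      fail(fr$tf, ": intersection member lists disagree with their counts")
    }
    if (!is.null(fr$phase_distribution)) {
      d <- fr$phase_distribution
      if (sum(d$n[d$phase != NO_DATA]) != attr(d, "n_ccr")) {
        fail(fr$tf, ": phase counts do not sum to the CCR total")
      }
    }
  }
  if (length(report$factors) >= 2) {
    expected <- intersect(report$factors[[1]]$partially_validated,
                          report$factors[[2]]$partially_validated)
    if (!setequal(report$shared_targets, expected)) {
      fail("shared targets do not equal the intersection of validated sets")
    }
  }
  invisible(TRUE)
}

#' @noRd
write_report <- function(report, out_dir) {
  staging <- tempfile("report_staging_")
  dir.create(staging, recursive = TRUE)
  on.exit(unlink(staging, recursive = TRUE), add = TRUE)

  for (fr in report$factors) {
    tf <- tolower(fr$tf)
    write_target_matrix(fr$matrix, file.path(staging, paste0("matrix_", tf, ".tsv")))
    readr::write_tsv(tibble::as_tibble(fr$similarity),
                     file.path(staging, paste0("similarity_", tf, ".tsv")),
                     progress = FALSE)
    write_intersections(fr$intersections,
                        file.path(staging, paste0("intersections_", tf, ".tsv")))
    readr::write_tsv(tibble::tibble(gene = fr$consensus),
                     file.path(staging, paste0("consensus_", tf, ".tsv")),
                     progress = FALSE)
    readr::write_tsv(tibble::as_tibble(fr$categories),
                     file.path(staging, paste0("validation_", tf, ".tsv")),
                     progress = FALSE)
    readr::write_tsv(category_counts(fr$categories),
                     file.path(staging, paste0("category_counts_", tf, ".tsv")),
                     progress = FALSE)
    readr::write_tsv(fr$directions,
                     file.path(staging, paste0("directions_", tf, ".tsv")),
                     progress = FALSE)
    if (!is.null(fr$phase_distribution)) {
      readr::write_tsv(tibble::as_tibble(fr$phase_distribution),
                       file.path(staging, paste0("phase_distribution_", tf, ".tsv")),
                       progress = FALSE)
    }
    if (!is.null(fr$enrichment)) {
      readr::write_tsv(fr$enrichment,
                       file.path(staging, paste0("phase_enrichment_", tf, ".tsv")),
                       progress = FALSE)
    }
    if (!is.null(fr$functional_tally)) {
      readr::write_tsv(fr$functional_tally,
                       file.path(staging, paste0("functional_tally_", tf, ".tsv")),
                       progress = FALSE)
    }
  }
  readr::write_tsv(tibble::tibble(gene = report$shared_targets),
                   file.path(staging, "shared_targets.tsv"), progress = FALSE)
  if (!is.null(report$network)) {
    readr::write_tsv(report$network$nodes, file.path(staging, "network_nodes.tsv"),
                     progress = FALSE)
    readr::write_tsv(report$network$edges, file.path(staging, "network_edges.tsv"),
                     progress = FALSE)
  }
  if (!is.null(report$baseline_distribution)) {
    readr::write_tsv(tibble::as_tibble(report$baseline_distribution),
                     file.path(staging, "phase_distribution_baseline.tsv"),
                     progress = FALSE)
  }

  meta <- list(
    k = report$config$k,
    universe_mode = report$config$universe_mode,
    cutoffs = as.list(report$config$cutoffs),
    oe_rule = report$config$oe_rule,
    factors = lapply(report$factors, function(fr) {
      list(tf = fr$tf,
           studies = vapply(fr$studies, `[[`, character(1), "study_id"),
           n_consensus = length(fr$consensus),
           n_partially_validated = length(fr$partially_validated),
           n_fully_validated = length(fr$fully_validated))
    }),
    n_shared_targets = length(report$shared_targets)
  )
  jsonlite::write_json(meta, file.path(staging, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)

  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  for (f in list.files(staging)) {
    file.copy(file.path(staging, f), file.path(out_dir, f), overwrite = TRUE)
  }
  invisible(out_dir)
}

#' Summarize a consensus report
#'
#' One row per factor with the headline cardinalities of the run: study
#' count, union of targets, consensus size at the configured `k`, and the
#' validated-set sizes.
#'
#' @param x A `consensus_report` from [run_pipeline()].
#' @param ... Unused.
#' @return A tibble.
#' @method glance consensus_report
#' @export
glance.consensus_report <- function(x, ...) {
  purrr::map_dfr(x$factors, function(fr) {
    g <- glance.target_matrix(fr$matrix)
    tibble::tibble(
      tf = fr$tf,
      n_studies = g$n_studies,
      n_union = g$n_union,
      k = x$config$k,
      n_consensus = length(fr$consensus),
      n_partially_validated = length(fr$partially_validated),
      n_fully_validated = length(fr$fully_validated),
      ccr_fraction = if (!is.null(fr$phase_distribution)) {
        attr(fr$phase_distribution, "ccr_fraction")
      } else NA_real_
    )
  })
}

#' @export
print.consensus_report <- function(x, ...) {
  cat("<consensus_report> k =", x$config$k, "\n")
  print(glance.consensus_report(x))
  cat("shared (partially) validated targets:", length(x$shared_targets), "\n")
  invisible(x)
}
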