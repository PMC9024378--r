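#' Read a tab-separated table
#'
#' All pipeline inputs share one TSV dialect: tab-separated, UTF-8, header
#' row required, lines starting with `#` skipped.
#' @noRd
read_tsv_input <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  readr::read_tsv(path, comment = "#", show_col_types = FALSE,
                  progress = FALSE, na = c("", "NA"))
}

#' Construct a study dataset from a target table
#'
#' A study dataset holds one binding study's Boolean target calls for one
#' transcription factor. Rows are filtered by the study's threshold rule
#' (or taken as-is for pre-called lists), gene names are normalized, and
#' duplicate gene rows collapse to a single membership: a gene is a target
#' if *any* of its rows passes the threshold, so multiple peaks per
#' promoter never create multi-membership.
#'
#' @param data Data frame with a `gene` column and, unless
#'   `threshold_rule = "precalled"`, the score column named by the rule.
#' @param study_id Study label, e.g. `"ostrow2014"`.
#' @param tf Transcription factor label, e.g. `"FKH1"`.
#' @param threshold_rule Either the string `"precalled"` (every listed gene
#'   is a target) or a list `list(column =, comparator =, cutoff =)` with
#'   comparator `">="` or `"<="`. Threshold direction is configurable per
#'   study because published scores differ in sign convention.
#' @param universe Optional [gene_universe()] for name normalization.
#'
#' @return Object of class `study_dataset`: a list with elements
#'   `study_id`, `tf`, `targets` (sorted character vector) and
#'   `threshold_rule`.
#' @export
study_dataset <- function(data, study_id, tf,
                          threshold_rule = "precalled", universe = NULL) {
  stopifnot(is.data.frame(data))
  if (!"gene" %in% names(data)) {
    stop("study table for '", study_id, "' has no 'gene' column", call. = FALSE)
  }
  keep <- !is.na(data$gene) & trimws(as.character(data$gene)) != ""
  data <- data[keep, , drop = FALSE]

  if (!identical(threshold_rule, "precalled")) {
    if (!is.list(threshold_rule) ||
        !all(c("column", "comparator", "cutoff") %in% names(threshold_rule))) {
      stop("threshold_rule must be \"precalled\" or list(column=, comparator=, cutoff=)",
           call. = FALSE)
    }
    col <- threshold_rule$column
    if (!col %in% names(data)) {
      stop("study table for '", study_id, "' is missing score column '", col, "'",
           call. = FALSE)
    }
    score <- suppressWarnings(as.numeric(data[[col]]))
    bad <- which(is.na(score))
    if (length(bad) > 0) {
      warning("study '", study_id, "': skipped ", length(bad),
              " row(s) with unparsable score (rows ",
              paste(utils::head(bad, 5), collapse = ", "),
              if (length(bad) > 5) ", ...", ")", call. = FALSE)
      data <- data[-bad, , drop = FALSE]
      score <- score[-bad]
    }
    pass <- switch(threshold_rule$comparator,
      ">=" = score >= threshold_rule$cutoff,
      "<=" = score <= threshold_rule$cutoff,
      stop("comparator must be \">=\" or \"<=\"", call. = FALSE)
    )
    data <- data[pass, , drop = FALSE]
  }

  targets <- sort(unique(normalize_gene_id(as.character(data$gene), universe)))
  if (length(targets) == 0) {
    warning("study '", study_id, "' (", tf, ") has an empty target set", call. = FALSE)
  }
  structure(
    list(study_id = as.character(study_id), tf = toupper(as.character(tf)),
         targets = targets, threshold_rule = threshold_rule),
    class = "study_dataset"
  )
}

#' @export
print.study_dataset <- function(x, ...) {
  rule <- if (identical(x$threshold_rule, "precalled")) "precalled"
          else paste(x$threshold_rule$column, x$threshold_rule$comparator,
                     x$threshold_rule$cutoff)
  cat("<study_dataset> ", x$study_id, " / ", x$tf, ": ",
      length(x$targets), " targets [", rule, "]\n", sep = "")
  invisible(x)
}

#' Read a study target table from TSV
#'
#' @param path Path to a TSV file with columns `gene` and optionally a
#'   score column.
#' @inheritParams study_dataset
#' @return A [study_dataset()].
#' @export
read_study_targets <- function(path, study_id, tf,
                               threshold_rule = "precalled", universe = NULL) {
  study_dataset(read_tsv_input(path), study_id = study_id, tf = tf,
                threshold_rule = threshold_rule, universe = universe)
}

#' Write a study dataset's target list to TSV
#'
#' Writes the target set one gene per row. Re-reading the file as a
#' pre-called study reproduces the target set exactly.
#' @param x A [study_dataset()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_study_targets <- function(x, path) {
  stopifnot(inherits(x, "study_dataset"))
  readr::write_tsv(tibble::tibble(gene = x$targets), path, progress = FALSE)
  invisible(path)
}

#' Construct deletion / overexpression validation tables
#'
#' Holds the two functional-validation inputs: a single score per gene for
#' the response of its transcript level to TF *deletion*, and an ordered
#' time course of scores for the response to TF *overexpression*. Genes
#' missing from a table carry no response evidence (they are not treated
#' as zero response); downstream they classify as non-responding on that
#' axis.
#'
#' @param deletion Data frame with columns `gene`, `score` (may be empty).
#' @param overexpression Data frame with a `gene` column followed by one
#'   numeric column per time point; every row must have the same number of
#'   time points (a ragged table is a format error).
#' @param cutoffs Named numeric vector `c(deletion =, overexpression =)`;
#'   both must be >= 0. A gene responds when its score magnitude reaches
#'   the cutoff.
#' @param universe Optional [gene_universe()].
#'
#' @return Object of class `validation_tables`: list with tibbles
#'   `deletion` (`gene`, `score`) and `overexpression` (`gene`, `t1`..`tk`)
#'   plus the `cutoffs`.
#' @export
validation_tables <- function(deletion = NULL, overexpression = NULL,
                              cutoffs = c(deletion = 1, overexpression = 1),
                              universe = NULL) {
  cutoffs <- c(deletion = unname(cutoffs["deletion"]),
               overexpression = unname(cutoffs["overexpression"]))
  if (any(is.na(cutoffs)) || any(cutoffs < 0)) {
    stop("validation cutoffs must be named, non-missing and >= 0", call. = FALSE)
  }

  if (is.null(deletion)) deletion <- tibble::tibble(gene = character(), score = numeric())
  stopifnot(is.data.frame(deletion))
  if (nrow(deletion) > 0 && !all(c("gene", "score") %in% names(deletion))) {
    stop("deletion table needs columns 'gene' and 'score'", call. = FALSE)
  }
  del <- tibble::tibble(
    gene = if (nrow(deletion)) normalize_gene_id(as.character(deletion$gene), universe, warn = FALSE) else character(),
    score = if (nrow(deletion)) as.numeric(deletion$score) else numeric()
  )
  if (anyDuplicated(del$gene)) {
    warning("deletion table: duplicated gene rows, keeping the first", call. = FALSE)
    del <- del[!duplicated(del$gene), ]
  }

  if (is.null(overexpression)) overexpression <- tibble::tibble(gene = character())
  stopifnot(is.data.frame(overexpression))
  oe <- tibble::as_tibble(overexpression)
  if (nrow(oe) > 0) {
    if (!"gene" %in% names(oe)) stop("overexpression table needs a 'gene' column", call. = FALSE)
    tc_cols <- setdiff(names(oe), "gene")
    if (length(tc_cols) < 1) {
      stop("overexpression table needs at least one time-point column", call. = FALSE)
    }
    tc <- lapply(oe[tc_cols], function(col) suppressWarnings(as.numeric(col)))
    ragged <- Reduce(`|`, lapply(tc, is.na))
    if (any(ragged)) {
      stop("overexpression table is ragged or non-numeric at row(s): ",
           paste(utils::head(which(ragged), 5), collapse = ", "),
           " (every gene needs the same number of time points)", call. = FALSE)
    }
    oe <- tibble::tibble(
      gene = normalize_gene_id(as.character(oe$gene), universe, warn = FALSE),
      !!!stats::setNames(tc, paste0("t", seq_along(tc_cols)))
    )
    if (anyDuplicated(oe$gene)) {
      warning("overexpression table: duplicated gene rows, keeping the first", call. = FALSE)
      oe <- oe[!duplicated(oe$gene), ]
    }
  }

  structure(
    list(deletion = del, overexpression = oe, cutoffs = cutoffs),
    class = "validation_tables"
  )
}

#' @export
print.validation_tables <- function(x, ...) {
  k <- max(0L, ncol(x$overexpression) - 1L)
  cat("<validation_tables> deletion: ", nrow(x$deletion), " genes; ",
      "overexpression: ", nrow(x$overexpression), " genes x ", k,
      " time points; cutoffs (", x$cutoffs[["deletion"]], ", ",
      x$cutoffs[["overexpression"]], ")\n", sep = "")
  invisible(x)
}

#' Read validation tables from TSV
#'
#' @param del_path TSV with columns `gene`, `score` (signed change upon TF
#'   deletion), or `NULL`.
#' @param oe_path TSV with a `gene` column and one column per
#'   overexpression time point, or `NULL`.
#' @inheritParams validation_tables
#' @return A [validation_tables()].
#' @export
read_validation_tables <- function(del_path = NULL, oe_path = NULL,
                                   cutoffs = c(deletion = 1, overexpression = 1),
                                   universe = NULL) {
  del <- if (!is.null(del_path)) read_tsv_input(del_path) else NULL
  oe <- if (!is.null(oe_path)) read_tsv_input(oe_path) else NULL
  validation_tables(del, oe, cutoffs = cutoffs, universe = universe)
}

#' Read a phase annotation from TSV
#'
#' @param path TSV with columns `gene` and `phase`.
#' @inheritParams phase_annotation
#' @return A [phase_annotation()].
#' @export
read_phase_annotation <- function(path, grouping = phase_grouping(),
                                  universe = NULL) {
  phase_annotation(read_tsv_input(path), grouping = grouping, universe = universe)
}

#' Read an alias table from TSV
#'
#' @param path TSV with columns `standard` and `systematic`.
#' @return Tibble with those two columns, suitable for [gene_universe()].
#' @export
read_alias_table <- function(path) {
  tab <- read_tsv_input(path)
  if (!all(c("standard", "systematic") %in% names(tab))) {
    stop("alias table needs columns 'standard' and 'systematic'", call. = FALSE)
  }
  tab
}

#' Construct a functional-annotation table
#'
#' Holds gene-level functional labels (e.g. top-level GO categories or KEGG
#' pathway names, as exported from annotation databases) and
#' regulatory/physical interaction edges.
#'
#' @param terms Data frame with columns `gene`, `term` and optionally
#'   `scheme` (one row per gene-label pair), or `NULL`.
#' @param edges Data frame with columns `source`, `target`, `type`
#'   (`"regulatory"` or `"physical"`) and optionally `evidence`, or
#'   `NULL`. Duplicate (source, target, type) triples collapse to one.
#' @param universe Optional [gene_universe()].
#' @return Object of class `annotation_table`: list with tibbles `terms`
#'   and `edges`.
#' @export
annotation_table <- function(terms = NULL, edges = NULL, universe = NULL) {
  if (is.null(terms)) {
    terms <- tibble::tibble(gene = character(), term = character(),
                            scheme = character())
  }
  stopifnot(is.data.frame(terms))
  if (nrow(terms) > 0 && !all(c("gene", "term") %in% names(terms))) {
    stop("terms table needs columns 'gene' and 'term'", call. = FALSE)
  }
  terms <- tibble::tibble(
    gene = if (nrow(terms)) normalize_gene_id(as.character(terms$gene), universe, warn = FALSE) else character(),
    term = if (nrow(terms)) as.character(terms$term) else character(),
    scheme = if ("scheme" %in% names(terms)) as.character(terms$scheme)
             else rep(NA_character_, nrow(terms))
  )
  terms <- dplyr::distinct(terms)

  if (is.null(edges)) {
    edges <- tibble::tibble(source = character(), target = character(),
                            type = character(), evidence = character())
  }
  stopifnot(is.data.frame(edges))
  if (nrow(edges) > 0) {
    if (!all(c("source", "target", "type") %in% names(edges))) {
      stop("edge table needs columns 'source', 'target' and 'type'", call. = FALSE)
    }
    bad_type <- setdiff(unique(edges$type), c("regulatory", "physical"))
    if (length(bad_type) > 0) {
      stop("unknown edge type(s): ", paste(bad_type, collapse = ", "),
           " (expected 'regulatory' or 'physical')", call. = FALSE)
    }
    edges <- tibble::tibble(
      source = normalize_gene_id(as.character(edges$source), universe, warn = FALSE),
      target = normalize_gene_id(as.character(edges$target), universe, warn = FALSE),
      type = as.character(edges$type),
      evidence = if ("evidence" %in% names(edges)) as.character(edges$evidence)
                 else rep(NA_character_, nrow(edges))
    )
    edges <- edges[!duplicated(edges[c("source", "target", "type")]), ]
  }

  structure(list(terms = tibble::as_tibble(terms), edges = tibble::as_tibble(edges)),
            class = "annotation_table")
}

#' Read a functional-annotation table from TSV files
#'
#' @param terms_path TSV with columns `gene`, `term` (and optionally
#'   `scheme`), or `NULL`.
#' @param edges_path TSV with columns `source`, `target`, `type`
#'   (and optionally `evidence`), or `NULL`.
#' @inheritParams annotation_table
#' @return An [annotation_table()].
#' @export
read_annotation <- function(terms_path = NULL, edges_path = NULL, universe = NULL) {
  terms <- if (!is.null(terms_path)) read_tsv_input(terms_path) else NULL
  edges <- if (!is.null(edges_path)) read_tsv_input(edges_path) else NULL
  annotation_table(terms, edges, universe = universe)
}

#' Read a gene universe from TSV files
#'
#' @param genes_path TSV with a `gene` column listing the universe.
#' @param alias_path Optional TSV alias table (see [read_alias_table()]).
#' @return A [gene_universe()].
#' @export
read_gene_universe <- function(genes_path, alias_path = NULL) {
  tab <- read_tsv_input(genes_path)
  if (!"gene" %in% names(tab)) stop("universe file needs a 'gene' column", call. = FALSE)
  alias <- if (!is.null(alias_path)) read_alias_table(alias_path) else NULL
  gene_universe(as.character(tab$gene), alias = alias)
}
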