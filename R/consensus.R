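#' Build a gene-by-study Boolean target matrix
#'
#' Summarizes each binding study as a Boolean vector over a common gene
#' list, the representation on which all downstream consensus operations
#' (similarity, intersections, k-of-n voting) work.
#'
#' In `"genome"` mode the rows are the declared gene universe; study
#' targets absent from the universe are appended as extra rows with a
#' warning so that no call is silently dropped. In `"union"` mode the rows
#' are just the union of the study target sets. The mode matters for
#' Hamming similarity, whose denominator is the row count.
#'
#' @param studies List of [study_dataset()] objects with distinct
#'   `study_id`s, all for the same transcription factor (set
#'   `allow_mixed_tf = TRUE` to override).
#' @param universe A [gene_universe()]; required in `"genome"` mode.
#' @param mode `"genome"` (default) or `"union"`.
#' @param allow_mixed_tf Permit studies of different factors in one matrix.
#'
#' @return Object of class `target_matrix`: a tibble whose first column is
#'   `gene` followed by one logical column per study (in the order given),
#'   with attributes `tf` and `mode`.
#' @examples
#' a <- study_dataset(data.frame(gene = c("G1", "G2")), "a", "FKH1")
#' b <- study_dataset(data.frame(gene = c("G2", "G3")), "b", "FKH1")
#' build_target_matrix(list(a, b), mode = "union")
#' @export
build_target_matrix <- function(studies, universe = NULL,
                                mode = c("genome", "union"),
                                allow_mixed_tf = FALSE) {
  mode <- match.arg(mode)
  if (!is.list(studies) || length(studies) == 0 ||
      !all(vapply(studies, inherits, logical(1), "study_dataset"))) {
    stop("`studies` must be a non-empty list of study_dataset objects", call. = FALSE)
  }
  ids <- vapply(studies, `[[`, character(1), "study_id")
  if (anyDuplicated(ids)) {
    stop("duplicate study_id(s): ", paste(unique(ids[duplicated(ids)]), collapse = ", "),
         call. = FALSE)
  }
  tfs <- unique(vapply(studies, `[[`, character(1), "tf"))
  if (length(tfs) > 1 && !allow_mixed_tf) {
    stop("studies span multiple factors (", paste(tfs, collapse = ", "),
         "); set allow_mixed_tf = TRUE to combine them", call. = FALSE)
  }

  sets <- lapply(studies, `[[`, "targets")
  all_targets <- sort(unique(unlist(sets)))
  if (mode == "genome") {
    if (is.null(universe)) stop("genome mode requires a gene universe", call. = FALSE)
    genes <- universe$genes
    extra <- setdiff(all_targets, genes)
    if (length(extra) > 0) {
      warning(length(extra), " study target(s) absent from the universe were appended: ",
              paste(utils::head(extra, 5), collapse = ", "),
              if (length(extra) > 5) ", ...", call. = FALSE)
      genes <- c(genes, extra)
    }
  } else {
    genes <- all_targets
  }

  cols <- lapply(sets, function(s) genes %in% s)
  out <- tibble::tibble(gene = genes, !!!stats::setNames(cols, ids))
  structure(out, tf = if (length(tfs) == 1) tfs else tfs, mode = mode,
            class = c("target_matrix", class(tibble::tibble())))
}

#' @noRd
tm_studies <- function(matrix) setdiff(names(matrix), "gene")

#' @noRd
tm_logical <- function(matrix) {
  as.matrix(matrix[tm_studies(matrix)]) * 1L
}

#' Per-study target totals
#'
#' @param matrix A [build_target_matrix()] result.
#' @return Tibble with columns `study` and `n_targets`, in matrix column
#'   order (the bottom-left barplot of an UpSet figure).
#' @export
study_totals <- function(matrix) {
  stopifnot(inherits(matrix, "target_matrix"))
  tibble::tibble(
    study = tm_studies(matrix),
    n_targets = unname(colSums(tm_logical(matrix)))
  )
}

#' @method tidy target_matrix
#' @export
tidy.target_matrix <- function(x, ...) {
  out <- tidyr::pivot_longer(tibble::as_tibble(x), -"gene",
                             names_to = "study", values_to = "target")
  dplyr::arrange(out, .data$study, .data$gene)
}

#' @method glance target_matrix
#' @export
glance.target_matrix <- function(x, ...) {
  m <- tm_logical(x)
  tibble::tibble(
    n_genes = nrow(x),
    n_studies = ncol(m),
    n_union = sum(rowSums(m) > 0),
    mode = attr(x, "mode")
  )
}

#' Hamming similarity between binding studies
#'
#' For each pair of studies, the fraction of genes on which the two
#' Boolean target vectors agree — counted as a target by both, or by
#' neither. The denominator is the full row set of the matrix, so the
#' value depends on whether the matrix was built in `"genome"` or
#' `"union"` mode; the mode is carried on the result for that reason.
#'
#' @param matrix A [build_target_matrix()] result with at least one gene
#'   row.
#' @return Object of class `hamming_similarity`: a tibble with columns
#'   `study1`, `study2`, `similarity` covering all ordered pairs
#'   (symmetric, unit diagonal). Use [as.matrix()] for the square form.
#' @examples
#' a <- study_dataset(data.frame(gene = c("g1", "g2")), "a", "FKH1")
#' b <- study_dataset(data.frame(gene = c("g2", "g3")), "b", "FKH1")
#' uni <- gene_universe(paste0("G", 1:5))
#' hamming_similarity(build_target_matrix(list(a, b), uni))
#' @export
hamming_similarity <- function(matrix) {
  stopifnot(inherits(matrix, "target_matrix"))
  m <- tm_logical(matrix)
  if (nrow(m) == 0) stop("cannot compute similarity over zero gene rows", call. = FALSE)
  agree <- crossprod(m) + crossprod(1L - m)
  sim <- agree / nrow(m)
  out <- tibble::as_tibble(as.table(sim), .name_repair = "minimal")
  names(out) <- c("study1", "study2", "similarity")
  out$study1 <- as.character(out$study1)
  out$study2 <- as.character(out$study2)
  structure(tibble::as_tibble(out),
            n_genes = nrow(m), mode = attr(matrix, "mode"),
            class = c("hamming_similarity", class(tibble::tibble())))
}

#' @export
as.matrix.hamming_similarity <- function(x, ...) {
  studies <- unique(x$study1)
  m <- matrix(NA_real_, length(studies), length(studies),
              dimnames = list(studies, studies))
  m[cbind(x$study1, x$study2)] <- x$similarity
  m
}

#' Exclusive (UpSet-style) study intersections
#'
#' Partitions the union of all study target sets by exact membership
#' pattern: a gene counts toward the subset of studies in which it is a
#' target and no other, the semantics of the dots-and-bars UpSet plot.
#' Subsets with no genes are omitted, so the exclusive counts always sum
#' to the size of the union.
#'
#' @param matrix A [build_target_matrix()] result.
#' @return Object of class `intersection_table`: a tibble with columns
#'   `studies` (`&`-joined study ids in matrix column order), `degree`
#'   (number of studies in the subset), `n_genes`, and `genes` (list
#'   column of sorted gene ids). Rows are ordered by count descending,
#'   then degree, then label. Per-study totals are attached as the
#'   `study_totals` attribute.
#' @export
exclusive_intersections <- function(matrix) {
  stopifnot(inherits(matrix, "target_matrix"))
  studies <- tm_studies(matrix)
  m <- tm_logical(matrix) == 1L
  hit <- rowSums(m) > 0
  if (!any(hit)) {
    out <- tibble::tibble(studies = character(), degree = integer(),
                          n_genes = integer(), genes = list())
  } else {
    genes <- matrix$gene[hit]
    pat <- apply(m[hit, , drop = FALSE], 1, function(r) {
      paste(studies[r], collapse = "&")
    })
    split_genes <- split(genes, pat)
    out <- tibble::tibble(
      studies = names(split_genes),
      degree = unname(lengths(strsplit(names(split_genes), "&", fixed = TRUE))),
      n_genes = unname(lengths(split_genes)),
      genes = unname(lapply(split_genes, sort))
    )
    out <- out[order(-out$n_genes, out$degree, out$studies), ]
  }
  structure(out, study_totals = study_totals(matrix),
            class = c("intersection_table", class(tibble::tibble())))
}

#' Write an intersection table to TSV
#'
#' Serializes the list column of member genes as a comma-joined string.
#' @param x An [exclusive_intersections()] result.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_intersections <- function(x, path) {
  stopifnot(inherits(x, "intersection_table"))
  flat <- tibble::tibble(
    studies = x$studies, degree = x$degree, n_genes = x$n_genes,
    genes = vapply(x$genes, paste, character(1), collapse = ",")
  )
  readr::write_tsv(flat, path, progress = FALSE)
  invisible(path)
}

#' k-of-n voting consensus
#'
#' Returns the genes called a target in at least `k` of the matrix's `n`
#' studies. With `k = 1` this is the union of all study sets; with
#' `k = n`, their intersection; consensus sets shrink monotonically as `k`
#' grows. Requiring a target to recur in at least four of six highly
#' variable binding studies is the selection rule this package was built
#' around.
#'
#' @param matrix A [build_target_matrix()] result.
#' @param k Integer between 1 and the number of studies.
#' @return Sorted character vector of consensus gene ids.
#' @export
k_of_n_consensus <- function(matrix, k) {
  stopifnot(inherits(matrix, "target_matrix"))
  n <- length(tm_studies(matrix))
  if (!is.numeric(k) || length(k) != 1 || is.na(k) || k != as.integer(k) ||
      k < 1 || k > n) {
    stop("`k` must be a single integer between 1 and ", n, call. = FALSE)
  }
  sort(matrix$gene[rowSums(tm_logical(matrix)) >= k])
}

#' Write a target matrix to TSV
#'
#' @param x A [build_target_matrix()] result.
#' @param path Output path; study columns are written as 0/1.
#' @return `path`, invisibly.
#' @export
write_target_matrix <- function(x, path) {
  stopifnot(inherits(x, "target_matrix"))
  flat <- tibble::as_tibble(x)
  for (s in tm_studies(x)) flat[[s]] <- as.integer(flat[[s]])
  readr::write_tsv(flat, path, progress = FALSE)
  invisible(path)
}
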