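#' Cell-cycle phase vocabulary
#'
#' The eight phases of peak expression used to annotate cell
#' cycle-regulated (CCR) genes, in cycle order, plus the `"NO_DATA"` token
#' for genes without an assigned phase.
#'
#' @return Character vector of the eight phase labels.
#' @export
cc_phases <- function() {
  c("G1(P)", "G1", "G1/S", "S", "G2", "G2/M", "M", "M/G1")
}

#' @rdname cc_phases
#' @export
NO_DATA <- "NO_DATA"

#' Phase-to-group mapping
#'
#' Groups the eight cell-cycle phases into the three biological stages used
#' for enrichment summaries: Early (growth), Mid (genome duplication) and
#' Late (cell division). The default mirrors the standard grouping
#' Early = G1(P), G1, G1/S; Mid = S; Late = G2, G2/M, M, M/G1. A custom
#' grouping must cover each of the eight phases exactly once.
#'
#' @param early,mid,late Character vectors of phase labels.
#' @return Named character vector mapping phase -> group
#'   (`"EARLY"`, `"MID"`, `"LATE"`).
#' @export
phase_grouping <- function(early = c("G1(P)", "G1", "G1/S"),
                           mid = "S",
                           late = c("G2", "G2/M", "M", "M/G1")) {
  all_phases <- c(early, mid, late)
  if (anyDuplicated(all_phases) || !setequal(all_phases, cc_phases())) {
    stop("grouping must cover the 8 cell-cycle phases exactly once", call. = FALSE)
  }
  grp <- c(
    stats::setNames(rep("EARLY", length(early)), early),
    stats::setNames(rep("MID", length(mid)), mid),
    stats::setNames(rep("LATE", length(late)), late)
  )
  grp[cc_phases()]
}

#' Construct a phase annotation
#'
#' Maps genes to their phase of peak expression. Phase strings must come
#' from the eight-phase vocabulary ([cc_phases()]); missing or explicit
#' no-data tokens (`"NO_DATA"`, `"No data"`, empty, `NA`) become
#' `"NO_DATA"`. Any other string is a format error that lists the
#' offending values.
#'
#' @param data Data frame with columns `gene` and `phase`.
#' @param grouping Phase-to-group map from [phase_grouping()].
#' @param universe Optional [gene_universe()] used to normalize gene names.
#'
#' @return Object of class `phase_annotation`: a tibble with columns
#'   `gene`, `phase`, `group` (`NA` for `NO_DATA` genes), with the
#'   grouping stored as an attribute.
#' @export
phase_annotation <- function(data, grouping = phase_grouping(), universe = NULL) {
  stopifnot(is.data.frame(data), all(c("gene", "phase") %in% names(data)))
  phase <- as.character(data$phase)
  phase[is.na(phase) | trimws(phase) == "" |
          toupper(trimws(phase)) %in% c("NO_DATA", "NO DATA", "NODATA", "NA")] <- NO_DATA
  phase <- ifelse(phase == NO_DATA, phase, trimws(phase))
  bad <- setdiff(unique(phase), c(cc_phases(), NO_DATA))
  if (length(bad) > 0) {
    stop("unknown cell-cycle phase value(s): ", paste(bad, collapse = ", "),
         "\n  expected one of: ", paste(cc_phases(), collapse = ", "),
         " or NO_DATA", call. = FALSE)
  }
  out <- tibble::tibble(
    gene = normalize_gene_id(as.character(data$gene), universe, warn = FALSE),
    phase = phase,
    group = unname(grouping[phase])
  )
  out <- out[!duplicated(out$gene), ]
  structure(out, grouping = grouping,
            class = c("phase_annotation", class(tibble::tibble())))
}

#' Look up phases for a gene set
#'
#' @param genes Character vector of gene identifiers.
#' @param ann A [phase_annotation()]. Genes absent from the annotation are
#'   returned as `"NO_DATA"`.
#' @return Character vector of phases, same length as `genes`.
#' @export
phase_of <- function(genes, ann) {
  stopifnot(inherits(ann, "phase_annotation"))
  idx <- match(genes, ann$gene)
  out <- ann$phase[idx]
  out[is.na(idx)] <- NO_DATA
  out
}
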