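#' Construct a gene universe
#'
#' A gene universe is the declared set of genes over which target matrices
#' are built and Hamming similarities are computed, together with an alias
#' map that translates standard gene names (e.g. `CLB2`) to systematic
#' names (e.g. `YPR119W`). Systematic names are the canonical identifiers;
#' the six binding studies report a mixture of naming conventions, so every
#' gene label entering the pipeline is passed through
#' [normalize_gene_id()].
#'
#' @param genes Character vector of gene identifiers (typically systematic
#'   names). Uppercased; duplicates removed, keeping first occurrence.
#' @param alias Optional alias table: a data frame with columns `standard`
#'   and `systematic`, or a named character vector (names = standard names,
#'   values = systematic names). Aliases whose systematic name is absent
#'   from `genes` are kept but flagged in the `unmapped_aliases` attribute.
#'
#' @return An object of class `gene_universe`: a list with elements
#'   `genes` (character) and `alias_map` (named character).
#' @examples
#' uni <- gene_universe(c("YPR119W", "YGR108W"),
#'                      alias = c(CLB2 = "YPR119W", CLB1 = "YGR108W"))
#' normalize_gene_id("clb2", uni)
#' @export
gene_universe <- function(genes, alias = NULL) {
  stopifnot(is.character(genes))
  genes <- toupper(trimws(genes))
  if (any(genes == "")) stop("gene universe contains empty identifiers", call. = FALSE)
  genes <- genes[!duplicated(genes)]

  alias_map <- character(0)
  if (!is.null(alias)) {
    if (is.data.frame(alias)) {
      if (!all(c("standard", "systematic") %in% names(alias))) {
        stop("alias table needs columns 'standard' and 'systematic'", call. = FALSE)
      }
      alias_map <- stats::setNames(
        toupper(trimws(alias$systematic)),
        toupper(trimws(alias$standard))
      )
    } else if (is.character(alias) && !is.null(names(alias))) {
      alias_map <- stats::setNames(toupper(trimws(alias)), toupper(trimws(names(alias))))
    } else {
      stop("`alias` must be a data frame or a named character vector", call. = FALSE)
    }
    alias_map <- alias_map[!duplicated(names(alias_map))]
  }

  unmapped <- alias_map[!alias_map %in% genes]
  out <- structure(
    list(genes = genes, alias_map = alias_map),
    unmapped_aliases = unmapped,
    class = "gene_universe"
  )
  out
}

#' @export
print.gene_universe <- function(x, ...) {
  cat("<gene_universe> ", length(x$genes), " genes, ",
      length(x$alias_map), " aliases", sep = "")
  unmapped <- attr(x, "unmapped_aliases")
  if (length(unmapped) > 0) {
    cat(" (", length(unmapped), " aliases map outside the universe)", sep = "")
  }
  cat("\n")
  invisible(x)
}

#' Normalize gene identifiers to canonical form
#'
#' Trims and uppercases a raw gene label and resolves it through the
#' universe's alias map (case-insensitively), returning the systematic name
#' when the label is a known standard name and the uppercased label
#' otherwise. Unmappable names are never dropped: they are kept verbatim
#' (uppercased) so that downstream set operations remain faithful to the
#' input, and a warning is raised when a result is absent from the declared
#' universe.
#'
#' The operation is idempotent: `normalize_gene_id(normalize_gene_id(x))`
#' equals `normalize_gene_id(x)` as long as alias targets are themselves
#' canonical (the usual case for standard -> systematic maps).
#'
#' @param name Character vector of raw gene labels.
#' @param universe Optional [gene_universe()]. When `NULL`, only trimming
#'   and uppercasing are applied.
#' @param warn Warn about results absent from `universe$genes`
#'   (default `TRUE`).
#'
#' @return Character vector of canonical gene identifiers.
#' @export
normalize_gene_id <- function(name, universe = NULL, warn = TRUE) {
  stopifnot(is.character(name))
  out <- toupper(trimws(name))
  if (any(is.na(out) | out == "")) {
    stop("empty or missing gene name at position(s): ",
         paste(which(is.na(out) | out == ""), collapse = ", "), call. = FALSE)
  }
  if (!is.null(universe)) {
    stopifnot(inherits(universe, "gene_universe"))
    hit <- match(out, names(universe$alias_map))
    mapped <- !is.na(hit)
    out[mapped] <- unname(universe$alias_map[hit[mapped]])
    if (warn) {
      missing <- setdiff(unique(out), universe$genes)
      if (length(missing) > 0) {
        warning(length(missing), " gene identifier(s) not in the declared universe: ",
                paste(utils::head(missing, 5), collapse = ", "),
                if (length(missing) > 5) ", ...", call. = FALSE)
      }
    }
  }
  out
}
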