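#' Cell-cycle phase distribution of a gene set
#'
#' Counts genes per phase of peak expression. Genes without an assigned
#' phase (absent from the annotation, or annotated `NO_DATA`) contribute
#' to the `ccr_fraction` denominator — they are part of the set — but are
#' excluded from the phase-fraction denominator, so phase fractions are
#' proportions *of the cell cycle-regulated (CCR) genes in the set*. The
#' `NO_DATA` row is retained for display with an `NA` fraction.
#'
#' @param genes Character vector of gene identifiers (duplicates removed).
#' @param ann A [phase_annotation()].
#' @return Object of class `phase_distribution`: tibble with columns
#'   `phase`, `group`, `n`, `fraction`; attributes `n_genes`, `n_ccr`,
#'   `ccr_fraction` and the grouping.
#' @examples
#' ann <- phase_annotation(data.frame(gene = c("G1", "G2"), phase = c("S", "S")))
#' phase_distribution(c("G1", "G2", "G3"), ann)
#' @export
phase_distribution <- function(genes, ann) {
  stopifnot(inherits(ann, "phase_annotation"))
  genes <- unique(genes)
  grouping <- attr(ann, "grouping")
  ph <- phase_of(genes, ann)
  levels <- c(cc_phases(), NO_DATA)
  n <- as.integer(table(factor(ph, levels = levels)))
  n_ccr <- sum(n[levels != NO_DATA])
  fraction <- ifelse(levels == NO_DATA, NA_real_,
                     if (n_ccr > 0) n[] / n_ccr else NA_real_)
  out <- tibble::tibble(
    phase = levels,
    group = c(unname(grouping[cc_phases()]), NA_character_),
    n = n,
    fraction = fraction
  )
  structure(out,
            n_genes = length(genes), n_ccr = n_ccr,
            ccr_fraction = if (length(genes) > 0) n_ccr / length(genes) else NA_real_,
            grouping = grouping,
            class = c("phase_distribution", class(tibble::tibble())))
}

#' @method glance phase_distribution
#' @export
glance.phase_distribution <- function(x, ...) {
  tibble::tibble(
    n_genes = attr(x, "n_genes"),
    n_ccr = attr(x, "n_ccr"),
    ccr_fraction = attr(x, "ccr_fraction")
  )
}

#' Early/Mid/Late group distribution
#'
#' Collapses a phase distribution onto the three cell-cycle stages
#' (growth, genome duplication, cell division). Fractions are over CCR
#' genes, as in [phase_distribution()].
#'
#' @param dist A [phase_distribution()].
#' @return Tibble with columns `group`, `n`, `fraction`.
#' @export
group_distribution <- function(dist) {
  stopifnot(inherits(dist, "phase_distribution"))
  ccr <- dist[dist$phase != NO_DATA, ]
  agg <- stats::aggregate(ccr$n, by = list(group = ccr$group), FUN = sum)
  agg <- agg[match(c("EARLY", "MID", "LATE"), agg$group), ]
  n_ccr <- attr(dist, "n_ccr")
  tibble::tibble(
    group = c("EARLY", "MID", "LATE"),
    n = as.integer(agg$x),
    fraction = if (n_ccr > 0) agg$x / n_ccr else NA_real_
  )
}

#' Phase over/underrepresentation relative to a baseline
#'
#' Compares a target set's phase distribution with a baseline distribution
#' (canonically: all CCR genes genome-wide), per phase and per
#' Early/Mid/Late group. A phase is overrepresented when the difference
#' (target fraction minus baseline fraction) is positive. The ratio is
#' reported alongside but is `NA` where the baseline fraction is zero;
#' no hypothesis test is attached — these are descriptive proportions.
#' Differences across phases sum to zero because both distributions sum
#' to one.
#'
#' @param target_dist,baseline_dist [phase_distribution()] objects over
#'   the same phase vocabulary and grouping.
#' @return Tibble with columns `level_type` (`"phase"`/`"group"`),
#'   `level`, `target_fraction`, `baseline_fraction`, `difference`,
#'   `ratio`.
#' @export
phase_enrichment <- function(target_dist, baseline_dist) {
  stopifnot(inherits(target_dist, "phase_distribution"),
            inherits(baseline_dist, "phase_distribution"))
  if (!identical(target_dist$phase, baseline_dist$phase) ||
      !identical(attr(target_dist, "grouping"), attr(baseline_dist, "grouping"))) {
    stop("target and baseline distributions use different phase vocabularies",
         call. = FALSE)
  }
  one_level <- function(level_type, level, tf, bf) {
    tibble::tibble(
      level_type = level_type, level = level,
      target_fraction = tf, baseline_fraction = bf,
      difference = tf - bf,
      ratio = ifelse(!is.na(bf) & bf > 0, tf / bf, NA_real_)
    )
  }
  t_ph <- target_dist[target_dist$phase != NO_DATA, ]
  b_ph <- baseline_dist[baseline_dist$phase != NO_DATA, ]
  rows_phase <- one_level("phase", t_ph$phase, t_ph$fraction, b_ph$fraction)
  t_gr <- group_distribution(target_dist)
  b_gr <- group_distribution(baseline_dist)
  rows_group <- one_level("group", t_gr$group, t_gr$fraction, b_gr$fraction)
  dplyr::bind_rows(rows_phase, rows_group)
}

#' Targets shared between two gene sets
#'
#' Plain set intersection, returned sorted for stable output files.
#' Commutative and idempotent. Used to quantify the overlap between the
#' validated target repertoires of two paralogous factors.
#'
#' @param set_a,set_b Character vectors of gene identifiers.
#' @return Sorted character vector.
#' @export
shared_targets <- function(set_a, set_b) {
  sort(intersect(unique(set_a), unique(set_b)))
}

#' Tally functional annotations over a gene set
#'
#' Counts how many genes of a set carry each functional label (e.g.
#' top-level GO category or KEGG pathway). A gene with several labels
#' increments each of them once; genes with no label in the chosen scheme
#' are counted under `UNANNOTATED`. Fractions use the full gene-set size
#' as denominator, so multi-label genes make fractions sum above one —
#' they answer "what share of targets has this function", not a partition.
#'
#' @param genes Character vector of gene identifiers.
#' @param ann An [annotation_table()].
#' @param scheme Optional scheme filter matched against the terms table's
#'   `scheme` column (e.g. `"GO_term_1"`, `"KEGG"`); `NULL` uses all rows.
#' @return Tibble with columns `term`, `n`, `fraction`, sorted by count
#'   descending then term.
#' @export
functional_tally <- function(genes, ann, scheme = NULL) {
  stopifnot(inherits(ann, "annotation_table"))
  genes <- unique(genes)
  if (length(genes) == 0) {
    return(tibble::tibble(term = character(), n = integer(), fraction = numeric()))
  }
  terms <- ann$terms
  if (!is.null(scheme)) terms <- terms[!is.na(terms$scheme) & terms$scheme == scheme, ]
  terms <- terms[terms$gene %in% genes, c("gene", "term")]
  terms <- dplyr::distinct(terms)
  unannotated <- setdiff(genes, terms$gene)
  if (length(unannotated) > 0) {
    terms <- dplyr::bind_rows(
      terms, tibble::tibble(gene = unannotated, term = "UNANNOTATED")
    )
  }
  out <- dplyr::count(terms, .data$term, name = "n")
  out$fraction <- out$n / length(genes)
  dplyr::arrange(out, dplyr::desc(.data$n), .data$term)
}

#' Export node and edge tables for a target network
#'
#' Builds the tables behind a regulatory/physical interaction figure: the
#' nodes are the given target genes plus the transcription factors
#' themselves, each carrying its phase of peak expression (`NO_DATA`
#' allowed), and the edges are the annotation's interactions restricted to
#' pairs with *both* endpoints in the node set. Nodes are ordered by phase
#' (cycle order, `NO_DATA` last) then lexicographically, giving the
#' clustering used by edge-bundled network layouts.
#'
#' @param genes Character vector of target gene identifiers.
#' @param ann An [annotation_table()] with an edge table.
#' @param phase_ann Optional [phase_annotation()] for node phases.
#' @param factors Character vector of factor node ids to include
#'   (default `c("FKH1", "FKH2")`).
#' @return List of class `network_tables` with tibbles `nodes`
#'   (`gene`, `phase`, `group`) and `edges`
#'   (`source`, `target`, `type`, `evidence`).
#' @export
export_network <- function(genes, ann, phase_ann = NULL,
                           factors = c("FKH1", "FKH2")) {
  stopifnot(inherits(ann, "annotation_table"))
  node_ids <- unique(c(toupper(factors), genes))
  if (!is.null(phase_ann)) {
    ph <- phase_of(node_ids, phase_ann)
    grouping <- attr(phase_ann, "grouping")
    gr <- unname(grouping[ph])
  } else {
    ph <- rep(NO_DATA, length(node_ids))
    gr <- rep(NA_character_, length(node_ids))
  }
  nodes <- tibble::tibble(gene = node_ids, phase = ph, group = gr)
  phase_rank <- match(nodes$phase, c(cc_phases(), NO_DATA))
  nodes <- nodes[order(phase_rank, nodes$gene), ]

  edges <- ann$edges
  edges <- edges[edges$source %in% node_ids & edges$target %in% node_ids, ]
  structure(list(nodes = nodes, edges = tibble::as_tibble(edges)),
            class = "network_tables")
}

#' @export
print.network_tables <- function(x, ...) {
  cat("<network_tables> ", nrow(x$nodes), " nodes, ", nrow(x$edges),
      " edges (", sum(x$edges$type == "regulatory"), " regulatory, ",
      sum(x$edges$type == "physical"), " physical)\n", sep = "")
  invisible(x)
}
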