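#' Plot a Hamming similarity matrix
#'
#' Heatmap of pairwise between-study agreement fractions.
#'
#' @param object A [hamming_similarity()] result.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot hamming_similarity
#' @export
autoplot.hamming_similarity <- function(object, ...) {
  studies <- unique(object$study1)
  df <- tibble::as_tibble(object)
  df$study1 <- factor(df$study1, levels = studies)
  df$study2 <- factor(df$study2, levels = rev(studies))
  ggplot2::ggplot(df, ggplot2::aes(.data$study1, .data$study2,
                                   fill = .data$similarity)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(label = sprintf("%.2f", .data$similarity)),
                       size = 3) +
    ggplot2::scale_fill_gradient(low = "white", high = "#2166ac",
                                 limits = c(0, 1)) +
    ggplot2::labs(x = NULL, y = NULL, fill = "Hamming\nsimilarity") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' UpSet-style plot of exclusive study intersections
#'
#' Draws the classic dots-and-bars figure: intersection-size bars on top,
#' a membership dot matrix underneath, intersections of at least
#' `highlight_degree` studies highlighted. Built from the intersection
#' *table*, which remains the contract; the figure is a view of it.
#'
#' @param x An [exclusive_intersections()] result.
#' @param n_max Show at most this many intersections (largest first).
#' @param highlight_degree Highlight intersections with at least this many
#'   studies (default 4); `NULL` disables.
#' @return A ggplot object (bars and dot matrix in aligned facets).
#' @export
plot_upset <- function(x, n_max = 40, highlight_degree = 4) {
  stopifnot(inherits(x, "intersection_table"))
  totals <- attr(x, "study_totals")
  studies <- totals$study
  df <- utils::head(tibble::as_tibble(x), n_max)
  df$rank <- seq_len(nrow(df))
  df$highlight <- if (is.null(highlight_degree)) FALSE else df$degree >= highlight_degree

  dots <- tidyr::crossing(rank = df$rank, study = studies)
  member <- purrr::map2(df$rank, strsplit(df$studies, "&", fixed = TRUE),
                        function(r, s) tibble::tibble(rank = r, study = s))
  member <- dplyr::bind_rows(member)
  dots$member <- paste(dots$rank, dots$study) %in% paste(member$rank, member$study)
  dots$study <- factor(dots$study, levels = rev(studies))

  bars <- ggplot2::ggplot(df, ggplot2::aes(.data$rank, .data$n_genes,
                                           fill = .data$highlight)) +
    ggplot2::geom_col(show.legend = FALSE) +
    ggplot2::geom_text(ggplot2::aes(label = .data$n_genes), vjust = -0.3, size = 2.8) +
    ggplot2::scale_fill_manual(values = c(`FALSE` = "grey35", `TRUE` = "#2166ac")) +
    ggplot2::labs(x = NULL, y = "Genes in intersection") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_blank(),
                   panel.grid.major.x = ggplot2::element_blank())

  matrix_panel <- ggplot2::ggplot(dots, ggplot2::aes(.data$rank, .data$study)) +
    ggplot2::geom_point(ggplot2::aes(alpha = .data$member), size = 2,
                        show.legend = FALSE) +
    ggplot2::scale_alpha_manual(values = c(`FALSE` = 0.15, `TRUE` = 1)) +
    ggplot2::labs(x = NULL, y = NULL) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_blank(),
                   panel.grid = ggplot2::element_blank())

  patchwork::wrap_plots(bars, matrix_panel, ncol = 1, heights = c(2, 1))
}

#' Plot a phase distribution
#'
#' Bar chart of the fraction of CCR genes peaking in each cell-cycle
#' phase, colored by Early/Mid/Late stage; the `NO_DATA` count is shown
#' in the subtitle rather than as a bar because phase fractions are over
#' CCR genes only.
#'
#' @param object A [phase_distribution()] result.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot phase_distribution
#' @export
autoplot.phase_distribution <- function(object, ...) {
  df <- tibble::as_tibble(object)
  df <- df[df$phase != NO_DATA, ]
  df$phase <- factor(df$phase, levels = cc_phases())
  ggplot2::ggplot(df, ggplot2::aes(.data$phase, .data$fraction,
                                   fill = .data$group)) +
    ggplot2::geom_col() +
    ggplot2::scale_fill_manual(values = c(EARLY = "#d6604d", MID = "#4393c3",
                                          LATE = "#5aae61")) +
    ggplot2::labs(x = "Phase of peak expression", y = "Fraction of CCR genes",
                  fill = "Stage",
                  subtitle = sprintf("%d of %d genes are CCR (%.0f%%)",
                                     attr(object, "n_ccr"),
                                     attr(object, "n_genes"),
                                     100 * attr(object, "ccr_fraction"))) +
    ggplot2::theme_minimal()
}

#' Plot phase over/underrepresentation
#'
#' Diverging bars of the difference between target and baseline phase
#' fractions; positive bars mark overrepresented phases.
#'
#' @param enrichment A [phase_enrichment()] result.
#' @param level_type `"phase"` or `"group"`.
#' @return A ggplot object.
#' @export
plot_phase_enrichment <- function(enrichment, level_type = c("phase", "group")) {
  level_type <- match.arg(level_type)
  df <- enrichment[enrichment$level_type == level_type, ]
  df$level <- factor(df$level, levels = if (level_type == "phase") cc_phases()
                                        else c("EARLY", "MID", "LATE"))
  ggplot2::ggplot(df, ggplot2::aes(.data$level, .data$difference,
                                   fill = .data$difference > 0)) +
    ggplot2::geom_col(show.legend = FALSE) +
    ggplot2::geom_hline(yintercept = 0, linewidth = 0.3) +
    ggplot2::scale_fill_manual(values = c(`TRUE` = "#2166ac", `FALSE` = "#b2182b")) +
    ggplot2::labs(x = NULL, y = "Target - baseline fraction of CCR genes") +
    ggplot2::theme_minimal()
}

#' Plot validation category counts
#'
#' Barplot of consensus targets per response category (responding to
#' both, deletion only, overexpression only, or neither perturbation).
#'
#' @param x A [validation_categories()] result, or a named list of them
#'   (one per factor) for a side-by-side comparison.
#' @return A ggplot object.
#' @export
plot_validation_counts <- function(x) {
  if (inherits(x, "validation_result")) x <- list(targets = x)
  df <- purrr::imap_dfr(x, function(v, nm) {
    tibble::add_column(category_counts(v), tf = nm, .before = 1)
  })
  df$category <- factor(df$category, levels = rev(validation_levels))
  ggplot2::ggplot(df, ggplot2::aes(.data$category, .data$n, fill = .data$tf)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL, y = "Consensus targets", fill = NULL) +
    ggplot2::theme_minimal()
}
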