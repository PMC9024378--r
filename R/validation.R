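#' Classify per-gene responses to TF deletion and overexpression
#'
#' Applies the threshold rules of the validation tables to each gene:
#'
#' * `deletion_direction` is `UP` when the deletion score is at or above
#'   `+cutoff`, `DOWN` when at or below `-cutoff`, otherwise `NONE`
#'   (including genes absent from the table — absence is lack of evidence,
#'   not a zero response).
#' * `oe_final_direction` applies the same rule to the *last* point of the
#'   overexpression time course: the biological question is where the
#'   transcript ends up after sustained overexpression.
#' * `oe_trajectory` flags non-monotone courses: `UP_THEN_DOWN` when some
#'   earlier point reaches `+cutoff` while the final point is at or below
#'   `-cutoff` (and the mirrored `DOWN_THEN_UP`). Both sides must cross
#'   the threshold — a mere sign change is not enough, which keeps noisy
#'   sub-threshold wobble from being labelled a reversal.
#'
#' @param genes Character vector of gene identifiers.
#' @param tables A [validation_tables()].
#' @return Tibble with columns `gene`, `deletion_direction`,
#'   `oe_final_direction`, `oe_trajectory`.
#' @export
classify_response <- function(genes, tables) {
  stopifnot(inherits(tables, "validation_tables"), is.character(genes))
  del_cut <- tables$cutoffs[["deletion"]]
  oe_cut <- tables$cutoffs[["overexpression"]]

  direction_of <- function(score, cutoff) {
    out <- rep("NONE", length(score))
    out[!is.na(score) & score >= cutoff] <- "UP"
    out[!is.na(score) & score <= -cutoff] <- "DOWN"
    out
  }

  del_score <- tables$deletion$score[match(genes, tables$deletion$gene)]
  deletion_direction <- direction_of(del_score, del_cut)

  oe <- tables$overexpression
  k <- max(0L, ncol(oe) - 1L)
  idx <- if (nrow(oe)) match(genes, oe$gene) else rep(NA_integer_, length(genes))
  oe_final_direction <- rep("NONE", length(genes))
  oe_trajectory <- rep("MONOTONE_OR_FLAT", length(genes))
  oe_any_direction <- rep("NONE", length(genes))
  if (k >= 1 && any(!is.na(idx))) {
    course <- as.matrix(oe[idx[!is.na(idx)], -1, drop = FALSE])
    final <- course[, k]
    fin_dir <- direction_of(final, oe_cut)
    oe_final_direction[!is.na(idx)] <- fin_dir
    any_up <- rowSums(course >= oe_cut) > 0
    any_down <- rowSums(course <= -oe_cut) > 0
    oe_any_direction[!is.na(idx)] <- ifelse(
      fin_dir != "NONE", fin_dir,
      ifelse(any_up, "UP", ifelse(any_down, "DOWN", "NONE"))
    )
    if (k >= 2) {
      earlier <- course[, -k, drop = FALSE]
      early_up <- rowSums(earlier >= oe_cut) > 0
      early_down <- rowSums(earlier <= -oe_cut) > 0
      traj <- rep("MONOTONE_OR_FLAT", nrow(course))
      traj[early_up & fin_dir == "DOWN"] <- "UP_THEN_DOWN"
      traj[early_down & fin_dir == "UP"] <- "DOWN_THEN_UP"
      oe_trajectory[!is.na(idx)] <- traj
    }
  }

  tibble::tibble(
    gene = genes,
    deletion_direction = deletion_direction,
    oe_final_direction = oe_final_direction,
    oe_any_direction = oe_any_direction,
    oe_trajectory = oe_trajectory
  )
}

#' Assign validation categories to consensus targets
#'
#' Crosses the deletion and overexpression responses into four categories:
#' `BOTH` (responds on both axes — "fully validated"), `DELETION_ONLY`,
#' `OVEREXPRESSION_ONLY`, and `NEITHER`. The categories partition the
#' consensus set; the "(partially) validated" set is everything except
#' `NEITHER`. Not every functional target is expected to respond to both
#' perturbations — paralogous factors can take over after a deletion, and
#' overexpression can be limited by rate-limiting cofactors — which is why
#' the one-axis categories are retained as evidence rather than discarded.
#'
#' @param consensus Character vector of consensus target genes (e.g. from
#'   [k_of_n_consensus()]).
#' @param tables A [validation_tables()].
#' @param oe_rule `"final"` (default) judges overexpression responsiveness
#'   at the last time point; `"any"` accepts a threshold crossing at any
#'   point of the course.
#' @return Object of class `validation_result`: tibble with columns
#'   `gene`, `category`, and the per-gene direction columns of
#'   [classify_response()].
#' @export
validation_categories <- function(consensus, tables,
                                  oe_rule = c("final", "any")) {
  oe_rule <- match.arg(oe_rule)
  stopifnot(is.character(consensus))
  if (length(consensus) == 0) {
    warning("empty consensus set: no genes to categorize", call. = FALSE)
  }
  cls <- classify_response(consensus, tables)
  oe_dir <- if (oe_rule == "final") cls$oe_final_direction else cls$oe_any_direction
  del_resp <- cls$deletion_direction != "NONE"
  oe_resp <- oe_dir != "NONE"
  category <- dplyr::case_when(
    del_resp & oe_resp ~ "BOTH",
    del_resp ~ "DELETION_ONLY",
    oe_resp ~ "OVEREXPRESSION_ONLY",
    .default = "NEITHER"
  )
  out <- tibble::add_column(cls, category = category, .after = "gene")
  structure(out, oe_rule = oe_rule, cutoffs = tables$cutoffs,
            class = c("validation_result", class(tibble::tibble())))
}

#' @noRd
validation_levels <- c("BOTH", "DELETION_ONLY", "OVEREXPRESSION_ONLY", "NEITHER")

#' Category counts for a validation result
#'
#' @param x A [validation_categories()] result.
#' @return Tibble with columns `category` and `n`, all four categories
#'   present (zero-filled).
#' @export
category_counts <- function(x) {
  stopifnot(inherits(x, "validation_result"))
  tab <- table(factor(x$category, levels = validation_levels))
  tibble::tibble(category = validation_levels, n = as.integer(tab))
}

#' Fully and (partially) validated gene sets
#'
#' `fully_validated()` returns the consensus genes responding to both
#' deletion and overexpression (`BOTH`); `partially_validated()` returns
#' those responding to at least one (`BOTH`, `DELETION_ONLY` or
#' `OVEREXPRESSION_ONLY`).
#'
#' @param x A [validation_categories()] result.
#' @return Sorted character vector of gene ids.
#' @export
fully_validated <- function(x) {
  stopifnot(inherits(x, "validation_result"))
  sort(x$gene[x$category == "BOTH"])
}

#' @rdname fully_validated
#' @export
partially_validated <- function(x) {
  stopifnot(inherits(x, "validation_result"))
  sort(x$gene[x$category != "NEITHER"])
}

#' @method glance validation_result
#' @export
glance.validation_result <- function(x, ...) {
  cnt <- category_counts(x)
  tibble::tibble(
    n_consensus = nrow(x),
    n_fully_validated = cnt$n[cnt$category == "BOTH"],
    n_partially_validated = sum(cnt$n[cnt$category != "NEITHER"]),
    oe_rule = attr(x, "oe_rule")
  )
}

#' Response-direction summary for the fully validated set
#'
#' Tallies, over the fully validated (`BOTH`) genes, the deletion response
#' directions, the overexpression final-point directions, and the
#' non-monotone trajectory labels. These are the axes along which the
#' biology is read: a direct activator's targets typically rise upon its
#' deletion being compensated, and fall by the end of its overexpression
#' course.
#'
#' @param x A [validation_categories()] result.
#' @return Tibble with columns `axis`, `direction`, `n` (all axis/direction
#'   combinations present, zero-filled).
#' @export
direction_summary <- function(x) {
  stopifnot(inherits(x, "validation_result"))
  full <- x[x$category == "BOTH", ]
  lv <- list(
    deletion = c("UP", "DOWN"),
    oe_final = c("UP", "DOWN"),
    oe_trajectory = c("UP_THEN_DOWN", "DOWN_THEN_UP")
  )
  cols <- list(full$deletion_direction, full$oe_final_direction, full$oe_trajectory)
  purrr::map2_dfr(names(lv), cols, function(axis, values) {
    tab <- table(factor(values, levels = lv[[axis]]))
    tibble::tibble(axis = axis, direction = lv[[axis]], n = as.integer(tab))
  })
}
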