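#' Univariate F-test scores of features against a target
#'
#' Scores each thermal feature by the F statistic of its univariate linear
#' association with a continuous target,
#' `F = r^2 (n - 2) / (1 - r^2)` on 1 and `n - 2` degrees of freedom (the
#' square of the t statistic for the correlation), with its p-value. A small
#' p-value marks the feature as a significant predictor. Rows flagged
#' incomplete are dropped first; constant features score 0 with a warning.
#'
#' @param table A feature table (from [feature_table()] or any data frame
#'   with the feature columns and the target), typically one ROI's rows.
#' @param target `"arv"` or `"mdf"` (or any numeric column name).
#' @param features Feature columns to score (default the nine thermal
#'   features present in `table`).
#' @return A tibble with `feature`, `f_statistic`, `p_value` and `rank`
#'   (1 = largest F; ties broken by feature declaration order).
#' @export
f_test_scores <- function(table, target = c("arv", "mdf"),
                          features = available_features(table)) {
  target <- if (is.character(target)) target[1] else stop("target must be a column name")
  stopifnot(target %in% names(table), length(features) > 0)
  if ("complete" %in% names(table)) {
    table <- table[table$complete %in% TRUE, , drop = FALSE]
  }
  y <- table[[target]]
  keep <- is.finite(y)
  n <- sum(keep)
  if (n < 3) stop("need at least 3 complete rows to score features", call. = FALSE)
  y <- y[keep]
  scores <- purrr::map_dbl(features, function(f) {
    x <- table[[f]][keep]
    if (stats::sd(x) == 0 || stats::sd(y) == 0) {
      warning("feature '", f, "' (or the target) is constant; F set to 0",
              call. = FALSE)
      return(0)
    }
    r <- stats::cor(x, y)
    r^2 * (n - 2) / max(1 - r^2, .Machine$double.eps)
  })
  out <- tibble::tibble(
    feature = features,
    f_statistic = scores,
    p_value = stats::pf(scores, 1, n - 2, lower.tail = FALSE),
    n = n
  )
  # ties broken by declaration order: stable sort on -F
  out$rank <- rank(-out$f_statistic, ties.method = "first")
  out
}

# feature columns present in the table with at least one finite value
# (all-NA columns are structurally unavailable, e.g. grad without patches)
available_features <- function(table) {
  cand <- intersect(thermal_feature_names(), names(table))
  cand[vapply(cand, function(f) any(is.finite(table[[f]])), logical(1))]
}

#' Keep the k features with the largest F statistics
#'
#' @param scores A tibble from [f_test_scores()].
#' @param k Number of features to keep (default 3, the number carried into
#'   the regression stage).
#' @return Character vector of `k` feature names, in descending-F order.
#' @export
select_top_k <- function(scores, k = 3) {
  stopifnot(k >= 0, k <= nrow(scores))
  if (k == 0) return(character(0))
  scores$feature[order(scores$rank)][seq_len(k)]
}

#' F-test score table across ROIs and targets
#'
#' Convenience wrapper replicating the feature-selection score figure:
#' every (ROI, target) combination scored separately.
#'
#' @param table A pooled feature table with a `roi_id` column.
#' @param targets Targets to score against.
#' @return A tibble with `target`, `roi_id` and the score columns.
#' @export
score_grid <- function(table, targets = c("arv", "mdf")) {
  combos <- tidyr::expand_grid(target = targets,
                               roi_id = sort(unique(table$roi_id)))
  purrr::pmap_dfr(combos, function(target, roi_id) {
    sub <- table[table$roi_id == roi_id, , drop = FALSE]
    dplyr::bind_cols(tibble::tibble(target = target, roi_id = roi_id),
                     f_test_scores(sub, target))
  })
}
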