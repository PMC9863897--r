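#' Nested leave-one-subject-out cross-validated regression
#'
#' Estimates how well a regressor family predicts an EMG target (ARV or MDF)
#' from thermal features of one ROI, with subject-level generalization: the
#' outer loop leaves each subject out in turn; the inner loop runs
#' leave-one-subject-out over the remaining subjects to pick the
#' hyperparameter grid point with the smallest validation RMSE; the model is
#' then refit on all outer-training rows and predicts the held-out subject.
#' Feature selection (default mode) and feature/target standardization use
#' outer-training rows only, so nothing about the test subject leaks into
#' training.
#'
#' @param table Pooled feature table (see [feature_table()]); rows of one
#'   ROI, or pass `roi` to filter.
#' @param target `"arv"` or `"mdf"`.
#' @param family Family name from [regressor_families()], or a family
#'   definition list.
#' @param roi Optional ROI id to filter `table` to.
#' @param k Number of features the F-test selection keeps (default 3).
#' @param selection_mode `"fold"` (default; selection inside each outer
#'   training fold) or `"global"` (replication mode: selection once on all
#'   rows, as when scores are computed globally before CV — optimistic,
#'   kept for comparability).
#' @param features Candidate feature columns.
#'
#' @return An object of class `tm_cv`: list with `predictions` (one row per
#'   held-out row: gold and predicted values on the raw and z scales),
#'   `fold_log` (per-fold selected features and chosen hyperparameters),
#'   pooled `rmse_z`, `r`, `r_p`, and metadata. `tidy()` returns the
#'   predictions, `glance()` the one-row summary.
#' @export
nested_loso_cv <- function(table, target = c("arv", "mdf"), family = "linear",
                           roi = NULL, k = 3,
                           selection_mode = c("fold", "global"),
                           features = available_features(table)) {
  target <- match.arg(target)
  selection_mode <- match.arg(selection_mode)
  fam <- resolve_family(family)
  if (!is.null(roi)) table <- table[table$roi_id == roi, , drop = FALSE]
  roi_label <- if (!is.null(roi)) roi else unique(table$roi_id)

  subj_all <- unique(table$subject_id)
  if ("complete" %in% names(table)) {
    dropped <- !table$complete
    if (any(dropped)) {
      message(sum(dropped), " incomplete row(s) excluded from modeling")
    }
    table <- table[!dropped, , drop = FALSE]
  }
  subjects <- unique(table$subject_id)
  if (length(subjects) < length(subj_all)) {
    warning("subject(s) ", paste(setdiff(subj_all, subjects), collapse = ", "),
            " have only flagged rows and are excluded", call. = FALSE)
  }
  if (length(subjects) < 3) {
    stop("nested LOSO CV needs at least 3 subjects with usable rows",
         call. = FALSE)
  }

  global_sel <- NULL
  if (selection_mode == "global") {
    global_sel <- select_top_k(f_test_scores(table, target, features), k)
  }

  preds <- vector("list", length(subjects))
  logs <- vector("list", length(subjects))
  for (fold in seq_along(subjects)) {
    test_subj <- subjects[fold]
    train <- table[table$subject_id != test_subj, , drop = FALSE]
    test <- table[table$subject_id == test_subj, , drop = FALSE]

    sel <- global_sel %||%
      select_top_k(f_test_scores(train, target, features), k)

    # standardization from outer-training statistics only
    mu_x <- vapply(train[sel], mean, numeric(1))
    sd_x <- vapply(train[sel], stats::sd, numeric(1))
    sd_x[sd_x == 0] <- 1
    mu_y <- mean(train[[target]])
    sd_y <- stats::sd(train[[target]])
    if (sd_y == 0) sd_y <- 1
    std <- function(df) {
      sweep(sweep(as.matrix(df[sel]), 2, mu_x), 2, sd_x, "/")
    }
    Xtr <- std(train)
    ytr <- (train[[target]] - mu_y) / sd_y

    chosen <- fam$grid[1, , drop = FALSE]
    if (nrow(fam$grid) > 1) {
      inner_subj <- unique(train$subject_id)
      grid_rmse <- rep(0, nrow(fam$grid))
      for (vs in inner_subj) {
        it <- train$subject_id != vs
        if (!is.null(fam$cv_grid)) {
          P <- fam$cv_grid(Xtr[it, , drop = FALSE], ytr[it],
                           Xtr[!it, , drop = FALSE], fam$grid)
          grid_rmse <- grid_rmse + colSums((P - ytr[!it])^2)
        } else {
          for (g in seq_len(nrow(fam$grid))) {
            m <- fam$fit(Xtr[it, , drop = FALSE], ytr[it],
                         as.list(fam$grid[g, ]))
            e <- fam$predict(m, Xtr[!it, , drop = FALSE]) - ytr[!it]
            grid_rmse[g] <- grid_rmse[g] + sum(e^2)
          }
        }
      }
      chosen <- fam$grid[which.min(grid_rmse), , drop = FALSE]
    }

    model <- fam$fit(Xtr, ytr, as.list(chosen))
    pred_z <- fam$predict(model, std(test))
    gold <- test[[target]]
    preds[[fold]] <- tibble::tibble(
      subject_id = test$subject_id,
      series_index = test$series_index,
      roi_id = test$roi_id,
      gold = gold,
      pred = pred_z * sd_y + mu_y,
      gold_z = (gold - mu_y) / sd_y,
      pred_z = pred_z
    )
    logs[[fold]] <- dplyr::bind_cols(
      tibble::tibble(fold = fold, test_subject = test_subj,
                     selected = paste(sel, collapse = ",")),
      chosen
    )
  }

  predictions <- dplyr::bind_rows(preds)
  rmse_z <- sqrt(mean((predictions$pred_z - predictions$gold_z)^2))
  ct <- stats::cor.test(predictions$pred, predictions$gold)
  structure(
    list(predictions = predictions,
         fold_log = dplyr::bind_rows(logs),
         target = target, family = fam$name, roi = roi_label,
         selection_mode = selection_mode, k = k,
         rmse_z = rmse_z, r = unname(ct$estimate), r_p = ct$p.value,
         n = nrow(predictions), n_folds = length(subjects)),
    class = "tm_cv"
  )
}

resolve_family <- function(family) {
  fams <- regressor_families()
  if (is.character(family)) {
    if (!family %in% names(fams)) {
      stop("unknown regressor family '", family, "'; available: ",
           paste(names(fams), collapse = ", "), call. = FALSE)
    }
    fam <- fams[[family]]
    fam$name <- family
    return(fam)
  }
  stopifnot(is.list(family), all(c("grid", "fit", "predict") %in% names(family)))
  family$name <- family$name %||% "custom"
  family
}

#' @export
print.tm_cv <- function(x, ...) {
  cat(sprintf(
    "Nested LOSO CV: %s ~ thermal features (ROI %s), family %s\n",
    x$target, paste(x$roi, collapse = "/"), x$family))
  cat(sprintf("  pooled n = %d over %d folds; RMSE_z = %.3f; r = %.3f (p = %.3g)\n",
              x$n, x$n_folds, x$rmse_z, x$r, x$r_p))
  invisible(x)
}

#' Run the full model-family x ROI x target result grid
#'
#' Replicates the study's result tables on a feature table: every regressor
#' family is cross-validated per ROI and per target, producing one row per
#' (family, ROI, target) with the pooled out-of-fold RMSE_z and correlation.
#' With the default five families, three ROIs and two targets this is a
#' 30-row grid.
#'
#' @inheritParams nested_loso_cv
#' @param targets Targets to estimate.
#' @param rois ROI ids (default all in `table`).
#' @param families Family names (default all five).
#' @param seed Optional seed fixed before the run so stochastic families
#'   (bagging bootstrap, GP restarts) are reproducible.
#' @return A tibble with columns `target`, `roi_id`, `family`, `rmse_z`,
#'   `r`, `r_p`, `n` and a `cv` list column of `tm_cv` objects, carrying
#'   class `tm_cv_grid`.
#' @export
run_all <- function(table, targets = c("arv", "mdf"),
                    rois = sort(unique(table$roi_id)),
                    families = names(regressor_families()),
                    k = 3, selection_mode = c("fold", "global"),
                    seed = NULL) {
  selection_mode <- match.arg(selection_mode)
  lapply(families, resolve_family)  # validate names before any compute
  if (!is.null(seed)) set.seed(seed)
  combos <- tidyr::expand_grid(target = targets, roi_id = rois,
                               family = families)
  rows <- purrr::pmap(combos, function(target, roi_id, family) {
    cv <- nested_loso_cv(table, target = target, family = family,
                         roi = roi_id, k = k,
                         selection_mode = selection_mode)
    tibble::tibble(target = target, roi_id = roi_id, family = family,
                   rmse_z = cv$rmse_z, r = cv$r, r_p = cv$r_p, n = cv$n,
                   cv = list(cv))
  })
  out <- dplyr::bind_rows(rows)
  class(out) <- c("tm_cv_grid", class(out))
  out
}

#' Best model per target from a result grid
#'
#' Picks, for each target, the (family, ROI) with the largest pooled
#' out-of-fold correlation, breaking ties by the lower RMSE_z.
#'
#' @param grid A result grid from [run_all()].
#' @return A tibble with one row per target (same columns as the grid).
#' @export
best_models <- function(grid) {
  grid |>
    dplyr::group_by(.data$target) |>
    dplyr::arrange(dplyr::desc(.data$r), .data$rmse_z, .by_group = TRUE) |>
    dplyr::slice(1) |>
    dplyr::ungroup()
}

`%||%` <- function(a, b) if (is.null(a)) b else a
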