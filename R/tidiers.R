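#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a cross-validation result
#'
#' @param x A `tm_cv` from [nested_loso_cv()].
#' @param ... Unused.
#' @return The per-row out-of-fold predictions as a tibble.
#' @export
tidy.tm_cv <- function(x, ...) x$predictions

#' One-row summary of a cross-validation result
#'
#' @inheritParams tidy.tm_cv
#' @export
glance.tm_cv <- function(x, ...) {
  tibble::tibble(target = x$target, family = x$family,
                 roi = paste(x$roi, collapse = "/"),
                 selection_mode = x$selection_mode, k = x$k,
                 rmse_z = x$rmse_z, r = x$r, r_p = x$r_p,
                 n = x$n, n_folds = x$n_folds)
}

#' Tidy an agreement report
#'
#' @param x A `tm_agreement` from [evaluate_agreement()].
#' @param ... Unused.
#' @return One row per pair: gold, predicted, difference and mean.
#' @export
tidy.tm_agreement <- function(x, ...) {
  tibble::tibble(gold = x$gold, predicted = x$predicted,
                 difference = x$predicted - x$gold,
                 mean_pair = (x$predicted + x$gold) / 2)
}

#' One-row summary of an agreement report
#'
#' @inheritParams tidy.tm_agreement
#' @export
glance.tm_agreement <- function(x, ...) {
  tibble::tibble(r = x$r, r_p = x$r_p, rmse_z = x$rmse_z, bias = x$bias,
                 loa_low = x$loa_low, loa_high = x$loa_high,
                 t_stat = x$t_stat, df = x$df, t_p = x$t_p,
                 slope = x$slope, intercept = x$intercept, n = x$n)
}
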