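#' Agreement battery between gold-standard and predicted values
#'
#' The pooled out-of-fold evaluation used on the best model per target:
#' Pearson correlation with two-sided p-value; RMSE on z-scored values
#' (both series standardized by the gold standard's mean and SD, so the
#' error is in gold-SD units); Bland-Altman bias (mean of predicted minus
#' gold) with 1.96-SD limits of agreement; a paired t-test on the
#' differences; and the calibration line from ordinary least squares of
#' gold on predicted (slope near 1 and intercept near 0 indicate an
#' unbiased estimator).
#'
#' @param gold Numeric gold-standard values (e.g. EMG-measured ARV).
#' @param predicted Numeric predictions of the same quantity, same length.
#' @return An object of class `tm_agreement`: a list of the report fields
#'   (`r`, `r_p`, `rmse_z`, `bias`, `loa_low`, `loa_high`, `t_stat`, `df`,
#'   `t_p`, `slope`, `intercept`, `n`) plus the pairs. The Bland-Altman
#'   sign convention is predicted - gold.
#' @export
#' @examples
#' evaluate_agreement(1:10, 1:10)$r
evaluate_agreement <- function(gold, predicted) {
  stopifnot(length(gold) == length(predicted), length(gold) >= 3,
            all(is.finite(gold)), all(is.finite(predicted)))
  n <- length(gold)
  diffs <- predicted - gold
  sd_g <- stats::sd(gold)
  if (sd_g == 0 || stats::sd(predicted) == 0) {
    warning("zero-variance input: correlation undefined", call. = FALSE)
    r <- NA_real_; r_p <- NA_real_
  } else {
    ct <- stats::cor.test(predicted, gold)
    r <- unname(ct$estimate); r_p <- ct$p.value
  }
  rmse_z <- if (sd_g > 0) sqrt(mean(diffs^2)) / sd_g else NA_real_
  bias <- mean(diffs)
  sd_d <- stats::sd(diffs)
  se_d <- sd_d / sqrt(n)
  t_stat <- if (se_d > 0) bias / se_d else 0
  ols <- stats::lm.fit(cbind(1, predicted), gold)$coefficients
  structure(
    list(r = r, r_p = r_p, rmse_z = rmse_z,
         bias = bias, loa_low = bias - 1.96 * sd_d,
         loa_high = bias + 1.96 * sd_d,
         t_stat = t_stat, df = n - 1,
         t_p = 2 * stats::pt(-abs(t_stat), n - 1),
         slope = unname(ols[2]), intercept = unname(ols[1]), n = n,
         gold = gold, predicted = predicted,
         sign_convention = "predicted - gold"),
    class = "tm_agreement"
  )
}

#' Fraction of differences inside the limits of agreement
#'
#' For Gaussian differences this approaches 0.95 by construction of the
#' 1.96-SD limits.
#'
#' @param report A `tm_agreement` from [evaluate_agreement()].
#' @return Fraction in `[0, 1]`.
#' @export
bland_altman_coverage <- function(report) {
  stopifnot(inherits(report, "tm_agreement"))
  d <- report$predicted - report$gold
  mean(d >= report$loa_low & d <= report$loa_high)
}

#' @export
print.tm_agreement <- function(x, ...) {
  cat(sprintf("Agreement over n = %d pairs (%s):\n", x$n, x$sign_convention))
  cat(sprintf("  r = %.3f (p = %.3g); RMSE_z = %.3f\n", x$r, x$r_p, x$rmse_z))
  cat(sprintf("  bias = %.4g, LoA [%.4g, %.4g]\n",
              x$bias, x$loa_low, x$loa_high))
  cat(sprintf("  paired t = %.3f (df = %d, p = %.3g)\n", x$t_stat, x$df, x$t_p))
  cat(sprintf("  calibration gold ~ predicted: slope %.3f, intercept %.4g\n",
              x$slope, x$intercept))
  invisible(x)
}
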