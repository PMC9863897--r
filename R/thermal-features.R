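#' Extract the post-exercise thermal analysis window
#'
#' Slices the skin-temperature record of one region of interest down to the
#' window the features are computed on: by convention the 10 s immediately
#' after the end of the exercise series (100 samples at the 10 Hz thermal
#' frame rate), starting at the exercise-end marker. The immediately
#' post-exercise window avoids motion artefacts while the subject is still
#' squatting.
#'
#' @param mean_trace Numeric ROI-mean temperature trace, degrees C.
#' @param exercise_end_index 1-based sample index of the end of the exercise.
#' @param fs Thermal sampling rate in Hz (default 10).
#' @param length_s Window length in seconds (default 10).
#' @param patch_frames Optional per-frame pixel patches for the same record:
#'   a 3-D array `[H, W, n_frames]` aligned with `mean_trace`.
#' @param context Optional label (e.g. "subject S01 series 2 ROI 3") used in
#'   error messages.
#'
#' @return A list with `values` (the window samples), `patches` (the matching
#'   frames, or `NULL`) and `fs`.
#' @export
extract_window <- function(mean_trace, exercise_end_index, fs = 10,
                           length_s = 10, patch_frames = NULL,
                           context = NULL) {
  n_win <- as.integer(floor(length_s * fs))
  last <- exercise_end_index + n_win - 1L
  if (exercise_end_index < 1 || last > length(mean_trace)) {
    where <- if (is.null(context)) "" else paste0(" for ", context)
    stop("thermal record", where, " has only ",
         max(0L, length(mean_trace) - exercise_end_index + 1L),
         " samples after the exercise-end marker; ", n_win, " needed",
         call. = FALSE)
  }
  idx <- exercise_end_index:last
  patches <- NULL
  if (!is.null(patch_frames)) {
    stopifnot(length(dim(patch_frames)) == 3)
    patches <- patch_frames[, , idx, drop = FALSE]
  }
  list(values = mean_trace[idx], patches = patches, fs = fs)
}

tm_mean <- function(w) mean(w)
tm_std <- function(w) stats::sd(w)  # 1/(N-1) normalization

# non-excess standardized moments: 1/N central moment over STD^k,
# with STD the (N-1)-normalized standard deviation
tm_kurtosis <- function(w) {
  s <- stats::sd(w)
  if (s == 0) return(NA_real_)
  mean((w - mean(w))^4) / s^4
}

tm_skewness <- function(w) {
  s <- stats::sd(w)
  if (s == 0) return(NA_real_)
  mean((w - mean(w))^3) / s^3
}

# empirical 90th percentile, linear interpolation between order statistics
tm_p90 <- function(w) unname(stats::quantile(w, 0.9, type = 7))

#' Mean power spectral density of a thermal window
#'
#' Mean over the positive-frequency bins (DC excluded, so the feature
#' reflects temperature oscillations rather than the absolute level) of the
#' one-sided periodogram. A single periodogram is used rather than Welch
#' averaging because a 100-sample window leaves no room for segmenting.
#'
#' @param w Numeric window samples.
#' @param fs Sampling rate in Hz.
#' @return Mean PSD over retained bins (power density units).
#' @export
tm_mean_psd <- function(w, fs = 10) {
  stopifnot(length(w) >= 8)
  if (all(w == 0)) return(0)
  psd <- periodogram_psd(w, fs)
  mean(psd$power[-1])
}

#' Sample entropy of a time series
#'
#' `SampEn(m, r) = -ln(A / B)` where `B` counts pairs of length-`m` template
#' vectors (delay `tau`) matching within tolerance `r` under the Chebyshev
#' (maximum) metric, `A` the corresponding count at length `m + 1`;
#' self-matches are excluded. Lower values indicate a more regular signal.
#' The tolerance is tied to the window's own standard deviation
#' (`r = r_frac * SD`), making the feature amplitude-invariant.
#'
#' @param w Numeric series.
#' @param m Template length (default 2).
#' @param r_frac Tolerance as a fraction of the series SD (default 0.2).
#' @param tau Sub-sampling delay between template elements (default 1).
#' @return Sample entropy in nats, or `NA` (flagged undefined) when the
#'   series is constant or no template pair matches at length `m + 1`.
#' @export
#' @examples
#' sample_entropy(rep(c(0, 1), 50))  # perfectly regular: 0
sample_entropy <- function(w, m = 2, r_frac = 0.2, tau = 1) {
  n <- length(w)
  stopifnot(n > m * tau + 1)
  s <- stats::sd(w)
  if (!is.finite(s) || s == 0) return(NA_real_)
  r <- r_frac * s
  n_templ <- n - m * tau
  # Chebyshev distances between length-(m+1) prefixes give both counts:
  # a pair matches at length m iff its first m coordinates are within r;
  # template i is (w[i], w[i + tau], ..., w[i + (m-1) tau])
  xm <- sapply(seq_len(m), function(k) w[seq_len(n_templ) + (k - 1) * tau])
  d_m <- cheb_dist(xm)
  diag(d_m) <- Inf  # exclude self-matches
  ext <- w[seq_len(n_templ) + m * tau]
  d_m1 <- pmax(d_m, abs(outer(ext, ext, "-")))
  b_count <- sum(d_m <= r)
  a_count <- sum(d_m1 <= r)
  if (b_count == 0 || a_count == 0) return(NA_real_)
  -log(a_count / b_count)
}

# pairwise Chebyshev (max-coordinate) distance matrix of row vectors
cheb_dist <- function(x) {
  d <- abs(outer(x[, 1], x[, 1], "-"))
  for (j in seq_len(ncol(x))[-1]) {
    d <- pmax(d, abs(outer(x[, j], x[, j], "-")))
  }
  d
}

#' Mean spatial temperature gradient of a patch sequence
#'
#' Per frame, central-difference gradients over interior pixels give a
#' gradient-magnitude field `sqrt((dT/dx)^2 + (dT/dy)^2)`; the per-frame
#' scalar is its mean, and the feature averages the per-frame scalars over
#' the window. Units: degrees C per pixel.
#'
#' @param patches 3-D array `[H, W, n_frames]`, `H, W >= 3`.
#' @return Mean gradient magnitude, or `NA` if `patches` is `NULL`.
#' @export
spatial_gradient <- function(patches) {
  if (is.null(patches)) return(NA_real_)
  dm <- dim(patches)
  stopifnot(length(dm) == 3, dm[1] >= 3, dm[2] >= 3)
  per_frame <- vapply(seq_len(dm[3]), function(k) {
    fr <- patches[, , k]
    gx <- (fr[2:(dm[1] - 1), 3:dm[2]] - fr[2:(dm[1] - 1), 1:(dm[2] - 2)]) / 2
    gy <- (fr[3:dm[1], 2:(dm[2] - 1)] - fr[1:(dm[1] - 2), 2:(dm[2] - 1)]) / 2
    mean(sqrt(gx^2 + gy^2))
  }, numeric(1))
  mean(per_frame)
}

#' Early-minus-late temperature difference (Delta)
#'
#' Mean of the first 2 s of the window minus the mean of its last 2 s: a
#' simple descriptor of the post-exercise temperature trend (positive when
#' the skin is cooling across the window).
#'
#' @inheritParams tm_mean_psd
#' @param span_s Sub-window length in seconds (default 2).
#' @return Temperature difference in degrees C.
#' @export
tm_delta <- function(w, fs = 10, span_s = 2) {
  k <- as.integer(round(span_s * fs))
  if (length(w) < 2 * k) {
    stop("window of ", length(w), " samples too short for a ", span_s,
         " s head/tail difference at ", fs, " Hz", call. = FALSE)
  }
  mean(w[seq_len(k)]) - mean(w[(length(w) - k + 1):length(w)])
}

#' All nine thermal features of one window
#'
#' Computes the full feature vector used as regression input: mean
#' temperature, SD, mean PSD, kurtosis, skewness, 90th percentile, sample
#' entropy, spatial gradient and the early-minus-late Delta. Features that
#' are undefined on the window (constant signal, no entropy matches, missing
#' patches) come back as `NA` and the row is marked incomplete.
#'
#' @param window A window list from [extract_window()], or a numeric vector
#'   (then `patches` and `fs` may be given directly).
#' @param patches Optional 3-D patch array when `window` is a bare vector.
#' @param fs Sampling rate when `window` is a bare vector.
#' @return A one-row tibble with the nine feature columns and a logical
#'   `complete` flag.
#' @export
extract_features <- function(window, patches = NULL, fs = 10) {
  if (is.list(window)) {
    patches <- window$patches
    fs <- window$fs
    window <- window$values
  }
  out <- tibble::tibble(
    mean_temp = tm_mean(window),
    std = tm_std(window),
    mean_psd = tm_mean_psd(window, fs),
    kurt = tm_kurtosis(window),
    skew = tm_skewness(window),
    p90 = tm_p90(window),
    sampen = sample_entropy(window),
    grad = spatial_gradient(patches),
    delta = tm_delta(window, fs)
  )
  out$complete <- !anyNA(out[thermal_feature_names()])
  out
}

#' Names of the nine thermal features, in declaration order
#'
#' The fixed order is also the tie-break order used by top-k feature
#' selection.
#' @return Character vector of length 9.
#' @export
thermal_feature_names <- function() {
  c("mean_temp", "std", "mean_psd", "kurt", "skew", "p90",
    "sampen", "grad", "delta")
}

#' Thermal feature table for a whole cohort
#'
#' Extracts the post-exercise window of every (subject, series, ROI) record
#' and computes the nine features, returning the pooled table that feature
#' selection and regression operate on.
#'
#' @param cohort A cohort object or its recordings tibble.
#' @param length_s Post-exercise window length in seconds (default 10).
#' @return A tibble with `subject_id`, `series_index`, `roi_id`, the nine
#'   feature columns and `complete`.
#' @export
thermal_feature_table <- function(cohort, length_s = 10) {
  rec <- cohort_recordings(cohort)
  res <- purrr::pmap_dfr(
    list(rec$subject_id, rec$series_index, rec$thermal_rois,
         rec$exercise_end_index, rec$thermal_fs),
    function(sid, sidx, rois, end_idx, fs) {
      purrr::pmap_dfr(
        list(rois$roi_id, rois$mean_trace, rois$patch_frames),
        function(roi, trace, patches) {
          ctx <- sprintf("subject %s series %d ROI %d", sid, sidx, roi)
          win <- extract_window(trace, end_idx, fs = fs, length_s = length_s,
                                patch_frames = patches, context = ctx)
          dplyr::bind_cols(
            tibble::tibble(subject_id = sid, series_index = sidx,
                           roi_id = roi),
            extract_features(win)
          )
        }
      )
    }
  )
  # a feature column that is NA everywhere (e.g. grad without patches) is
  # structurally unavailable; only row-level undefined values flag rows
  avail <- thermal_feature_names()[vapply(thermal_feature_names(), function(f) {
    any(is.finite(res[[f]]))
  }, logical(1))]
  res$complete <- stats::complete.cases(res[avail])
  n_bad <- sum(!res$complete)
  if (n_bad > 0) {
    message(n_bad, " feature row(s) have undefined entries and are flagged incomplete")
  }
  res
}

#' Pooled feature-plus-target table
#'
#' Joins the thermal feature table with the per-series EMG targets (ARV,
#' MDF); one row per (subject, series, ROI). This is the unit that feature
#' selection and leave-one-subject-out cross-validation consume.
#'
#' @inheritParams thermal_feature_table
#' @return A tibble with identifiers, the nine features, `complete`, `arv`
#'   and `mdf`.
#' @export
feature_table <- function(cohort, length_s = 10) {
  feats <- thermal_feature_table(cohort, length_s = length_s)
  targets <- emg_targets(cohort)
  dplyr::left_join(feats, targets[c("subject_id", "series_index", "arv", "mdf")],
                   by = c("subject_id", "series_index"))
}
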