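#' Specify a synthetic squat-protocol cohort
#'
#' Describes the statistical world the synthetic generator draws from: a
#' cohort of subjects each performing a fixed number of squat series to
#' exhaustion, with surface-EMG recorded at `emg_fs` and three thermal
#' regions of interest at `thermal_fs`. The `coupling` parameter controls
#' what fraction of the informative thermal-feature variance is explained by
#' the series' true ARV/MDF (0 = pure noise, 1 = deterministic link), which
#' is what parameter-recovery and null-calibration studies vary.
#'
#' @param n_subjects Number of subjects (default 10).
#' @param n_series Squat series per subject (default 5).
#' @param emg_fs EMG sampling rate, Hz (default 250).
#' @param thermal_fs Thermal frame rate, Hz (default 10; must give at least
#'   100 samples in a 10 s window).
#' @param series_duration_s Length-2 numeric: first- and last-series mean
#'   durations in seconds (default `c(60, 30)`; durations shrink across
#'   series as the subject tires, with small jitter).
#' @param rest_window_s Seconds of post-exercise thermal recording kept per
#'   series (default 15; must be at least 10).
#' @param coupling Fraction in `[0, 1]` of informative-feature variance
#'   explained by the true EMG metrics (default 0.8).
#' @param noise_sd Within-window AR(1) temperature noise SD in degrees C
#'   (default 0.1, of the order of real frame-to-frame skin-temperature
#'   fluctuation; the camera NETD is ~0.03).
#' @param fatigue_slope Fractional per-series decrease of the EMG band
#'   center frequency (default 0.05, giving ~20% spectral compression over
#'   five series).
#' @param arv_growth Fractional per-series EMG amplitude growth (default
#'   0.15, mimicking progressive recruitment during fatigue).
#' @param f0_hz Initial EMG band center frequency, Hz (default 80).
#' @param band_sd_hz Spectral half-width (Gaussian SD) of the EMG band, Hz
#'   (default 15).
#' @param patch_dim Side of the square pixel patch carrying the spatial
#'   gradient feature (default 8).
#' @param with_patches Generate per-frame pixel patches? (default TRUE).
#' @param seed RNG seed; identical specs with identical seeds produce
#'   bit-identical cohorts.
#'
#' @return An object of class `tm_cohort_spec` (a named list).
#' @export
#' @examples
#' spec <- cohort_spec(n_subjects = 3, seed = 1)
#' spec$coupling
cohort_spec <- function(n_subjects = 10, n_series = 5, emg_fs = 250,
                        thermal_fs = 10, series_duration_s = c(60, 30),
                        rest_window_s = 15, coupling = 0.8, noise_sd = 0.1,
                        fatigue_slope = 0.05, arv_growth = 0.15,
                        f0_hz = 80, band_sd_hz = 15, patch_dim = 8,
                        with_patches = TRUE, seed = 1) {
  spec <- list(
    n_subjects = as.integer(n_subjects), n_series = as.integer(n_series),
    emg_fs = emg_fs, thermal_fs = thermal_fs,
    series_duration_s = series_duration_s, rest_window_s = rest_window_s,
    coupling = coupling, noise_sd = noise_sd, fatigue_slope = fatigue_slope,
    arv_growth = arv_growth, f0_hz = f0_hz, band_sd_hz = band_sd_hz,
    patch_dim = as.integer(patch_dim), with_patches = isTRUE(with_patches),
    seed = as.integer(seed)
  )
  validate_cohort_spec(spec)
  structure(spec, class = "tm_cohort_spec")
}

validate_cohort_spec <- function(spec) {
  if (spec$n_subjects < 2) {
    stop("cohort needs at least 2 subjects", call. = FALSE)
  }
  if (spec$n_series < 1) stop("n_series must be positive", call. = FALSE)
  if (spec$coupling < 0 || spec$coupling > 1) {
    stop("coupling must lie in [0, 1]", call. = FALSE)
  }
  if (spec$thermal_fs * 10 < 100) {
    stop("thermal_fs must give at least 100 samples in a 10 s window",
         call. = FALSE)
  }
  if (spec$rest_window_s < 10) {
    stop("rest_window_s must be at least 10 s (the feature window)",
         call. = FALSE)
  }
  if (spec$noise_sd < 0) stop("noise_sd must be non-negative", call. = FALSE)
  if (length(spec$series_duration_s) != 2 ||
      any(spec$series_duration_s < 10)) {
    stop("series_duration_s must give two durations of at least 10 s",
         call. = FALSE)
  }
  if (spec$fatigue_slope < 0 || spec$fatigue_slope * (spec$n_series - 1) >= 0.9) {
    stop("fatigue_slope would drive the EMG band center to (near) zero",
         call. = FALSE)
  }
  if (spec$patch_dim < 3) stop("patch_dim must be at least 3", call. = FALSE)
  invisible(spec)
}

#' Generate a synthetic EMG + thermal cohort
#'
#' Draws a cohort with the coupled structure the analysis assumes. Each
#' series' EMG is band-limited Gaussian noise (Gaussian-shaped spectrum
#' centered at a per-series frequency that declines with `fatigue_slope`, so
#' the true MDF falls within subject) under a per-repetition burst envelope
#' whose amplitude grows with `arv_growth` (so the true ARV rises). Each
#' thermal ROI record keeps 5 s of late-exercise context plus
#' `rest_window_s` of post-exercise signal; within the post-exercise window
#' the level (hence MeanTemp/90th-percentile), the linear trend (hence
#' Delta) and the planted patch gradient mix a `sqrt(coupling)`-weighted
#' map of the standardized true ARV/MDF with `sqrt(1 - coupling)`-weighted
#' subject/series noise, on top of AR(1) temperature noise (coefficient 0.9
#' at 10 Hz, stationary SD `noise_sd`).
#'
#' The latent `true_arv`/`true_mdf` in the ground truth are the generator's
#' own computation on the realized trace (mean rectified value; spectral
#' median of the raw periodogram), so checking them against the package's
#' Welch/Butterworth measurement path is a genuine two-route comparison.
#'
#' @param spec A [cohort_spec()].
#' @return An object of class `tm_cohort`: a list with
#'   * `recordings` — tibble, one row per (subject, series), with list
#'     columns `emg` (numeric trace) and `thermal_rois` (a tibble of 3 ROI
#'     records with `mean_trace` and `patch_frames` list columns), plus
#'     `exercise_end_index` into the thermal trace;
#'   * `ground_truth` — tibble of latent per-series `true_arv`, `true_mdf`;
#'   * `planted` — tibble flagging which features were generated as
#'     informative for which target;
#'   * `spec` — the input specification.
#' @export
#' @examples
#' cohort <- generate_cohort(cohort_spec(n_subjects = 2, seed = 42,
#'                                       with_patches = FALSE))
#' nrow(cohort$recordings)
generate_cohort <- function(spec) {
  validate_cohort_spec(spec)
  set.seed(spec$seed)
  ns <- spec$n_subjects
  nk <- spec$n_series
  subj_ids <- sprintf("S%02d", seq_len(ns))

  # --- EMG pass: realized traces and their latent metrics -------------------
  emg_rows <- vector("list", ns * nk)
  row <- 0L
  subj_amp <- exp(stats::rnorm(ns, 0, 0.15)) * 100   # ~100 uV baseline
  subj_f0 <- spec$f0_hz + stats::rnorm(ns, 0, 4)
  for (i in seq_len(ns)) {
    for (s in seq_len(nk)) {
      row <- row + 1L
      dur <- series_duration(spec, s) + stats::runif(1, -3, 3)
      dur <- max(10, dur)
      fc <- subj_f0[i] * (1 - spec$fatigue_slope * (s - 1))
      amp <- subj_amp[i] * (1 + spec$arv_growth * (s - 1))
      trace <- synth_emg_series(dur, spec$emg_fs, fc, spec$band_sd_hz, amp)
      psd <- periodogram_psd(trace, spec$emg_fs)
      emg_rows[[row]] <- tibble::tibble(
        subject_id = subj_ids[i], series_index = s,
        duration_s = dur, emg = list(trace),
        true_arv = mean(abs(trace)),
        true_mdf = median_frequency(psd$freq, psd$power)
      )
    }
  }
  emg_tbl <- dplyr::bind_rows(emg_rows)

  # standardized latent metrics drive the thermal coupling
  z_arv <- as.numeric(scale(emg_tbl$true_arv))
  z_mdf <- as.numeric(scale(emg_tbl$true_mdf))

  # --- thermal pass ---------------------------------------------------------
  root_c <- sqrt(spec$coupling)
  root_n <- sqrt(1 - spec$coupling)
  g_level <- 0.4    # degC of ARV-driven level variation
  g_trend <- 0.15   # degC of MDF-driven end-to-end trend
  g_grad <- 0.05    # degC/pixel baseline planted gradient
  base_subj <- 31 + root_n * 0.5 * stats::rnorm(ns)
  roi_offset <- c(0, -0.15, 0.1)
  fs_t <- spec$thermal_fs
  n_pre <- as.integer(round(5 * fs_t))
  n_post <- as.integer(round(spec$rest_window_s * fs_t))
  phi <- 0.9

  thermal_col <- vector("list", nrow(emg_tbl))
  for (k in seq_len(nrow(emg_tbl))) {
    i <- match(emg_tbl$subject_id[k], subj_ids)
    rois <- vector("list", 3)
    for (roi in 1:3) {
      level <- base_subj[i] + roi_offset[roi] +
        g_level * (root_c * z_arv[k] + root_n * stats::rnorm(1))
      trend <- g_trend * (root_c * z_mdf[k] + root_n * stats::rnorm(1))
      t_post <- (seq_len(n_post) - 1) / fs_t
      post <- level + trend * (t_post - 5) / 5
      pre <- seq(level - 0.3, level, length.out = n_pre)
      trace <- c(pre, post) + ar1_noise(n_pre + n_post, phi, spec$noise_sd)
      patches <- NULL
      if (spec$with_patches) {
        slope <- g_grad * pmax(0.02, 1 + 0.4 * (root_c * z_arv[k] +
                                                  root_n * stats::rnorm(1)))
        patches <- planted_patches(trace, spec$patch_dim, slope)
      }
      rois[[roi]] <- tibble::tibble(
        roi_id = roi, mean_trace = list(trace), patch_frames = list(patches)
      )
    }
    thermal_col[[k]] <- dplyr::bind_rows(rois)
  }

  recordings <- tibble::tibble(
    subject_id = emg_tbl$subject_id,
    series_index = emg_tbl$series_index,
    duration_s = emg_tbl$duration_s,
    emg = emg_tbl$emg,
    emg_fs = spec$emg_fs,
    thermal_fs = fs_t,
    exercise_end_index = n_pre + 1L,
    thermal_rois = thermal_col
  )
  ground_truth <- emg_tbl[c("subject_id", "series_index",
                            "true_arv", "true_mdf")]
  planted <- tibble::tibble(
    feature = thermal_feature_names(),
    informative_arv = thermal_feature_names() %in% c("mean_temp", "p90", "grad"),
    informative_mdf = thermal_feature_names() %in% "delta"
  )
  if (!spec$with_patches) {
    planted$informative_arv[planted$feature == "grad"] <- FALSE
  }
  structure(
    list(recordings = recordings, ground_truth = ground_truth,
         planted = planted, spec = spec),
    class = "tm_cohort"
  )
}

#' @export
print.tm_cohort <- function(x, ...) {
  cat("Synthetic EMG/thermal cohort:", x$spec$n_subjects, "subjects x",
      x$spec$n_series, "series (coupling =", x$spec$coupling,
      ", seed =", x$spec$seed, ")\n")
  invisible(x)
}

series_duration <- function(spec, s) {
  d <- spec$series_duration_s
  if (spec$n_series == 1) return(d[1])
  d[1] - (d[1] - d[2]) * (s - 1) / (spec$n_series - 1)
}

# band-limited Gaussian noise via Gaussian spectral shaping, under a
# per-repetition (3 s squat cycle) burst envelope
synth_emg_series <- function(duration_s, fs, center_hz, band_sd_hz, amplitude) {
  n <- as.integer(round(duration_s * fs))
  white <- stats::rnorm(n)
  freq <- (seq_len(n) - 1) / n * fs
  freq <- pmin(freq, fs - freq)  # fold to [0, fs/2]
  h <- exp(-(freq - center_hz)^2 / (2 * band_sd_hz^2))
  x <- Re(stats::fft(stats::fft(white) * h, inverse = TRUE)) / n
  x <- x / stats::sd(x)
  t <- (seq_len(n) - 1) / fs
  envelope <- 0.25 + 0.75 * sin(pi * (t %% 3) / 3)^2
  amplitude * envelope * x
}

ar1_noise <- function(n, phi, sd_stationary) {
  if (sd_stationary == 0) return(numeric(n))
  innov <- stats::rnorm(n, 0, sd_stationary * sqrt(1 - phi^2))
  as.numeric(stats::filter(innov, phi, method = "recursive",
                           init = stats::rnorm(1, 0, sd_stationary)))
}

# frames share the trace's mean level; a left-right linear ramp of the given
# slope (degC/pixel) is planted, plus small pixel noise
planted_patches <- function(trace, dim_px, slope) {
  n <- length(trace)
  ramp <- matrix(rep((seq_len(dim_px) - (dim_px + 1) / 2) * slope,
                     each = dim_px), dim_px, dim_px)
  px_noise <- stats::rnorm(dim_px * dim_px * n, 0, 0.005)
  arr <- array(px_noise, c(dim_px, dim_px, n))
  arr + outer(ramp, rep(1, n)) +
    aperm(array(rep(trace, each = 1), c(n, dim_px, dim_px)), c(2, 3, 1))
}
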