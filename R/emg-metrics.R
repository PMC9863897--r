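#' Condition a raw surface-EMG trace
#'
#' High-pass filters the trace with a zero-lag Butterworth filter (default
#' 20 Hz cut-off, 3rd order, forward-backward so no phase distortion) and
#' rectifies it. The filtered-but-unrectified trace is kept alongside the
#' rectified one: amplitude metrics (ARV) use the rectified path while
#' spectral metrics (MDF) must use the unrectified path, since rectification
#' distorts the power spectrum.
#'
#' @param x Numeric raw EMG samples.
#' @param fs Sampling frequency in Hz (default 250).
#' @param cutoff_hz High-pass cut-off in Hz (default 20, the conventional
#'   corner frequency for dynamic contractions such as squats).
#' @param order Butterworth order (default 3).
#'
#' @return A list with elements `filtered` (zero-phase high-passed trace),
#'   `rectified` (its absolute value) and `fs`.
#' @export
#' @examples
#' x <- sin(2 * pi * 50 * seq(0, 2, by = 1 / 250))
#' pp <- emg_preprocess(x)
#' mean(pp$rectified)
emg_preprocess <- function(x, fs = 250, cutoff_hz = 20, order = 3) {
  stopifnot(is.numeric(x), all(is.finite(x)))
  coef <- butter_filter(order, cutoff_hz, fs, "high")
  filtered <- filtfilt_zero_phase(coef, x)
  list(filtered = filtered, rectified = abs(filtered), fs = fs)
}

#' Average rectified value (ARV)
#'
#' The arithmetic mean of the rectified EMG over the full motor task,
#' `ARV = (1/N) sum |EMG[n]|` — the amplitude descriptor of muscle
#' activation. The number of samples N is whatever the series lasted, so
#' fatiguing series of different durations are each averaged over their own
#' length.
#'
#' @param rectified Numeric non-negative rectified EMG samples.
#' @return The ARV, in the amplitude units of the input.
#' @export
compute_arv <- function(rectified) {
  if (length(rectified) == 0) stop("cannot compute ARV of an empty trace", call. = FALSE)
  stopifnot(all(is.finite(rectified)))
  mean(abs(rectified))
}

#' Median frequency (MDF) of the EMG power spectrum
#'
#' The frequency splitting the Welch power spectrum into two equal-power
#' halves; MDF shifts downwards as the muscle fatigues. The spectrum is
#' estimated by Welch's method with the FFT length set to the next power of
#' two at or above the trace length; the returned value is the first
#' frequency bin at which the cumulative power reaches half the total
#' (lowest-index rule, since exact equality is generically unattainable on a
#' discrete spectrum).
#'
#' @param x Numeric high-pass-filtered (not rectified) EMG trace.
#' @param fs Sampling frequency in Hz.
#' @param min_duration_s Minimum trace duration for spectral estimation
#'   (default 2 s).
#' @return MDF in Hz.
#' @export
compute_mdf <- function(x, fs = 250, min_duration_s = 2) {
  stopifnot(is.numeric(x), all(is.finite(x)))
  if (length(x) < min_duration_s * fs) {
    stop("trace too short for spectral estimation: ", length(x),
         " samples < ", min_duration_s, " s x ", fs, " Hz", call. = FALSE)
  }
  psd <- welch_psd(x, fs)
  median_frequency(psd$freq, psd$power)
}

# first bin at which cumulative power reaches half the total
median_frequency <- function(freq, power) {
  total <- sum(power)
  if (total <= 0) stop("zero total power: median frequency undefined", call. = FALSE)
  idx <- which(cumsum(power) >= total / 2)[1]
  freq[idx]
}

#' Per-series EMG targets for a cohort
#'
#' Computes the regression targets — one (ARV, MDF) pair per squat series —
#' for every recording in a cohort: the raw EMG is conditioned with
#' [emg_preprocess()], ARV is taken from the rectified trace and MDF from the
#' filtered unrectified trace. A default 10-subject, 5-series cohort yields
#' 50 rows.
#'
#' @param cohort A cohort object from [generate_cohort()] or [read_cohort()],
#'   or its `recordings` tibble.
#' @inheritParams emg_preprocess
#' @return A tibble with columns `subject_id`, `series_index`, `arv`, `mdf`,
#'   `n_samples`.
#' @export
emg_targets <- function(cohort, cutoff_hz = 20, order = 3) {
  rec <- cohort_recordings(cohort)
  purrr::pmap_dfr(
    list(rec$subject_id, rec$series_index, rec$emg, rec$emg_fs),
    function(sid, sidx, emg, fs) {
      pp <- emg_preprocess(emg, fs = fs, cutoff_hz = cutoff_hz, order = order)
      tibble::tibble(
        subject_id = sid,
        series_index = sidx,
        arv = compute_arv(pp$rectified),
        mdf = compute_mdf(pp$filtered, fs = fs),
        n_samples = length(emg)
      )
    }
  )
}

cohort_recordings <- function(cohort) {
  if (inherits(cohort, "tm_cohort")) return(cohort$recordings)
  if (is.data.frame(cohort)) return(cohort)
  stop("expected a tm_cohort or a recordings data frame", call. = FALSE)
}
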