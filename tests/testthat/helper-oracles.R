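# Independent brute-force oracles. These deliberately re-derive quantities
# with the most naive possible code paths and must stay independent of the
# package implementations they check.

# naive O(N^2) double-loop sample entropy (Chebyshev distance, self-matches
# excluded), m/r/tau as in the implementation
brute_sampen <- function(w, m = 2, r_frac = 0.2, tau = 1) {
  n <- length(w)
  s <- stats::sd(w)
  if (s == 0) return(NA_real_)
  r <- r_frac * s
  n_templ <- n - m * tau
  a <- 0L
  b <- 0L
  for (i in seq_len(n_templ)) {
    for (j in seq_len(n_templ)) {
      if (j == i) next
      ti <- w[seq(i, by = tau, length.out = m)]
      tj <- w[seq(j, by = tau, length.out = m)]
      if (max(abs(ti - tj)) <= r) {
        b <- b + 1L
        ti1 <- w[seq(i, by = tau, length.out = m + 1)]
        tj1 <- w[seq(j, by = tau, length.out = m + 1)]
        if (max(abs(ti1 - tj1)) <= r) a <- a + 1L
      }
    }
  }
  if (b == 0L || a == 0L) return(NA_real_)
  -log(a / b)
}

# direct-DFT one-sided periodogram (no fft), for small windows
brute_periodogram <- function(x, fs) {
  n <- length(x)
  k <- 0:(n %/% 2)
  power <- vapply(k, function(kk) {
    re <- sum(x * cos(-2 * pi * kk * (0:(n - 1)) / n))
    im <- sum(x * sin(-2 * pi * kk * (0:(n - 1)) / n))
    (re^2 + im^2) / (fs * n)
  }, numeric(1))
  dbl <- rep(2, length(k))
  dbl[1] <- 1
  if (n %% 2 == 0) dbl[length(k)] <- 1
  list(freq = k * fs / n, power = power * dbl)
}

# brute-force cumulative-sum median frequency over a given spectrum
brute_mdf_from_spectrum <- function(freq, power) {
  half <- sum(power) / 2
  acc <- 0
  for (i in seq_along(power)) {
    acc <- acc + power[i]
    if (acc >= half) return(freq[i])
  }
  NA_real_
}

# per-pixel central-difference gradient magnitude, bluntly looped
brute_gradient <- function(patches) {
  dm <- dim(patches)
  per_frame <- numeric(dm[3])
  for (k in seq_len(dm[3])) {
    acc <- c()
    for (i in 2:(dm[1] - 1)) {
      for (j in 2:(dm[2] - 1)) {
        gx <- (patches[i, j + 1, k] - patches[i, j - 1, k]) / 2
        gy <- (patches[i + 1, j, k] - patches[i - 1, j, k]) / 2
        acc <- c(acc, sqrt(gx^2 + gy^2))
      }
    }
    per_frame[k] <- mean(acc)
  }
  mean(per_frame)
}

# a small pooled feature table built directly (no signal generation), for
# cross-validation mechanics tests: n_subjects x n_series rows of ROI 1
make_toy_table <- function(n_subjects = 6, n_series = 5, seed = 1,
                           signal = 1) {
  set.seed(seed)
  n <- n_subjects * n_series
  tab <- tibble::tibble(
    subject_id = rep(sprintf("S%02d", seq_len(n_subjects)), each = n_series),
    series_index = rep(seq_len(n_series), n_subjects),
    roi_id = 1L,
    mean_temp = stats::rnorm(n),
    std = stats::rnorm(n),
    mean_psd = stats::rnorm(n),
    kurt = stats::rnorm(n),
    skew = stats::rnorm(n),
    p90 = stats::rnorm(n),
    sampen = stats::rnorm(n),
    grad = stats::rnorm(n),
    delta = stats::rnorm(n),
    complete = TRUE
  )
  tab$arv <- signal * (tab$mean_temp + 0.5 * tab$p90) + stats::rnorm(n, 0, 0.3)
  tab$mdf <- signal * tab$delta + stats::rnorm(n, 0, 0.3)
  tab
}

# quadprog solve of the ridge-stabilized SVR dual (independent of the
# package's coordinate-descent solver)
qp_svr_beta <- function(K, y, C, eps, ridge = 1e-7) {
  n <- length(y)
  D <- K + diag(ridge, n)
  Dmat <- rbind(cbind(D, -D), cbind(-D, D)) + diag(ridge, 2 * n)
  dvec <- c(y - eps, -y - eps)
  A <- cbind(diag(2 * n), -diag(2 * n))
  bvec <- c(rep(0, 2 * n), rep(-C, 2 * n))
  sol <- quadprog::solve.QP(Dmat, dvec, A, bvec)$solution
  sol[1:n] - sol[(n + 1):(2 * n)]
}
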