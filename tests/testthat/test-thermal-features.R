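test_that("window extraction slices exactly the post-exercise samples", {
  trace <- seq(20, 40, length.out = 300)
  w <- extract_window(trace, 101, fs = 10, length_s = 10)
  expect_length(w$values, 100)
  expect_identical(w$values, trace[101:200])
  # shorter window on a tail
  w2 <- extract_window(trace[201:300], 1, fs = 10, length_s = 2)
  expect_identical(w2$values, trace[201:220])
  expect_error(extract_window(trace, 300, context = "subject S01 series 2 ROI 3"),
               "S01 series 2 ROI 3")
  expect_error(extract_window(trace, 250), "100 needed")
})

test_that("moment features follow their printed normalizations", {
  const <- rep(30, 100)
  expect_identical(tm_mean(const), 30)
  expect_identical(tm_std(const), 0)
  expect_identical(tm_kurtosis(const), NA_real_)
  expect_identical(tm_skewness(const), NA_real_)
  # p90 against a sorting-based oracle with linear interpolation
  w <- sample(1:100)
  ord <- sort(w)
  h <- 0.9 * (100 - 1) + 1
  p90_oracle <- ord[floor(h)] + (h - floor(h)) * (ord[floor(h) + 1] - ord[floor(h)])
  expect_equal(tm_p90(w), p90_oracle)
  # STD uses 1/(N-1); kurtosis/skewness use 1/N central moments over STD powers
  set.seed(5)
  g <- rnorm(50)
  expect_equal(tm_std(g), sqrt(sum((g - mean(g))^2) / 49))
  expect_equal(tm_kurtosis(g), mean((g - mean(g))^4) / tm_std(g)^4)
  expect_equal(tm_skewness(g), mean((g - mean(g))^3) / tm_std(g)^3)
  # large-sample Gaussian: non-excess kurtosis -> 3, skewness -> 0
  set.seed(6)
  big <- rnorm(2e5)
  expect_equal(tm_kurtosis(big), 3, tolerance = 0.05)
  expect_equal(tm_skewness(big), 0, tolerance = 0.05)
})

test_that("mean PSD excludes DC and scales quadratically", {
  expect_identical(tm_mean_psd(rep(0, 100)), 0)
  # sinusoid: matches the direct-DFT periodogram oracle
  w <- 2 * sin(2 * pi * 2 * (0:99) / 10) + 30
  ora <- brute_periodogram(w, 10)
  expect_equal(tm_mean_psd(w, 10), mean(ora$power[-1]), tolerance = 1e-10)
  set.seed(8)
  r <- rnorm(100)
  expect_equal(tm_mean_psd(3 * r, 10), 9 * tm_mean_psd(r, 10))
})

test_that("sample entropy: regular signals, oracle equality, noise ordering", {
  # perfectly regular alternating series: every m-match extends
  expect_identical(sample_entropy(rep(c(0, 1), 60)), 0)
  expect_identical(sample_entropy(rep(1, 50)), NA_real_)
  # exact equality with the naive O(N^2) double-loop oracle
  set.seed(9)
  for (n in c(30, 75, 120, 200)) {
    w <- as.numeric(arima.sim(list(ar = 0.6), n))
    expect_identical(sample_entropy(w), brute_sampen(w))
  }
  # tau > 1 also matches the oracle
  w <- rnorm(90)
  expect_identical(sample_entropy(w, m = 2, tau = 2),
                   brute_sampen(w, m = 2, tau = 2))
  # i.i.d. noise is less regular than AR(1) of the same SD
  set.seed(10)
  se_iid <- se_ar <- numeric(30)
  for (k in 1:30) {
    se_iid[k] <- sample_entropy(rnorm(100))
    ar <- as.numeric(arima.sim(list(ar = 0.9), 100))
    se_ar[k] <- sample_entropy(ar / sd(ar))
  }
  expect_gt(mean(se_iid), mean(se_ar))
})

test_that("spatial gradient: plane ramps and brute-force equality", {
  flat <- array(25, c(8, 8, 10))
  expect_identical(spatial_gradient(flat), 0)
  # planar ramp a*x has gradient magnitude a on interior pixels
  a <- 0.37
  ramp <- array(rep(a * rep(1:8, each = 8), 10), c(8, 8, 10))
  ramp <- aperm(ramp, c(2, 1, 3))  # vary along columns (x)
  expect_equal(spatial_gradient(ramp), a)
  set.seed(12)
  rnd <- array(rnorm(8 * 8 * 4), c(8, 8, 4))
  expect_equal(spatial_gradient(rnd), brute_gradient(rnd), tolerance = 1e-12)
  expect_identical(spatial_gradient(NULL), NA_real_)
})

test_that("delta contrasts the first and last two seconds", {
  expect_identical(tm_delta(rep(30, 100)), 0)
  # linear ramp of slope s degC/s over 10 s: sub-window centers 8 s apart
  s <- 0.23
  w <- 30 + s * (0:99) / 10
  expect_equal(tm_delta(w), -8 * s)
  set.seed(13)
  r <- rnorm(100)
  expect_equal(tm_delta(r), mean(r[1:20]) - mean(r[81:100]))
  expect_error(tm_delta(rnorm(30)), "too short")
})

test_that("the full feature vector is deterministic and flags degenerate windows", {
  set.seed(14)
  w <- 30 + cumsum(rnorm(100, 0, 0.05))
  p <- array(rnorm(8 * 8 * 100, 30), c(8, 8, 100))
  f1 <- extract_features(w, patches = p, fs = 10)
  f2 <- extract_features(w, patches = p, fs = 10)
  expect_identical(f1, f2)
  expect_true(f1$complete)
  expect_identical(ncol(f1), 10L)  # nine features + the flag
  fc <- extract_features(rep(30, 100), fs = 10)
  expect_identical(fc$mean_temp, 30)
  expect_identical(fc$std, 0)
  expect_true(is.na(fc$kurt) && is.na(fc$skew) && is.na(fc$sampen))
  expect_false(fc$complete)
})

test_that("cohort feature table has 9 features x 3 ROIs per series", {
  cohort <- generate_cohort(cohort_spec(n_subjects = 3, seed = 15))
  tab <- thermal_feature_table(cohort)
  expect_identical(nrow(tab), 3L * 5L * 3L)
  expect_true(all(thermal_feature_names() %in% names(tab)))
  expect_identical(sort(unique(tab$roi_id)), 1:3)
  full <- feature_table(cohort)
  expect_true(all(c("arv", "mdf") %in% names(full)))
  expect_identical(nrow(full), nrow(tab))
})

test_that("feature translation and scale behavior", {
  set.seed(16)
  shift_inv <- c("std", "mean_psd", "kurt", "skew", "sampen", "grad", "delta")
  shift_cov <- c("mean_temp", "p90")
  scale_lin <- c("mean_temp", "std", "p90", "delta", "grad")
  scale_inv <- c("kurt", "skew", "sampen")
  for (rep in 1:25) {
    w <- 30 + as.numeric(arima.sim(list(ar = 0.8), 100)) * 0.2
    p <- array(rnorm(8 * 8 * 100, 30, 0.1), c(8, 8, 100))
    cshift <- runif(1, -5, 5)
    cscale <- runif(1, 0.2, 4)
    f0 <- extract_features(w, p, fs = 10)
    fs_ <- extract_features(w + cshift, p + cshift, fs = 10)
    fm <- extract_features(w * cscale, p * cscale, fs = 10)
    for (nm in shift_inv) expect_equal(fs_[[nm]], f0[[nm]], tolerance = 1e-9)
    for (nm in shift_cov) expect_equal(fs_[[nm]], f0[[nm]] + cshift, tolerance = 1e-9)
    for (nm in scale_lin) expect_equal(fm[[nm]], f0[[nm]] * cscale, tolerance = 1e-9)
    for (nm in scale_inv) expect_equal(fm[[nm]], f0[[nm]], tolerance = 1e-9)
    expect_equal(fm$mean_psd, f0$mean_psd * cscale^2, tolerance = 1e-9)
  }
})
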