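# a counting family wrapping linear regression, used to probe the CV
# mechanics (fit calls, training rows seen) without stochastic noise
counting_family <- function(recorder, grid = tibble::tibble(lambda = c(0, 0.1))) {
  list(
    name = "probe",
    grid = grid,
    fit = function(X, y, params) {
      recorder$fits <- recorder$fits + 1L
      recorder$train_rows <- c(recorder$train_rows, nrow(X))
      recorder$snapshots[[length(recorder$snapshots) + 1L]] <-
        list(X = X, y = y)
      lam <- params$lambda
      XtX <- crossprod(cbind(1, X)) + diag(lam, ncol(X) + 1)
      list(coef = solve(XtX, crossprod(cbind(1, X), y)))
    },
    predict = function(model, X) drop(cbind(1, X) %*% model$coef)
  )
}

test_that("a perfect predictor in the feature set yields r > 0.99", {
  tab <- make_toy_table(n_subjects = 6, seed = 30)
  tab$p90 <- tab$arv
  cv <- nested_loso_cv(tab, "arv", "linear")
  expect_gt(cv$r, 0.99)
  expect_lt(cv$rmse_z, 0.2)
})

test_that("fold structure: one outer fold per subject, inner LOSO over the rest", {
  tab <- make_toy_table(n_subjects = 10, seed = 31)
  rec <- new.env()
  rec$fits <- 0L; rec$train_rows <- integer(0); rec$snapshots <- list()
  cv <- nested_loso_cv(tab, "arv", counting_family(rec))
  expect_identical(cv$n_folds, 10L)
  expect_identical(nrow(cv$predictions), 50L)
  # every row predicted exactly once
  expect_identical(anyDuplicated(cv$predictions[c("subject_id", "series_index")]), 0L)
  # 10 outer x (9 inner folds x 2 grid points) + 10 refits
  expect_identical(rec$fits, 10L * 9L * 2L + 10L)
  # fold log records selection and the chosen grid point
  expect_identical(nrow(cv$fold_log), 10L)
  expect_true(all(c("selected", "lambda") %in% names(cv$fold_log)))
})

test_that("test-subject rows never touch training statistics (sentinel)", {
  tab <- make_toy_table(n_subjects = 6, seed = 32)
  run_probe <- function(t) {
    rec <- new.env()
    rec$fits <- 0L; rec$train_rows <- integer(0); rec$snapshots <- list()
    nested_loso_cv(t, "arv", counting_family(rec, tibble::tibble(lambda = 0)))
    rec$snapshots
  }
  base_snaps <- run_probe(tab)
  subjects <- unique(tab$subject_id)
  for (s in subjects[c(1, 4)]) {
    poisoned <- tab
    hit <- poisoned$subject_id == s
    poisoned[hit, thermal_feature_names()] <-
      poisoned[hit, thermal_feature_names()] + 1e6
    poisoned$arv[hit] <- poisoned$arv[hit] - 1e6
    snaps <- run_probe(poisoned)
    fold <- match(s, subjects)
    # the fold holding s out trains on identical (standardized) data
    expect_identical(snaps[[fold]], base_snaps[[fold]])
  }
})

test_that("permuted targets carry no signal through the CV", {
  tab <- make_toy_table(n_subjects = 8, seed = 33)
  set.seed(34)
  rs <- replicate(5, {
    shuf <- tab
    shuf$arv <- sample(shuf$arv)
    nested_loso_cv(shuf, "arv", "linear")$r
  })
  expect_lt(abs(mean(rs)), 0.35)
})

test_that("pooled metrics match recomputation from stored predictions", {
  tab <- make_toy_table(n_subjects = 6, seed = 35)
  cv <- nested_loso_cv(tab, "arv", "linear")
  p <- cv$predictions
  expect_equal(cv$rmse_z, sqrt(mean((p$pred_z - p$gold_z)^2)), tolerance = 1e-12)
  expect_equal(cv$r, cor(p$pred, p$gold), tolerance = 1e-12)
  expect_equal(cv$r_p, cor.test(p$pred, p$gold)$p.value, tolerance = 1e-12)
})

test_that("every family fits, predicts and is reproducible under a seed", {
  tab <- make_toy_table(n_subjects = 5, n_series = 4, seed = 36)
  for (fam in names(regressor_families())) {
    set.seed(37)
    cv1 <- nested_loso_cv(tab, "arv", fam)
    set.seed(37)
    cv2 <- nested_loso_cv(tab, "arv", fam)
    expect_identical(cv1$predictions, cv2$predictions)
    expect_true(is.finite(cv1$r))
    expect_gte(cv1$rmse_z, 0)
  }
})

test_that("run_all produces the 5-family x 3-ROI x 2-target grid", {
  tab <- dplyr::bind_rows(
    make_toy_table(n_subjects = 5, seed = 38),
    within(make_toy_table(n_subjects = 5, seed = 38), roi_id <- 2L),
    within(make_toy_table(n_subjects = 5, seed = 38), roi_id <- 3L)
  )
  fams <- c("linear", "ensemble")
  g <- run_all(tab, families = fams, seed = 39)
  expect_identical(nrow(g), 2L * 3L * length(fams))
  expect_identical(run_all(tab, families = fams, seed = 39)$r, g$r)
  b <- best_models(g)
  expect_identical(nrow(b), 2L)
  expect_identical(b$r[b$target == "arv"], max(g$r[g$target == "arv"]))
  expect_error(run_all(tab, families = "deep_net"), "unknown regressor family")
})

test_that("subjects with only flagged rows are excluded with a warning", {
  tab <- make_toy_table(n_subjects = 5, seed = 40)
  tab$complete[tab$subject_id == "S05"] <- FALSE
  expect_warning(cv <- nested_loso_cv(tab, "arv", "linear"), "S05")
  expect_identical(cv$n_folds, 4L)
  expect_error(
    suppressWarnings(nested_loso_cv(tab[tab$subject_id %in% c("S01", "S02", "S05"), ],
                                    "arv", "linear")),
    "at least 3 subjects"
  )
})

test_that("SVR coordinate descent agrees with the quadprog dual oracle", {
  skip_if_not_installed("quadprog")
  set.seed(41)
  n <- 35
  X <- matrix(rnorm(n * 3), n)
  y <- drop(X %*% c(0.8, -0.4, 0.2)) + rnorm(n, 0, 0.2)
  fams <- regressor_families()
  for (ls in c(NA, 1)) {
    K <- if (is.na(ls)) tcrossprod(X) + 1 else
      thermomyo:::rbf_kernel(X, X, ls) + 1
    for (C in c(0.5, 5)) {
      beta_cd <- thermomyo:::svr_dual_cd(K, y, C, 0.1)
      beta_qp <- qp_svr_beta(K, y, C, 0.1)
      expect_lt(max(abs(K %*% (beta_cd - beta_qp))), 0.05)
    }
  }
})

test_that("bagged trees reduce to the sample mean under huge min_leaf", {
  set.seed(42)
  X <- matrix(rnorm(40), 20, 2)
  y <- rnorm(20)
  boot <- matrix(rep(1:20, 5), 20)  # identity bootstrap, 5 trees
  trees <- thermomyo:::forest_fit(X, y, boot, min_leaf = 20L)
  expect_equal(as.numeric(thermomyo:::forest_predict(trees, X)),
               rep(mean(y), 20), tolerance = 1e-12)
  # a single split on a step function is found exactly
  ys <- ifelse(X[, 1] > 0, 2, -2)
  trees2 <- thermomyo:::forest_fit(X, ys, boot, min_leaf = 1L)
  expect_equal(as.numeric(thermomyo:::forest_predict(trees2, X)), ys,
               tolerance = 1e-12)
})

test_that("GP regression interpolates smooth functions and matches the ridge identity", {
  set.seed(43)
  X <- matrix(seq(-2, 2, length.out = 25), ncol = 1)
  y <- sin(1.5 * X[, 1])
  m <- thermomyo:::gp_fit(X, y, restarts = 1)
  expect_lt(max(abs(thermomyo:::gp_predict(m, X) - y)), 0.1)
  # with fixed hyperparameters the GP mean equals kernel ridge regression
  K <- m$sf^2 * thermomyo:::rbf_kernel(X, X, m$ls)
  ridge <- K %*% solve(K + diag(m$sn^2 + 1e-8, nrow(X)), y)
  expect_equal(thermomyo:::gp_predict(m, X), drop(ridge), tolerance = 1e-8)
})
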