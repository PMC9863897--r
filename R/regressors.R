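#' The five regressor families
#'
#' Returns the registry of model families evaluated by the nested
#' cross-validation: ordinary linear regression, epsilon-SVR with linear and
#' Gaussian (RBF) kernels, bagged regression trees ("ensemble"), and
#' Gaussian process regression with a squared-exponential kernel. Each entry
#' carries its hyperparameter grid (searched by the inner CV loop) and
#' `fit`/`predict` closures operating on standardized feature matrices.
#'
#' Hyperparameter grids are small and logged by the CV: SVR uses
#' `C in 10^(-1..2)`, `eps in {0.01, 0.1}` and, for the Gaussian kernel,
#' length scales `{0.3, 1, 3}` on standardized features; bagged trees use
#' `{50, 200}` trees with minimum leaf sizes `{1, 5}`; the GP optimizes its
#' kernel by marginal likelihood with `{1, 5}` random restarts.
#'
#' @return A named list of family definitions.
#' @export
regressor_families <- function() {
  list(
    linear = list(
      label = "LR",
      grid = tibble::tibble(.dummy = 1),
      fit = function(X, y, params) {
        list(coef = stats::lm.fit(cbind(1, X), y)$coefficients)
      },
      predict = function(model, X) {
        cf <- ifelse(is.na(model$coef), 0, model$coef)
        drop(cbind(1, X) %*% cf)
      }
    ),
    svr_linear = list(
      label = "SVR (Linear)",
      grid = tidyr::expand_grid(C = 10^(-1:2), eps = c(0.01, 0.1)),
      fit = function(X, y, params) {
        K <- tcrossprod(X) + 1
        beta <- svr_dual_cd(K, y, params$C, params$eps)
        list(X = X, beta = beta)
      },
      predict = function(model, X) {
        drop((tcrossprod(X, model$X) + 1) %*% model$beta)
      },
      cv_grid = function(Xtr, ytr, Xval, grid) {
        K <- tcrossprod(Xtr) + 1
        Kval <- tcrossprod(Xval, Xtr) + 1
        svr_grid_predict(K, Kval, ytr, grid)
      }
    ),
    svr_gaussian = list(
      label = "SVR (Gaussian)",
      grid = tidyr::expand_grid(length_scale = c(0.3, 1, 3),
                                C = 10^(-1:2), eps = c(0.01, 0.1)),
      fit = function(X, y, params) {
        K <- rbf_kernel(X, X, params$length_scale) + 1
        beta <- svr_dual_cd(K, y, params$C, params$eps)
        list(X = X, beta = beta, ls = params$length_scale)
      },
      predict = function(model, X) {
        drop((rbf_kernel(X, model$X, model$ls) + 1) %*% model$beta)
      },
      cv_grid = function(Xtr, ytr, Xval, grid) {
        out <- matrix(NA_real_, nrow(Xval), nrow(grid))
        for (ls in unique(grid$length_scale)) {
          sub <- which(grid$length_scale == ls)
          K <- rbf_kernel(Xtr, Xtr, ls) + 1
          Kval <- rbf_kernel(Xval, Xtr, ls) + 1
          out[, sub] <- svr_grid_predict(K, Kval, ytr, grid[sub, , drop = FALSE])
        }
        out
      }
    ),
    ensemble = list(
      label = "Ensemble",
      grid = tidyr::expand_grid(n_trees = c(50, 200), min_leaf = c(1, 5)),
      fit = function(X, y, params) {
        n <- nrow(X)
        boot <- matrix(sample.int(n, n * params$n_trees, replace = TRUE),
                       nrow = n)
        list(trees = forest_fit(X, y, boot, as.integer(params$min_leaf)))
      },
      predict = function(model, X) {
        as.numeric(forest_predict(model$trees, X))
      }
    ),
    gaussian_process = list(
      label = "Gaussian",
      grid = tibble::tibble(restarts = c(1, 5)),
      fit = function(X, y, params) gp_fit(X, y, restarts = params$restarts),
      predict = function(model, X) gp_predict(model, X),
      cv_grid = function(Xtr, ytr, Xval, grid) {
        models <- gp_fit_checkpoints(Xtr, ytr, grid$restarts)
        vapply(models, function(m) gp_predict(m, Xval), numeric(nrow(Xval)))
      }
    )
  )
}

# batched SVR solves over a (C, eps) grid sharing one Gram matrix; solutions
# are warm-started across ascending C within each eps for speed
svr_grid_predict <- function(K, Kval, y, grid) {
  out <- matrix(NA_real_, nrow(Kval), nrow(grid))
  for (eps in unique(grid$eps)) {
    rows <- which(grid$eps == eps)
    rows <- rows[order(grid$C[rows])]
    beta <- NULL
    for (g in rows) {
      beta <- svr_dual_cd(K, y, grid$C[g], eps, warm = beta)
      out[, g] <- Kval %*% beta
    }
  }
  out
}

rbf_kernel <- function(A, B, length_scale) {
  d2 <- outer(rowSums(A^2), rowSums(B^2), "+") - 2 * tcrossprod(A, B)
  exp(-pmax(d2, 0) / (2 * length_scale^2))
}

# Gaussian process regression, squared-exponential kernel plus noise.
# Hyperparameters (log length scale, log signal SD, log noise SD) maximize
# the marginal likelihood via L-BFGS-B; extra restarts draw random inits.
gp_fit <- function(X, y, restarts = 1) {
  gp_fit_checkpoints(X, y, restarts)[[1]]
}

# fit with max(checkpoints) restarts, returning one model per checkpoint:
# model k is the best fit among the first checkpoints[k] initializations
# (the first init is fixed, the rest random), so nested restart counts
# share their optimizations
gp_fit_checkpoints <- function(X, y, checkpoints) {
  n <- nrow(X)
  d2 <- as.matrix(stats::dist(X))^2
  nll <- function(theta) {
    ls <- exp(theta[1]); sf <- exp(theta[2]); sn <- exp(theta[3])
    K <- sf^2 * exp(-d2 / (2 * ls^2)) + diag(sn^2 + 1e-8, n)
    L <- tryCatch(chol(K), error = function(e) NULL)
    if (is.null(L)) return(1e10)
    alpha <- backsolve(L, forwardsolve(t(L), y))
    as.numeric(0.5 * sum(y * alpha) + sum(log(diag(L))) +
                 0.5 * n * log(2 * pi))
  }
  # analytic gradient in log-parameters: dNLL = 1/2 tr((Kinv - aa') dK)
  nll_grad <- function(theta) {
    ls <- exp(theta[1]); sf <- exp(theta[2]); sn <- exp(theta[3])
    Kse <- sf^2 * exp(-d2 / (2 * ls^2))
    K <- Kse + diag(sn^2 + 1e-8, n)
    L <- tryCatch(chol(K), error = function(e) NULL)
    if (is.null(L)) return(c(0, 0, 0))
    alpha <- backsolve(L, forwardsolve(t(L), y))
    W <- chol2inv(L) - tcrossprod(alpha)
    c(0.5 * sum(W * (Kse * d2 / ls^2)),
      sum(W * Kse),
      sum(diag(W)) * sn^2)
  }
  max_r <- max(checkpoints)
  inits <- list(c(0, 0, log(0.1)))
  if (max_r > 1) {
    for (k in seq_len(max_r - 1)) {
      inits[[k + 1]] <- c(stats::runif(1, log(0.2), log(3)),
                          stats::runif(1, log(0.3), log(2)),
                          stats::runif(1, log(0.02), log(1)))
    }
  }
  make_model <- function(theta) {
    ls <- exp(theta[1]); sf <- exp(theta[2]); sn <- exp(theta[3])
    K <- sf^2 * exp(-d2 / (2 * ls^2)) + diag(sn^2 + 1e-8, n)
    L <- chol(K)
    alpha <- backsolve(L, forwardsolve(t(L), y))
    list(X = X, alpha = alpha, ls = ls, sf = sf, sn = sn)
  }
  best_par <- inits[[1]]
  best_val <- Inf
  out <- vector("list", length(checkpoints))
  for (k in seq_len(max_r)) {
    fit <- tryCatch(
      stats::optim(inits[[k]], nll, nll_grad, method = "L-BFGS-B",
                   lower = rep(log(1e-3), 3), upper = rep(log(1e3), 3),
                   control = list(maxit = 100)),
      error = function(e) NULL
    )
    if (!is.null(fit) && fit$value < best_val) {
      best_val <- fit$value
      best_par <- fit$par
    }
    hit <- which(checkpoints == k)
    if (length(hit) > 0) {
      m <- make_model(best_par)
      for (h in hit) out[[h]] <- m
    }
  }
  out
}

gp_predict <- function(model, X) {
  Ks <- model$sf^2 * rbf_kernel(X, model$X, model$ls)
  drop(Ks %*% model$alpha)
}
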