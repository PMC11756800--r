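# Natural-gradient boosting of a bivariate-normal predictive distribution.
#
# Each sample carries parameters theta = (mu1, mu2, a, b, c) where the
# covariance is Sigma = L L' with L = [[exp(a), 0], [c, exp(b)]] (always
# SPD).  Boosting fits one regression tree per parameter per stage to the
# negative-log-likelihood natural gradient (Fisher-preconditioned), with a
# stage-level line search on the step scale.  The Fisher information is
# block-diagonal in (mu) and (a, b, c) and closed-form in this
# parametrization, so the natural gradient costs O(1) per sample.

#' Probabilistic regressor training conditions
#'
#' @param n_stages boosting stages (default 150).
#' @param learning_rate stage shrinkage (default 0.087).
#' @param max_depth regression-tree depth (default 3).
#' @param min_samples minimum training-set size accepted (default 50).
#' @param valid_fraction held-out fraction used to pick the best stage
#'   count by validation NLL (0 disables early stage selection).
#' @export
regressor_spec <- function(n_stages = 150L, learning_rate = 0.087,
                           max_depth = 3L, min_samples = 50L,
                           valid_fraction = 0) {
  structure(list(n_stages = as.integer(n_stages),
                 learning_rate = learning_rate,
                 max_depth = as.integer(max_depth),
                 min_samples = as.integer(min_samples),
                 valid_fraction = valid_fraction),
            class = "regressor_spec")
}

CLAMP_LOG_SD <- c(-12, 6)

# Per-sample NLL, score and natural gradient for theta matrix (n x 5).
ngb_nll <- function(theta, y) {
  e1 <- y[, 1] - theta[, 1]
  e2 <- y[, 2] - theta[, 2]
  s1 <- exp(theta[, 3]); s2 <- exp(theta[, 4]); cc <- theta[, 5]
  z1 <- e1 / s1
  z2 <- (e2 - cc * z1) / s2
  0.5 * (z1^2 + z2^2) + theta[, 3] + theta[, 4] + log(2 * pi)
}

ngb_natural_gradient <- function(theta, y) {
  e1 <- y[, 1] - theta[, 1]
  e2 <- y[, 2] - theta[, 2]
  s1 <- exp(theta[, 3]); s2 <- exp(theta[, 4]); cc <- theta[, 5]
  z1 <- e1 / s1
  z2 <- (e2 - cc * z1) / s2
  # scores (gradients of the per-sample NLL)
  # d/dmu = -Sigma^{-1} e = -L^{-T} z ; with L^{-T} = [[1/s1, -c/(s1 s2)],[0, 1/s2]]
  g_m1 <- -(z1 / s1 - cc * z2 / (s1 * s2))
  g_m2 <- -(z2 / s2)
  g_a <- 1 - z1^2 + (cc / s2) * z1 * z2
  g_b <- 1 - z2^2
  g_c <- -z1 * z2 / s2
  # natural gradient: mu block preconditioned by Sigma (=Fisher^{-1});
  # (a,c) block by the closed-form inverse Fisher; b decoupled (F_bb = 2).
  sig11 <- s1^2
  sig12 <- s1 * cc
  sig22 <- cc^2 + s2^2
  n_m1 <- sig11 * g_m1 + sig12 * g_m2
  n_m2 <- sig12 * g_m1 + sig22 * g_m2
  gam <- cc / s2
  n_a <- 0.5 * g_a + (gam * s2 / 2) * g_c
  n_c <- (gam * s2 / 2) * g_a + (s2^2 * (2 + gam^2) / 2) * g_c
  n_b <- g_b / 2
  cbind(n_m1, n_m2, n_a, n_b, n_c)
}

NGB_BINS <- 64L

# Per-feature quantile bin edges for the binned base trees.
ngb_make_bins <- function(x, n_bins = NGB_BINS) {
  lapply(seq_len(ncol(x)), function(f) {
    e <- unique(stats::quantile(x[, f],
                                probs = seq_len(n_bins - 1L) / n_bins,
                                names = FALSE, type = 7))
    as.numeric(e)
  })
}

#' Train the probabilistic boosting regressor
#'
#' @param features N x d numeric matrix (reduced features, or any feature
#'   space).
#' @param labels N x 2 matrix of target parameters.
#' @param spec a [regressor_spec()].
#' @param seed RNG seed (tree fitting is deterministic; the seed fixes any
#'   tie-breaking randomness).
#' @param verbose print stage progress every 25 stages.
#' @return an `ngb_regressor` object.
#' @export
train_regressor <- function(features, labels, spec = regressor_spec(),
                            seed = 1L, verbose = FALSE) {
  features <- as.matrix(features)
  labels <- as.matrix(labels)
  stopifnot(ncol(labels) == 2, nrow(features) == nrow(labels))
  if (nrow(features) < spec$min_samples) {
    stop("too few training samples (", nrow(features), " < ",
         spec$min_samples, ")")
  }
  if (any(apply(labels, 2, stats::sd) < 1e-12)) {
    stop("degenerate labels: zero variance")
  }
  colnames(features) <- paste0("f", seq_len(ncol(features)))
  n0 <- nrow(features)
  val_idx <- integer(0)
  if (spec$valid_fraction > 0 && n0 >= 100L) {
    nv <- max(10L, floor(spec$valid_fraction * n0))
    val_idx <- with_seed(derive_seed(seed, "ngb_val"),
                         sort(sample(n0, nv)))
  }
  fit_idx <- setdiff(seq_len(n0), val_idx)
  xv <- features[val_idx, , drop = FALSE]
  yv <- labels[val_idx, , drop = FALSE]
  features <- features[fit_idx, , drop = FALSE]
  labels <- labels[fit_idx, , drop = FALSE]
  n <- nrow(features)
  bins <- ngb_make_bins(features)
  xb <- cart_bin_cpp(features, bins)
  xbv <- cart_bin_cpp(xv, bins)
  # marginal MLE initialization (shared by all samples)
  mu0 <- colMeans(labels)
  S <- stats::cov(labels) * (n - 1) / n
  L <- t(chol(S + diag(1e-12, 2)))
  theta0 <- c(mu0[1], mu0[2], log(L[1, 1]), log(L[2, 2]), L[2, 1])
  theta <- matrix(theta0, n, 5, byrow = TRUE)
  theta_v <- matrix(rep(theta0, each = length(val_idx)), length(val_idx), 5)
  trees <- vector("list", spec$n_stages)
  scales <- numeric(spec$n_stages)
  rho_grid <- c(2, 1, 0.5, 0.25)
  best_val <- Inf
  best_m <- spec$n_stages
  with_seed(seed, {
    for (m in seq_len(spec$n_stages)) {
      ng <- ngb_natural_gradient(theta, labels)
      stage <- vector("list", 5L)
      pred <- matrix(0, n, 5)
      for (p in 1:5) {
        tr <- cart_fit_cpp(xb, ng[, p], spec$max_depth, NGB_BINS)
        stage[[p]] <- tr
        pred[, p] <- cart_predict_cpp(tr, xb)
      }
      # line search on the stage scale
      best_rho <- rho_grid[1]
      best_nll <- Inf
      for (rho in rho_grid) {
        th <- theta - spec$learning_rate * rho * pred
        th[, 3] <- clamp(th[, 3], CLAMP_LOG_SD[1], CLAMP_LOG_SD[2])
        th[, 4] <- clamp(th[, 4], CLAMP_LOG_SD[1], CLAMP_LOG_SD[2])
        nll <- sum(ngb_nll(th, labels))
        if (is.finite(nll) && nll < best_nll) {
          best_nll <- nll
          best_rho <- rho
        }
      }
      theta <- theta - spec$learning_rate * best_rho * pred
      theta[, 3] <- clamp(theta[, 3], CLAMP_LOG_SD[1], CLAMP_LOG_SD[2])
      theta[, 4] <- clamp(theta[, 4], CLAMP_LOG_SD[1], CLAMP_LOG_SD[2])
      trees[[m]] <- stage
      scales[m] <- spec$learning_rate * best_rho
      if (length(val_idx)) {
        for (p in 1:5) {
          theta_v[, p] <- theta_v[, p] -
            scales[m] * cart_predict_cpp(stage[[p]], xbv)
        }
        theta_v[, 3] <- clamp(theta_v[, 3], CLAMP_LOG_SD[1], CLAMP_LOG_SD[2])
        theta_v[, 4] <- clamp(theta_v[, 4], CLAMP_LOG_SD[1], CLAMP_LOG_SD[2])
        vnll <- mean(ngb_nll(theta_v, yv))
        if (is.finite(vnll) && vnll < best_val) {
          best_val <- vnll
          best_m <- m
        }
      }
      if (verbose && m %% 25L == 0L) {
        message(sprintf("stage %3d  mean NLL %.4f", m,
                        mean(ngb_nll(theta, labels))))
      }
    }
  })
  structure(list(theta0 = theta0, trees = trees, scales = scales,
                 spec = spec, d = ncol(features), bins = bins,
                 n_use = if (length(val_idx)) best_m else spec$n_stages,
                 feature_names = colnames(features)),
            class = "ngb_regressor")
}

# Predict the theta matrix for new features.
ngb_theta <- function(regressor, features) {
  features <- as.matrix(features)
  stopifnot(ncol(features) == regressor$d)
  xb <- cart_bin_cpp(features, regressor$bins)
  theta <- matrix(regressor$theta0, nrow(features), 5, byrow = TRUE)
  n_use <- if (is.null(regressor$n_use)) length(regressor$trees) else
    regressor$n_use
  for (m in seq_len(n_use)) {
    for (p in 1:5) {
      theta[, p] <- theta[, p] -
        regressor$scales[m] * cart_predict_cpp(regressor$trees[[m]][[p]], xb)
    }
  }
  theta[, 3] <- clamp(theta[, 3], CLAMP_LOG_SD[1], CLAMP_LOG_SD[2])
  theta[, 4] <- clamp(theta[, 4], CLAMP_LOG_SD[1], CLAMP_LOG_SD[2])
  theta
}

theta_to_posterior <- function(th) {
  s1 <- exp(th[3]); s2 <- exp(th[4]); cc <- th[5]
  L <- matrix(c(s1, cc, 0, s2), 2, 2)
  cov <- L %*% t(L)
  # guard: floor eigenvalues at 1e-10 (cannot trigger for finite theta, but
  # protects downstream log-densities against pathological inputs)
  ev <- eigen(cov, symmetric = TRUE)
  if (any(ev$values < 1e-10)) {
    warning("covariance repaired by eigenvalue flooring")
    cov <- ev$vectors %*% diag(pmax(ev$values, 1e-10)) %*% t(ev$vectors)
  }
  structure(list(mean = th[1:2], cov = cov), class = "sample_posterior")
}

#' Predict a per-sample posterior
#'
#' @param regressor an `ngb_regressor`.
#' @param feature one feature vector, or a matrix of features.
#' @return a `sample_posterior` (mean, 2x2 SPD covariance), or a list of
#'   them for matrix input.
#' @export
predict_sample_posterior <- function(regressor, feature) {
  stopifnot(inherits(regressor, "ngb_regressor"))
  if (is.null(dim(feature))) feature <- matrix(feature, 1)
  th <- ngb_theta(regressor, feature)
  out <- lapply(seq_len(nrow(th)), function(i) theta_to_posterior(th[i, ]))
  if (length(out) == 1L) out[[1]] else out
}
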