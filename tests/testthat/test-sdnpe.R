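# Probabilistic regressor and the lattice posterior machinery.

test_that("regressor guards: sample floor and degenerate labels", {
  x <- matrix(rnorm(40 * 2), 40, 2)
  y <- cbind(runif(40), runif(40))
  expect_error(train_regressor(x, y), "too few")
  y2 <- cbind(rep(0.7, 120), runif(120))
  expect_error(train_regressor(matrix(rnorm(240), 120, 2), y2),
               "degenerate")
})

test_that("regressor recovers labels from near-noiseless features", {
  set.seed(6)
  n <- 700
  lab <- cbind(runif(n, 0.6, 1), runif(n, 0.6, 1))
  x <- lab + matrix(rnorm(2 * n, 0, 1e-4), n, 2)
  reg <- train_regressor(x[1:600, ], lab[1:600, ], seed = 2L)
  th <- patternfit:::ngb_theta(reg, x[601:700, ])
  expect_lt(sqrt(mean((th[, 1:2] - lab[601:700, ])^2)), 0.01)
  # constant labels with tiny jitter
  labc <- cbind(0.8 + rnorm(n, 0, 1e-3), 0.7 + rnorm(n, 0, 1e-3))
  regc <- train_regressor(matrix(rnorm(2 * n), n, 2), labc[1:n, ], seed = 3L)
  thc <- patternfit:::ngb_theta(regc, matrix(rnorm(60), 30, 2))
  expect_true(all(abs(thc[, 1] - 0.8) < 0.01))
  expect_true(all(abs(thc[, 2] - 0.7) < 0.01))
  # determinism
  reg2 <- train_regressor(x[1:600, ], lab[1:600, ],
                          spec = regressor_spec(n_stages = 25L), seed = 9L)
  reg3 <- train_regressor(x[1:600, ], lab[1:600, ],
                          spec = regressor_spec(n_stages = 25L), seed = 9L)
  expect_identical(patternfit:::ngb_theta(reg2, x[601:610, ]),
                   patternfit:::ngb_theta(reg3, x[601:610, ]))
})

test_that("sample posterior densities behave on the lattice", {
  lat <- parameter_lattice()
  sp <- structure(list(mean = c(0.82, 0.77), cov = diag(0.0008, 2)),
                  class = "sample_posterior")
  d <- density_on_lattice(sp, lat)
  expect_equal(sum(d) * 0.005^2, 1, tolerance = 0.02)
  peak <- which(d == max(d), arr.ind = TRUE)
  expect_equal(lat$x[peak[1]], 0.82, tolerance = 0.005)
  expect_equal(lat$y[peak[2]], 0.77, tolerance = 0.005)
  # half-cell origin shift changes the evaluated max density < 5%
  lat2 <- parameter_lattice(origin = c(0.55, 0.55) + 0.0025)
  d2 <- density_on_lattice(sp, lat2)
  expect_lt(abs(max(d2) - max(d)) / max(d), 0.05)
})

test_that("prior estimation: identical posteriors, mixtures, uniformity", {
  lat <- parameter_lattice()
  # regressor trained on features ~ labels gives per-sample posteriors
  # centred on the labels; identical features -> identical posteriors
  set.seed(8)
  n <- 400
  lab <- cbind(runif(n, 0.6, 1), runif(n, 0.6, 1))
  x <- lab + matrix(rnorm(2 * n, 0, 1e-3), n, 2)
  reg <- train_regressor(x, lab, spec = regressor_spec(n_stages = 60L),
                         seed = 1L)
  one <- x[5, , drop = FALSE]
  pr1 <- estimate_prior(reg, one[rep(1, 7), ], lat)
  d1 <- density_on_lattice(predict_sample_posterior(reg, x[5, ]), lat)
  expect_lt(max(abs(pr1$density - normalize_density(d1, lat))), 1e-9)
  # two disjoint narrow normals average to a half-weight mixture
  pa <- structure(list(mean = c(0.7, 0.7), cov = diag(1e-4, 2)),
                  class = "sample_posterior")
  pb <- structure(list(mean = c(0.9, 0.9), cov = diag(1e-4, 2)),
                  class = "sample_posterior")
  mix <- normalize_density((density_on_lattice(pa, lat) +
                              density_on_lattice(pb, lat)) / 2, lat)
  da <- density_on_lattice(pa, lat)
  ia <- which(da == max(da), arr.ind = TRUE)
  expect_equal(mix[ia] / max(da), 0.5, tolerance = 0.01)
  # uniform training labels -> prior close to uniform (TV < 0.15).
  # Moderate feature noise so the per-sample posteriors are wide enough
  # to smooth over the Monte-Carlo point set (the Monte-Carlo average of
  # near-delta posteriors is a spike train, not a density estimate).
  set.seed(9)
  nn <- 1000
  lab2 <- cbind(runif(nn, 0.6, 1), runif(nn, 0.6, 1))
  x2 <- lab2 + matrix(rnorm(2 * nn, 0, 0.05), nn, 2)
  reg2 <- train_regressor(x2, lab2,
                          spec = regressor_spec(n_stages = 100L), seed = 1L)
  prior <- estimate_prior(reg2, x2, lat)
  boxmask <- outer(lat$x >= 0.6 & lat$x <= 1.0,
                   lat$y >= 0.6 & lat$y <= 1.0, "&")
  unif <- boxmask / (sum(boxmask) * 0.005^2)
  tv <- 0.5 * sum(abs(prior$density - unif)) * 0.005^2
  expect_lt(tv, 0.15)
})

test_that("posterior integration matches the Gaussian-product closed form", {
  lat <- parameter_lattice()
  unif <- matrix(1 / 0.25, 100, 100)
  set.seed(12)
  for (N in c(1, 2, 5, 10)) {
    sps <- lapply(seq_len(N), function(i) {
      A <- matrix(rnorm(4, 0, 0.01), 2, 2)
      structure(list(mean = c(0.8, 0.8) + rnorm(2, 0, 0.02),
                     cov = diag(0.002, 2) + crossprod(A)),
                class = "sample_posterior")
    })
    post <- integrate_posteriors(sps, unif, lat)
    prec <- Reduce(`+`, lapply(sps, function(s) solve(s$cov)))
    mu <- solve(prec, Reduce(`+`, lapply(sps, function(s)
      solve(s$cov, s$mean))))
    closed <- structure(list(mean = as.numeric(mu), cov = solve(prec)),
                        class = "sample_posterior")
    dc <- normalize_density(density_on_lattice(closed, lat), lat)
    expect_lt(lattice_kl(dc, post$density, lat), 1e-3)
    # normalization invariant
    expect_equal(sum(post$density) * 0.005^2, 1, tolerance = 1e-9)
  }
  # N = 1 identity and permutation invariance on random inputs
  sp <- structure(list(mean = c(0.75, 0.9), cov = diag(0.001, 2)),
                  class = "sample_posterior")
  p1 <- integrate_posteriors(list(sp), unif, lat)
  expect_equal(p1$density,
               normalize_density(density_on_lattice(sp, lat), lat),
               tolerance = 1e-9)
  sps <- lapply(1:5, function(i)
    structure(list(mean = c(0.8, 0.8) + rnorm(2, 0, 0.02),
                   cov = diag(0.003, 2)), class = "sample_posterior"))
  pa <- integrate_posteriors(sps, unif, lat)
  pb <- integrate_posteriors(sps[c(3, 1, 5, 2, 4)], unif, lat)
  expect_equal(pa$density, pb$density, tolerance = 1e-12)
})

test_that("generalization error arithmetic and monotonicity", {
  lat <- parameter_lattice(origin = c(0, 0), cell = 0.005, n = 100L)
  up <- structure(list(density = matrix(4, 100, 100), lattice = lat),
                  class = "integrated_posterior")
  ge <- generalization_error(list(up, up), rbind(c(0.1, 0.1), c(0.3, 0.4)))
  expect_equal(ge$value, -log(4), tolerance = 1e-12)
  expect_error(generalization_error(list(up), rbind(c(2, 2))), "outside")
  # sharper posterior centred on the truth lowers the error
  mk <- function(s) {
    sp <- structure(list(mean = c(0.25, 0.25), cov = diag(s, 2)),
                    class = "sample_posterior")
    structure(list(density = normalize_density(
      density_on_lattice(sp, lat), lat), lattice = lat),
      class = "integrated_posterior")
  }
  e_sharp <- generalization_error(list(mk(1e-4)), rbind(c(0.25, 0.25)))
  e_flat <- generalization_error(list(mk(1e-2)), rbind(c(0.25, 0.25)))
  expect_lt(e_sharp$value, e_flat$value)
})

test_that("conjugate linear-regression oracle identities", {
  pc <- diag(0.25, 2)
  p0 <- analytic_linreg_posterior(matrix(0, 0, 2), numeric(0), 0.1,
                                  c(0, 0), pc)
  expect_equal(p0$mean, c(0, 0))
  expect_equal(p0$cov, pc)
  # near-interpolation: one observation y = a * x at x = 1, sigma -> 0
  p1 <- analytic_linreg_posterior(matrix(1, 1, 1), 0.37, 1e-4,
                                  prior_mean = 0,
                                  prior_cov = matrix(1, 1, 1))
  expect_equal(p1$mean, 0.37, tolerance = 1e-3)
  # doubling the observations halves the covariance under a flat prior
  X <- matrix(rnorm(12), 6, 2)
  y <- rnorm(6)
  a1 <- analytic_linreg_posterior(X, y, 0.2)
  a2 <- analytic_linreg_posterior(rbind(X, X), c(y, y), 0.2)
  expect_equal(a2$cov, a1$cov / 2, tolerance = 1e-6)
  expect_error(analytic_linreg_posterior(cbind(1:3, 1:3), rnorm(3), 0.1),
               "singular")
})

test_that("HPD membership and KL basics", {
  lat <- parameter_lattice()
  sp <- structure(list(mean = c(0.8, 0.8), cov = diag(0.001, 2)),
                  class = "sample_posterior")
  post <- structure(list(density = normalize_density(
    density_on_lattice(sp, lat), lat), lattice = lat),
    class = "integrated_posterior")
  expect_true(hpd_contains(post, c(0.8, 0.8), 0.95))
  expect_false(hpd_contains(post, c(0.6, 1.0), 0.95))
  d <- post$density
  expect_equal(lattice_kl(d, d, lat), 0, tolerance = 1e-12)
  expect_gt(lattice_kl(d, matrix(1 / 0.25, 100, 100), lat), 0)
})

test_that("redundant linear model: the posterior concentrates on the
           identified ridge", {
  r <- run_linreg_validation("redundant", train_size = 5000L, n_obs = 20L,
                             n_cases = 25L, seed = 62L)
  # top-10% mass region intersects the analytic posterior's ridge crest
  expect_gte(r$coverage, 0.8)
  expect_lt(r$median_kl, 1)
})
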