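# Linear-stability analytics: dispersion relation, closed forms vs the
# numeric eigenvalue oracle, and the image-spectrum wavenumber reader.

test_that("growth rate matches a direct 2x2 eigenvalue computation", {
  p <- turing_params(f_v = 0.9, g_v = 0.8)
  # k = 0: trace -0.29, det 0.321, complex pair -> lambda = tr/2
  expect_equal(growth_rate(0, p), -0.145, tolerance = 1e-12)
  # generic k: compare against eigen() directly
  for (k in c(0.3, 0.9, 1.4, 2.5)) {
    M <- matrix(c(p$f_u - p$D_u * k^2, p$g_u,
                  -p$f_v, -p$g_v - p$D_v * k^2), 2, 2)
    expect_equal(growth_rate(k, p),
                 max(Re(eigen(M, only.values = TRUE)$values)),
                 tolerance = 1e-10)
  }
  # diffusion-dominated limit is strongly negative
  expect_lt(growth_rate(50, p), -min(p$D_u, p$D_v) * 50^2 / 2)
  # continuity: the largest jump shrinks with the grid (the real/complex
  # branch switch has a sqrt-singular slope, so a fixed bound is wrong)
  jump <- function(n) max(abs(diff(growth_rate(seq(0, 3, length.out = n),
                                               p))))
  expect_lt(jump(16000), jump(1000))
  expect_lt(jump(16000), 0.02)
})

test_that("closed-form k_max agrees with the numeric dispersion argmax", {
  draws <- 0
  set.seed(101)
  while (draws < 100) {
    p <- turing_params(runif(1, 0.6, 1.0), runif(1, 0.6, 1.0))
    if (!has_positive_band(p)) next
    draws <- draws + 1
    kc <- kmax_closed(p)
    kn <- kmax_numeric(p)
    expect_lt(abs(kc - kn) / kn, 1e-3)
  }
})

test_that("closed-form D_k matches numeric band edges", {
  set.seed(202)
  draws <- 0
  while (draws < 25) {
    p <- turing_params(runif(1, 0.6, 1.0), runif(1, 0.6, 1.0))
    if (!has_positive_band(p)) next
    draws <- draws + 1
    b <- band_numeric(p)
    expect_lt(abs(growth_rate(b["k_left"], p)), 1e-6)
    expect_lt(abs(growth_rate(b["k_right"], p)), 1e-6)
    expect_lt(b["k_left"], kmax_numeric(p))
    expect_gt(b["k_right"], kmax_numeric(p))
    expect_equal(dk_closed(p),
                 log(b[["k_right"]]^2 / b[["k_left"]]^2),
                 tolerance = 1e-3)
  }
})

test_that("degenerate and band-less inputs raise errors", {
  expect_error(kmax_closed(turing_params(0.9, 0.8, D_u = 1, D_v = 1)),
               "degenerate")
  # stable homogeneous state but band condition fails (A^2 < 4 Du Dv det J)
  p_dead <- turing_params(1.2, 0.6)
  expect_false(has_positive_band(p_dead))
  expect_error(kmax_numeric(p_dead), "no positive")
  expect_error(band_numeric(p_dead), "no positive")
})

test_that("k_max scales as sqrt(c) under simultaneous time rescaling", {
  p <- turing_params(0.85, 0.7)
  for (c_ in c(0.5, 2, 4)) {
    p2 <- turing_params(f_v = c_ * p$f_v, g_v = c_ * p$g_v,
                        f_u = c_ * p$f_u, g_u = c_ * p$g_u,
                        D_u = c_ * p$D_u, D_v = c_ * p$D_v)
    expect_equal(kmax_closed(p2), kmax_closed(p), tolerance = 1e-10)
    # rescaling reaction terms only (not diffusion) shifts k by sqrt(c)
    p3 <- turing_params(f_v = c_ * p$f_v, g_v = c_ * p$g_v,
                        f_u = c_ * p$f_u, g_u = c_ * p$g_u,
                        D_u = p$D_u, D_v = p$D_v)
    expect_equal(kmax_closed(p3), sqrt(c_) * kmax_closed(p),
                 tolerance = 1e-10)
  }
})

test_that("two-parameter factored form has the expected coefficients", {
  form <- kmax_two_param_form(turing_params(0.8, 0.8))
  expect_equal(signif(form$prefactor, 2), 3.3)
  expect_equal(form$coef_gv, 0.1, tolerance = 1e-12)
  expect_equal(round(form$coef_fv, 2), 0.31)
  # the factored expression reproduces the closed form across the box
  set.seed(7)
  for (i in 1:20) {
    p <- turing_params(runif(1, 0.6, 1), runif(1, 0.6, 1))
    if (!has_positive_band(p)) next
    k_fact <- form$prefactor *
      sqrt(form$coef_fv * sqrt(p$f_v) - form$coef_gv * (p$f_u + p$g_v))
    expect_equal(k_fact, kmax_closed(p), tolerance = 1e-10)
  }
})

test_that("dominant wavenumber reads a known grating and is symmetric", {
  g <- grating(128, 16)
  expect_equal(dominant_wavenumber(g), 2 * pi / 16,
               tolerance = 2 * pi / 128 + 1e-9)
  img <- matrix(runif(64 * 64), 64, 64)
  expect_equal(dominant_wavenumber(img), dominant_wavenumber(t(img)))
  expect_error(dominant_wavenumber(matrix(0.4, 32, 32)), "flat")
})
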