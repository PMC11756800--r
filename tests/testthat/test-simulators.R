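# Simulator contracts: fixed points, conservation laws, determinism, and
# spectral consistency with the stability analytics.

test_that("Turing: zero state is a fixed point and seeds give determinism", {
  p <- turing_params(0.9, 0.8)
  z <- matrix(0, 32, 32)
  u <- simulate_turing(p, size = 32L, steps = 200L,
                       init = list(u = z, v = z))
  expect_true(all(u == 0))
  u1 <- simulate_turing(p, size = 32L, steps = 300L, seed = 5L)
  u2 <- simulate_turing(p, size = 32L, steps = 300L, seed = 5L)
  expect_identical(u1, u2)
  expect_error(simulate_turing(p, dt = 0.5, size = 16L, steps = 10L),
               "unstable")
})

test_that("Turing: band-less parameters decay, banded ones grow a pattern", {
  p_dead <- turing_params(1.2, 0.6)     # numerically verified: no band
  expect_false(has_positive_band(p_dead))
  # dt small enough that explicit Euler damps the oscillatory k=0 pair
  u <- simulate_turing(p_dead, size = 32L, steps = 8000L, seed = 2L,
                       init_amp = 0.01, dt = 0.1)
  expect_lt(max(abs(u)), 0.01)
  p_live <- turing_params(0.9078, 0.8018)
  ul <- simulate_turing(p_live, size = 48L, steps = 4000L, seed = 2L,
                        dt = 0.2)
  expect_gt(max(abs(ul)), 0.1)
  expect_lt(abs(dominant_wavenumber(ul) - kmax_closed(p_live)) /
              kmax_closed(p_live), 0.25)
})

test_that("Gray-Scott: homogeneous state is fixed; patterns evolve in time", {
  gp <- gray_scott_params(capture_times = c(100L, 300L))
  snaps <- simulate_gray_scott(gp, size = 32L, perturb = FALSE)
  expect_true(all(snaps[[1]] == 1))
  expect_true(all(snaps[[2]] == 1))
  gp2 <- gray_scott_params(capture_times = c(1000L, 2000L, 4000L))
  sn <- simulate_gray_scott(gp2, size = 48L, seed = 3L)
  expect_length(sn, 3L)
  expect_gt(max(abs(sn[[1]] - sn[[2]])), 1e-3)
  expect_gt(max(abs(sn[[2]] - sn[[3]])), 1e-3)
  expect_length(simulate_gray_scott(
    gray_scott_params(capture_times = integer(0)), size = 16L), 0L)
})

test_that("KT model: zero kernel freezes the state; clipping bounds hold", {
  pz <- kt_params(act_amp = 0, inh_amp = 0, steps = 10L)
  u0 <- patternfit:::with_seed(1L, matrix(runif(32^2, -0.01, 0.01) + 0.5,
                                          32, 32))
  u <- simulate_kt(pz, size = 32L, seed = 1L)
  expect_equal(u, u0, tolerance = 1e-12)
  p <- kt_params()
  uk <- simulate_kt(p, size = 64L, seed = 2L)
  expect_true(all(uk >= 0 & uk <= 1))
  k <- dominant_wavenumber(uk)
  expect_gt(k, 0)
  expect_lt(k, pi)
  expect_error(simulate_kt(kt_params(inh_r = 40), size = 64L), "larger")
})

test_that("Edwards-Wilkinson: flat no-noise fixed point and roughening", {
  pe <- ew_params(noise_amp = 0, steps = 50L)
  h <- simulate_edwards_wilkinson(pe, size = 32L)
  expect_true(all(h == 0))
  expect_error(ew_params(nu = 4, dt = 0.1), "unstable")
  # mean drift within 5 sigma of its sampling distribution
  p <- ew_params(noise_amp = 1, dt = 0.1, steps = 100L)
  h2 <- simulate_edwards_wilkinson(p, size = 32L, seed = 9L)
  drift_sd <- p$noise_amp * sqrt(p$dt * p$steps) / 32
  expect_lt(abs(mean(h2)), 5 * drift_sd)
  # interface width grows in expectation over early steps (20 seeds)
  w_early <- mean(sapply(1:20, function(s)
    sd(simulate_edwards_wilkinson(ew_params(steps = 20L), 24L, seed = s))))
  w_late <- mean(sapply(1:20, function(s)
    sd(simulate_edwards_wilkinson(ew_params(steps = 120L), 24L, seed = s))))
  expect_gt(w_late, w_early)
})

test_that("Eden and DLA growth contracts", {
  e <- simulate_growth(growth_config("eden", 500L), size = 64L, seed = 4L)
  expect_equal(sum(e$grid), 501)                 # seed + one cell per event
  expect_false(e$truncated)
  d1 <- simulate_growth(growth_config("dla", 1L), size = 64L, seed = 4L)
  expect_equal(sum(d1$grid), 2)
  occ <- which(d1$grid == 1, arr.ind = TRUE)
  expect_equal(sum(abs(occ[1, ] - occ[2, ])), 1)  # 4-adjacent to the seed
  d2 <- simulate_growth(growth_config("dla", 120L), size = 64L, seed = 8L)
  d3 <- simulate_growth(growth_config("dla", 120L), size = 64L, seed = 8L)
  expect_identical(d2$grid, d3$grid)
})

test_that("L-system rewriting and rendering", {
  s0 <- l_system_spec(axiom = "F", productions = c(X = "F"),
                      iterations = 3L)
  expect_equal(l_system_string(s0), "F")
  s1 <- l_system_spec(axiom = "F", productions = c(F = "F[+F]F"),
                      iterations = 1L)
  expect_equal(l_system_string(s1), "F[+F]F")
  s2 <- l_system_spec(axiom = "F", productions = c(F = "F[+F]F"),
                      iterations = 2L)
  expect_equal(l_system_string(s2), "F[+F]F[+F[+F]F]F[+F]F")
  img <- generate_l_system(s2, size = 64L)
  expect_true(all(img %in% c(0, 1)))
  expect_gt(sum(img), 0)
  bad <- l_system_spec(axiom = "F[", iterations = 0L)
  expect_error(generate_l_system(bad), "unbalanced")
})

test_that("phase field: no nucleus is stationary; replicates differ by seed", {
  pp <- phase_field_params(noise_amp = 0, steps = 50L)
  p0 <- simulate_phase_field(pp, size = 32L, nucleus = FALSE)
  expect_true(all(p0 == 0))
  pa <- simulate_phase_field(phase_field_params(steps = 400L), 48L, seed = 1L)
  pb <- simulate_phase_field(phase_field_params(steps = 400L), 48L, seed = 2L)
  expect_true(all(pa >= 0 & pa <= 1))
  expect_gt(max(abs(pa - pb)), 1e-6)
  pa2 <- simulate_phase_field(phase_field_params(steps = 400L), 48L, seed = 1L)
  expect_identical(pa, pa2)
})

test_that("Cahn-Hilliard conserves mass and coarsens", {
  ch <- cahn_hilliard_params(steps = 400L)
  init <- patternfit:::with_seed(3L, matrix(runif(48^2, -0.1, 0.1), 48, 48))
  u <- simulate_cahn_hilliard(ch, size = 48L, init = init)
  expect_lt(abs(mean(u) - mean(init)), 1e-8)
  u0 <- simulate_cahn_hilliard(cahn_hilliard_params(steps = 100L),
                               size = 32L, init = matrix(0, 32, 32))
  expect_true(all(u0 == 0))
  snaps <- simulate_cahn_hilliard(cahn_hilliard_params(steps = 4000L),
                                  size = 64L, seed = 5L,
                                  snapshots = c(300L, 4000L))
  k_early <- dominant_wavenumber(snaps[[1]])
  k_late <- dominant_wavenumber(snaps[[2]])
  expect_lt(k_late, k_early)
})
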