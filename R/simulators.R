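# Pattern-forming simulators.  Every simulator is deterministic given its
# seed (all randomness flows through R's RNG) and emits a raw square field;
# rendering to [0,1] images is the imaging module's job.

#' Simulate the two-species Turing reaction-diffusion model
#'
#' Explicit Euler integration of the linear + cubic reaction-diffusion
#' system on a periodic square lattice (unit spacing).  Integration stops
#' early once the relative L2 change of the u field per `check_every` steps
#' falls below `tol` (quasi-steady state).
#'
#' @param params a [turing_params()] object.
#' @param size lattice side (cells).
#' @param dt time step; must satisfy `dt <= 1/(4*max(D_u, D_v))`.
#' @param steps maximum number of steps.
#' @param seed RNG seed for the initial noise.
#' @param init optional list(u, v) of initial fields; default is uniform
#'   noise `U(-init_amp, init_amp)` about the homogeneous state.
#' @param init_amp initial noise amplitude.
#' @param tol early-exit tolerance on the relative L2 change.
#' @param check_every steps between convergence checks.
#' @param full return list(u, v, steps_run) instead of just u.
#' @return final u field (matrix), or a list when `full = TRUE`.
#' @export
simulate_turing <- function(params, size = 128L, dt = 0.1, steps = 20000L,
                            seed = 1L, init = NULL, init_amp = 0.01,
                            tol = 1e-5, check_every = 1000L, full = FALSE) {
  stopifnot(inherits(params, "turing_params"))
  if (dt > 1 / (4 * max(params$D_u, params$D_v)) + 1e-12) {
    stop("unstable time step: need dt <= 1/(4*max(D_u, D_v))")
  }
  if (is.null(init)) {
    init <- with_seed(seed, list(
      u = matrix(runif(size^2, -init_amp, init_amp), size, size),
      v = matrix(runif(size^2, -init_amp, init_amp), size, size)))
  }
  stopifnot(all(is.finite(init$u)), all(is.finite(init$v)))
  res <- turing_sim_cpp(init$u, init$v, params$f_u, params$f_v, params$g_u,
                        params$g_v, params$q, params$D_u, params$D_v,
                        dt, as.integer(steps), as.integer(check_every), tol)
  if (full) res else res$u
}

#' Gray-Scott parameter set
#'
#' Defaults are the classic spot/stripe-forming lattice regime
#' (`D_u = 0.16`, `D_v = 0.08`, `dt = 1` on a unit-spacing grid).
#'
#' @param F feed rate; `k` kill rate (both nonnegative).
#' @param k kill rate.
#' @param D_u,D_v diffusivities.
#' @param capture_times strictly increasing snapshot step counts.
#' @export
gray_scott_params <- function(F = 0.037, k = 0.06, D_u = 0.16, D_v = 0.08,
                              capture_times = c(2000L, 4000L, 8000L,
                                                16000L, 24000L, 32000L)) {
  stopifnot(F >= 0, k >= 0,
            length(capture_times) == 0 || all(diff(capture_times) > 0))
  structure(list(F = F, k = k, D_u = D_u, D_v = D_v,
                 capture_times = as.integer(capture_times)),
            class = "gray_scott_params")
}

#' Simulate the Gray-Scott model
#'
#' @param params a [gray_scott_params()] object.
#' @param size lattice side.
#' @param seed RNG seed for the initial perturbation.
#' @param dt time step.
#' @param perturb add the central square perturbation (u=0.5, v=0.25) plus
#'   small noise; with `FALSE` the homogeneous state (1, 0) is kept.
#' @return list of u-field snapshots, one per capture time.
#' @export
simulate_gray_scott <- function(params, size = 128L, seed = 1L, dt = 1.0,
                                perturb = TRUE) {
  stopifnot(inherits(params, "gray_scott_params"))
  u <- matrix(1, size, size)
  v <- matrix(0, size, size)
  if (perturb) {
    w <- max(2L, size %/% 16L)
    c0 <- size %/% 2L
    idx <- (c0 - w):(c0 + w)
    u[idx, idx] <- 0.5
    v[idx, idx] <- 0.25
    noise <- with_seed(seed, matrix(runif(size^2, -0.01, 0.01), size, size))
    u <- u + noise
    v <- v + abs(noise)
  }
  snaps <- gray_scott_cpp(u, v, params$F, params$k, params$D_u, params$D_v,
                          dt, params$capture_times)
  lapply(snaps, identity)
}

#' Kernel-based Turing (KT) model parameters
#'
#' Interaction kernel with short-range activation (amplitude `act_amp`,
#' radius `act_r`) and longer-range inhibition (`inh_amp`, radius `inh_r`).
#'
#' @param act_amp,act_r activation amplitude and radius (pixels).
#' @param inh_amp,inh_r inhibition amplitude and radius; `inh_r > act_r`.
#' @param clip c(low, high) state bounds.
#' @param dt synchronous update step size.
#' @param steps iteration count.
#' @export
kt_params <- function(act_amp = 0.08, act_r = 2, inh_amp = 0.018, inh_r = 5,
                      clip = c(0, 1), dt = 1, steps = 100L) {
  stopifnot(inh_r > act_r, clip[1] < clip[2])
  structure(list(act_amp = act_amp, act_r = act_r, inh_amp = inh_amp,
                 inh_r = inh_r, clip = clip, dt = dt,
                 steps = as.integer(steps)),
            class = "kt_params")
}

# Periodic FFT convolution with a kernel given as a full-size field centred
# at the origin cell.
fft_convolve <- function(x, kernel_fft) {
  Re(stats::fft(stats::fft(x) * kernel_fft, inverse = TRUE)) / length(x)
}

kt_kernel <- function(size, act_amp, act_r, inh_amp, inh_r) {
  d <- c(0:(size %/% 2), (size - size %/% 2 - 1):1)
  r <- sqrt(outer(d^2, d^2, "+"))
  k <- matrix(0, size, size)
  k[r <= act_r] <- act_amp
  k[r > act_r & r <= inh_r] <- -inh_amp
  k
}

#' Simulate the kernel-based Turing model
#'
#' Synchronous update `u <- clip(u + dt * (u * kernel))` where `*` is
#' periodic convolution with the activation-minus-inhibition kernel.
#'
#' @param params a [kt_params()] object.
#' @param size lattice side.
#' @param seed RNG seed for the initial noise.
#' @return final state field (matrix).
#' @export
simulate_kt <- function(params, size = 128L, seed = 1L) {
  stopifnot(inherits(params, "kt_params"))
  if (2 * params$inh_r + 1 > size) stop("kernel larger than grid")
  ker <- kt_kernel(size, params$act_amp, params$act_r,
                   params$inh_amp, params$inh_r)
  kf <- stats::fft(ker)
  u <- with_seed(seed, matrix(runif(size^2, -0.01, 0.01) + 0.5, size, size))
  u <- clamp(u, params$clip[1], params$clip[2])
  for (s in seq_len(params$steps)) {
    u <- clamp(u + params$dt * fft_convolve(u, kf),
               params$clip[1], params$clip[2])
  }
  u
}

#' Edwards-Wilkinson interface parameters
#'
#' @param nu relaxation coefficient; explicit stability needs `nu*dt <= 1/4`.
#' @param noise_amp noise amplitude (per sqrt(time)).
#' @param dt time step; `steps` step count.
#' @param steps step count.
#' @export
ew_params <- function(nu = 1, noise_amp = 1, dt = 0.1, steps = 500L) {
  if (nu * dt > 0.25 + 1e-12) stop("unstable: need nu*dt <= 1/4")
  structure(list(nu = nu, noise_amp = noise_amp, dt = dt,
                 steps = as.integer(steps)), class = "ew_params")
}

#' Simulate the Edwards-Wilkinson interface model
#'
#' `h <- h + dt*nu*Lap(h) + noise_amp*sqrt(dt)*N(0,1)` per cell per step.
#'
#' @param params an [ew_params()] object.
#' @param size lattice side.
#' @param seed RNG seed.
#' @param init optional initial height field (default flat 0).
#' @return height field (matrix).
#' @export
simulate_edwards_wilkinson <- function(params, size = 128L, seed = 1L,
                                       init = NULL) {
  stopifnot(inherits(params, "ew_params"))
  if (is.null(init)) init <- matrix(0, size, size)
  with_seed(seed,
    edwards_wilkinson_cpp(init, params$nu, params$noise_amp,
                          params$dt, params$steps))
}

#' Stochastic growth configuration (Eden / DLA)
#'
#' @param model "eden" or "dla".
#' @param n_events growth events (Eden) or walkers (DLA).
#' @param seed_site c(row, col) cluster seed; default grid centre.
#' @param launch_pad DLA launch radius = cluster radius + `launch_pad`.
#' @param kill_factor DLA kill radius = `kill_factor` * launch radius.
#' @export
growth_config <- function(model = c("eden", "dla"), n_events = 2000L,
                          seed_site = NULL, launch_pad = 5,
                          kill_factor = 3) {
  model <- match.arg(model)
  stopifnot(n_events >= 0)
  structure(list(model = model, n_events = as.integer(n_events),
                 seed_site = seed_site, launch_pad = launch_pad,
                 kill_factor = kill_factor), class = "growth_config")
}

#' Simulate stochastic lattice growth (Eden or DLA)
#'
#' Eden: each event occupies one uniformly chosen perimeter site.
#' DLA: walkers launched at the launch radius stick on 4-neighbour contact.
#'
#' @param config a [growth_config()] object.
#' @param size lattice side.
#' @param seed RNG seed.
#' @return list(grid, truncated, events_done): binary occupancy matrix plus
#'   a truncation flag (cluster met the grid edge early).
#' @export
simulate_growth <- function(config, size = 128L, seed = 1L) {
  stopifnot(inherits(config, "growth_config"))
  site <- if (is.null(config$seed_site)) rep(size %/% 2L, 2L) else config$seed_site
  stopifnot(all(site >= 1), all(site <= size))
  with_seed(seed, {
    if (config$model == "eden") {
      r <- eden_cpp(config$n_events, size, site[1] - 1L, site[2] - 1L)
      list(grid = r$grid, truncated = r$truncated, events_done = r$events_done)
    } else {
      r <- dla_cpp(config$n_events, size, site[1] - 1L, site[2] - 1L,
                   config$launch_pad, config$kill_factor, 200000L)
      list(grid = r$grid, truncated = r$truncated, events_done = r$particles_done)
    }
  })
}

#' L-system specification
#'
#' @param axiom start string.
#' @param productions named character vector mapping symbols to replacement
#'   strings; symbols without a rule are copied unchanged.
#' @param iterations rewrite count.
#' @param angle turn angle in degrees for `+`/`-`.
#' @param step step length in pixels (before auto-scaling).
#' @export
l_system_spec <- function(axiom = "F",
                          productions = c(F = "F[+F]F[-F]F"),
                          iterations = 4L, angle = 25, step = 4) {
  stopifnot(iterations >= 0)
  structure(list(axiom = axiom, productions = productions,
                 iterations = as.integer(iterations), angle = angle,
                 step = step), class = "l_system_spec")
}

#' Rewrite an L-system string
#'
#' @param spec an [l_system_spec()] object.
#' @return the string after `iterations` parallel rewrites.
#' @export
l_system_string <- function(spec) {
  s <- spec$axiom
  for (i in seq_len(spec$iterations)) {
    chars <- strsplit(s, "")[[1]]
    out <- vapply(chars, function(ch) {
      if (ch %in% names(spec$productions)) spec$productions[[ch]] else ch
    }, character(1))
    s <- paste0(out, collapse = "")
  }
  s
}

#' Render an L-system by turtle graphics
#'
#' Supports `F` (draw forward), `+`/`-` (turn), `[`/`]` (push/pop state).
#' The path is auto-scaled to fit the raster with a 4-pixel margin.
#'
#' @param spec an [l_system_spec()] object.
#' @param size raster side.
#' @return binary matrix rendering.
#' @export
generate_l_system <- function(spec, size = 128L) {
  s <- l_system_string(spec)
  chars <- strsplit(s, "")[[1]]
  bad <- setdiff(unique(chars), c("F", "+", "-", "[", "]", names(spec$productions)))
  if (length(bad)) {
    bad2 <- setdiff(bad, c(LETTERS, letters))  # bare symbols act as no-ops
    if (length(bad2)) stop("undrawable symbols: ", paste(bad2, collapse = ","))
  }
  depth <- cumsum((chars == "[") - (chars == "]"))
  if (any(depth < 0) || depth[length(depth)] != 0) stop("unbalanced brackets")
  # walk the turtle, collecting segments
  x <- 0; y <- 0; th <- pi / 2
  stack <- list()
  seg <- matrix(numeric(0), ncol = 4)
  segs <- vector("list", sum(chars == "F"))
  nseg <- 0L
  for (ch in chars) {
    if (ch == "F") {
      x2 <- x + spec$step * cos(th)
      y2 <- y + spec$step * sin(th)
      nseg <- nseg + 1L
      segs[[nseg]] <- c(x, y, x2, y2)
      x <- x2; y <- y2
    } else if (ch == "+") {
      th <- th + spec$angle * pi / 180
    } else if (ch == "-") {
      th <- th - spec$angle * pi / 180
    } else if (ch == "[") {
      stack[[length(stack) + 1L]] <- c(x, y, th)
    } else if (ch == "]") {
      st <- stack[[length(stack)]]
      stack[[length(stack)]] <- NULL
      x <- st[1]; y <- st[2]; th <- st[3]
    }
  }
  img <- matrix(0, size, size)
  if (nseg == 0L) return(img)
  segs <- do.call(rbind, segs[seq_len(nseg)])
  xr <- range(c(segs[, 1], segs[, 3]))
  yr <- range(c(segs[, 2], segs[, 4]))
  margin <- 4
  span <- max(xr[2] - xr[1], yr[2] - yr[1], 1e-9)
  sc <- (size - 1 - 2 * margin) / span
  mapx <- function(v) 1 + margin + (v - xr[1]) * sc
  mapy <- function(v) 1 + margin + (v - yr[1]) * sc
  for (i in seq_len(nrow(segs))) {
    x1 <- mapx(segs[i, 1]); y1 <- mapy(segs[i, 2])
    x2 <- mapx(segs[i, 3]); y2 <- mapy(segs[i, 4])
    np <- max(2L, ceiling(max(abs(x2 - x1), abs(y2 - y1))) * 2L)
    xs <- round(seq(x1, x2, length.out = np))
    ys <- round(seq(y1, y2, length.out = np))
    img[cbind(clamp(xs, 1, size), clamp(ys, 1, size))] <- 1
  }
  img
}

#' Phase-field (anisotropic solidification) parameters
#'
#' Kobayashi-style dendritic growth: a phase variable coupled to a
#' temperature field with anisotropic interface energy.
#'
#' @param delta anisotropy strength; `j_mode` anisotropy mode number.
#' @param j_mode anisotropy mode number.
#' @param theta0 anisotropy phase offset (radians).
#' @param tau interface mobility (relaxation time).
#' @param K latent-heat coupling constant.
#' @param noise_amp initial-noise amplitude applied to the phase field.
#' @param eps_bar mean interface width parameter.
#' @param alpha,gamma_c,Teq driving-force constants.
#' @param dx,dt,steps discretization.
#' @export
phase_field_params <- function(delta = 0.04, j_mode = 6L, theta0 = 0,
                               tau = 3e-4, K = 1.6, noise_amp = 0.01,
                               eps_bar = 0.01, alpha = 0.9, gamma_c = 10,
                               Teq = 1, dx = 0.03, dt = 2e-4,
                               steps = 2000L) {
  structure(list(delta = delta, j_mode = as.integer(j_mode), theta0 = theta0,
                 tau = tau, K = K, noise_amp = noise_amp, eps_bar = eps_bar,
                 alpha = alpha, gamma_c = gamma_c, Teq = Teq, dx = dx,
                 dt = dt, steps = as.integer(steps)),
            class = "phase_field_params")
}

#' Simulate anisotropic phase-field growth from a central nucleus
#'
#' Replicates differ only through the initial-noise seed.
#'
#' @param params a [phase_field_params()] object.
#' @param size lattice side.
#' @param seed RNG seed for the initial noise.
#' @param nucleus place a central seed nucleus (radius ~2 cells).
#' @return phase field (matrix in \[0,1\]).
#' @export
simulate_phase_field <- function(params, size = 128L, seed = 1L,
                                 nucleus = TRUE) {
  stopifnot(inherits(params, "phase_field_params"))
  p <- matrix(0, size, size)
  if (nucleus) {
    c0 <- size / 2
    d <- sqrt(outer((seq_len(size) - c0)^2, (seq_len(size) - c0)^2, "+"))
    p[d <= 2] <- 1
  }
  if (params$noise_amp > 0) {
    p <- p + with_seed(seed,
      matrix(runif(size^2, -params$noise_amp, params$noise_amp), size, size))
    p <- clamp(p, 0, 1)
  }
  T0 <- matrix(0, size, size)
  res <- phase_field_cpp(p, T0, params$eps_bar, params$delta, params$j_mode,
                         params$theta0, params$tau, params$alpha,
                         params$gamma_c, params$Teq, params$K,
                         params$dx, params$dt, params$steps)
  res$phase
}

#' Cahn-Hilliard parameters
#'
#' The lattice spacing must resolve the interface width `sqrt(gamma)`
#' (cells of side `dx < sqrt(gamma)`), otherwise domain walls pin on the
#' grid and coarsening freezes.
#'
#' @param gamma interface parameter.
#' @param mobility mobility constant.
#' @param dx lattice spacing (default 0.25, resolving `sqrt(0.1)`).
#' @param dt time step; `steps` step count.
#' @param steps step count.
#' @export
cahn_hilliard_params <- function(gamma = 0.1, mobility = 1, dx = 0.25,
                                 dt = 0.01, steps = 4000L) {
  structure(list(gamma = gamma, mobility = mobility, dx = dx, dt = dt,
                 steps = as.integer(steps)), class = "cahn_hilliard_params")
}

#' Simulate the Cahn-Hilliard equation
#'
#' Semi-implicit spectral integration of
#' `du/dt = M * Lap(u^3 - u - gamma*Lap(u))` on a periodic lattice; the
#' spatial mean (mass) is conserved exactly by the scheme.
#'
#' @param params a [cahn_hilliard_params()] object.
#' @param size lattice side.
#' @param seed RNG seed for the initial noise.
#' @param init optional initial field; default `U(-0.1, 0.1)` noise.
#' @param snapshots optional increasing step counts; when given, a list of
#'   fields is returned.
#' @return final field, or list of snapshot fields.
#' @export
simulate_cahn_hilliard <- function(params, size = 128L, seed = 1L,
                                   init = NULL, snapshots = NULL) {
  stopifnot(inherits(params, "cahn_hilliard_params"))
  if (is.null(init)) {
    init <- with_seed(seed, matrix(runif(size^2, -0.1, 0.1), size, size))
  }
  fr <- c(0:(size %/% 2), -((size - size %/% 2 - 1):1)) *
    (2 * pi / (size * params$dx))
  k2 <- outer(fr^2, fr^2, "+")
  M <- params$mobility
  denom <- 1 + params$dt * M * params$gamma * k2^2
  u <- init
  uhat <- stats::fft(u)
  out <- list()
  want <- if (is.null(snapshots)) integer(0) else as.integer(snapshots)
  for (s in seq_len(params$steps)) {
    nl <- stats::fft(u^3 - u)
    uhat <- (uhat - params$dt * M * k2 * nl) / denom
    u <- Re(stats::fft(uhat, inverse = TRUE)) / length(u)
    if (!all(is.finite(u))) stop("Cahn-Hilliard diverged at step ", s)
    if (s %in% want) out[[as.character(s)]] <- u
  }
  if (is.null(snapshots)) u else out
}
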