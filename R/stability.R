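# Linear stability analytics for the two-species Turing model
#
#   du/dt = f_u u - f_v v + q u^2 - u^3 + D_u Lap(u)
#   dv/dt = g_u u - g_v v             + D_v Lap(v)
#
# Linearized about the homogeneous state (0,0) the Jacobian is
# J = [[f_u, -f_v], [g_u, -g_v]] and a Fourier mode with wavenumber k grows
# at the rate given by the dominant eigenvalue of J - k^2 diag(D_u, D_v).

#' Turing model parameter set
#'
#' Constructor with the fixed reaction constants used throughout the
#' estimation task as defaults: only `f_v` and `g_v` are free there.
#'
#' @param f_v,g_v free linear reaction coefficients (1/time).
#' @param f_u,g_u fixed linear reaction coefficients (1/time).
#' @param q quadratic reaction coefficient.
#' @param D_u,D_v diffusion coefficients (length^2/time), both positive.
#' @return object of class `turing_params`.
#' @export
turing_params <- function(f_v, g_v, f_u = 0.51, g_u = 0.81, q = 0,
                          D_u = 0.1, D_v = 1.0) {
  stopifnot(D_u > 0, D_v > 0)
  p <- list(f_u = f_u, f_v = f_v, g_u = g_u, g_v = g_v, q = q,
            D_u = D_u, D_v = D_v)
  stopifnot(all(vapply(p, is.finite, logical(1))))
  structure(p, class = "turing_params")
}

#' Growth rate of a spatial mode (dispersion relation)
#'
#' @param k wavenumber(s), `k >= 0`.
#' @param params a [turing_params()] object.
#' @return real growth rate(s): max real part of the eigenvalues of
#'   `J - k^2 diag(D_u, D_v)`.
#' @export
growth_rate <- function(k, params) {
  stopifnot(inherits(params, "turing_params"), all(k >= 0))
  s <- k^2
  a11 <- params$f_u - params$D_u * s
  a22 <- -params$g_v - params$D_v * s
  tr <- a11 + a22
  det <- a11 * a22 + params$f_v * params$g_u
  disc <- tr^2 - 4 * det
  lam <- ifelse(disc >= 0, (tr + sqrt(pmax(disc, 0))) / 2, tr / 2)
  as.numeric(lam)
}

#' Sampled dispersion curve
#'
#' @param params a [turing_params()] object.
#' @param k_max upper end of the sampled wavenumber range.
#' @param n number of sample points.
#' @return data.frame with columns `k` and `lambda`.
#' @export
dispersion_curve <- function(params, k_max = pi, n = 512L) {
  k <- seq(0, k_max, length.out = n)
  data.frame(k = k, lambda = growth_rate(k, params))
}

# k_max^2 in closed form.  Derived by maximizing the "+" eigenvalue branch
# over s = k^2; the root choice and all signs are pinned by the numeric
# dispersion oracle (kmax_numeric), not by transcription.
kmax_squared_closed <- function(params) {
  with(params, {
    if (abs(D_u - D_v) < 1e-12) {
      stop("degenerate diffusion: D_u == D_v has no closed-form maximum")
    }
    num <- (D_u + D_v) * sqrt(f_v * g_u) - sqrt(D_u * D_v) * (f_u + g_v)
    num / (sqrt(D_u * D_v) * (D_v - D_u))
  })
}

#' Fastest-growing wavenumber, closed form
#'
#' @param params a [turing_params()] object with `D_u != D_v` and a positive
#'   band of unstable wavenumbers.
#' @return the wavenumber maximizing [growth_rate()].
#' @export
kmax_closed <- function(params) {
  s <- kmax_squared_closed(params)
  if (!is.finite(s) || s <= 0 || growth_rate(sqrt(s), params) <= 0) {
    stop("no positive dispersion band: closed-form k_max undefined")
  }
  sqrt(s)
}

#' Fastest-growing wavenumber, numeric oracle
#'
#' Dense scan of the dispersion relation over (0, k_hi] refined by
#' `stats::optimize` to ~1e-8.  Independent of [kmax_closed()].
#'
#' @param params a [turing_params()] object.
#' @param k_hi upper scan bound (default: lattice Nyquist, `pi`).
#' @param n_grid scan resolution.
#' @return the argmax wavenumber.
#' @export
kmax_numeric <- function(params, k_hi = pi, n_grid = 10000L) {
  k <- seq(1e-6, k_hi, length.out = n_grid)
  lam <- growth_rate(k, params)
  if (max(lam) <= 0) stop("no positive dispersion band found in scan")
  i <- which.max(lam)
  lo <- k[max(1L, i - 1L)]
  hi <- k[min(n_grid, i + 1L)]
  opt <- stats::optimize(function(kk) growth_rate(kk, params),
                         interval = c(lo, hi), maximum = TRUE,
                         tol = 1e-10)
  opt$maximum
}

# Band-edge auxiliaries: the unstable band is where det(J - s D) < 0, a
# quadratic in s = k^2 with roots (A +/- B) / (2 D_u D_v).
band_auxiliaries <- function(params) {
  with(params, {
    A <- D_v * f_u - D_u * g_v
    rad <- A^2 - 4 * D_u * D_v * (f_v * g_u - f_u * g_v)
    B <- if (rad >= 0) sqrt(rad) else NA_real_
    list(A = A, B = B)
  })
}

#' Log band-ratio feature D_k, closed form
#'
#' `D_k = ln((A+B)/(A-B)) = ln(k_right^2 / k_left^2)`: the log width of the
#' unstable wavenumber band.  Larger values indicate a labyrinthine rather
#' than straight-striped pattern.
#'
#' @param params a [turing_params()] object.
#' @return D_k (dimensionless).
#' @export
dk_closed <- function(params) {
  ab <- band_auxiliaries(params)
  if (!is.finite(ab$B) || ab$A <= 0 || ab$B >= ab$A || ab$B < 0) {
    stop("no positive band (requires A > B >= 0): D_k undefined")
  }
  if (ab$B == 0) return(0)
  log((ab$A + ab$B) / (ab$A - ab$B))
}

#' Unstable band edges, numeric oracle
#'
#' Bisection for the two zero crossings of the dispersion relation.
#'
#' @param params a [turing_params()] object.
#' @param k_hi upper scan bound.
#' @return numeric c(k_left, k_right).
#' @export
band_numeric <- function(params, k_hi = pi) {
  km <- kmax_numeric(params, k_hi = k_hi)
  f <- function(k) growth_rate(k, params)
  if (f(km) <= 0) stop("no positive band")
  left <- stats::uniroot(f, c(1e-9, km), tol = 1e-10)$root
  # expand right bracket until lambda < 0
  hi <- km * 1.5
  while (f(hi) > 0) hi <- hi * 1.5
  right <- stats::uniroot(f, c(km, hi), tol = 1e-10)$root
  c(k_left = left, k_right = right)
}

#' Two-parameter factored form of closed-form k_max
#'
#' Specializing the closed form to fixed `f_u`, `g_u`, `D_u`, `D_v` leaves a
#' two-parameter expression in `(f_v, g_v)`:
#' `k_max = C * sqrt(b * sqrt(f_v) - a * (f_u + g_v))`, factored so that the
#' inner `g_v` coefficient `a` equals `D_u`.  The leading coefficient is
#' then `C = 1 / sqrt(D_u * (D_v - D_u))`.
#'
#' @param params a [turing_params()] object supplying the fixed constants.
#' @return list with `prefactor` (C), `coef_fv` (b) and `coef_gv` (a).
#' @export
kmax_two_param_form <- function(params = turing_params(0.8, 0.8)) {
  with(params, {
    if (D_v <= D_u) stop("requires D_v > D_u")
    # k_max^2 = p * sqrt(f_v) - r * (f_u + g_v)
    p <- (D_u + D_v) * sqrt(g_u) / (sqrt(D_u * D_v) * (D_v - D_u))
    r <- 1 / (D_v - D_u)
    scale <- r / D_u
    list(prefactor = sqrt(scale), coef_fv = p / scale, coef_gv = D_u)
  })
}

#' Test for a positive dispersion band
#'
#' @param params a [turing_params()] object.
#' @return TRUE when some wavenumber has positive growth rate.
#' @export
has_positive_band <- function(params) {
  # require a stable homogeneous state (k = 0) plus a band of growing
  # finite-wavelength modes: the Turing condition
  if (growth_rate(0, params) >= 0) return(FALSE)
  s <- tryCatch(kmax_squared_closed(params), error = function(e) NA_real_)
  if (is.finite(s) && s > 0 && growth_rate(sqrt(s), params) > 0) return(TRUE)
  k <- seq(1e-6, pi, length.out = 2000L)
  any(growth_rate(k, params) > 0)
}

#' Dominant wavenumber of a pattern image
#'
#' Argmax of the radially averaged power spectrum (DC excluded), reported in
#' radians per pixel; with the simulators' unit lattice spacing this is
#' directly comparable to [kmax_closed()].
#'
#' @param img square numeric matrix (a pattern image or raw field).
#' @return dominant wavenumber (radians/pixel).
#' @export
dominant_wavenumber <- function(img) {
  sp <- radial_power_spectrum(img, demean = TRUE)
  pos <- sp$radius > 0
  if (all(sp$power[pos] < 1e-24)) {
    stop("flat image: dominant wavenumber undefined")
  }
  sp$wavenumber[pos][which.max(sp$power[pos])]
}
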