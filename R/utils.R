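#' @keywords internal
"_PACKAGE"

#' @useDynLib patternfit, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats runif rnorm optimize uniroot predict sd quantile setNames
#' @importFrom utils head read.csv write.csv
NULL

#' Deterministic seed fan-out
#'
#' Derives a stage-specific RNG seed (below 2^31) from a global seed and a
#' stage name, so one integer reproduces a whole experiment.
#'
#' @param global_seed integer global seed.
#' @param stage character stage name.
#' @return integer seed.
#' @export
derive_seed <- function(global_seed, stage) {
  stopifnot(is.numeric(global_seed), length(global_seed) == 1L)
  bytes <- utf8ToInt(paste0("patternfit:", stage))
  h <- as.double(global_seed %% 2147483647)
  for (b in bytes) h <- (h * 31 + b) %% 2147483647
  as.integer(h)
}

# Evaluate `expr` under a temporary RNG state seeded with `seed`, restoring
# the caller's state afterwards.
with_seed <- function(seed, expr) {
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    set.seed(NULL)
  }
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  set.seed(seed)
  expr
}

#' Radially averaged power spectrum of a square image
#'
#' Averages the 2-D FFT power over annuli of integer radius in frequency
#' space.  With unit lattice spacing the bin centres correspond to physical
#' wavenumbers `2*pi*r/n` (radians per pixel), directly comparable to the
#' analytic wavenumbers of [growth_rate()].
#'
#' @param img numeric matrix (square).
#' @param demean subtract the spatial mean first (suppresses the DC bin).
#' @return list with `power` (mean power per annulus, radius 0..n/2) and
#'   `wavenumber` (the matching physical wavenumbers).
#' @export
radial_power_spectrum <- function(img, demean = TRUE) {
  stopifnot(is.matrix(img), nrow(img) == ncol(img))
  n <- nrow(img)
  x <- if (demean) img - mean(img) else img
  p <- Mod(stats::fft(x))^2
  fr <- c(0:(n %/% 2), -((n - n %/% 2 - 1):1))  # FFT frequency indices
  r <- sqrt(outer(fr^2, fr^2, "+"))
  bin <- pmin(round(r), n %/% 2)
  pow <- as.vector(tapply(as.vector(p), as.vector(bin), mean))
  rad <- sort(unique(as.vector(bin)))
  list(power = pow, wavenumber = 2 * pi * rad / n, radius = rad)
}

# Clamp helper
clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)
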