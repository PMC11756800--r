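# Shared fixtures.  Expensive objects are built lazily once per test run
# and cached in this environment.

fixture_env <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (is.null(fixture_env[[name]])) fixture_env[[name]] <- builder()
  fixture_env[[name]]
}

# A small but diverse multi-model embedding store (used by the retrieval
# tests): freshly generated scaled-down selection dataset.
small_selection_store <- function() {
  fixture("small_store", function() {
    cfg <- selection_config(
      counts = c(turing = 16L, kt = 16L, gray_scott = 18L,
                 edwards_wilkinson = 8L, eden = 10L, dla = 8L,
                 l_system = 10L, phase_field = 6L),
      size = 48L, fast = TRUE)
    dir <- file.path(tempdir(), "pf_small_sel")
    man <- build_selection_dataset(cfg, out_dir = dir, seed = 42L,
                                   render = TRUE)
    # blur scaled to the 48-px image size (1.5 px at the native 128)
    encode_dataset(man, encoder_spec(input_size = 48L), blur_sigma = 0.75)
  })
}

# Sinusoidal grating of a given wavelength (pixels).
grating <- function(n, wavelength, angle = 0) {
  x <- outer(seq_len(n), rep(1, n))
  y <- outer(rep(1, n), seq_len(n))
  0.5 + 0.5 * sin(2 * pi * (cos(angle) * x + sin(angle) * y) / wavelength)
}

# Random Turing parameters with a verified positive dispersion band.
random_banded_params <- function(seed) {
  with_seed_local(seed, {
    repeat {
      p <- turing_params(runif(1, 0.6, 1.0), runif(1, 0.6, 1.0))
      if (has_positive_band(p)) return(p)
    }
  })
}

with_seed_local <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv())
  } else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  expr
}
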