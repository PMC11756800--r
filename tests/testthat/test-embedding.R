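# The deterministic spectral encoder and the embedding-store contracts.

test_that("fallback embeddings are 512-d, unit norm and deterministic", {
  set.seed(1)
  img <- matrix(runif(64 * 64), 64, 64)
  v1 <- spectral_fallback_features(img)
  v2 <- spectral_fallback_features(img)
  expect_length(v1, 512L)
  expect_equal(sqrt(sum(v1^2)), 1, tolerance = 1e-9)
  expect_identical(v1, v2)
  # constant image still yields a unit vector
  vc <- spectral_fallback_features(matrix(0.5, 64, 64))
  expect_equal(sqrt(sum(vc^2)), 1, tolerance = 1e-9)
})

test_that("radial-spectrum sub-features are rotation invariant and locate
           a grating", {
  set.seed(2)
  img <- matrix(runif(64 * 64), 64, 64)
  rot90 <- t(img)[, 64:1]
  s1 <- radial_power_spectrum(img)
  s2 <- radial_power_spectrum(rot90)
  expect_lt(max(abs(s1$power - s2$power)), 1e-6 * max(s1$power))
  g <- grating(128, 16)                        # wavenumber 2*pi/16
  sp <- radial_power_spectrum(g)
  pk <- sp$wavenumber[sp$radius > 0][which.max(sp$power[sp$radius > 0])]
  expect_equal(pk, 2 * pi / 16, tolerance = 2 * pi / 128 + 1e-12)
})

test_that("clip adapter errors explicitly instead of silently substituting", {
  img <- matrix(0.5, 32, 32)
  expect_error(encode(img, encoder_spec("clip_vit_b32")),
               "encoder unavailable")
})

test_that("same-parameter Turing pairs are closer than Turing-DLA pairs", {
  hits <- 0L
  for (i in 1:10) {
    p <- random_banded_params(300 + i)
    ua <- normalize_field(simulate_turing(p, size = 48L, dt = 0.2,
                                          steps = 2000L, seed = 2 * i))
    ub <- normalize_field(simulate_turing(p, size = 48L, dt = 0.2,
                                          steps = 2000L, seed = 2 * i + 1))
    dla <- simulate_growth(growth_config("dla", 150L), size = 48L,
                           seed = i)$grid
    va <- encode(blur(ua, 1.5), encoder_spec(input_size = 48L))
    vb <- encode(blur(ub, 1.5), encoder_spec(input_size = 48L))
    vd <- encode(blur(dla, 1.5), encoder_spec(input_size = 48L))
    if (cosine_similarity(va, vb) > cosine_similarity(va, vd)) {
      hits <- hits + 1L
    }
  }
  expect_gte(hits, 9L)
})

test_that("encode_dataset aligns vectors with manifest rows and is
           reproducible", {
  store <- small_selection_store()
  n <- nrow(store$manifest)
  expect_equal(dim(store$vectors), c(n, 512L))
  expect_false(anyNA(store$vectors))
  # re-encoding three rows from files reproduces their vectors
  idx <- c(1L, n %/% 2L, n)
  st2 <- encode_dataset(store$manifest[idx, ],
                        encoder_spec(input_size = 48L),
                        blur_sigma = store$blur_sigma)
  expect_equal(st2$vectors, store$vectors[idx, ], tolerance = 1e-12)
  # missing image aborts with a report
  bad <- store$manifest[1:3, ]
  bad$path[2] <- file.path(tempdir(), "nope.png")
  expect_error(encode_dataset(bad, encoder_spec(input_size = 48L)),
               "missing image")
  # store round trip
  base <- tempfile("store")
  save_store(store, base)
  st3 <- load_store(base)
  expect_equal(st3$vectors, store$vectors, tolerance = 1e-12)
  expect_identical(st3$encoder, store$encoder)
})
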