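# Cosine retrieval, crop scanning and MAP@k scoring.

test_that("cosine similarity identities and scale invariance", {
  v <- c(1, 2, -3, 0.5)
  expect_equal(cosine_similarity(v, v), 1)
  expect_equal(cosine_similarity(v, -v), -1)
  e1 <- c(1, 0); e12 <- c(1, 1) / sqrt(2)
  expect_equal(cosine_similarity(e1, e12), 0.70711, tolerance = 1e-5)
  expect_equal(cosine_similarity(3.7 * v, 0.01 * v), 1, tolerance = 1e-12)
  expect_error(cosine_similarity(v, rep(0, 4)), "zero-norm")
})

toy_store <- function(vectors, models) {
  structure(list(vectors = vectors,
                 manifest = data.frame(model = models,
                                       stringsAsFactors = FALSE),
                 encoder = "spectral_fallback", blur_sigma = 0),
            class = "embedding_store")
}

test_that("rank_similar: self-retrieval, orthogonality, permutation", {
  V <- diag(4)
  st <- toy_store(V, c("a", "b", "c", "d"))
  rk <- rank_similar(V[2, ], st, top_n = 4L)
  expect_equal(rk$row[1], 2L)
  expect_equal(rk$score[1], 1)
  expect_equal(rk$score[-1], rep(0, 3))
  # ranking is a permutation prefix: no duplicates
  expect_equal(sort(rk$row), 1:4)
  expect_warning(rank_similar(V[1, ], st, top_n = 10L), "truncating")
  expect_true(all(diff(rk$score) <= 0))
})

test_that("average precision at k hand cases", {
  rk <- data.frame(row = 1:3, model = c("P", "N", "P"),
                   score = c(0.9, 0.8, 0.7))
  expect_equal(average_precision_at_k(rk, "P", 3), 5 / 6, tolerance = 1e-9)
  expect_equal(average_precision_at_k(rk, "P", 3, normalize = "k"),
               (1 + 2 / 3) / 3, tolerance = 1e-9)
  rk2 <- data.frame(row = 1:3, model = rep("P", 3), score = c(3, 2, 1))
  expect_equal(average_precision_at_k(rk2, "P", 3), 1)
  expect_equal(average_precision_at_k(rk2, "X", 3), 0)
})

test_that("map matrix: orthogonal-subspace stores give the identity", {
  # two models in orthogonal subspaces
  V <- rbind(cbind(matrix(abs(rnorm(12)), 4, 3), matrix(0, 4, 3)),
             cbind(matrix(0, 4, 3), matrix(abs(rnorm(12)), 4, 3)))
  st <- toy_store(V, rep(c("m1", "m2"), each = 4))
  M <- map_matrix(st, k = 3L)
  expect_equal(unname(diag(M)), c(1, 1))
  expect_equal(M[1, 2], 0)
  expect_equal(M[2, 1], 0)
  # single-model store
  st1 <- toy_store(matrix(abs(rnorm(20)), 5, 4), rep("only", 5))
  M1 <- map_matrix(st1, k = 3L)
  expect_equal(dim(M1), c(1L, 1L))
  expect_equal(M1[1, 1], 1)
  expect_true(all(M >= 0 & M <= 1))
})

test_that("crop scan evaluates 11 variants and finds exact matches", {
  store <- small_selection_store()
  # a stored image as target: ratio 1.0 must dominate with score ~1
  img <- read_image(store$manifest$path[5])
  rk <- crop_scan_select(img, store, encoder_spec(input_size = 48L),
                         top_n = 3L)
  expect_equal(attr(rk, "crop_ratio"), 1.0)
  expect_equal(rk$row[1], 5L)
  expect_gt(rk$score[1], 0.999)
  # zoomed-out 2x2 montage of a stored pattern: small ratio recovers it
  m <- rbind(cbind(img, img), cbind(img, img))
  montage <- resize_image(m, 48L)
  rk2 <- crop_scan_select(montage, store, encoder_spec(input_size = 48L),
                          top_n = 3L)
  expect_lte(attr(rk2, "crop_ratio"), 0.75)
})

test_that("Turing target retrieves reaction-diffusion-like models", {
  store <- small_selection_store()
  rd_models <- c("turing", "kt", "gray_scott")
  hits <- 0L
  for (i in 1:10) {
    p <- random_banded_params(700 + i)
    img <- normalize_field(simulate_turing(p, size = 48L, dt = 0.2,
                                           steps = 2000L, seed = 50 + i))
    v <- encode(blur(img, store$blur_sigma),
                encoder_spec(input_size = 48L))
    rk <- rank_similar(v, store, top_n = 3L)
    if (all(rk$model %in% rd_models)) hits <- hits + 1L
  }
  expect_gte(hits, 8L)
})

test_that("cross-model MAP matrix shows the Turing-KT affinity", {
  store <- small_selection_store()
  # k beyond the per-model count so the ranking must cross model borders
  # (the scaled analogue of k = 50 on the full dataset)
  M <- map_matrix(store, k = 20L)
  expect_true(all(M >= 0 & M <= 1))
  ord <- names(sort(M["turing", ], decreasing = TRUE))
  expect_setequal(ord[1:2], c("turing", "kt"))
})
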