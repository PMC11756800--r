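# Grid labels, mining, triplet loss and the contrastive reducer.

test_that("grid labels: corners, clamping and interior cells", {
  expect_equal(unlist(assign_grid_label(0.6, 0.6)[c("i", "j")]),
               c(i = 0L, j = 0L))
  expect_equal(unlist(assign_grid_label(1.0, 1.0)[c("i", "j")]),
               c(i = 9L, j = 9L))
  expect_equal(unlist(assign_grid_label(0.79, 0.92)[c("i", "j")]),
               c(i = 4L, j = 8L))
  expect_error(assign_grid_label(0.5, 0.8), "outside")
  # vectorized ids are consistent
  g <- assign_grid_label(c(0.6, 1.0), c(0.6, 1.0))
  expect_equal(g$id, c(1L, 100L))
})

test_that("triplet loss hand values", {
  a <- c(0, 0)
  expect_equal(triplet_loss(a, a, c(1, 0), margin = 0.1), 0)
  expect_equal(triplet_loss(a, c(1, 0), c(0, 1), margin = 0.1), 0.1)
  expect_equal(triplet_loss(a, c(0.5, 0), c(0.2, 0), margin = 0.1), 0.4)
})

test_that("mining: vacuous batches, the latent exclusion rule", {
  z <- matrix(rnorm(10), 5, 2)
  same <- rep(1L, 5)
  expect_equal(nrow(mine_triplets(z, same, diag(5))), 0L)
  # crafted 3-sample batch: anchor 1, far positive 2, hard negative 3
  # (the negative must sit inside the mining band to be selected at all)
  z3 <- rbind(c(0, 1), c(1, 0), c(0.1, 1))
  lab3 <- c(1L, 1L, 2L)
  sims_ok <- matrix(c(1, 0.9, 0.1,
                      0.9, 1, 0.1,
                      0.1, 0.1, 1), 3, 3)
  tri <- mine_triplets(z3, lab3, sims_ok, epsilon = 0.2)
  expect_true(any(tri[, "a"] == 1 & tri[, "p"] == 2 & tri[, "n"] == 3))
  # latent similarity of the negative exceeds the positive: excluded
  sims_bad <- matrix(c(1, 0.2, 0.9,
                       0.2, 1, 0.1,
                       0.9, 0.1, 1), 3, 3)
  tri2 <- mine_triplets(z3, lab3, sims_bad, epsilon = 0.2)
  expect_false(any(tri2[, "a"] == 1 & tri2[, "p"] == 2 & tri2[, "n"] == 3))
  # equal similarities: kept (exclusion is strict)
  sims_eq <- matrix(0.5, 3, 3); diag(sims_eq) <- 1
  tri3 <- mine_triplets(z3, lab3, sims_eq, epsilon = 0.2)
  expect_true(any(tri3[, "a"] == 1 & tri3[, "p"] == 2 & tri3[, "n"] == 3))
})

test_that("mining equals a brute-force multi-similarity enumeration", {
  set.seed(5)
  z <- matrix(rnorm(24), 12, 2)
  lab <- rep(1:3, each = 4)
  lsims <- matrix(1, 12, 12)   # latent exclusion inert
  eps <- 0.2
  got <- mine_triplets(z, lab, lsims, epsilon = eps)
  nv <- sqrt(rowSums(z^2))
  S <- (z %*% t(z)) / outer(nv, nv)
  want <- list()
  for (a in 1:12) {
    pos <- setdiff(which(lab == lab[a]), a)
    neg <- which(lab != lab[a])
    kn <- neg[S[a, neg] > min(S[a, pos]) - eps]
    kp <- pos[S[a, pos] < max(S[a, neg]) + eps]
    for (p in kp) for (n in kn) {
      want[[length(want) + 1L]] <- c(a, p, n)
    }
  }
  want <- do.call(rbind, want)
  expect_equal(nrow(got), nrow(want))
  key <- function(m) sort(paste(m[, 1], m[, 2], m[, 3]))
  expect_equal(key(got), key(want))
})

test_that("excluded triplets contribute exactly zero loss", {
  z <- rbind(c(0, 0), c(3, 0), c(0.1, 0))   # d(a,p)=3 >> d(a,n)=0.1
  lab <- c(1L, 1L, 2L)
  lsims <- matrix(c(1, 0.1, 0.9,
                    0.1, 1, 0.2,
                    0.9, 0.2, 1), 3, 3)     # negative closer in latent space
  tri <- mine_triplets(z, lab, lsims, epsilon = 10)
  lg <- patternfit:::triplet_loss_grad(z, tri, margin = 0.1)
  expect_equal(lg$loss, 0)
  expect_true(all(lg$dz == 0))
})

test_that("reducer has the stated layer shapes and inference behavior", {
  m <- patternfit:::mlp_init(seed = 3L)
  expect_equal(reducer_shape(m),
               c(512L, 256L, 128L, 128L, 64L, 64L, 32L, 32L, 16L, 2L))
  # batch norm only on hidden layers 1-2
  has_bn <- vapply(m$layers, function(l) !is.null(l$bn), logical(1))
  expect_equal(which(has_bn), c(1L, 2L))
  expect_error(reduce_features(rnorm(512), m), "untrained")
})

test_that("training separates a two-cluster toy problem and is seeded", {
  set.seed(11)
  mk <- function(center, n) {
    t(vapply(seq_len(n), function(i) center + rnorm(512, 0, 0.05),
             numeric(512)))
  }
  c1 <- rnorm(512); c2 <- rnorm(512)
  x <- rbind(mk(c1, 50), mk(c2, 50))
  lab <- rep(1:2, each = 50)
  vi <- c(1:10, 51:60)
  ts <- train_spec(max_epochs = 40L, patience = 10L, seed = 4L)
  red <- train_reducer(x[-vi, ], lab[-vi], x[vi, ], lab[vi], tspec = ts)
  expect_gte(red$best_map_at_r, 0.9)
  # nearest-neighbour label accuracy in the reduced space
  z <- reduce_features(x[vi, ], red)
  d <- as.matrix(dist(z))
  diag(d) <- Inf
  nn <- apply(d, 1, which.min)
  expect_gt(mean(lab[vi][nn] == lab[vi]), 0.9)
  # determinism and batch-vs-single consistency
  red2 <- train_reducer(x[-vi, ], lab[-vi], x[vi, ], lab[vi], tspec = ts)
  expect_identical(reduce_features(x[vi, ], red),
                   reduce_features(x[vi, ], red2))
  single <- t(vapply(vi, function(i) reduce_features(x[i, ], red),
                     numeric(2)))
  expect_equal(single, z, tolerance = 1e-6, ignore_attr = TRUE)
})

test_that("early stopping fires after the patience window when the metric
           is flat", {
  set.seed(2)
  x <- matrix(rnorm(40 * 512), 40, 512)
  lab <- rep(1L, 40)                # single label: no triplets, no updates
  ts <- train_spec(max_epochs = 100L, patience = 20L, seed = 1L)
  red <- train_reducer(x, lab, x[1:10, ], lab[1:10], tspec = ts)
  expect_equal(red$epochs_run, 21L)
  expect_equal(red$best_epoch, 1L)
})
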