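# Contrastive metric learning of the 512 -> 2 reducer.
#
# Architecture: 512-256-128-128-64-64-32-32-16-2 MLP, ReLU on hidden
# layers, batch normalization on hidden layers 1-2, dropout 0.2 on hidden
# layers 1, 2 and 4.  Trained with triplet loss (margin 0.1) on grid-label
# positives, pairs picked by multi-similarity mining (epsilon 0.2) in the
# current reduced space, and triplets whose anchor-negative similarity
# exceeds the anchor-positive similarity in the *source* latent space
# excluded from the loss.  Early stopping tracks validation MAP@R.

#' Grid label for a parameter pair
#'
#' The parameter box is divided into an `n_grid` x `n_grid` lattice of
#' cells; parameters in the same cell are positives for each other.
#' Exact upper-boundary values clamp to the last index.
#'
#' @param f_v,g_v parameter values inside the closed box.
#' @param box c(lo, hi) for both axes.
#' @param n_grid cells per axis (default 10).
#' @return list(i, j, id): 0-based cell indices and a 1-based scalar id.
#' @export
assign_grid_label <- function(f_v, g_v, box = c(0.6, 1.0), n_grid = 10L) {
  if (any(f_v < box[1] - 1e-12) || any(f_v > box[2] + 1e-12) ||
      any(g_v < box[1] - 1e-12) || any(g_v > box[2] + 1e-12)) {
    stop("parameters outside the grid box")
  }
  w <- (box[2] - box[1]) / n_grid
  i <- clamp(floor((f_v - box[1]) / w), 0, n_grid - 1L)
  j <- clamp(floor((g_v - box[1]) / w), 0, n_grid - 1L)
  list(i = as.integer(i), j = as.integer(j),
       id = as.integer(i * n_grid + j + 1L))
}

#' Reducer training conditions
#'
#' @param batch_size,learning_rate,weight_decay,margin,epsilon,max_epochs,patience
#'   training hyperparameters (defaults: 32, 1e-3, 1e-3, 0.1, 0.2, 100, 20).
#' @param seed RNG seed controlling initialization, batching and dropout.
#' @export
train_spec <- function(batch_size = 32L, learning_rate = 0.001,
                       weight_decay = 0.001, margin = 0.1, epsilon = 0.2,
                       max_epochs = 100L, patience = 20L, seed = 1L) {
  structure(list(batch_size = as.integer(batch_size),
                 learning_rate = learning_rate,
                 weight_decay = weight_decay, margin = margin,
                 epsilon = epsilon, max_epochs = as.integer(max_epochs),
                 patience = as.integer(patience), seed = as.integer(seed)),
            class = "train_spec")
}

# ---- MLP core -------------------------------------------------------------

reducer_widths <- function() c(512L, 256L, 128L, 128L, 64L, 64L, 32L, 32L, 16L, 2L)
reducer_bn_layers <- function() c(1L, 2L)       # hidden layers with batch norm
reducer_dropout_layers <- function() c(1L, 2L, 4L)

mlp_init <- function(widths = reducer_widths(), seed = 1L) {
  nlay <- length(widths) - 1L
  with_seed(seed, {
    layers <- vector("list", nlay)
    for (l in seq_len(nlay)) {
      fan_in <- widths[l]
      W <- matrix(rnorm(fan_in * widths[l + 1L]) * sqrt(2 / fan_in),
                  fan_in, widths[l + 1L])
      layers[[l]] <- list(W = W, b = numeric(widths[l + 1L]))
      if (l %in% reducer_bn_layers()) {
        layers[[l]]$bn <- list(gamma = rep(1, widths[l + 1L]),
                               beta = numeric(widths[l + 1L]),
                               rmean = numeric(widths[l + 1L]),
                               rvar = rep(1, widths[l + 1L]))
      }
    }
    structure(list(layers = layers, widths = widths, trained = FALSE),
              class = "pattern_reducer")
  })
}

# Forward pass.  training=TRUE uses batch statistics + dropout (masks drawn
# from the current RNG stream); returns caches for backprop.
mlp_forward <- function(model, x, training = FALSE, dropout_p = 0.2) {
  nlay <- length(model$layers)
  caches <- vector("list", nlay)
  h <- x
  eps <- 1e-5
  for (l in seq_len(nlay)) {
    ly <- model$layers[[l]]
    z <- sweep(h %*% ly$W, 2, ly$b, "+")
    cache <- list(x = h)
    if (!is.null(ly$bn)) {
      if (training) {
        mu <- colMeans(z)
        zc <- sweep(z, 2, mu)
        va <- colMeans(zc^2)
        xhat <- sweep(zc, 2, sqrt(va + eps), "/")
        cache$bn <- list(xhat = xhat, inv_sd = 1 / sqrt(va + eps),
                         mu = mu, va = va)
      } else {
        xhat <- sweep(sweep(z, 2, ly$bn$rmean), 2,
                      sqrt(ly$bn$rvar + eps), "/")
      }
      z <- sweep(sweep(xhat, 2, ly$bn$gamma, "*"), 2, ly$bn$beta, "+")
    }
    if (l < nlay) {                       # hidden layer: ReLU (+ dropout)
      a <- pmax(z, 0)
      cache$relu_mask <- z > 0
      if (training && l %in% reducer_dropout_layers() && dropout_p > 0) {
        mask <- matrix(runif(length(a)) >= dropout_p, nrow(a), ncol(a)) /
          (1 - dropout_p)
        a <- a * mask
        cache$drop_mask <- mask
      }
      h <- a
    } else {
      h <- z
    }
    caches[[l]] <- cache
  }
  list(out = h, caches = caches)
}

# Backward pass: returns per-layer gradients.
mlp_backward <- function(model, caches, dout) {
  nlay <- length(model$layers)
  grads <- vector("list", nlay)
  g <- dout
  for (l in rev(seq_len(nlay))) {
    ly <- model$layers[[l]]
    cache <- caches[[l]]
    if (l < nlay) {
      if (!is.null(cache$drop_mask)) g <- g * cache$drop_mask
      g <- g * cache$relu_mask
    }
    gr <- list()
    if (!is.null(ly$bn)) {
      bn <- cache$bn
      gr$dgamma <- colSums(g * bn$xhat)
      gr$dbeta <- colSums(g)
      m <- nrow(g)
      gy <- sweep(g, 2, ly$bn$gamma, "*")
      g <- sweep(gy - matrix(colMeans(gy), m, ncol(g), byrow = TRUE) -
                   bn$xhat * matrix(colMeans(gy * bn$xhat), m, ncol(g),
                                    byrow = TRUE),
                 2, bn$inv_sd, "*")
    }
    gr$dW <- crossprod(cache$x, g)
    gr$db <- colSums(g)
    grads[[l]] <- gr
    if (l > 1L) g <- g %*% t(ly$W)
  }
  grads
}

# Update batch-norm running statistics (PyTorch momentum convention).
mlp_update_running <- function(model, caches, momentum = 0.1) {
  for (l in seq_along(model$layers)) {
    bnc <- caches[[l]]$bn
    if (!is.null(bnc)) {
      m <- length(caches[[l]]$relu_mask) / length(bnc$mu)
      unbiased <- bnc$va * m / max(m - 1, 1)
      model$layers[[l]]$bn$rmean <-
        (1 - momentum) * model$layers[[l]]$bn$rmean + momentum * bnc$mu
      model$layers[[l]]$bn$rvar <-
        (1 - momentum) * model$layers[[l]]$bn$rvar + momentum * unbiased
    }
  }
  model
}

adam_init <- function(model) {
  lapply(model$layers, function(ly) {
    s <- list(mW = ly$W * 0, vW = ly$W * 0, mb = ly$b * 0, vb = ly$b * 0)
    if (!is.null(ly$bn)) {
      s$mg <- ly$bn$gamma * 0; s$vg <- s$mg
      s$mbt <- s$mg; s$vbt <- s$mg
    }
    s
  })
}

adam_step <- function(model, grads, state, t, lr, wd,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  corr1 <- 1 - beta1^t
  corr2 <- 1 - beta2^t
  upd <- function(p, g, m, v) {
    g <- g + wd * p                      # L2-coupled weight decay
    m <- beta1 * m + (1 - beta1) * g
    v <- beta2 * v + (1 - beta2) * g^2
    p <- p - lr * (m / corr1) / (sqrt(v / corr2) + eps)
    list(p = p, m = m, v = v)
  }
  for (l in seq_along(model$layers)) {
    r <- upd(model$layers[[l]]$W, grads[[l]]$dW, state[[l]]$mW, state[[l]]$vW)
    model$layers[[l]]$W <- r$p; state[[l]]$mW <- r$m; state[[l]]$vW <- r$v
    r <- upd(model$layers[[l]]$b, grads[[l]]$db, state[[l]]$mb, state[[l]]$vb)
    model$layers[[l]]$b <- r$p; state[[l]]$mb <- r$m; state[[l]]$vb <- r$v
    if (!is.null(model$layers[[l]]$bn)) {
      r <- upd(model$layers[[l]]$bn$gamma, grads[[l]]$dgamma,
               state[[l]]$mg, state[[l]]$vg)
      model$layers[[l]]$bn$gamma <- r$p; state[[l]]$mg <- r$m
      state[[l]]$vg <- r$v
      r <- upd(model$layers[[l]]$bn$beta, grads[[l]]$dbeta,
               state[[l]]$mbt, state[[l]]$vbt)
      model$layers[[l]]$bn$beta <- r$p; state[[l]]$mbt <- r$m
      state[[l]]$vbt <- r$v
    }
  }
  list(model = model, state = state)
}

# ---- mining and loss ------------------------------------------------------

#' Triplet margin loss
#'
#' `max(0, d(a,p) - d(a,n) + margin)` with Euclidean distance.
#'
#' @param anchor,positive,negative reduced feature vectors.
#' @param margin nonnegative margin.
#' @return the loss value (>= 0).
#' @export
triplet_loss <- function(anchor, positive, negative, margin = 0.1) {
  stopifnot(margin >= 0)
  dap <- sqrt(sum((anchor - positive)^2))
  dan <- sqrt(sum((anchor - negative)^2))
  max(0, dap - dan + margin)
}

#' Mine triplets with multi-similarity selection and latent-space exclusion
#'
#' Pair selection follows multi-similarity mining with parameter `epsilon`
#' on cosine similarities in the current reduced space: for each anchor, a
#' negative is kept when `sim(a,n) > min_p sim(a,p) - epsilon` and a
#' positive when `sim(a,p) < max_n sim(a,n) + epsilon`.  Kept positives and
#' negatives of an anchor are combined into triplets, and any triplet whose
#' anchor-negative cosine similarity in the *source* latent space strictly
#' exceeds its anchor-positive similarity is excluded.
#'
#' @param reduced N x d matrix of current reduced features.
#' @param labels integer grid-label ids (length N).
#' @param latent_sims N x N cosine-similarity matrix in the source (CLIP or
#'   fallback) latent space, used only for the exclusion rule.
#' @param epsilon mining band width.
#' @return integer matrix with columns a, p, n (possibly 0 rows).
#' @export
mine_triplets <- function(reduced, labels, latent_sims, epsilon = 0.2) {
  n <- length(labels)
  if (n < 2L) return(matrix(integer(0), 0, 3, dimnames = list(NULL, c("a", "p", "n"))))
  nv <- sqrt(rowSums(reduced^2))
  nv[nv < 1e-12] <- 1e-12
  sims <- (reduced %*% t(reduced)) / outer(nv, nv)
  out <- vector("list", n)
  for (a in seq_len(n)) {
    pos <- which(labels == labels[a])
    pos <- pos[pos != a]
    neg <- which(labels != labels[a])
    if (!length(pos) || !length(neg)) next
    keep_n <- neg[sims[a, neg] > min(sims[a, pos]) - epsilon]
    keep_p <- pos[sims[a, pos] < max(sims[a, neg]) + epsilon]
    if (!length(keep_p) || !length(keep_n)) next
    tri <- expand.grid(p = keep_p, n = keep_n, KEEP.OUT.ATTRS = FALSE)
    ok <- !(latent_sims[cbind(a, tri$n)] > latent_sims[cbind(a, tri$p)])
    tri <- tri[ok, , drop = FALSE]
    if (nrow(tri)) {
      out[[a]] <- cbind(a = a, p = tri$p, n = tri$n)
    }
  }
  out <- out[!vapply(out, is.null, logical(1))]
  if (!length(out)) {
    return(matrix(integer(0), 0, 3, dimnames = list(NULL, c("a", "p", "n"))))
  }
  res <- do.call(rbind, out)
  colnames(res) <- c("a", "p", "n")
  res
}

# Mean triplet loss over mined triplets plus gradient wrt reduced features.
triplet_loss_grad <- function(z, triplets, margin) {
  nt <- nrow(triplets)
  dz <- z * 0
  if (nt == 0L) return(list(loss = 0, dz = dz, active = 0L))
  da <- z[triplets[, "a"], , drop = FALSE] - z[triplets[, "p"], , drop = FALSE]
  dn <- z[triplets[, "a"], , drop = FALSE] - z[triplets[, "n"], , drop = FALSE]
  dap <- sqrt(rowSums(da^2) + 1e-16)
  dan <- sqrt(rowSums(dn^2) + 1e-16)
  viol <- dap - dan + margin
  act <- viol > 0
  loss <- mean(pmax(viol, 0))
  if (!any(act)) return(list(loss = loss, dz = dz, active = 0L))
  w <- 1 / nt
  ga <- (da[act, , drop = FALSE] / dap[act]) - (dn[act, , drop = FALSE] / dan[act])
  gp <- -da[act, , drop = FALSE] / dap[act]
  gn <- dn[act, , drop = FALSE] / dan[act]
  ia <- triplets[act, "a"]; ip <- triplets[act, "p"]; in_ <- triplets[act, "n"]
  for (r in seq_along(ia)) {
    dz[ia[r], ] <- dz[ia[r], ] + w * ga[r, ]
    dz[ip[r], ] <- dz[ip[r], ] + w * gp[r, ]
    dz[in_[r], ] <- dz[in_[r], ] + w * gn[r, ]
  }
  list(loss = loss, dz = dz, active = sum(act))
}

#' MAP@R retrieval score in a feature space
#'
#' For each query, `R` is the number of other samples sharing its label;
#' the score is the average precision over the `R` nearest neighbours
#' (Euclidean), averaged over queries with `R >= 1`.
#'
#' @param feats N x d feature matrix.
#' @param labels integer labels (length N).
#' @return MAP@R in \[0, 1\].
#' @export
map_at_r <- function(feats, labels) {
  n <- length(labels)
  d2 <- as.matrix(stats::dist(feats))^2
  scores <- numeric(0)
  for (q in seq_len(n)) {
    same <- labels == labels[q]
    R <- sum(same) - 1L
    if (R < 1L) next
    ord <- order(d2[q, -q])
    neigh_labels <- labels[-q][ord][seq_len(R)]
    hit <- neigh_labels == labels[q]
    if (!any(hit)) {
      scores <- c(scores, 0)
    } else {
      hp <- which(hit)
      scores <- c(scores, sum(cumsum(hit)[hp] / hp) / R)
    }
  }
  if (!length(scores)) return(NA_real_)
  mean(scores)
}

# ---- training -------------------------------------------------------------

#' Train the 512 -> 2 contrastive reducer
#'
#' @param train_x N x 512 matrix of latent vectors.
#' @param train_labels integer grid-label ids for the training rows.
#' @param val_x,val_labels validation split (disjoint from training).
#' @param tspec a [train_spec()].
#' @param verbose print per-epoch progress.
#' @return a trained `pattern_reducer` (checkpoint with the best validation
#'   MAP@R; fields `best_map_at_r`, `epochs_run`, `history`).
#' @export
train_reducer <- function(train_x, train_labels, val_x, val_labels,
                          tspec = train_spec(), verbose = FALSE) {
  stopifnot(nrow(train_x) == length(train_labels),
            nrow(val_x) == length(val_labels))
  if (nrow(train_x) == 0L) stop("empty training set")
  model <- mlp_init(seed = tspec$seed)
  state <- adam_init(model)
  # latent-space cosine similarities for the exclusion rule
  nv <- sqrt(rowSums(train_x^2)); nv[nv < 1e-12] <- 1e-12
  xn <- train_x / nv
  best <- list(map = -Inf, model = model, epoch = 0L)
  t_adam <- 0L
  hist <- numeric(0)
  with_seed(tspec$seed + 1L, {
    for (epoch in seq_len(tspec$max_epochs)) {
      ord <- sample(nrow(train_x))
      nb <- ceiling(length(ord) / tspec$batch_size)
      for (b in seq_len(nb)) {
        idx <- ord[((b - 1L) * tspec$batch_size + 1L):
                     min(b * tspec$batch_size, length(ord))]
        if (length(idx) < 3L) next
        fw <- mlp_forward(model, train_x[idx, , drop = FALSE],
                          training = TRUE)
        lsims <- xn[idx, , drop = FALSE] %*% t(xn[idx, , drop = FALSE])
        tri <- mine_triplets(fw$out, train_labels[idx], lsims,
                             epsilon = tspec$epsilon)
        model <- mlp_update_running(model, fw$caches)
        lg <- triplet_loss_grad(fw$out, tri, tspec$margin)
        if (lg$active == 0L) next
        grads <- mlp_backward(model, fw$caches, lg$dz)
        t_adam <- t_adam + 1L
        st <- adam_step(model, grads, state, t_adam,
                        tspec$learning_rate, tspec$weight_decay)
        model <- st$model
        state <- st$state
      }
      zval <- mlp_forward(model, val_x, training = FALSE)$out
      m <- map_at_r(zval, val_labels)
      hist <- c(hist, m)
      if (verbose) {
        message(sprintf("epoch %3d  val MAP@R %.4f", epoch, m))
      }
      if (is.finite(m) && m > best$map) {
        best <- list(map = m, model = model, epoch = epoch)
      }
      if (epoch - best$epoch >= tspec$patience) break
    }
  })
  out <- best$model
  out$trained <- TRUE
  out$best_map_at_r <- best$map
  out$best_epoch <- best$epoch
  out$epochs_run <- length(hist)
  out$history <- hist
  out$tspec <- tspec
  out
}

#' Reduce latent vectors to 2-d features
#'
#' Inference mode: dropout off, batch normalization uses running statistics.
#'
#' @param x a length-512 vector or N x 512 matrix.
#' @param model a trained `pattern_reducer`.
#' @return N x 2 matrix (or length-2 vector for vector input).
#' @export
reduce_features <- function(x, model) {
  stopifnot(inherits(model, "pattern_reducer"))
  if (!isTRUE(model$trained)) stop("untrained reducer model")
  vec <- is.null(dim(x))
  if (vec) x <- matrix(x, 1)
  out <- mlp_forward(model, x, training = FALSE)$out
  if (vec) as.numeric(out) else out
}

#' Layer widths of a reducer (introspection)
#'
#' @param model a `pattern_reducer`.
#' @return integer vector of layer widths including input and output.
#' @export
reducer_shape <- function(model) {
  c(nrow(model$layers[[1]]$W),
    vapply(model$layers, function(l) ncol(l$W), integer(1)))
}
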