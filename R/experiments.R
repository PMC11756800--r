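# End-to-end estimation experiments: dataset bundle construction, SD-NPE
# model fitting, posterior estimation for image groups, synthetic-truth
# recovery, and the three-way dimensionality-reduction comparison.

#' Build an estimation experiment bundle
#'
#' Generates the Turing estimation dataset (manifest, simulated images,
#' latent vectors, grid labels) at a chosen problem size.  This is the
#' expensive, shareable part of every estimation experiment.
#'
#' @param n_train,n_val dataset sizes.
#' @param size image side length.
#' @param dt,steps Turing integration settings.
#' @param seed dataset seed.
#' @param blur_sigma preprocessing blur before encoding.
#' @param box parameter box.
#' @param progress print progress dots while simulating.
#' @return list(manifest, train_x, val_x, train_labels (n x 2 matrix),
#'   val_labels, train_grid, val_grid, box, encoder_spec, blur_sigma).
#' @export
build_estimation_bundle <- function(n_train = 2000L, n_val = 300L,
                                    size = 48L, dt = 0.2, steps = 2000L,
                                    seed = 1L, blur_sigma = 1.5,
                                    box = c(0.6, 1.0), progress = FALSE) {
  manifest <- build_estimation_dataset(n_train = n_train, n_val = n_val,
                                       box = box, seed = seed, size = size,
                                       dt = dt, steps = steps)
  images <- render_estimation_images(manifest, progress = progress)
  spec <- encoder_spec("spectral_fallback", input_size = size)
  store <- encode_dataset(manifest, spec, images = images,
                          blur_sigma = blur_sigma)
  tr <- manifest$split == "train"
  grid <- assign_grid_label(manifest$f_v, manifest$g_v, box = box)
  list(manifest = manifest,
       train_x = store$vectors[tr, , drop = FALSE],
       val_x = store$vectors[!tr, , drop = FALSE],
       train_labels = cbind(manifest$f_v, manifest$g_v)[tr, , drop = FALSE],
       val_labels = cbind(manifest$f_v, manifest$g_v)[!tr, , drop = FALSE],
       train_grid = grid$id[tr], val_grid = grid$id[!tr],
       box = box, encoder_spec = spec, blur_sigma = blur_sigma,
       size = size, dt = dt, steps = steps, seed = seed)
}

#' Fit the full SD-NPE estimation model on a bundle
#'
#' Trains the contrastive reducer, the probabilistic regressor on the
#' reduced features, and the Monte-Carlo prior.
#'
#' @param bundle a [build_estimation_bundle()] result.
#' @param tspec reducer training conditions ([train_spec()]).
#' @param rspec regressor conditions ([regressor_spec()]); the default
#'   enables validation-based stage selection, which keeps the predictive
#'   covariance calibrated (overconfident per-image posteriors are
#'   amplified by the multi-image product).
#' @param lattice parameter lattice for prior/posterior work.
#' @param seed seed for regressor fitting.
#' @return list(reducer, regressor, prior, lattice, bundle_meta).
#' @export
fit_sdnpe <- function(bundle, tspec = train_spec(),
                      rspec = regressor_spec(valid_fraction = 0.15),
                      lattice = parameter_lattice(), seed = 1L) {
  reducer <- train_reducer(bundle$train_x, bundle$train_grid,
                           bundle$val_x, bundle$val_grid, tspec = tspec)
  ztr <- reduce_features(bundle$train_x, reducer)
  regressor <- train_regressor(ztr, bundle$train_labels, spec = rspec,
                               seed = derive_seed(seed, "sdnpe_ngb"))
  prior <- estimate_prior(regressor, ztr, lattice)
  list(reducer = reducer, regressor = regressor, prior = prior,
       lattice = lattice,
       bundle_meta = bundle[c("size", "dt", "steps", "blur_sigma", "box")])
}

#' Posterior for a group of target images
#'
#' Blurs and encodes each image, reduces, predicts per-image posteriors,
#' and integrates them with the model's prior.
#'
#' @param model a [fit_sdnpe()] result.
#' @param images list of target images (raw \[0,1\] matrices).
#' @param spec encoder spec (defaults to the bundle's input size).
#' @return an `integrated_posterior`.
#' @export
estimate_parameters <- function(model, images,
                                spec = encoder_spec(
                                  input_size = model$bundle_meta$size)) {
  emb <- t(vapply(images, function(im) {
    img <- if (model$bundle_meta$blur_sigma > 0) {
      blur(im, model$bundle_meta$blur_sigma)
    } else im
    encode(img, spec)
  }, numeric(PF_EMBED_DIM)))
  z <- reduce_features(emb, model$reducer)
  sp <- predict_sample_posterior(model$regressor, z)
  if (inherits(sp, "sample_posterior")) sp <- list(sp)
  integrate_posteriors(sp, model$prior, model$lattice)
}

# Simulate a group of target images for one truth.
simulate_target_group <- function(f_v, g_v, n_images, size, dt, steps,
                                  seed) {
  lapply(seq_len(n_images), function(i) {
    normalize_field(simulate_turing(turing_params(f_v, g_v), size = size,
                                    dt = dt, steps = steps,
                                    seed = derive_seed(seed, paste0("tg", i))))
  })
}

#' Synthetic-truth recovery experiment
#'
#' Draws truths uniformly in the box, simulates `images_per_truth` target
#' images per truth, runs SD-NPE, and checks whether each truth lies in the
#' `level`-HPD region of its integrated posterior.
#'
#' @param model a [fit_sdnpe()] result.
#' @param n_truths number of synthetic truths.
#' @param images_per_truth target images per truth (default 20).
#' @param seed experiment seed.
#' @param level HPD mass (default 0.95).
#' @param keep_posteriors also return the integrated posteriors.
#' @param keep_embeddings also return the per-group latent vectors (for
#'   reuse by [run_reduction_comparison()]).
#' @return list(coverage, hits (logical), truths (n x 2), posteriors?,
#'   emb_groups?).
#' @export
run_turing_recovery <- function(model, n_truths = 40L,
                                images_per_truth = 20L, seed = 1L,
                                level = 0.95, keep_posteriors = FALSE,
                                keep_embeddings = FALSE) {
  box <- model$bundle_meta$box
  truths <- with_seed(derive_seed(seed, "truths"),
                      cbind(runif(n_truths, box[1], box[2]),
                            runif(n_truths, box[1], box[2])))
  hits <- logical(n_truths)
  posts <- if (keep_posteriors) vector("list", n_truths) else NULL
  embs <- if (keep_embeddings) vector("list", n_truths) else NULL
  spec <- encoder_spec(input_size = model$bundle_meta$size)
  for (i in seq_len(n_truths)) {
    imgs <- simulate_target_group(truths[i, 1], truths[i, 2],
                                  images_per_truth,
                                  model$bundle_meta$size,
                                  model$bundle_meta$dt,
                                  model$bundle_meta$steps,
                                  derive_seed(seed, paste0("truth", i)))
    emb <- t(vapply(imgs, function(im) {
      encode(blur(im, model$bundle_meta$blur_sigma), spec)
    }, numeric(PF_EMBED_DIM)))
    z <- reduce_features(emb, model$reducer)
    sp <- predict_sample_posterior(model$regressor, z)
    if (inherits(sp, "sample_posterior")) sp <- list(sp)
    post <- integrate_posteriors(sp, model$prior, model$lattice)
    hits[i] <- hpd_contains(post, truths[i, ], level = level)
    if (keep_posteriors) posts[[i]] <- post
    if (keep_embeddings) embs[[i]] <- emb
  }
  out <- list(coverage = mean(hits), hits = hits, truths = truths)
  if (keep_posteriors) out$posteriors <- posts
  if (keep_embeddings) out$emb_groups <- embs
  out
}

#' Three-way dimensionality-reduction comparison
#'
#' Compares the generalization error (negative mean log posterior density
#' at the truth) of SD-NPE built on (a) the contrastive reducer, (b) a
#' UMAP projection, and (c) the raw latent vectors, across training seeds.
#' Test groups (truth + image-group embeddings) are shared by all arms.
#'
#' @param bundle a [build_estimation_bundle()] result.
#' @param n_truths test groups.
#' @param images_per_truth images per group.
#' @param seeds vector of training seeds.
#' @param tspec reducer training spec (seed field is overridden per run).
#' @param rspec regressor spec.
#' @param lattice parameter lattice.
#' @param arms which arms to run.
#' @param seed experiment seed (truths + target images).
#' @param truths,emb_groups optional precomputed truth matrix and
#'   per-group latent vectors (e.g. from [run_turing_recovery()] with
#'   `keep_embeddings = TRUE`); when supplied, no new simulation runs.
#' @param reducers optional list of pre-trained reducers, one per seed
#'   (position-matched to `seeds`), reused by the contrastive arm.
#' @param verbose print arm/seed progress.
#' @return list(errors: matrix arms x seeds, mean_errors, truths).
#' @export
run_reduction_comparison <- function(bundle, n_truths = 40L,
                                     images_per_truth = 20L,
                                     seeds = 1:3,
                                     tspec = train_spec(),
                                     rspec = regressor_spec(),
                                     lattice = parameter_lattice(),
                                     arms = c("contrastive", "umap", "none"),
                                     seed = 1L, truths = NULL,
                                     emb_groups = NULL, reducers = NULL,
                                     verbose = FALSE) {
  box <- bundle$box
  if (is.null(truths)) {
    truths <- with_seed(derive_seed(seed, "cmp_truths"),
                        cbind(runif(n_truths, box[1], box[2]),
                              runif(n_truths, box[1], box[2])))
  }
  n_truths <- nrow(truths)
  if (is.null(emb_groups)) {
    # shared target-group embeddings
    emb_groups <- lapply(seq_len(n_truths), function(i) {
      imgs <- simulate_target_group(truths[i, 1], truths[i, 2],
                                    images_per_truth, bundle$size,
                                    bundle$dt, bundle$steps,
                                    derive_seed(seed, paste0("cmp_truth", i)))
      t(vapply(imgs, function(im) {
        encode(blur(im, bundle$blur_sigma), bundle$encoder_spec)
      }, numeric(PF_EMBED_DIM)))
    })
  }
  eval_arm <- function(feat_train, feat_groups, run_seed) {
    reg <- train_regressor(feat_train, bundle$train_labels, spec = rspec,
                           seed = run_seed)
    prior <- estimate_prior(reg, feat_train, lattice)
    posts <- lapply(feat_groups, function(fg) {
      sp <- predict_sample_posterior(reg, fg)
      if (inherits(sp, "sample_posterior")) sp <- list(sp)
      integrate_posteriors(sp, prior, lattice)
    })
    generalization_error(posts, truths)$value
  }
  errors <- matrix(NA_real_, length(arms), length(seeds),
                   dimnames = list(arms, paste0("seed", seeds)))
  for (si in seq_along(seeds)) {
    s <- seeds[si]
    if ("contrastive" %in% arms) {
      red <- if (!is.null(reducers) && length(reducers) >= si &&
                 !is.null(reducers[[si]])) {
        reducers[[si]]
      } else {
        ts <- tspec
        ts$seed <- as.integer(s)
        train_reducer(bundle$train_x, bundle$train_grid,
                      bundle$val_x, bundle$val_grid, tspec = ts)
      }
      ztr <- reduce_features(bundle$train_x, red)
      zg <- lapply(emb_groups, function(e) reduce_features(e, red))
      errors["contrastive", si] <- eval_arm(ztr, zg, s)
      if (verbose) message("contrastive seed ", s, ": ",
                           round(errors["contrastive", si], 3))
    }
    if ("umap" %in% arms) {
      stacked <- do.call(rbind, emb_groups)
      up <- umap_project(bundle$train_x, new_x = list(stacked), seed = s)
      idx <- cumsum(vapply(emb_groups, nrow, integer(1)))
      starts <- c(1L, utils::head(idx, -1) + 1L)
      zg <- lapply(seq_along(emb_groups), function(i) {
        up$new[[1]][starts[i]:idx[i], , drop = FALSE]
      })
      errors["umap", si] <- eval_arm(up$train, zg, s)
      if (verbose) message("umap seed ", s, ": ",
                           round(errors["umap", si], 3))
    }
    if ("none" %in% arms) {
      # the raw-latent arm has no stochastic training step, so one fit
      # serves every seed column
      if (si == 1L || rspec$valid_fraction > 0) {
        errors["none", si] <- eval_arm(bundle$train_x, emb_groups, s)
      } else {
        errors["none", si] <- errors["none", 1L]
      }
      if (verbose) message("none seed ", s, ": ",
                           round(errors["none", si], 3))
    }
  }
  list(errors = errors, mean_errors = rowMeans(errors), truths = truths)
}
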