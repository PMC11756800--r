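# Image -> 512-d latent vectors.  Two encoders share one interface:
#  * "clip_vit_b32": adapter for a frozen zero-shot CLIP ViT-B/32 image
#    encoder.  Weights are not bundled; selecting it without a configured
#    backend raises an explicit error (never a silent substitution).
#  * "spectral_fallback": a deterministic, dependency-free encoder built
#    from rotation-aware spectral statistics, projected to 512 dimensions.
#    It is the default for all offline work and tests.

PF_EMBED_DIM <- 512L

#' Encoder specification
#'
#' @param name "spectral_fallback" (deterministic, offline) or
#'   "clip_vit_b32" (external zero-shot CLIP adapter).
#' @param input_size encoder-native input side length.
#' @return object of class `encoder_spec`.
#' @export
encoder_spec <- function(name = c("spectral_fallback", "clip_vit_b32"),
                         input_size = 128L) {
  name <- match.arg(name)
  structure(list(name = name, deterministic = TRUE,
                 input_size = as.integer(input_size)),
            class = "encoder_spec")
}

# Fixed random projection from the raw feature blocks to 512 dimensions.
# Seeded once; cached for the session.
pf_env <- new.env(parent = emptyenv())

projection_matrix <- function(d_in) {
  key <- paste0("proj_", d_in)
  if (is.null(pf_env[[key]])) {
    pf_env[[key]] <- with_seed(791031L,
      matrix(rnorm(d_in * PF_EMBED_DIM) / sqrt(d_in), d_in, PF_EMBED_DIM))
  }
  pf_env[[key]]
}

block_norm <- function(x) {
  n <- sqrt(sum(x^2))
  if (n < 1e-12) x else x / n
}

#' Spectral fallback features of a pattern image
#'
#' Concatenates (a) a 64-bin radially averaged log power spectrum computed
#' on a zero-padded FFT (padding sharpens the localization of the spectral
#' peak well below the raw bin width), (b) a 16-bin gradient-orientation
#' energy histogram, (c) a 32-bin intensity histogram and (d) eight
#' spectral summary statistics (interpolated peak wavenumber, centroid,
#' spread, quartiles, peak sharpness), maps the 120 raw features to 512
#' dimensions by a fixed seeded random projection, and L2-normalizes.
#'
#' @param image square numeric matrix in \[0,1\].
#' @return unit-norm numeric vector of length 512.
#' @export
spectral_fallback_features <- function(image) {
  stopifnot(is.matrix(image), nrow(image) == ncol(image))
  n <- nrow(image)
  # (a) radial log-spectrum on a zero-padded transform, 64 bins over
  # (0, Nyquist]
  pad <- max(128L, n)
  big <- matrix(0, pad, pad)
  big[seq_len(n), seq_len(n)] <- image - mean(image)
  sp <- radial_power_spectrum(big, demean = FALSE)
  pos <- sp$radius > 0
  ptot <- sum(sp$power[pos])
  p <- sp$power[pos] / max(ptot, 1e-300)
  kk <- 2 * pi * sp$radius[pos] / pad              # physical wavenumber
  rel <- sp$radius[pos] / (pad %/% 2)              # (0, 1]
  bin <- clamp(ceiling(rel * 64), 1, 64)
  spec64 <- vapply(1:64, function(b) {
    i <- bin == b
    if (any(i)) mean(p[i]) else 0
  }, numeric(1))
  spec64 <- log10(spec64 + 1e-8)
  spec64 <- spec64 - mean(spec64)                  # centred log power
  # (d) spectral summaries: interpolated peak, moments, quartiles
  imax <- which.max(p)
  kpk <- kk[imax]
  if (imax > 1 && imax < length(p)) {              # quadratic refinement
    y1 <- p[imax - 1]; y2 <- p[imax]; y3 <- p[imax + 1]
    den <- y1 - 2 * y2 + y3
    if (abs(den) > 1e-300) {
      kpk <- kk[imax] + 0.5 * (y1 - y3) / den * (kk[2] - kk[1])
    }
  }
  m1 <- sum(kk * p)
  m2 <- sqrt(max(sum((kk - m1)^2 * p), 0))
  qs <- cumsum(p)
  kq <- tryCatch(stats::approx(qs, kk, xout = c(0.25, 0.5, 0.75),
                               ties = "ordered")$y,
                 error = function(e) rep(m1, 3))
  kq[is.na(kq)] <- m1
  sharp <- p[imax]
  summ8 <- c(kpk, m1, m2, kq, sharp, log10(ptot + 1e-12)) / 4
  if (ptot < 1e-20) {
    spec64[] <- 0
    summ8[] <- 0
  }
  # (b) gradient-orientation energy histogram (orientation mod pi)
  gx <- image[c(2:n, 1), ] - image[c(n, 1:(n - 1)), ]
  gy <- image[, c(2:n, 1)] - image[, c(n, 1:(n - 1))]
  mag2 <- gx^2 + gy^2
  th <- atan2(gy, gx) %% pi
  ob <- clamp(floor(th / pi * 16) + 1, 1, 16)
  ori16 <- vapply(1:16, function(b) sum(mag2[ob == b]), numeric(1))
  ori16 <- ori16 / max(sum(ori16), 1e-300)
  ori16 <- ori16 - mean(ori16)     # anisotropy only; isotropic images ~ 0
  # (c) intensity histogram
  ib <- clamp(floor(clamp(image, 0, 1) * 32) + 1, 1, 32)
  int32 <- tabulate(ib, 32) / length(image)
  int32 <- int32 - mean(int32)
  # the centred log-spectrum and the summary block dominate (unit norm);
  # the two centred histogram blocks act as bounded modifiers
  # summ8 keeps its absolute scale (already O(1)): the peak position's
  # absolute value, not its direction, carries the wavelength
  raw <- c(block_norm(spec64), 2 * ori16, int32, summ8)
  v <- as.numeric(raw %*% projection_matrix(length(raw)))
  v / sqrt(sum(v^2))
}

#' Encode one image into the shared 512-d latent space
#'
#' @param image square matrix in \[0,1\], already preprocessed (blurred)
#'   per the pipeline configuration.
#' @param spec an [encoder_spec()].
#' @return numeric vector of length 512.
#' @export
encode <- function(image, spec = encoder_spec()) {
  stopifnot(inherits(spec, "encoder_spec"))
  if (spec$name == "clip_vit_b32") {
    stop("encoder unavailable: the CLIP ViT-B/32 adapter requires an ",
         "external weight backend that is not configured; use ",
         'encoder_spec("spectral_fallback") instead')
  }
  img <- if (nrow(image) != spec$input_size) {
    resize_image(image, spec$input_size)
  } else {
    image
  }
  spectral_fallback_features(img)
}

#' Encode every image of a dataset manifest
#'
#' @param manifest a dataset manifest (see [build_selection_dataset()]);
#'   must carry a `path` column unless `images` is given.
#' @param spec an [encoder_spec()].
#' @param images optional list of in-memory images, row-aligned with the
#'   manifest (skips file I/O).
#' @param blur_sigma Gaussian blur applied before encoding (pixels).
#' @return an `embedding_store`: list(vectors = N x 512 matrix, manifest,
#'   encoder, blur_sigma).
#' @export
encode_dataset <- function(manifest, spec = encoder_spec(), images = NULL,
                           blur_sigma = 1.5) {
  n <- nrow(manifest)
  if (is.null(images)) {
    missing <- manifest$path[!file.exists(manifest$path)]
    if (length(missing)) {
      stop("missing image files (", length(missing), "): ",
           paste(utils::head(missing, 5), collapse = ", "))
    }
  } else {
    stopifnot(length(images) == n)
  }
  vectors <- matrix(NA_real_, n, PF_EMBED_DIM)
  for (i in seq_len(n)) {
    img <- if (is.null(images)) read_image(manifest$path[i]) else images[[i]]
    if (blur_sigma > 0) img <- blur(img, blur_sigma)
    vectors[i, ] <- encode(img, spec)
  }
  structure(list(vectors = vectors, manifest = manifest,
                 encoder = spec$name, blur_sigma = blur_sigma),
            class = "embedding_store")
}

#' Save / load an embedding store
#'
#' The vector array is stored as an RDS archive next to a JSON metadata
#' sidecar (encoder id, row count, manifest columns).
#'
#' @param store an `embedding_store`.
#' @param path base path (".rds" is appended to `path` for the array).
#' @return `save_store`: `path`, invisibly.  `load_store`: the store.
#' @export
save_store <- function(store, path) {
  stopifnot(inherits(store, "embedding_store"))
  saveRDS(store, paste0(path, ".rds"))
  meta <- list(encoder = store$encoder, n = nrow(store$vectors),
               dim = ncol(store$vectors), blur_sigma = store$blur_sigma)
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE)
  invisible(path)
}

#' @rdname save_store
#' @export
load_store <- function(path) {
  readRDS(paste0(path, ".rds"))
}
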