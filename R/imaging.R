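# Field-to-image plumbing: normalization, Gaussian blurring, the center-crop
# series used for scale scanning, and 8-bit grayscale PNG I/O.
# Pattern images are square numeric matrices with intensities in [0,1].

#' Normalize a raw field to a pattern image
#'
#' Min-max scaling to \[0,1\]; a constant field maps to uniform 0.5.
#'
#' @param field finite numeric matrix.
#' @return matrix with values in \[0,1\].
#' @export
normalize_field <- function(field) {
  if (!all(is.finite(field))) stop("field contains non-finite values")
  r <- range(field)
  if (r[2] - r[1] < 1e-300) {
    return(matrix(0.5, nrow(field), ncol(field)))
  }
  (field - r[1]) / (r[2] - r[1])
}

# 1-D Gaussian kernel, truncated at 3 sigma, normalized.
gaussian_kernel_1d <- function(sigma) {
  r <- max(1L, ceiling(3 * sigma))
  x <- (-r):r
  k <- exp(-x^2 / (2 * sigma^2))
  k / sum(k)
}

# Reflective-padding 1-D convolution along matrix rows.
conv_rows_reflect <- function(m, k) {
  r <- (length(k) - 1L) %/% 2L
  n <- nrow(m)
  idx <- c(rev(seq_len(r)), seq_len(n), n + 1 - seq_len(r))  # reflect
  mp <- m[idx, , drop = FALSE]
  out <- matrix(0, n, ncol(m))
  for (i in seq_along(k)) {
    out <- out + k[i] * mp[i:(i + n - 1L), , drop = FALSE]
  }
  out
}

#' Gaussian blur with reflective padding
#'
#' Separable Gaussian low-pass; `sigma = 0` is the identity.  The kernel is
#' normalized, so the spatial mean is preserved.
#'
#' @param image square numeric matrix.
#' @param sigma standard deviation in pixels, `>= 0`.
#' @return blurred matrix.
#' @export
blur <- function(image, sigma = 1.5) {
  if (sigma < 0) stop("sigma must be nonnegative")
  if (sigma == 0) return(image)
  k <- gaussian_kernel_1d(sigma)
  t(conv_rows_reflect(t(conv_rows_reflect(image, k)), k))
}

#' Bilinear resize of a square image
#'
#' @param image numeric matrix.
#' @param size target side length.
#' @return resized matrix.
#' @export
resize_image <- function(image, size) {
  n <- nrow(image)
  m <- ncol(image)
  if (n == size && m == size) return(image)
  # map target pixel centres into source coordinates
  sx <- (seq_len(size) - 0.5) * (n / size) + 0.5 - 1e-9
  sy <- (seq_len(size) - 0.5) * (m / size) + 0.5 - 1e-9
  x0 <- clamp(floor(sx), 1, n); x1 <- clamp(x0 + 1, 1, n)
  y0 <- clamp(floor(sy), 1, m); y1 <- clamp(y0 + 1, 1, m)
  wx <- sx - x0
  wy <- sy - y0
  a <- image[x0, y0, drop = FALSE] * outer(1 - wx, 1 - wy) +
       image[x1, y0, drop = FALSE] * outer(wx, 1 - wy) +
       image[x0, y1, drop = FALSE] * outer(1 - wx, wy) +
       image[x1, y1, drop = FALSE] * outer(wx, wy)
  a
}

#' Center-crop series for scale scanning
#'
#' Crops the image center at ratios 0.50, 0.55, ..., 1.00 of the side
#' length and resizes each crop back to `out_size` (default: input size).
#' Odd crop windows round down to even sizes.
#'
#' @param image square numeric matrix.
#' @param out_size side length of the returned images.
#' @return list of `list(ratio=, image=)`, length 11.
#' @export
center_crop_series <- function(image, out_size = nrow(image)) {
  stopifnot(nrow(image) == ncol(image))
  n <- nrow(image)
  ratios <- 0.5 + 0.05 * (0:10)
  lapply(ratios, function(r) {
    w <- floor(n * r)
    if (w %% 2L == 1L) w <- w - 1L
    w <- max(2L, w)
    lo <- n %/% 2L - w %/% 2L + 1L
    idx <- lo:(lo + w - 1L)
    list(ratio = r, image = resize_image(image[idx, idx, drop = FALSE],
                                         out_size))
  })
}

#' Read a pattern image from PNG
#'
#' RGB input is converted to luminance; non-square input is squared by
#' center-cropping (default) or zero-padding.
#'
#' @param path PNG file.
#' @param square "crop" or "pad" strategy for non-square input.
#' @return square matrix in \[0,1\].
#' @export
read_image <- function(path, square = c("crop", "pad")) {
  square <- match.arg(square)
  a <- tryCatch(png::readPNG(path), error = function(e) {
    stop("cannot read image: ", path, " (", conditionMessage(e), ")")
  })
  img <- if (length(dim(a)) == 3L) {
    if (dim(a)[3] >= 3L) {
      0.299 * a[, , 1] + 0.587 * a[, , 2] + 0.114 * a[, , 3]
    } else {
      a[, , 1]
    }
  } else {
    a
  }
  n <- nrow(img); m <- ncol(img)
  if (n != m) {
    if (square == "crop") {
      w <- min(n, m)
      ri <- (n - w) %/% 2L + seq_len(w)
      ci <- (m - w) %/% 2L + seq_len(w)
      img <- img[ri, ci, drop = FALSE]
    } else {
      w <- max(n, m)
      out <- matrix(0, w, w)
      out[(w - n) %/% 2L + seq_len(n), (w - m) %/% 2L + seq_len(m)] <- img
      img <- out
    }
  }
  img
}

#' Write a pattern image as 8-bit grayscale PNG
#'
#' @param image matrix in \[0,1\].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_image <- function(image, path) {
  stopifnot(all(image >= -1e-9), all(image <= 1 + 1e-9))
  png::writePNG(clamp(image, 0, 1), path)
  invisible(path)
}

#' Preprocess an external photograph for retrieval
#'
#' Luminance conversion (done by [read_image()]), contrast stretching to
#' the central 98% intensity range, and blurring, mirroring the treatment
#' of simulated patterns.
#'
#' @param image square matrix in \[0,1\].
#' @param sigma blur strength in pixels.
#' @return preprocessed image.
#' @export
preprocess_photo <- function(image, sigma = 1.5) {
  q <- stats::quantile(image, c(0.01, 0.99), names = FALSE)
  img <- clamp((image - q[1]) / max(q[2] - q[1], 1e-12), 0, 1)
  blur(img, sigma)
}
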