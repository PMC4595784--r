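#' Grayscale image helpers
#'
#' Images throughout the package are plain numeric matrices with intensities
#' in \[0, 1\] (rows = image rows, columns = image columns).  These helpers
#' validate that contract and measure pixel-space distances.
#'
#' @name gray-images
NULL

#' Validate a grayscale image
#'
#' @param img numeric matrix with values in \[0, 1\].
#' @param arg name used in error messages.
#' @return the image, invisibly, after validation.
#' @export
validate_gray_image <- function(img, arg = "img") {
  if (!is.matrix(img) || !is.numeric(img)) {
    stop(sprintf("`%s` must be a numeric matrix", arg), call. = FALSE)
  }
  if (anyNA(img) || any(!is.finite(img))) {
    stop(sprintf("`%s` contains non-finite values", arg), call. = FALSE)
  }
  rng <- range(img)
  if (rng[1] < -1e-9 || rng[2] > 1 + 1e-9) {
    stop(sprintf("`%s` intensities must lie in [0, 1]", arg), call. = FALSE)
  }
  invisible(img)
}

#' Euclidean pixel distance between two images
#'
#' The distance is the L2 norm of the intensity difference taken directly on
#' pixels, the standard way of equating the low-level magnitude of two image
#' changes before comparing how strongly they modulate model units.
#'
#' @param a,b grayscale images of identical dimensions.
#' @return a non-negative scalar; zero iff the images are identical.
#' @examples
#' a <- matrix(0, 2, 2)
#' b <- matrix(c(0.3, 0, 0.4, 0), 2, 2)
#' pixel_distance(a, b)  # 0.5
#' @export
pixel_distance <- function(a, b) {
  validate_gray_image(a, "a")
  validate_gray_image(b, "b")
  if (!identical(dim(a), dim(b))) {
    stop("images must have identical dimensions", call. = FALSE)
  }
  sqrt(sum((a - b)^2))
}

# Block-average downsampling by an integer factor (used for anti-aliasing:
# shapes are rasterized on a supersampled grid, then averaged down).
block_downsample <- function(m, factor) {
  if (factor == 1L) return(m)
  h <- nrow(m) %/% factor
  w <- ncol(m) %/% factor
  dim(m) <- c(factor, h, factor * w)
  m <- colMeans(m)                       # h x (factor*w)
  m <- matrix(m, nrow = h)
  dim(m) <- c(h, factor, w)
  out <- apply(m, c(1, 3), mean)
  matrix(out, nrow = h, ncol = w)
}

# Bilinear upsampling of a small matrix to (nr, nc); used for smooth
# background clutter fields.
bilinear_upsample <- function(m, nr, nc) {
  sr <- nrow(m); sc <- ncol(m)
  ri <- seq(1, sr, length.out = nr)
  ci <- seq(1, sc, length.out = nc)
  r0 <- pmin(floor(ri), sr - 1L); fr <- ri - r0
  c0 <- pmin(floor(ci), sc - 1L); fc <- ci - c0
  a <- m[r0, c0, drop = FALSE]; b <- m[r0 + 1L, c0, drop = FALSE]
  cc <- m[r0, c0 + 1L, drop = FALSE]; d <- m[r0 + 1L, c0 + 1L, drop = FALSE]
  wa <- outer(1 - fr, 1 - fc); wb <- outer(fr, 1 - fc)
  wc <- outer(1 - fr, fc); wd <- outer(fr, fc)
  a * wa + b * wb + cc * wc + d * wd
}

# Integer-pixel translation with background fill (for invariance tests).
#' Shift an image by whole pixels
#'
#' @param img grayscale image.
#' @param dr,dc row/column shift in pixels (positive = down/right).
#' @param fill intensity used for exposed borders.
#' @return shifted image of the same size.
#' @export
shift_image <- function(img, dr = 0L, dc = 0L, fill = NULL) {
  if (is.null(fill)) fill <- as.numeric(stats::median(img))
  h <- nrow(img); w <- ncol(img)
  out <- matrix(fill, h, w)
  sr <- max(1L, 1L + dr):min(h, h + dr)
  sc <- max(1L, 1L + dc):min(w, w + dc)
  out[sr, sc] <- img[sr - dr, sc - dc]
  out
}

#' Write a grayscale image to PNG
#'
#' @param img grayscale image.
#' @param path output file path.
#' @export
write_gray_png <- function(img, path) {
  validate_gray_image(img)
  png::writePNG(img, target = path)
  invisible(path)
}

#' Read a grayscale PNG
#'
#' Color images are converted to luminance.
#'
#' @param path PNG file path.
#' @return a grayscale image matrix.
#' @export
read_gray_png <- function(path) {
  x <- png::readPNG(path)
  if (length(dim(x)) == 3L) {
    x <- 0.299 * x[, , 1] + 0.587 * x[, , 2] + 0.114 * x[, , 3]
  }
  x
}
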