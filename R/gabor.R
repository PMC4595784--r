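#' Gabor filter bank for the S1 stage
#'
#' Builds the oriented Gabor kernels of the first simple-cell stage and the
#' pairing of filter sizes into scale bands for the complex-cell (C1) stage.
#' Kernel parameters follow the standard HMAX parameterization: filter sizes
#' from 7 to 21 px in steps of 2, effective width and wavelength growing
#' with size, spatial aspect ratio 0.3, circular support.  Consecutive size
#' pairs form one scale band; each band has its own C1 pooling neighborhood
#' and subsampling stride.
#'
#' Every kernel is zero-mean and unit-norm, so S1 responses (normalized
#' cross-correlations) are bounded by 1 and vanish on uniform input.
#'
#' @param n_orientations number of equally spaced orientations (>= 2).
#' @param filter_sizes odd kernel sides in pixels; consecutive pairs form
#'   scale bands.
#' @param pool_sizes C1 spatial pooling neighborhood (in S1 units) per band.
#' @param pool_strides C1 subsampling stride per band.
#' @param aspect spatial aspect ratio of the Gabor envelope.
#' @return an object of class `gabor_bank`.
#' @export
gabor_bank <- function(n_orientations = 4L,
                       filter_sizes = seq(7L, 21L, by = 2L),
                       pool_sizes = c(8L, 10L, 12L, 14L),
                       pool_strides = c(4L, 5L, 6L, 7L),
                       aspect = 0.3) {
  stopifnot(n_orientations >= 2L, all(filter_sizes %% 2L == 1L),
            length(filter_sizes) %% 2L == 0L)
  n_bands <- length(filter_sizes) / 2L
  stopifnot(length(pool_sizes) == n_bands, length(pool_strides) == n_bands,
            all(pool_sizes >= 1L), all(pool_strides >= 1L))
  orientations <- seq(0, 180, length.out = n_orientations + 1L)[seq_len(n_orientations)]
  sigma <- 0.0036 * filter_sizes^2 + 0.35 * filter_sizes + 0.18
  lambda <- sigma / 0.8
  kernels <- lapply(seq_along(filter_sizes), function(si) {
    lapply(orientations, function(th) {
      gabor_kernel(filter_sizes[si], th, sigma[si], lambda[si], aspect)
    })
  })
  bands <- lapply(seq_len(n_bands), function(b) {
    list(size_idx = c(2L * b - 1L, 2L * b),
         pool_size = as.integer(pool_sizes[b]),
         stride = as.integer(pool_strides[b]))
  })
  structure(list(n_orientations = as.integer(n_orientations),
                 orientations = orientations,
                 filter_sizes = as.integer(filter_sizes),
                 sigma = sigma, lambda = lambda, aspect = aspect,
                 kernels = kernels, bands = bands),
            class = "gabor_bank")
}

# One zero-mean, unit-norm Gabor kernel with circular support.
# theta is the preferred bar orientation in degrees (0 = bar along the
# kernel's x/column axis); the sinusoid modulates perpendicular to the bar.
gabor_kernel <- function(size, theta, sigma, lambda, aspect = 0.3) {
  r <- (size - 1) / 2
  x <- matrix(-r:r, size, size, byrow = TRUE)   # column offset
  y <- matrix(-r:r, size, size)                 # row offset
  th <- theta * pi / 180
  along <- x * cos(th) + y * sin(th)
  perp <- -x * sin(th) + y * cos(th)
  g <- exp(-(perp^2 + aspect^2 * along^2) / (2 * sigma^2)) *
    cos(2 * pi * perp / lambda)
  g[x^2 + y^2 > r^2] <- 0
  g <- g - mean(g)
  g / sqrt(sum(g^2))
}

#' @export
print.gabor_bank <- function(x, ...) {
  cat(sprintf(
    "<gabor_bank> %d orientations x %d sizes (%d-%d px), %d scale bands\n",
    x$n_orientations, length(x$filter_sizes), min(x$filter_sizes),
    max(x$filter_sizes), length(x$bands)))
  invisible(x)
}
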