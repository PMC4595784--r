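#' The four-stage feedforward model
#'
#' `hmax_model()` bundles the Gabor bank with the S2/C2 tuning parameters.
#' The four stages are: S1, absolute contrast-normalized Gabor filtering;
#' C1, local max pooling over position and adjacent scales; S2, Gaussian
#' radial-basis tuning of C1 patches to imprinted prototypes; C2, a global
#' max over positions and scale bands per prototype.
#'
#' S2 tuning is *energy-relative*: a prototype with weights `w` responds
#' with `exp(-gamma0 / ||w||^2 * ||w - x||^2)`, i.e. the base sharpness
#' `gamma0` applies to the distance measured relative to the prototype's
#' own energy.  This fixes the response to a blank (all-zero) input at
#' `exp(-gamma0)` for every unit regardless of patch size or content, so
#' all units share one dynamic range instead of saturating when their
#' preferred pattern happens to have low energy.  The default `gamma0 = 4`
#' puts the blank response near 0.02 and a pattern at half the prototype's
#' relative distance near `exp(-1)`.
#'
#' @param bank a [gabor_bank()].
#' @param patch_sizes S2 prototype patch sides, in C1 units.
#' @param gamma optional named vector of base sharpness `gamma0` per patch
#'   size.
#' @return an object of class `hmax_model`.
#' @export
hmax_model <- function(bank = gabor_bank(), patch_sizes = c(4L, 8L, 12L),
                       gamma = NULL) {
  stopifnot(inherits(bank, "gabor_bank"), all(patch_sizes >= 1L))
  patch_sizes <- as.integer(patch_sizes)
  if (is.null(gamma)) {
    gamma <- stats::setNames(rep(4, length(patch_sizes)),
                             as.character(patch_sizes))
  }
  stopifnot(all(gamma > 0), all(is.finite(gamma)),
            all(as.character(patch_sizes) %in% names(gamma)))
  structure(list(bank = bank, patch_sizes = patch_sizes, gamma = gamma),
            class = "hmax_model")
}

#' @export
print.hmax_model <- function(x, ...) {
  cat(sprintf("<hmax_model> patch sizes {%s}, gamma {%s}\n",
              paste(x$patch_sizes, collapse = ", "),
              paste(signif(x$gamma, 3), collapse = ", ")))
  print(x$bank)
  invisible(x)
}

#' S1 stage: oriented Gabor filtering
#'
#' Each S1 value is the absolute normalized cross-correlation between a
#' zero-mean, unit-norm Gabor kernel and the local (mean-centered) image
#' patch, so responses lie in \[0, 1\], vanish on uniform input, and are
#' exactly invariant to affine intensity rescaling.  Responses where the
#' kernel window does not fit fully inside the image are set to 0.
#'
#' @param image grayscale image matrix.
#' @param bank a [gabor_bank()].
#' @return list of class `s1_maps`: one `H x W x n_orientations` array per
#'   filter size.
#' @export
s1_response <- function(image, bank = gabor_bank()) {
  validate_gray_image(image, "image")
  H <- nrow(image); W <- ncol(image)
  smax <- max(bank$filter_sizes)
  if (H < smax || W < smax) {
    stop(sprintf("image (%dx%d) smaller than the largest kernel (%d)",
                 H, W, smax), call. = FALSE)
  }
  img2 <- image^2
  out <- vector("list", length(bank$filter_sizes))
  for (si in seq_along(bank$filter_sizes)) {
    s <- bank$filter_sizes[si]
    n <- s * s
    loc_sum <- box_sum(image, s)
    loc_sumsq <- box_sum(img2, s)
    denom <- sqrt(pmax(loc_sumsq - loc_sum^2 / n, 0))
    ok <- denom > 1e-10
    maps <- array(0, dim = c(H, W, bank$n_orientations))
    for (oi in seq_len(bank$n_orientations)) {
      k <- bank$kernels[[si]][[oi]]
      kf <- k[rev(seq_len(nrow(k))), rev(seq_len(ncol(k))), drop = FALSE]
      num <- abs(conv2_same(image, kf))
      r <- matrix(0, H, W)
      r[ok] <- pmin(num[ok] / denom[ok], 1)
      m <- (s - 1L) / 2L
      r[c(seq_len(m), H - seq_len(m) + 1L), ] <- 0
      r[, c(seq_len(m), W - seq_len(m) + 1L)] <- 0
      maps[, , oi] <- r
    }
    out[[si]] <- maps
  }
  structure(out, class = "s1_maps", bank_sizes = bank$filter_sizes)
}

#' C1 stage: local max pooling over position and scale
#'
#' Each C1 unit takes the max of its afferent S1 units over a square
#' spatial neighborhood and over the two adjacent filter sizes of its scale
#' band, subsampled by the band's stride.
#'
#' @param s1 result of [s1_response()] (a list of per-size arrays; arrays of
#'   matching dimensions are required within each band).
#' @param bank the [gabor_bank()] whose `bands` define pooling.
#' @return list of class `c1_maps`: per band, a list with `maps` (array
#'   `nr x nc x n_orientations`), and the window geometry (`row_starts`,
#'   `col_starts`, `pool_size`).
#' @export
c1_response <- function(s1, bank = gabor_bank()) {
  out <- vector("list", length(bank$bands))
  for (b in seq_along(bank$bands)) {
    band <- bank$bands[[b]]
    idx <- band$size_idx[band$size_idx <= length(s1)]
    m <- s1[[idx[1]]]
    if (length(idx) > 1L) for (j in idx[-1]) m <- pmax(m, s1[[j]])
    H <- dim(m)[1]; W <- dim(m)[2]; O <- dim(m)[3]
    p <- min(band$pool_size, H, W)
    st <- band$stride
    rs <- seq(1L, H - p + 1L, by = st)
    cs <- seq(1L, W - p + 1L, by = st)
    acc <- array(-Inf, dim = c(length(rs), length(cs), O))
    for (dr in 0:(p - 1L)) {
      for (dc in 0:(p - 1L)) {
        acc <- pmax(acc, m[rs + dr, cs + dc, , drop = FALSE])
      }
    }
    out[[b]] <- list(maps = acc, row_starts = rs, col_starts = cs,
                     pool_size = p, stride = st)
  }
  structure(out, class = "c1_maps")
}

#' Gaussian radial-basis tuning
#'
#' The response of a simple unit with preferred pattern `w` to afferent
#' pattern `x` is `exp(-gamma * ||w - x||^2)`: 1 at the preferred pattern,
#' strictly decreasing in the distance.
#'
#' @param x afferent activity pattern (numeric vector).
#' @param w preferred pattern (same length).
#' @param gamma tuning sharpness (> 0).
#' @return scalar in (0, 1\].
#' @examples
#' gaussian_tuning(c(1, 1), c(0, 0), 0.5)  # exp(-1)
#' @export
gaussian_tuning <- function(x, w, gamma) {
  if (length(x) != length(w)) {
    stop("`x` and `w` must have equal length", call. = FALSE)
  }
  stopifnot(gamma > 0, is.finite(gamma))
  exp(-gamma * sum((w - x)^2))
}

#' Imprint an S2 prototype from C1 activity
#'
#' Stores the flattened C1 patch (all orientations) at a given position and
#' scale band as a prototype weight vector — the imprinting learning rule:
#' the unit's preferred feature is the activity pattern it happened to see.
#'
#' @param c1 result of [c1_response()].
#' @param band scale band index.
#' @param position integer `c(row, col)` of the patch's top-left corner in
#'   C1 coordinates (1-based).
#' @param patch_size patch side in C1 units.
#' @param source optional metadata (image/frame id) recorded on the
#'   prototype.
#' @return an object of class `s2_prototype` with fields `w`, `patch_size`,
#'   `band`, `position`, `source`.
#' @export
imprint_prototype <- function(c1, band, position, patch_size, source = NULL) {
  stopifnot(inherits(c1, "c1_maps"))
  maps <- c1[[band]]$maps
  p <- as.integer(patch_size)
  r <- position[1]; cc <- position[2]
  if (r < 1L || cc < 1L || r + p - 1L > dim(maps)[1] ||
      cc + p - 1L > dim(maps)[2]) {
    stop("prototype patch out of bounds for this band", call. = FALSE)
  }
  w <- as.vector(maps[r:(r + p - 1L), cc:(cc + p - 1L), , drop = FALSE])
  structure(list(w = w, patch_size = p, band = as.integer(band),
                 position = as.integer(position),
                 n_orientations = dim(maps)[3], source = source),
            class = "s2_prototype")
}

# All p x p patches of a C1 band as rows of a matrix (positions in
# column-major order; patch elements flattened row, column, orientation —
# matching imprint_prototype()).
im2col_patches <- function(maps, p) {
  H <- dim(maps)[1]; W <- dim(maps)[2]; O <- dim(maps)[3]
  nr <- H - p + 1L; nc <- W - p + 1L
  if (nr < 1L || nc < 1L) return(NULL)
  X <- matrix(0, nr * nc, p * p * O)
  d <- 0L
  for (o in seq_len(O)) {
    for (dc in 0:(p - 1L)) {
      for (dr in 0:(p - 1L)) {
        d <- d + 1L
        X[, d] <- as.vector(maps[(1:nr) + dr, (1:nc) + dc, o])
      }
    }
  }
  X
}

#' S2 stage: Gaussian tuning of C1 patches to one prototype
#'
#' Applies [gaussian_tuning()] between the prototype and every valid C1
#' patch position in every scale band where the patch fits, with the
#' energy-relative sharpness `gamma0 / ||w||^2` (see [hmax_model()]).
#'
#' @param c1 result of [c1_response()].
#' @param prototype an [imprint_prototype()] result.
#' @param model an [hmax_model()] (supplies the base sharpness).
#' @return list of class `s2_maps`: per band, a matrix of responses (or
#'   `NULL` where the patch does not fit).
#' @export
s2_response <- function(c1, prototype, model = hmax_model()) {
  stopifnot(inherits(c1, "c1_maps"), inherits(prototype, "s2_prototype"))
  p <- prototype$patch_size
  gamma <- effective_gamma(model, p, sum(prototype$w^2))
  out <- lapply(c1, function(band) {
    X <- im2col_patches(band$maps, p)
    if (is.null(X)) return(NULL)
    d2 <- rowSums(sweep(X, 2L, prototype$w)^2)
    nr <- dim(band$maps)[1] - p + 1L
    matrix(exp(-gamma * d2), nrow = nr)
  })
  structure(out, class = "s2_maps")
}

#' C2 stage: global max pooling
#'
#' @param s2 result of [s2_response()].
#' @return scalar: the max response over all positions and scale bands.
#' @export
c2_response <- function(s2) {
  vals <- unlist(lapply(s2, function(m) if (is.null(m)) NULL else max(m)))
  if (length(vals) == 0L) {
    stop("prototype does not fit in any scale band", call. = FALSE)
  }
  max(vals)
}

# Energy-relative sharpness: gamma0 / ||w||^2 (vectorized over prototype
# norms).  A floor on the norm guards all-zero prototypes.
effective_gamma <- function(model, patch_size, wnorm2) {
  gamma0 <- model$gamma[[as.character(patch_size)]]
  if (is.null(gamma0)) gamma0 <- 4
  gamma0 / pmax(wnorm2, 1e-8)
}

# Batch C2: responses of many prototypes to one C1 representation.
# Uses the expansion ||w - x||^2 = ||w||^2 + ||x||^2 - 2<w, x> so one
# matrix product per (band, patch size) covers all prototypes.
c2_batch <- function(c1, prototypes, model) {
  K <- length(prototypes)
  if (K == 0L) return(numeric(0))
  psizes <- vapply(prototypes, `[[`, integer(1), "patch_size")
  out <- rep(NA_real_, K)
  for (p in unique(psizes)) {
    ki <- which(psizes == p)
    Wm <- do.call(rbind, lapply(prototypes[ki], `[[`, "w"))
    wn <- rowSums(Wm^2)
    gamma <- effective_gamma(model, p, wn)
    mind2 <- rep(Inf, length(ki))
    for (band in c1) {
      X <- im2col_patches(band$maps, p)
      if (is.null(X)) next
      xn <- rowSums(X^2)
      cp <- X %*% t(Wm)
      d2 <- sweep(-2 * cp, 1L, xn, `+`)     # xn - 2<w,x> per row
      d2min <- apply(d2, 2L, min) + wn       # add ||w||^2 after the min
      mind2 <- pmin(mind2, d2min)
    }
    if (any(!is.finite(mind2))) {
      stop(sprintf("patch size %d does not fit in any scale band", p),
           call. = FALSE)
    }
    out[ki] <- exp(-gamma * pmax(mind2, 0))
  }
  out
}

#' Encode an image as a C2 population activity vector
#'
#' Runs the full S1 -> C1 -> S2 -> C2 cascade and returns one C2 activity
#' per prototype (each prototype here is a single-view feature column, as in
#' the original model).
#'
#' @param image grayscale image matrix (or a precomputed `c1_maps`).
#' @param prototypes list of [imprint_prototype()] results.
#' @param model an [hmax_model()].
#' @return named numeric vector of length `length(prototypes)`, values in
#'   (0, 1\].
#' @export
encode <- function(image, prototypes, model = hmax_model()) {
  stopifnot(length(prototypes) >= 1L)
  c1 <- if (inherits(image, "c1_maps")) image else
    c1_response(s1_response(image, model$bank), model$bank)
  v <- c2_batch(c1, prototypes, model)
  names(v) <- if (!is.null(names(prototypes))) names(prototypes) else
    sprintf("unit%03d", seq_along(prototypes))
  v
}
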