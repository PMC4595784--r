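#' Parametric description of a volumetric shape primitive
#'
#' A `shape_spec` is the degrees-of-freedom record for the stimulus renderer.
#' It describes a geon-style primitive (brick, cylinder, cone, wedge) as a
#' shaded 2-D silhouette: an axis of a given length, a width profile around
#' it, end caps, and a shading profile.  Continuous fields support graded
#' metric (MP) changes; categorical fields — straight vs. curved axis,
#' parallel vs. tapered sides, polygonal vs. curved cross-section — are the
#' non-accidental (NAP) switches.
#'
#' @param primitive_kind one of `"brick"`, `"cylinder"`, `"cone"`, `"wedge"`.
#' @param axis_curvature dimensionless bend of the main axis; 0 = straight.
#' @param taper sidewall taper in \[0, 1); 0 = parallel sides.  Defaults to 0
#'   for brick/cylinder and a tapered profile for cone/wedge.
#' @param cross_section `"polygonal"` (flat caps, faceted shading) or
#'   `"curved"` (rounded caps, smooth shading).  Defaults by kind.
#' @param cap_roundness optional numeric in \[0, 1\] giving the blend between
#'   a polygonal (0) and fully curved (1) cross-section; defaults to 0/1
#'   according to `cross_section`.  Used to give the cross-section switch a
#'   continuous calibration magnitude.
#' @param aspect_ratio length/width of the primitive (> 0).
#' @param apex_angle skew angle of the top edge, degrees (metric "angle at a
#'   point" axis).
#' @param in_plane_rotation image-plane rotation, degrees.
#' @param size axis length as a fraction of the canvas, in (0, 1\].
#' @param albedo peak surface reflectance in (0, 1\].
#' @param texture optional list with `freq`, `amp`, `phase` describing a
#'   sinusoidal surface texture along the axis (used by the video generator).
#' @return an object of class `shape_spec`.
#' @export
shape_spec <- function(primitive_kind = c("brick", "cylinder", "cone", "wedge"),
                       axis_curvature = 0,
                       taper = NULL,
                       cross_section = NULL,
                       cap_roundness = NULL,
                       aspect_ratio = 2.2,
                       apex_angle = 0,
                       in_plane_rotation = 0,
                       size = 0.55,
                       albedo = 1,
                       texture = NULL) {
  primitive_kind <- match.arg(primitive_kind)
  defaults <- list(
    brick    = list(taper = 0,    cross_section = "polygonal"),
    cylinder = list(taper = 0,    cross_section = "curved"),
    cone     = list(taper = 0.9, cross_section = "curved"),
    wedge    = list(taper = 0.8, cross_section = "polygonal")
  )[[primitive_kind]]
  if (is.null(taper)) taper <- defaults$taper
  if (is.null(cross_section)) cross_section <- defaults$cross_section
  cross_section <- match.arg(cross_section, c("polygonal", "curved"))
  if (is.null(cap_roundness)) {
    cap_roundness <- if (cross_section == "curved") 1 else 0
  }
  spec <- structure(list(
    primitive_kind = primitive_kind,
    axis_curvature = axis_curvature,
    taper = taper,
    cross_section = cross_section,
    cap_roundness = cap_roundness,
    aspect_ratio = aspect_ratio,
    apex_angle = apex_angle,
    in_plane_rotation = in_plane_rotation,
    size = size,
    albedo = albedo,
    texture = texture
  ), class = "shape_spec")
  validate_shape_spec(spec)
  spec
}

#' @export
print.shape_spec <- function(x, ...) {
  cat(sprintf(
    "<shape_spec> %s: size %.2f, aspect %.2f, taper %.2f, curvature %.2f,\n  cross-section %s (roundness %.2f), apex %.1f deg, rotation %.1f deg\n",
    x$primitive_kind, x$size, x$aspect_ratio, x$taper, x$axis_curvature,
    x$cross_section, x$cap_roundness, x$apex_angle, x$in_plane_rotation))
  invisible(x)
}

validate_shape_spec <- function(spec) {
  num <- c("axis_curvature", "taper", "cap_roundness", "aspect_ratio",
           "apex_angle", "in_plane_rotation", "size", "albedo")
  for (f in num) {
    v <- spec[[f]]
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v)) {
      stop(sprintf("shape_spec field `%s` must be a finite scalar", f),
           call. = FALSE)
    }
  }
  if (spec$size <= 0.01 || spec$size > 1) {
    stop("shape_spec `size` must lie in (0.01, 1]: degenerate geometry",
         call. = FALSE)
  }
  if (spec$aspect_ratio <= 0.05) {
    stop("shape_spec `aspect_ratio` must be > 0.05: degenerate geometry",
         call. = FALSE)
  }
  if (spec$axis_curvature < 0) stop("`axis_curvature` must be >= 0", call. = FALSE)
  if (spec$taper < 0 || spec$taper >= 1) stop("`taper` must lie in [0, 1)", call. = FALSE)
  if (spec$cap_roundness < 0 || spec$cap_roundness > 1) {
    stop("`cap_roundness` must lie in [0, 1]", call. = FALSE)
  }
  invisible(spec)
}

#' Canvas parameters for the stimulus renderer
#'
#' @param size canvas side in pixels (square canvas).
#' @param background uniform background intensity.
#' @param supersample integer anti-aliasing factor (shapes are rasterized at
#'   `size * supersample` and block-averaged down).
#' @return a list of class `canvas_params`.
#' @export
canvas_params <- function(size = 128L, background = 0.5, supersample = 2L) {
  stopifnot(size >= 16L, supersample >= 1L,
            background >= 0, background <= 1)
  structure(list(size = as.integer(size), background = background,
                 supersample = as.integer(supersample)),
            class = "canvas_params")
}

# Rasterize one primitive on arbitrary coordinate grids.
#
# xs, ys: matrices of x/y coordinates (canvas units, origin at the shape
# centre, y pointing up).  Returns list(mask, shade): mask is 0/1 membership,
# shade the surface intensity where mask == 1.
render_primitive_grid <- function(spec, xs, ys) {
  phi <- spec$in_plane_rotation * pi / 180
  xr <- xs * cos(phi) + ys * sin(phi)
  yr <- -xs * sin(phi) + ys * cos(phi)

  L <- spec$size
  h0 <- L / (2 * spec$aspect_ratio)
  t <- yr / L + 0.5
  tc <- pmin(pmax(t, 0), 1)
  # mean-zero arc bend: the whole axis curves, so the ends swing sideways
  # and the side tangents change everywhere (a curved-axis geon, not a
  # mid-body bulge that leaves the distinctive end regions untouched)
  bend <- spec$axis_curvature * L * (4 * (tc - 0.5)^2 - 1 / 3)
  # opening-angle ramp: the apex angle widens the profile toward the top
  # and narrows it toward the bottom (metric "angle at a point" axis)
  ramp <- tan(pmin(spec$apex_angle, 60) * pi / 180) * L / (2 * h0)
  ramp <- pmin(pmax(ramp, -1.8), 1.8)
  # area-preserving taper tilt: the sides rotate about mid-height, so
  # "parallel vs tapered" is a contour change rather than a mass change
  hw <- h0 * (1 - spec$taper * (tc - 0.5)) * (1 + ramp * (tc - 0.5))
  hw <- pmax(hw, 0.03 * h0)
  u <- (xr - bend) / hw
  t_top <- 1

  core <- (t >= 0) & (t <= t_top) & (abs(u) <= 1)

  rho <- spec$cap_roundness
  mask <- core
  if (rho > 0) {
    # elliptical end caps whose depth grows with roundness
    e0 <- 0.55 * rho * 2 * h0 * (1 + 0.5 * spec$taper) / L
    e1 <- 0.55 * rho * 2 * h0 * (1 - 0.5 * spec$taper) / L
    if (e0 > 0) {
      cap_b <- (t < 0) & ((t / e0)^2 + u^2 <= 1)
      mask <- mask | cap_b
    }
    if (e1 > 0) {
      tau <- (t - t_top) / e1
      cap_t <- (t > t_top) & (tau^2 + u^2 <= 1)
      mask <- mask | cap_t
    }
  }

  uc <- pmin(pmax(u, -1), 1)
  # the two shading profiles share (almost) one mean luminance, so the
  # polygonal/curved switch is read out from gradient shape and limb
  # darkening at the contours, not from a luminance-mass change
  shade_flat <- 0.82 + 0.14 * uc
  shade_curved <- 0.35 + 0.65 * sqrt(pmax(1 - uc^2, 0))
  shade <- (1 - rho) * shade_flat + rho * shade_curved
  if (!is.null(spec$texture)) {
    tx <- spec$texture
    shade <- shade * (1 + tx$amp * sin(2 * pi * tx$freq * tc + tx$phase))
  }
  shade <- pmin(pmax(shade * spec$albedo, 0), 1)
  list(mask = mask, shade = shade)
}

#' Render a shape specification to a grayscale image
#'
#' Rendering is a pure function of the specification and canvas: the same
#' inputs always produce bitwise-identical pixels.  The primitive is drawn as
#' a shaded silhouette on a uniform background, anti-aliased by supersampled
#' rasterization.
#'
#' @param spec a [shape_spec()].
#' @param canvas a [canvas_params()].
#' @return a grayscale image matrix (`canvas$size` square, values in \[0, 1\]).
#' @examples
#' img <- render_shape(shape_spec("cylinder"), canvas_params(64))
#' dim(img)
#' @export
render_shape <- function(spec, canvas = canvas_params()) {
  validate_shape_spec(spec)
  stopifnot(inherits(canvas, "canvas_params"))
  G <- canvas$size * canvas$supersample
  cw <- (seq_len(G) - (G + 1) / 2) / G
  xs <- matrix(cw, G, G, byrow = TRUE)
  ys <- matrix(rev(cw), G, G)
  prim <- render_primitive_grid(spec, xs, ys)
  img <- canvas$background + prim$mask * (prim$shade - canvas$background)
  out <- block_downsample(img, canvas$supersample)
  pmin(pmax(out, 0), 1)
}
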