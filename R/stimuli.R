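#' Stimulus families: graded metric variants and a calibrated
#' non-accidental variant
#'
#' A stimulus family consists of a rendered base shape, four metric (MP)
#' variants of strictly increasing amplitude along one continuous axis, and
#' one non-accidental (NAP) variant obtained by flipping a categorical
#' property (straight vs. curved axis, parallel vs. tapered sides, polygonal
#' vs. curved cross-section).  The NAP variant is calibrated so that its
#' pixel-space distance from the base does not exceed that of the second
#' metric step (MP2) — the classical control ensuring that any extra
#' sensitivity to the NAP change cannot be explained by a larger image
#' change.
#'
#' @name stimulus-families
NULL

# Metric axes: name -> function(spec, amplitude) -> spec.
# Amplitudes are dimensionless fractions of each axis' full range.
mp_axes <- list(
  apex_angle = function(spec, amp) {
    spec$apex_angle <- spec$apex_angle + 55 * amp
    spec
  },
  aspect_ratio = function(spec, amp) {
    spec$aspect_ratio <- spec$aspect_ratio * (1 + amp)
    spec
  },
  size = function(spec, amp) {
    spec$size <- min(spec$size * (1 + 0.6 * amp), 0.95)
    spec
  }
)

# Categorical switches: name -> function(spec, magnitude in (0, 1]) -> spec.
# Any magnitude above the categorical floor constitutes the qualitative flip;
# the magnitude only scales how far the flipped property is expressed.
nap_switches <- list(
  axis_curvature = function(spec, mag) {
    if (spec$axis_curvature > 0) {
      stop("axis_curvature switch requires a straight-axis base", call. = FALSE)
    }
    spec$axis_curvature <- 0.18 * mag
    spec
  },
  taper = function(spec, mag) {
    if (spec$taper > 0) {
      stop("taper switch requires a parallel-sided base", call. = FALSE)
    }
    spec$taper <- 0.6 * mag
    spec
  },
  cross_section = function(spec, mag) {
    target <- if (spec$cross_section == "polygonal") 1 else 0
    spec$cap_roundness <- spec$cap_roundness +
      (target - spec$cap_roundness) * mag
    spec$cross_section <- if (target == 1) "curved" else "polygonal"
    spec
  }
)

#' Names of the available metric axes and categorical switches
#' @return character vector of axis names.
#' @export
mp_axis_names <- function() names(mp_axes)

#' @rdname mp_axis_names
#' @export
nap_switch_names <- function() names(nap_switches)

apply_mp <- function(spec, axis, amp) {
  f <- mp_axes[[axis]]
  if (is.null(f)) stop(sprintf("unknown metric axis `%s`", axis), call. = FALSE)
  validate_shape_spec(f(spec, amp))
}

apply_nap <- function(spec, switch, mag) {
  f <- nap_switches[[switch]]
  if (is.null(f)) stop(sprintf("unknown NAP switch `%s`", switch), call. = FALSE)
  validate_shape_spec(f(spec, mag))
}

#' Build one stimulus family
#'
#' Renders the base shape, four metric variants of increasing amplitude along
#' `mp_axis`, and one non-accidental variant obtained by flipping
#' `nap_switch` at magnitude `nap_magnitude`.  The returned family is *not*
#' yet pixel-calibrated; see [calibrate_nap()].
#'
#' @param base_spec a [shape_spec()] for the base shape.
#' @param mp_axis one of [mp_axis_names()].
#' @param mp_amplitudes four non-negative, strictly increasing amplitudes
#'   (fractions of the axis range).
#' @param nap_switch one of [nap_switch_names()]; must differ from `mp_axis`.
#' @param nap_magnitude magnitude in (0, 1\] of the categorical flip.
#' @param canvas a [canvas_params()].
#' @param family_id identifier string.
#' @return an object of class `stim_family` with elements `base`, `mp`
#'   (list of 4 images), `nap`, the generating specs, and pixel distances.
#' @export
make_family <- function(base_spec, mp_axis, mp_amplitudes,
                        nap_switch, nap_magnitude = 1,
                        canvas = canvas_params(),
                        family_id = "family") {
  stopifnot(inherits(base_spec, "shape_spec"))
  if (identical(mp_axis, nap_switch)) {
    stop("`mp_axis` and `nap_switch` must be distinct dimensions", call. = FALSE)
  }
  if (length(mp_amplitudes) != 4L || any(mp_amplitudes < 0) ||
      any(diff(mp_amplitudes) <= 0)) {
    stop("`mp_amplitudes` must be 4 non-negative strictly increasing values",
         call. = FALSE)
  }
  if (nap_magnitude <= 0 || nap_magnitude > 1) {
    stop("`nap_magnitude` must lie in (0, 1]", call. = FALSE)
  }
  base <- render_shape(base_spec, canvas)
  mp_specs <- lapply(mp_amplitudes, function(a) apply_mp(base_spec, mp_axis, a))
  mp <- lapply(mp_specs, render_shape, canvas = canvas)
  nap_spec <- apply_nap(base_spec, nap_switch, nap_magnitude)
  nap <- render_shape(nap_spec, canvas)
  fam <- structure(list(
    family_id = family_id,
    base_spec = base_spec,
    mp_axis = mp_axis,
    mp_amplitudes = mp_amplitudes,
    nap_switch = nap_switch,
    nap_magnitude = nap_magnitude,
    canvas = canvas,
    base = base, mp = mp, nap = nap
  ), class = "stim_family")
  fam$distances <- family_distances(fam)
  fam
}

#' Pixel distances of all variants of a family from its base
#'
#' @param family a `stim_family`.
#' @return named numeric vector `mp1`..`mp4`, `nap`.
#' @export
family_distances <- function(family) {
  d_mp <- vapply(family$mp, pixel_distance, numeric(1), b = family$base)
  c(stats::setNames(d_mp, paste0("mp", 1:4)),
    nap = pixel_distance(family$nap, family$base))
}

#' @export
print.stim_family <- function(x, ...) {
  d <- x$distances
  cat(sprintf(
    "<stim_family> %s (%s): MP axis %s, NAP switch %s (mag %.3f)\n  d(base, MP1..4) = %s; d(base, NAP) = %.2f\n",
    x$family_id, x$base_spec$primitive_kind, x$mp_axis, x$nap_switch,
    x$nap_magnitude, paste(sprintf("%.2f", d[1:4]), collapse = ", "),
    d[["nap"]]))
  invisible(x)
}

#' Calibrate the NAP variant of a family in pixel space
#'
#' Searches (by bisection on the switch magnitude) for the largest NAP
#' magnitude whose pixel distance from the base does not exceed the MP2
#' distance, stopping within `tol` relative distance.  A categorical floor
#' protects the qualitative nature of the switch: magnitudes below
#' `floor_frac * max(mp_amplitudes)` are not accepted, and if even the floor
#' magnitude exceeds the MP2 distance the calibration is infeasible.
#'
#' @param family a `stim_family` from [make_family()].
#' @param floor_frac categorical floor as a fraction of the largest MP
#'   amplitude (default 0.25).
#' @param tol relative distance tolerance of the bisection (default 0.01).
#' @param max_iter maximum bisection iterations.
#' @return the calibrated `stim_family` (unchanged if it already satisfies
#'   the bound).
#' @export
calibrate_nap <- function(family, floor_frac = 0.25, tol = 0.01,
                          max_iter = 40L) {
  stopifnot(inherits(family, "stim_family"))
  target <- family$distances[["mp2"]]
  if (target <= 0) {
    stop(sprintf(
      "calibration infeasible for family `%s`: MP2 is identical to base (target distance 0)",
      family$family_id), call. = FALSE)
  }
  if (family$distances[["nap"]] <= target) return(family)

  floor_mag <- floor_frac * max(family$mp_amplitudes)
  # only the NAP image depends on the magnitude; render just that during
  # the search and reassemble the family once at the end
  nap_at <- function(mag) {
    render_shape(apply_nap(family$base_spec, family$nap_switch, mag),
                 family$canvas)
  }
  d_at <- function(img) pixel_distance(img, family$base)

  lo <- floor_mag
  img_lo <- nap_at(lo)
  if (d_at(img_lo) > target) {
    stop(sprintf(
      "calibration infeasible for family `%s`: NAP distance %.3f at the categorical floor exceeds the MP2 distance %.3f",
      family$family_id, d_at(img_lo), target), call. = FALSE)
  }
  hi <- family$nap_magnitude
  best_mag <- lo
  best_img <- img_lo
  for (i in seq_len(max_iter)) {
    mid <- (lo + hi) / 2
    img_mid <- nap_at(mid)
    d <- d_at(img_mid)
    if (d <= target) {
      best_mag <- mid
      best_img <- img_mid
      lo <- mid
      if (target - d <= tol * target) break
    } else {
      hi <- mid
    }
  }
  family$nap_magnitude <- best_mag
  family$nap <- best_img
  family$distances <- family_distances(family)
  family
}

# The 36-combination allocation across primitive kinds, metric axes and
# categorical switches.  Kinds with a tapered base cannot take the
# parallel->tapered switch; their third slot reuses the curvature switch on
# a rotated base variant so the full set still spans all four kinds evenly.
family_plan <- function() {
  rows <- list()
  add <- function(kind, mp, nap, variant) {
    rows[[length(rows) + 1L]] <<- list(kind = kind, mp = mp, nap = nap,
                                       variant = variant)
  }
  for (kind in c("brick", "cylinder")) {
    for (mp in names(mp_axes)) {
      for (nap in c("axis_curvature", "taper", "cross_section")) {
        add(kind, mp, nap, 0L)
      }
    }
  }
  for (kind in c("cone", "wedge")) {
    for (mp in names(mp_axes)) {
      add(kind, mp, "axis_curvature", 0L)
      add(kind, mp, "cross_section", 0L)
      add(kind, mp, "axis_curvature", 1L)  # rotated base variant
    }
  }
  rows
}

base_spec_for <- function(kind, variant, jitter) {
  base <- switch(kind,
    brick    = shape_spec("brick",    aspect_ratio = 2.2, size = 0.55),
    cylinder = shape_spec("cylinder", aspect_ratio = 2.6, size = 0.60),
    cone     = shape_spec("cone",     aspect_ratio = 1.8, size = 0.60),
    wedge    = shape_spec("wedge",    aspect_ratio = 1.9, size = 0.55))
  base$in_plane_rotation <- base$in_plane_rotation + jitter[1] +
    if (variant == 1L) 40 else 0
  base$aspect_ratio <- base$aspect_ratio * (1 + jitter[2])
  base$size <- min(max(base$size * (1 + jitter[3]), 0.2), 0.9)
  validate_shape_spec(base)
  base
}

#' Generate the full calibrated stimulus set
#'
#' Builds `n_families` stimulus families spanning the four primitive kinds,
#' the three metric axes and the three categorical switches, each with four
#' graded MP variants and a pixel-calibrated NAP variant.  Small seeded
#' jitter on the base pose/shape diversifies the set; generation is
#' deterministic under `seed`.  Every emitted family satisfies
#' `d(base, NAP) <= d(base, MP2)` and `d(base, MPk)` non-decreasing in `k`
#' (families violating monotonicity are regenerated with fresh jitter).
#'
#' @param n_families number of families (default 36).
#' @param seed integer RNG seed.
#' @param canvas a [canvas_params()].
#' @param mp_amplitudes default metric amplitudes shared by all families.
#' @return an object of class `stim_set`: list with `families` (list of
#'   `stim_family`) and `manifest` (a tibble, one row per family).
#' @export
build_stimulus_set <- function(n_families = 36L, seed = 1L,
                               canvas = canvas_params(),
                               mp_amplitudes = c(0.25, 0.5, 0.75, 1)) {
  stopifnot(n_families >= 1L)
  plan <- family_plan()
  withr::with_seed(seed, {
    families <- vector("list", n_families)
    for (i in seq_len(n_families)) {
      p <- plan[[(i - 1L) %% length(plan) + 1L]]
      fid <- sprintf("fam%02d_%s_%s_vs_%s", i, p$kind, p$mp, p$nap)
      fam <- NULL
      for (attempt in 1:5) {
        jitter <- c(stats::runif(1, -10, 10), stats::runif(1, -0.1, 0.1),
                    stats::runif(1, -0.08, 0.08))
        bs <- base_spec_for(p$kind, p$variant, jitter)
        cand <- make_family(bs, p$mp, mp_amplitudes, p$nap,
                            nap_magnitude = 1, canvas = canvas,
                            family_id = fid)
        d_mp <- cand$distances[1:4]
        if (all(diff(d_mp) >= 0) && d_mp[1] > 0) {
          fam <- tryCatch(calibrate_nap(cand), error = function(e) NULL)
          if (!is.null(fam)) break
        }
      }
      if (is.null(fam)) {
        stop(sprintf("could not generate a monotone family for `%s`", fid),
             call. = FALSE)
      }
      families[[i]] <- fam
    }
  })
  manifest <- purrr::map_dfr(families, function(f) {
    d <- f$distances
    tibble::tibble(
      family_id = f$family_id,
      primitive_kind = f$base_spec$primitive_kind,
      mp_axis = f$mp_axis,
      nap_switch = f$nap_switch,
      nap_magnitude = f$nap_magnitude,
      amp_mp1 = f$mp_amplitudes[1], amp_mp2 = f$mp_amplitudes[2],
      amp_mp3 = f$mp_amplitudes[3], amp_mp4 = f$mp_amplitudes[4],
      d_mp1 = d[["mp1"]], d_mp2 = d[["mp2"]], d_mp3 = d[["mp3"]],
      d_mp4 = d[["mp4"]], d_nap = d[["nap"]]
    )
  })
  structure(list(families = families, manifest = manifest,
                 canvas = canvas, seed = seed),
            class = "stim_set")
}

#' @export
print.stim_set <- function(x, ...) {
  cat(sprintf("<stim_set> %d families (%d images each), %dx%d px, seed %d\n",
              length(x$families), 6L, x$canvas$size, x$canvas$size, x$seed))
  invisible(x)
}

#' All images of a stimulus set as a flat named list
#'
#' Names follow `<family_id>.<base|mp1..mp4|nap>`.
#'
#' @param set a `stim_set`.
#' @return named list of grayscale images.
#' @export
stimulus_images <- function(set) {
  out <- list()
  for (f in set$families) {
    imgs <- c(list(base = f$base),
              stats::setNames(f$mp, paste0("mp", 1:4)),
              list(nap = f$nap))
    names(imgs) <- paste(f$family_id, names(imgs), sep = ".")
    out <- c(out, imgs)
  }
  out
}

#' Write a stimulus set to disk
#'
#' Writes `<family_id>_{base,mp1..mp4,nap}.png` plus `manifest.csv`.
#'
#' @param set a `stim_set`.
#' @param dir output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_stimulus_set <- function(set, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  for (f in set$families) {
    write_gray_png(f$base, file.path(dir, paste0(f$family_id, "_base.png")))
    for (k in 1:4) {
      write_gray_png(f$mp[[k]], file.path(dir, sprintf("%s_mp%d.png",
                                                       f$family_id, k)))
    }
    write_gray_png(f$nap, file.path(dir, paste0(f$family_id, "_nap.png")))
  }
  utils::write.csv(set$manifest, file.path(dir, "manifest.csv"),
                   row.names = FALSE)
  invisible(dir)
}
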