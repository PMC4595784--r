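#' Synthetic video sequences of objects under smooth 3-D transformation
#'
#' The generator emulates short consumer-camera clips of a fixed object
#' viewed while the camera drifts slowly around it: each sequence combines
#' small translation, scaling, and in-depth rotation, rendered as grayscale
#' frames over a cluttered background.  Objects are compositions of 1-3
#' shaded primitives arranged on a circle; in-depth rotation is emulated
#' orthographically (part positions revolve, widths foreshorten, depth order
#' changes), which reproduces the view-dependent appearance changes that
#' temporal pooling is meant to absorb.
#'
#' @name video-sequences
NULL

#' Motion parameters of one sequence
#'
#' @param rotation_span total in-depth rotation over the sequence, degrees.
#' @param translation_span total image-plane translation, pixels.
#' @param scale_span total relative scale change (e.g. 0.2 = +/-10%).
#' @param fps frames per second.
#' @param duration sequence length in seconds.
#' @param jitter_sd standard deviation of seeded per-frame pose jitter
#'   (degrees for rotation, pixels for translation); mimics handheld shake.
#' @return a list of class `motion_params`.
#' @export
motion_params <- function(rotation_span = 60, translation_span = 4,
                          scale_span = 0.2, fps = 30, duration = 1,
                          jitter_sd = 0.3) {
  stopifnot(fps > 0, duration > 0,
            is.finite(rotation_span), is.finite(translation_span),
            is.finite(scale_span), jitter_sd >= 0)
  structure(list(rotation_span = rotation_span,
                 translation_span = translation_span,
                 scale_span = scale_span, fps = fps, duration = duration,
                 jitter_sd = jitter_sd),
            class = "motion_params")
}

#' Random 3-D object specification for one category
#'
#' A category's object is a fixed composition of 1-3 shaded primitives, each
#' sitting at an angular station on a circle around the object's vertical
#' axis, with a per-category sinusoidal surface texture.  All sequences of a
#' category depict this same object; only pose and background vary.
#'
#' @param seed integer seed identifying the category object.
#' @return a list of class `object_spec`.
#' @export
object_spec <- function(seed) {
  withr::with_seed(as.integer(seed), {
    n_parts <- sample(1:3, 1)
    parts <- lapply(seq_len(n_parts), function(i) {
      kind <- sample(c("brick", "cylinder", "cone", "wedge"), 1)
      list(
        kind = kind,
        size = stats::runif(1, 0.32, 0.5),
        aspect_ratio = stats::runif(1, 1.4, 3),
        station = stats::runif(1, 0, 360),   # angular position, degrees
        radius = if (n_parts == 1) 0 else stats::runif(1, 0.08, 0.18),
        y_offset = stats::runif(1, -0.12, 0.12),
        rotation = stats::runif(1, -25, 25),
        albedo = stats::runif(1, 0.55, 1),
        texture = list(freq = sample(1:4, 1), amp = stats::runif(1, 0.05, 0.2),
                       phase = stats::runif(1, 0, 2 * pi))
      )
    })
    structure(list(seed = as.integer(seed), parts = parts),
              class = "object_spec")
  })
}

# Smooth clutter background: seeded low-resolution Gaussian field,
# bilinearly upsampled and squeezed to moderate contrast around mid-gray.
clutter_background <- function(size, seed, supersample = 1L) {
  g <- size * supersample
  withr::with_seed(as.integer(seed), {
    low <- matrix(stats::rnorm(64), 8, 8)
  })
  f <- bilinear_upsample(low, g, g)
  f <- (f - mean(f)) / max(stats::sd(f), 1e-12)
  pmin(pmax(0.5 + 0.09 * f, 0.2), 0.8)
}

#' Render one view of an object
#'
#' @param obj an [object_spec()].
#' @param theta in-depth rotation angle, degrees.
#' @param dx,dy image-plane translation in canvas units.
#' @param scale relative scale factor.
#' @param background background image on the supersampled grid, or a scalar
#'   intensity.
#' @param canvas a [canvas_params()].
#' @return a grayscale image.
#' @export
render_object_view <- function(obj, theta = 0, dx = 0, dy = 0, scale = 1,
                               background = 0.5,
                               canvas = canvas_params(64L, supersample = 2L)) {
  G <- canvas$size * canvas$supersample
  cw <- (seq_len(G) - (G + 1) / 2) / G
  xs <- matrix(cw, G, G, byrow = TRUE)
  ys <- matrix(rev(cw), G, G)
  img <- if (is.matrix(background)) background else matrix(background, G, G)

  ang <- (vapply(obj$parts, `[[`, numeric(1), "station") + theta) * pi / 180
  depth <- sin(ang)                      # larger = closer to the viewer
  for (i in order(depth)) {              # paint back to front
    p <- obj$parts[[i]]
    a <- ang[i]
    fore <- 0.45 + 0.55 * abs(cos(a))    # width foreshortening
    cx <- p$radius * cos(a) * scale + dx
    cy <- p$y_offset * scale + dy
    spec <- shape_spec(p$kind,
                       aspect_ratio = p$aspect_ratio / fore,
                       in_plane_rotation = p$rotation,
                       size = min(p$size * scale, 0.95),
                       albedo = p$albedo * (0.8 + 0.2 * depth[i]),
                       texture = p$texture)
    prim <- render_primitive_grid(spec, xs - cx, ys - cy)
    img[prim$mask] <- prim$shade[prim$mask]
  }
  out <- block_downsample(img, canvas$supersample)
  pmin(pmax(out, 0), 1)
}

#' Generate one video sequence
#'
#' Frames interpolate the pose linearly from start to end (rotation,
#' translation, scale), with small seeded Gaussian jitter per frame.
#'
#' @param obj an [object_spec()].
#' @param motion a [motion_params()].
#' @param seed integer seed (controls jitter and background).
#' @param start_theta initial in-depth viewpoint, degrees.
#' @param background_seed seed of the clutter background (defaults to
#'   `seed`).
#' @param canvas a [canvas_params()] for the frames.
#' @param category_label,sequence_id metadata carried on the result.
#' @return an object of class `video_sequence`: list with `frames` (list of
#'   grayscale images), `fps`, labels and the generating parameters.
#' @export
generate_sequence <- function(obj, motion = motion_params(), seed = 1L,
                              start_theta = 0, background_seed = seed,
                              canvas = canvas_params(64L, supersample = 2L),
                              category_label = "object",
                              sequence_id = "seq") {
  stopifnot(inherits(obj, "object_spec"), inherits(motion, "motion_params"))
  n_frames <- round(motion$fps * motion$duration)
  if (n_frames < 2) stop("sequence must have at least 2 frames", call. = FALSE)
  bg <- clutter_background(canvas$size, background_seed, canvas$supersample)
  s <- seq(0, 1, length.out = n_frames)
  theta <- start_theta + s * motion$rotation_span
  dx <- (s - 0.5) * motion$translation_span / canvas$size
  scl <- 1 + (s - 0.5) * motion$scale_span
  withr::with_seed(as.integer(seed), {
    jt <- matrix(stats::rnorm(n_frames * 3, sd = motion$jitter_sd),
                 n_frames, 3)
  })
  frames <- lapply(seq_len(n_frames), function(k) {
    render_object_view(obj,
                       theta = theta[k] + jt[k, 1],
                       dx = dx[k] + jt[k, 2] / canvas$size,
                       dy = jt[k, 3] / canvas$size,
                       scale = scl[k], background = bg, canvas = canvas)
  })
  structure(list(frames = frames, category_label = category_label,
                 sequence_id = sequence_id, fps = motion$fps,
                 motion = motion, seed = as.integer(seed),
                 start_theta = start_theta,
                 background_seed = as.integer(background_seed)),
            class = "video_sequence")
}

#' @export
print.video_sequence <- function(x, ...) {
  cat(sprintf("<video_sequence> %s (%s): %d frames @ %g fps, %dx%d px\n",
              x$sequence_id, x$category_label, length(x$frames), x$fps,
              nrow(x$frames[[1]]), ncol(x$frames[[1]])))
  invisible(x)
}

#' Scale profiles for the video database
#'
#' `"full"` is the full-scale profile (12 categories, 20+ sequences each,
#' 3-5 s at 30 Hz); `"desk"` is the reduced profile used for routine runs on
#' a single CPU (5 sequences per category, 1 s each, 64x64 frames, and a
#' frame stride of 3 when extracting classifier features).
#'
#' @param profile `"desk"` or `"full"`.
#' @return a named list of [generate_video_database()] arguments plus
#'   `frame_stride`.
#' @export
video_profile <- function(profile = c("desk", "full")) {
  profile <- match.arg(profile)
  switch(profile,
    desk = list(n_categories = 12L, n_per_category = 5L, fps = 30,
                duration_range = c(1, 1), frame_size = 64L,
                frame_stride = 3L),
    full = list(n_categories = 12L, n_per_category = 20L, fps = 30,
                 duration_range = c(3, 5), frame_size = 64L,
                 frame_stride = 1L))
}

#' Generate a synthetic video database
#'
#' One fixed object per category; per sequence the background, initial
#' viewpoint, rotation magnitude, translation and scale change all vary
#' (seeded).  Deterministic under `seed`.
#'
#' @param n_categories number of object categories.
#' @param n_per_category sequences per category.
#' @param fps frames per second.
#' @param duration_range range (seconds) from which each sequence's duration
#'   is drawn uniformly.
#' @param frame_size frame side in pixels.
#' @param seed integer RNG seed.
#' @param jitter_sd per-frame pose jitter passed to [motion_params()].
#' @return an object of class `video_db`: list with `sequences`,
#'   `categories`, and a `manifest` tibble (one row per sequence).
#' @export
generate_video_database <- function(n_categories = 12L, n_per_category = 20L,
                                    fps = 30, duration_range = c(3, 5),
                                    frame_size = 64L, seed = 1L,
                                    jitter_sd = 0.3) {
  stopifnot(n_categories >= 1L, n_per_category >= 1L)
  canvas <- canvas_params(frame_size, supersample = 2L)
  categories <- sprintf("object%02d", seq_len(n_categories))
  withr::with_seed(as.integer(seed), {
    object_seeds <- sample.int(1e6, n_categories)
    draws <- list()
    for (ci in seq_len(n_categories)) {
      for (si in seq_len(n_per_category)) {
        draws[[length(draws) + 1L]] <- list(
          ci = ci, si = si,
          duration = stats::runif(1, duration_range[1], duration_range[2]),
          rotation_span = stats::runif(1, 30, 90),
          translation_span = stats::runif(1, 2, 6),
          scale_span = stats::runif(1, 0.1, 0.3),
          start_theta = stats::runif(1, 0, 360),
          seq_seed = sample.int(1e6, 1),
          bg_seed = sample.int(1e6, 1)
        )
      }
    }
  })
  objects <- lapply(object_seeds, object_spec)
  sequences <- lapply(draws, function(d) {
    motion <- motion_params(rotation_span = d$rotation_span,
                            translation_span = d$translation_span,
                            scale_span = d$scale_span, fps = fps,
                            duration = d$duration, jitter_sd = jitter_sd)
    generate_sequence(objects[[d$ci]], motion, seed = d$seq_seed,
                      start_theta = d$start_theta,
                      background_seed = d$bg_seed, canvas = canvas,
                      category_label = categories[d$ci],
                      sequence_id = sprintf("%s_seq%02d",
                                            categories[d$ci], d$si))
  })
  manifest <- purrr::map_dfr(sequences, function(s) {
    tibble::tibble(sequence_id = s$sequence_id,
                   category = s$category_label,
                   fps = s$fps, n_frames = length(s$frames),
                   duration = s$motion$duration,
                   rotation_span = s$motion$rotation_span,
                   translation_span = s$motion$translation_span,
                   scale_span = s$motion$scale_span,
                   start_theta = s$start_theta,
                   background_seed = s$background_seed,
                   seed = s$seed)
  })
  structure(list(sequences = sequences, categories = categories,
                 objects = objects, manifest = manifest, canvas = canvas,
                 seed = as.integer(seed)),
            class = "video_db")
}

#' @export
print.video_db <- function(x, ...) {
  cat(sprintf(
    "<video_db> %d sequences, %d categories, %dx%d px frames, seed %d\n",
    length(x$sequences), length(x$categories), x$canvas$size, x$canvas$size,
    x$seed))
  invisible(x)
}

#' Write a video database to disk
#'
#' Each sequence becomes a directory of zero-padded PNG frames; the database
#' manifest is written as `manifest.csv`.
#'
#' @param db a `video_db`.
#' @param dir output directory.
#' @return `dir`, invisibly.
#' @export
write_video_database <- function(db, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  for (s in db$sequences) {
    sdir <- file.path(dir, s$sequence_id)
    if (!dir.exists(sdir)) dir.create(sdir)
    for (k in seq_along(s$frames)) {
      write_gray_png(s$frames[[k]], file.path(sdir, sprintf("frame%04d.png", k)))
    }
  }
  utils::write.csv(db$manifest, file.path(dir, "manifest.csv"),
                   row.names = FALSE)
  invisible(dir)
}
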