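#' Feature columns learned from transformation sequences
#'
#' The temporal-pooling extension groups several S2 prototypes — the same
#' retinotopic patch imprinted at different frames of a short (~300 ms)
#' window of a transformation sequence — into one feature column.  The
#' column's C2 response is the max over its member views, exactly as the
#' original model's C2 takes a max over positions and scales; with a single
#' view per column the extended model reduces bit-exactly to the original.
#'
#' @name feature-columns
NULL

new_feature_column <- function(views, sequence_id, window, patch_size, band,
                               position, column_id) {
  structure(list(views = views, sequence_id = sequence_id, window = window,
                 patch_size = patch_size, band = band, position = position,
                 column_id = column_id),
            class = "feature_column")
}

#' @export
print.feature_column <- function(x, ...) {
  cat(sprintf(
    "<feature_column> %s: %d view(s) of a %dx%d patch (band %d) from %s frames %d-%d\n",
    x$column_id, length(x$views), x$patch_size, x$patch_size, x$band,
    x$sequence_id, x$window[1], x$window[2]))
  invisible(x)
}

#' Learn feature columns from a video database
#'
#' For each column a sequence, a window start, a scale band and a patch
#' position are drawn (seeded); `views_per_column` frames evenly spaced
#' across the `window_ms` window are then imprinted at that same
#' retinotopic position and band.  Patches whose first-view C1 activity is
#' nearly constant (below `min_patch_sd`) are redrawn, so columns encode
#' actual image structure rather than blank background.
#'
#' The random draws do not depend on `views_per_column`, so columns learned
#' with different view counts from the same seed share their windows,
#' positions and first views — the matched original-model baseline is the
#' first view of each column.
#'
#' @param db a [generate_video_database()] result.
#' @param model an [hmax_model()].
#' @param n_columns number of feature columns.
#' @param views_per_column number of views per column (1 = original model).
#' @param window_ms temporal window length in milliseconds (default 300).
#' @param patch_sizes patch sides cycled across columns (equal counts).
#' @param tracking `"fixed"` keeps one retinotopic anchor for all views;
#'   `"local"` lets each subsequent view's patch follow the feature by a
#'   greedy local search (within `search_radius` C1 units of the previous
#'   view) for the position most similar to the previous view's pattern,
#'   so the views capture the feature's own transformation rather than
#'   mixing it with retinal drift.
#' @param search_radius local-search radius in C1 units (tracking mode).
#' @param seed integer RNG seed.
#' @param min_patch_sd redraw threshold on the first-view patch standard
#'   deviation.
#' @param max_tries redraws allowed per column before accepting the last.
#' @return an object of class `feature_columns` (list of `feature_column`
#'   plus attributes recording the learning configuration).
#' @export
learn_columns <- function(db, model = hmax_model(), n_columns = 150L,
                          views_per_column = 5L, window_ms = 300,
                          patch_sizes = model$patch_sizes,
                          tracking = c("fixed", "local"),
                          search_radius = 2L, seed = 1L,
                          min_patch_sd = 0.02, max_tries = 20L) {
  tracking <- match.arg(tracking)
  stopifnot(inherits(db, "video_db"), n_columns >= 1L,
            views_per_column >= 1L)
  fps <- db$sequences[[1]]$fps
  win <- temporal_window_frames(window_ms, fps)
  if (win < views_per_column) {
    stop(sprintf(
      "window of %d frames (%g ms at %g fps) is shorter than views_per_column = %d",
      win, window_ms, fps, views_per_column), call. = FALSE)
  }
  long_enough <- which(vapply(db$sequences, function(s) length(s$frames),
                              integer(1)) >= win)
  if (length(long_enough) == 0L) {
    stop("no sequence is at least one temporal window long", call. = FALSE)
  }

  c1_cache <- new.env(parent = emptyenv())
  c1_of <- function(seq_idx, frame) {
    key <- sprintf("s%d_f%d", seq_idx, frame)
    got <- get0(key, envir = c1_cache)
    if (is.null(got)) {
      got <- c1_response(s1_response(db$sequences[[seq_idx]]$frames[[frame]],
                                     model$bank), model$bank)
      assign(key, got, envir = c1_cache)
    }
    got
  }

  columns <- vector("list", n_columns)
  withr::with_seed(as.integer(seed), {
    for (i in seq_len(n_columns)) {
      p <- patch_sizes[(i - 1L) %% length(patch_sizes) + 1L]
      pick <- NULL
      for (try in seq_len(max_tries)) {
        si <- long_enough[sample.int(length(long_enough), 1L)]
        nfr <- length(db$sequences[[si]]$frames)
        f0 <- sample.int(nfr - win + 1L, 1L)
        c1 <- c1_of(si, f0)
        fits <- which(vapply(c1, function(b) {
          all(dim(b$maps)[1:2] >= p)
        }, logical(1)))
        if (length(fits) == 0L) next
        band <- fits[sample.int(length(fits), 1L)]
        dm <- dim(c1[[band]]$maps)
        r <- sample.int(dm[1] - p + 1L, 1L)
        cc <- sample.int(dm[2] - p + 1L, 1L)
        patch <- c1[[band]]$maps[r:(r + p - 1L), cc:(cc + p - 1L), ,
                                 drop = FALSE]
        pick <- list(si = si, f0 = f0, band = band, pos = c(r, cc))
        if (stats::sd(patch) >= min_patch_sd) break
      }
      if (is.null(pick)) {
        stop(sprintf("no valid patch found for column %d (patch size %d)",
                     i, p), call. = FALSE)
      }
      vf <- round(seq(pick$f0, pick$f0 + win - 1L,
                      length.out = views_per_column))
      views <- vector("list", length(vf))
      pos <- pick$pos
      for (vi in seq_along(vf)) {
        c1v <- c1_of(pick$si, vf[vi])
        if (tracking == "local" && vi > 1L) {
          pos <- track_patch(c1v[[pick$band]]$maps, p, pos,
                             views[[vi - 1L]]$w, search_radius)
        }
        views[[vi]] <- imprint_prototype(
          c1v, pick$band, pos, p,
          source = list(sequence = db$sequences[[pick$si]]$sequence_id,
                        frame = vf[vi]))
      }
      columns[[i]] <- new_feature_column(
        views, db$sequences[[pick$si]]$sequence_id,
        c(pick$f0, pick$f0 + win - 1L), p, pick$band, pick$pos,
        sprintf("col%03d", i))
    }
  })
  structure(columns, class = "feature_columns",
            config = list(n_columns = n_columns,
                          views_per_column = as.integer(views_per_column),
                          window_ms = window_ms, window_frames = win,
                          patch_sizes = patch_sizes, tracking = tracking,
                          search_radius = as.integer(search_radius),
                          seed = as.integer(seed),
                          min_patch_sd = min_patch_sd))
}

# Greedy local search: the patch position within `radius` of `pos` whose
# pattern is closest (L2) to the previous view's pattern.
track_patch <- function(maps, p, pos, w_prev, radius) {
  H <- dim(maps)[1]; W <- dim(maps)[2]
  rs <- max(1L, pos[1] - radius):min(H - p + 1L, pos[1] + radius)
  cs <- max(1L, pos[2] - radius):min(W - p + 1L, pos[2] + radius)
  best <- pos; best_d <- Inf
  for (r in rs) {
    for (cc in cs) {
      x <- as.vector(maps[r:(r + p - 1L), cc:(cc + p - 1L), , drop = FALSE])
      d <- sum((x - w_prev)^2)
      if (d < best_d) { best_d <- d; best <- c(r, cc) }
    }
  }
  as.integer(best)
}

#' Frames spanned by a temporal window
#'
#' @param window_ms window length in milliseconds.
#' @param fps frame rate.
#' @return integer frame count, `round(window_ms / 1000 * fps)`.
#' @export
temporal_window_frames <- function(window_ms, fps) {
  as.integer(round(window_ms / 1000 * fps))
}

#' @export
print.feature_columns <- function(x, ...) {
  cfg <- attr(x, "config")
  cat(sprintf(
    "<feature_columns> %d columns, %d view(s) each, %g ms window (%d frames), patch sizes {%s}\n",
    length(x), cfg$views_per_column, cfg$window_ms, cfg$window_frames,
    paste(cfg$patch_sizes, collapse = ", ")))
  invisible(x)
}

#' Single-view baseline prototypes of a column set
#'
#' The matched original-model baseline: the first view of every column.
#'
#' @param columns a [learn_columns()] result.
#' @return named list of `s2_prototype`.
#' @export
original_prototypes <- function(columns) {
  stats::setNames(lapply(columns, function(col) col$views[[1]]),
                  vapply(columns, `[[`, character(1), "column_id"))
}

#' Extended C2: max over the views of one feature column
#'
#' @param image grayscale image or precomputed `c1_maps`.
#' @param column a `feature_column`.
#' @param model an [hmax_model()].
#' @return scalar in (0, 1\].
#' @export
extended_c2 <- function(image, column, model = hmax_model()) {
  stopifnot(inherits(column, "feature_column"), length(column$views) >= 1L)
  c1 <- if (inherits(image, "c1_maps")) image else
    c1_response(s1_response(image, model$bank), model$bank)
  max(c2_batch(c1, column$views, model))
}

#' Encode an image with extended (temporally pooled) feature columns
#'
#' Component `k` is the max C2 response over the views of column `k`.  With
#' single-view columns this is exactly [encode()] on the corresponding
#' prototypes.
#'
#' @param image grayscale image or precomputed `c1_maps`.
#' @param columns a [learn_columns()] result.
#' @param model an [hmax_model()].
#' @return named numeric vector, one value in (0, 1\] per column.
#' @export
encode_extended <- function(image, columns, model = hmax_model()) {
  stopifnot(length(columns) >= 1L)
  both <- encode_both(image, columns, model)
  both$extended
}

# Original and extended activity vectors from one shared C2 pass over all
# view prototypes (guarantees matched comparisons and halves the cost).
encode_both <- function(image, columns, model = hmax_model()) {
  c1 <- if (inherits(image, "c1_maps")) image else
    c1_response(s1_response(image, model$bank), model$bank)
  views <- unlist(lapply(columns, `[[`, "views"), recursive = FALSE)
  nv <- vapply(columns, function(col) length(col$views), integer(1))
  v <- c2_batch(c1, views, model)
  idx <- rep.int(seq_along(columns), nv)
  first <- c(1L, cumsum(nv)[-length(nv)] + 1L)
  ids <- vapply(columns, `[[`, character(1), "column_id")
  list(original = stats::setNames(v[first], ids),
       extended = stats::setNames(as.numeric(
         tapply(v, idx, max)), ids))
}
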