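#' Feature matrices for all (or a stride of) frames of a video database
#'
#' Encodes frames with the extended columns and their matched single-view
#' baseline in one shared C2 pass per frame.
#'
#' @param db a [generate_video_database()] result.
#' @param columns a [learn_columns()] result.
#' @param model an [hmax_model()].
#' @param frame_stride keep every `frame_stride`-th frame of each sequence.
#' @return list with matrices `original` and `extended` (frames x columns)
#'   and `info`, a tibble with `sequence_id` and `category` per row.
#' @export
frame_features <- function(db, columns, model = hmax_model(),
                           frame_stride = 1L) {
  stopifnot(inherits(db, "video_db"), frame_stride >= 1L)
  info <- list(); orig <- list(); ext <- list()
  for (s in db$sequences) {
    idx <- seq(1L, length(s$frames), by = frame_stride)
    for (k in idx) {
      both <- encode_both(s$frames[[k]], columns, model)
      orig[[length(orig) + 1L]] <- both$original
      ext[[length(ext) + 1L]] <- both$extended
      info[[length(info) + 1L]] <- tibble::tibble(
        sequence_id = s$sequence_id, category = s$category_label, frame = k)
    }
  }
  list(original = do.call(rbind, orig), extended = do.call(rbind, ext),
       info = dplyr::bind_rows(info))
}

#' Run the full NAP-versus-MP experiment
#'
#' Generates the stimulus set and video database, learns temporally pooled
#' feature columns, encodes all stimuli with the extended model and its
#' matched single-view baseline, and runs the modulation analysis for both.
#'
#' @param seed master integer seed; sub-seeds for the generators and
#'   learning are derived deterministically from it.
#' @param n_families stimulus families to generate.
#' @param profile video database scale profile, see [video_profile()].
#' @param model an [hmax_model()].
#' @param n_columns,views_per_column,window_ms passed to [learn_columns()].
#' @param criterion passed to [modulation_analysis()].
#' @param db optional pre-generated video database (skips generation).
#' @param stim_set optional pre-generated stimulus set.
#' @return list with `stim_set`, `db`, `columns`, `responses` (both
#'   models), and `modulation` — a list of `nap_modulation` objects named
#'   `original` and `extended`.
#' @export
run_nap_experiment <- function(seed = 1L, n_families = 36L,
                               profile = "desk", model = hmax_model(),
                               n_columns = 150L, views_per_column = 5L,
                               window_ms = 300,
                               criterion = responsiveness_criterion(),
                               db = NULL, stim_set = NULL) {
  seeds <- derive_seeds(seed, 3L)
  prof <- video_profile(profile)
  if (is.null(stim_set)) {
    # probes share the video frames' canonical input scale: the model sees
    # every image through the same front end, so probing at a different
    # resolution than training would confound scale with shape
    stim_set <- build_stimulus_set(n_families, seed = seeds[1],
                                   canvas = canvas_params(prof$frame_size))
  }
  if (is.null(db)) {
    db <- generate_video_database(
      n_categories = prof$n_categories, n_per_category = prof$n_per_category,
      fps = prof$fps, duration_range = prof$duration_range,
      frame_size = prof$frame_size, seed = seeds[2])
  }
  columns <- learn_columns(db, model, n_columns = n_columns,
                           views_per_column = views_per_column,
                           window_ms = window_ms, seed = seeds[3])
  responses <- stimulus_responses(stim_set, columns, model)
  modulation <- lapply(
    stats::setNames(c("original", "extended"), c("original", "extended")),
    function(mn) {
      modulation_analysis(dplyr::filter(responses, .data$model == mn),
                          criterion = criterion)
    })
  list(stim_set = stim_set, db = db, columns = columns,
       responses = responses, modulation = modulation, model = model,
       seed = as.integer(seed))
}

#' Run the viewpoint-generalization classification experiment
#'
#' @param db a [generate_video_database()] result.
#' @param columns a [learn_columns()] result.
#' @param model an [hmax_model()].
#' @param frame_stride frame subsampling for feature extraction.
#' @param n_splits random sequence-level splits.
#' @param seed integer seed for the splits.
#' @param features optional precomputed [frame_features()] result.
#' @return an `svm_benchmark` object (the `features` used are attached as
#'   attribute `"features"`).
#' @export
run_view_generalization <- function(db, columns, model = hmax_model(),
                                    frame_stride = 3L, n_splits = 15L,
                                    seed = 1L, features = NULL) {
  if (is.null(features)) {
    features <- frame_features(db, columns, model, frame_stride)
  }
  bench <- svm_benchmark(
    list(original = features$original, extended = features$extended),
    labels = features$info$category,
    sequence_ids = features$info$sequence_id,
    n_splits = n_splits, seed = seed)
  attr(bench, "features") <- features
  bench
}

# Deterministic 31-bit sub-seeds from a master seed.
derive_seeds <- function(seed, n) {
  withr::with_seed(as.integer(seed), {
    sample.int(.Machine$integer.max - 1L, n)
  })
}
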