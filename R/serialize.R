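#' Serialize learned feature columns to portable JSON
#'
#' Writes a versioned, self-describing JSON container holding the learning
#' configuration and, per column, the window metadata and the full weight
#' vector of every view.  Weights are written as decimal strings with 17
#' significant digits, which reproduces the binary doubles exactly on read.
#'
#' @param columns a [learn_columns()] result.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_columns <- function(columns, path) {
  stopifnot(inherits(columns, "feature_columns"))
  payload <- list(
    schema = "hmaxtp/feature_columns",
    schema_version = 1L,
    config = attr(columns, "config"),
    columns = lapply(columns, function(col) {
      list(column_id = col$column_id,
           sequence_id = col$sequence_id,
           window = col$window,
           patch_size = col$patch_size,
           band = col$band,
           position = col$position,
           views = lapply(col$views, function(v) {
             list(w = sprintf("%.17g", v$w), patch_size = v$patch_size,
                  band = v$band,
                  position = v$position, n_orientations = v$n_orientations,
                  source = v$source)
           }))
    }))
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read feature columns written by [write_columns()]
#'
#' @param path JSON file path.
#' @return a `feature_columns` object.
#' @export
read_columns <- function(path) {
  payload <- jsonlite::read_json(path, simplifyVector = FALSE)
  if (!identical(payload$schema, "hmaxtp/feature_columns")) {
    stop("not a feature-columns container", call. = FALSE)
  }
  columns <- lapply(payload$columns, function(col) {
    views <- lapply(col$views, function(v) {
      structure(list(w = as.numeric(unlist(v$w)),
                     patch_size = as.integer(v$patch_size),
                     band = as.integer(v$band),
                     position = as.integer(unlist(v$position)),
                     n_orientations = as.integer(v$n_orientations),
                     source = v$source),
                class = "s2_prototype")
    })
    new_feature_column(views, col$sequence_id,
                       as.integer(unlist(col$window)),
                       as.integer(col$patch_size), as.integer(col$band),
                       as.integer(unlist(col$position)), col$column_id)
  })
  cfg <- payload$config
  cfg$patch_sizes <- as.integer(unlist(cfg$patch_sizes))
  structure(columns, class = "feature_columns", config = cfg)
}
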