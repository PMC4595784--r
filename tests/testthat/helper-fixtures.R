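# Shared fixtures, memoised so expensive objects are built once per run.

.fixture_env <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  got <- get0(name, envir = .fixture_env)
  if (is.null(got)) {
    got <- builder()
    assign(name, got, envir = .fixture_env)
  }
  got
}

# A small bank (two filter sizes = one scale band) for fast unit tests.
tiny_bank <- function() {
  fixture("tiny_bank", function() {
    gabor_bank(n_orientations = 4L, filter_sizes = c(7L, 9L),
               pool_sizes = 6L, pool_strides = 3L)
  })
}

tiny_model <- function() {
  fixture("tiny_model", function() {
    hmax_model(tiny_bank(), patch_sizes = c(2L, 4L))
  })
}

# One rendered mid-size test image.
tiny_image <- function() {
  fixture("tiny_image", function() {
    render_shape(shape_spec("cylinder", in_plane_rotation = 20),
                 canvas_params(48L))
  })
}

# A very small video database (2 categories x 3 sequences x 15 frames,
# 48 px frames) for the temporal-pooling unit tests.
tiny_db <- function() {
  fixture("tiny_db", function() {
    generate_video_database(n_categories = 2L, n_per_category = 3L,
                            fps = 30, duration_range = c(0.5, 0.5),
                            frame_size = 48L, seed = 7L)
  })
}

tiny_columns <- function(views = 3L) {
  key <- paste0("tiny_columns_", views)
  fixture(key, function() {
    learn_columns(tiny_db(), tiny_model(), n_columns = 8L,
                  views_per_column = views, window_ms = 300,
                  patch_sizes = c(2L, 4L), seed = 5L)
  })
}

# Brute-force oracles -------------------------------------------------------

# Neighborhood/scale max pooling, naive loops.
oracle_pool_max <- function(maps_list, pool, stride) {
  H <- dim(maps_list[[1]])[1]; W <- dim(maps_list[[1]])[2]
  O <- dim(maps_list[[1]])[3]
  rs <- seq(1L, H - pool + 1L, by = stride)
  cs <- seq(1L, W - pool + 1L, by = stride)
  out <- array(NA_real_, c(length(rs), length(cs), O))
  for (o in seq_len(O)) {
    for (i in seq_along(rs)) {
      for (j in seq_along(cs)) {
        vals <- vapply(maps_list, function(m) {
          max(m[rs[i]:(rs[i] + pool - 1L), cs[j]:(cs[j] + pool - 1L), o])
        }, numeric(1))
        out[i, j, o] <- max(vals)
      }
    }
  }
  out
}

# Exhaustive signed-rank p-value: enumerate all 2^n sign assignments of the
# midranked absolute differences.
oracle_signed_rank_p <- function(x, y) {
  d <- x - y
  d <- d[d != 0]
  n <- length(d)
  r <- rank(abs(d))
  w <- sum(r[d > 0])
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  ws <- as.vector(signs %*% r)
  p_le <- mean(ws <= w + 1e-9)
  p_ge <- mean(ws >= w - 1e-9)
  min(1, 2 * min(p_le, p_ge))
}
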