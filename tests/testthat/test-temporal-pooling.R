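test_that("a 300 ms window at 30 Hz spans 9 frames", {
  expect_identical(temporal_window_frames(300, 30), 9L)
  expect_identical(temporal_window_frames(300, 10), 3L)
})

test_that("column learning is deterministic and respects window geometry", {
  cols <- tiny_columns(views = 3L)
  cols2 <- learn_columns(tiny_db(), tiny_model(), n_columns = 8L,
                         views_per_column = 3L, window_ms = 300,
                         patch_sizes = c(2L, 4L), seed = 5L)
  expect_equal(cols, cols2, ignore_attr = FALSE)
  for (col in cols) {
    expect_length(col$views, 3L)
    expect_equal(col$window[2] - col$window[1] + 1L,
                 temporal_window_frames(300, 30))
    # all views share the patch geometry (same feature, different frames)
    for (v in col$views) {
      expect_identical(v$patch_size, col$patch_size)
      expect_identical(v$band, col$band)
      expect_identical(v$position, col$position)
      fr <- v$source$frame
      expect_true(fr >= col$window[1] && fr <= col$window[2])
    }
  }
})

test_that("a window shorter than the view count is rejected", {
  expect_error(
    learn_columns(tiny_db(), tiny_model(), n_columns = 2L,
                  views_per_column = 12L, window_ms = 300, seed = 1L),
    "shorter than")
})

test_that("single-view columns reproduce the original model bit-exactly", {
  cols1 <- tiny_columns(views = 1L)
  cols3 <- tiny_columns(views = 3L)
  # same seed: same windows, positions, first views
  for (i in seq_along(cols1)) {
    expect_identical(cols1[[i]]$views[[1]], cols3[[i]]$views[[1]])
    expect_length(cols1[[i]]$views, 1L)
  }
  model <- tiny_model()
  img <- tiny_image()
  ext <- encode_extended(img, cols1, model)
  orig <- encode(img, original_prototypes(cols1), model)
  expect_identical(unname(ext), unname(orig))
})

test_that("extended C2 is the running max over member views", {
  model <- tiny_model()
  cols <- tiny_columns(views = 3L)
  img <- tiny_image()
  c1 <- c1_response(s1_response(img, model$bank), model$bank)
  for (col in cols[1:4]) {
    per_view <- vapply(col$views, function(v) {
      c2_response(s2_response(c1, v, model))
    }, numeric(1))
    running <- -Inf
    for (pv in per_view) running <- max(running, pv)
    e <- extended_c2(c1, col, model)
    expect_equal(e, running, tolerance = 1e-9)
    expect_true(all(e >= per_view - 1e-9))
  }
})

test_that("extended encoding dominates every single-view sub-column and
           scores 1 on imprinted frames", {
  model <- tiny_model()
  cols <- tiny_columns(views = 3L)
  db <- tiny_db()
  img <- tiny_image()
  ext <- encode_extended(img, cols, model)
  orig <- encode(img, original_prototypes(cols), model)
  expect_true(all(ext >= orig - 1e-12))
  expect_length(ext, length(cols))

  # presenting a frame whose patch was imprinted into column k -> k = 1
  col <- cols[[2]]
  seq_idx <- which(vapply(db$sequences, `[[`, character(1), "sequence_id")
                   == col$sequence_id)
  frame <- db$sequences[[seq_idx]]$frames[[col$views[[1]]$source$frame]]
  v <- encode_extended(frame, cols, model)
  expect_equal(unname(v[2]), 1, tolerance = 1e-9)
})

test_that("temporal pooling stabilizes responses across a column's own
           window", {
  model <- tiny_model()
  cols <- tiny_columns(views = 3L)
  db <- tiny_db()
  seqs <- stats::setNames(db$sequences,
                          vapply(db$sequences, `[[`, character(1),
                                 "sequence_id"))
  var_ext <- c(); var_single <- c()
  for (col in cols) {
    frames <- seqs[[col$sequence_id]]$frames[col$window[1]:col$window[2]]
    c1s <- lapply(frames, function(f) {
      c1_response(s1_response(f, model$bank), model$bank)
    })
    ev <- vapply(c1s, function(c1) extended_c2(c1, col, model), numeric(1))
    var_ext <- c(var_ext, stats::var(ev))
    sv <- vapply(col$views, function(view) {
      resp <- vapply(c1s, function(c1) {
        max(hmaxtp:::c2_batch(c1, list(view), model))
      }, numeric(1))
      stats::var(resp)
    }, numeric(1))
    var_single <- c(var_single, min(sv))
  }
  # across columns, pooled responses vary no more than the steadiest
  # single view (statistical assertion)
  expect_lte(mean(var_ext), mean(var_single) + 1e-12)
})

test_that("feature columns survive a JSON round trip losslessly", {
  cols <- tiny_columns(views = 3L)
  path <- withr::local_tempfile(fileext = ".json")
  write_columns(cols, path)
  back <- read_columns(path)
  expect_length(back, length(cols))
  for (i in seq_along(cols)) {
    expect_identical(back[[i]]$views[[1]]$w, cols[[i]]$views[[1]]$w)
    expect_identical(back[[i]]$position, cols[[i]]$position)
    expect_identical(back[[i]]$window, cols[[i]]$window)
  }
  model <- tiny_model()
  img <- tiny_image()
  expect_identical(encode_extended(img, back, model),
                   encode_extended(img, cols, model))
})
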