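test_that("rendering is deterministic and sensitive to geometry", {
  cv <- canvas_params(48L)
  spec <- shape_spec("cylinder", in_plane_rotation = 10)
  a <- render_shape(spec, cv)
  b <- render_shape(spec, cv)
  expect_identical(a, b)
  expect_equal(dim(a), c(48L, 48L))
  expect_true(all(a >= 0 & a <= 1))

  curved <- spec
  curved$axis_curvature <- 0.3
  expect_gt(pixel_distance(a, render_shape(curved, cv)), 0)
})

test_that("degenerate geometry is rejected before rendering", {
  expect_error(shape_spec("brick", size = 0), "degenerate")
  expect_error(shape_spec("brick", aspect_ratio = 0), "degenerate")
  expect_error(shape_spec("brick", size = NA_real_), "finite")
})

test_that("pixel_distance is a Euclidean metric on intensities", {
  a <- matrix(0, 2, 2)
  b <- matrix(c(0.3, 0, 0.4, 0), 2, 2)
  expect_identical(pixel_distance(a, a), 0)
  expect_equal(pixel_distance(a, b), 0.5)

  set.seed(1)
  for (i in 1:5) {
    x <- matrix(runif(16), 4, 4)
    y <- matrix(runif(16), 4, 4)
    expect_equal(pixel_distance(x, y), pixel_distance(y, x))
  }
  expect_error(pixel_distance(a, matrix(0, 3, 3)), "dimensions")
})

test_that("make_family varies MP and NAP along distinct dimensions", {
  cv <- canvas_params(48L)
  bs <- shape_spec("cylinder")
  fam <- make_family(bs, "aspect_ratio", c(0, 0.2, 0.4, 0.6),
                     "axis_curvature", nap_magnitude = 0.5, canvas = cv)
  # zero first amplitude: MP1 identical to the base
  expect_identical(fam$mp[[1]], fam$base)
  # the NAP variant of a straight-axis base has curvature > 0, rest equal
  nap_spec <- apply_nap(bs, "axis_curvature", 0.5)
  expect_gt(nap_spec$axis_curvature, 0)
  for (f in c("taper", "aspect_ratio", "size", "apex_angle")) {
    expect_identical(nap_spec[[f]], bs[[f]])
  }
  expect_error(
    make_family(bs, "aspect_ratio", c(0.1, 0.2, 0.3, 0.4), "aspect_ratio"),
    "distinct")
  expect_error(
    make_family(bs, "aspect_ratio", c(0.4, 0.3, 0.2, 0.1), "axis_curvature"),
    "increasing")
})

test_that("NAP calibration enforces the MP2 pixel bound", {
  cv <- canvas_params(48L)
  fam <- make_family(shape_spec("cylinder"), "size", c(0.25, 0.5, 0.75, 1),
                     "taper", nap_magnitude = 1, canvas = cv)
  cal <- calibrate_nap(fam)
  expect_lte(cal$distances[["nap"]], cal$distances[["mp2"]])

  # already satisfying the bound: returned unchanged
  again <- calibrate_nap(cal)
  expect_identical(again$nap, cal$nap)
  expect_identical(again$nap_magnitude, cal$nap_magnitude)

  # a family whose MP2 equals its base leaves no room for any
  # categorical change
  broken <- fam
  broken$mp[[2]] <- broken$base
  broken$distances <- family_distances(broken)
  expect_error(calibrate_nap(broken), "infeasible")
})

test_that("generated stimulus sets satisfy the calibration and
           monotonicity invariants", {
  set <- build_stimulus_set(6L, seed = 42L, canvas = canvas_params(48L))
  expect_length(set$families, 6L)
  for (f in set$families) {
    d <- f$distances
    expect_lte(d[["nap"]], d[["mp2"]] + 1e-9)
    expect_true(all(diff(d[1:4]) >= 0))
    expect_length(f$mp, 4L)
    dims <- vapply(c(list(f$base), f$mp, list(f$nap)), dim,
                   integer(2))
    expect_true(all(dims == dims[, 1]))
  }
  # deterministic under seed
  set2 <- build_stimulus_set(6L, seed = 42L, canvas = canvas_params(48L))
  expect_identical(set$manifest, set2$manifest)
  expect_identical(set$families[[3]]$nap, set2$families[[3]]$nap)

  one <- build_stimulus_set(1L, seed = 3L, canvas = canvas_params(48L))
  expect_length(one$families, 1L)
})

test_that("stimulus sets round-trip through PNG files and a manifest", {
  set <- build_stimulus_set(1L, seed = 3L, canvas = canvas_params(48L))
  dir <- withr::local_tempdir()
  write_stimulus_set(set, dir)
  fam <- set$families[[1]]
  files <- list.files(dir, pattern = "\\.png$")
  expect_length(files, 6L)
  back <- read_gray_png(file.path(dir, paste0(fam$family_id, "_base.png")))
  expect_lt(max(abs(back - fam$base)), 1 / 255)
  man <- read.csv(file.path(dir, "manifest.csv"))
  expect_equal(man$family_id, fam$family_id)
})
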