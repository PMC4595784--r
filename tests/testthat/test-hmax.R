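test_that("Gabor kernels are zero-mean and unit-norm", {
  bank <- tiny_bank()
  for (ks in bank$kernels) {
    for (k in ks) {
      expect_lt(abs(mean(k)), 1e-12)
      expect_equal(sum(k^2), 1, tolerance = 1e-12)
    }
  }
})

test_that("S1 responses vanish on uniform input and prefer the matching
           orientation", {
  bank <- tiny_bank()
  u <- matrix(0.3, 32, 32)
  expect_equal(max(unlist(s1_response(u, bank))), 0)

  G <- 33L
  r <- seq_len(G) - (G + 1) / 2
  for (oi in seq_along(bank$orientations)) {
    th <- bank$orientations[oi] * pi / 180
    x <- matrix(r, G, G, byrow = TRUE)
    y <- matrix(r, G, G)
    perp <- -x * sin(th) + y * cos(th)
    bar <- 0.2 + 0.6 * (abs(perp) < 2)
    s1 <- s1_response(bar, bank)
    peaks <- vapply(seq_along(bank$orientations), function(o) {
      max(vapply(s1, function(a) max(a[, , o]), numeric(1)))
    }, numeric(1))
    expect_equal(which.max(peaks), oi)
  }
})

test_that("S1 is exactly invariant to affine intensity rescaling", {
  bank <- tiny_bank()
  img <- tiny_image()
  a <- s1_response(img, bank)
  b <- s1_response(0.45 * img + 0.3, bank)
  expect_lt(max(abs(unlist(a) - unlist(b))), 1e-6)
})

test_that("images smaller than the largest kernel are rejected", {
  expect_error(s1_response(matrix(0.5, 6, 6), tiny_bank()), "smaller")
})

test_that("C1 equals identity pooling with pool size 1 and passes constants", {
  one_band <- list(bands = list(list(size_idx = 1L, pool_size = 1L,
                                     stride = 1L)))
  s1 <- list(array(runif(8 * 8 * 2), c(8, 8, 2)))
  c1 <- c1_response(s1, one_band)
  expect_equal(c1[[1]]$maps, s1[[1]])

  s1c <- list(array(0.7, c(8, 8, 2)))
  pooled <- c1_response(s1c, list(bands = list(list(size_idx = 1L,
                                                    pool_size = 3L,
                                                    stride = 2L))))
  expect_true(all(pooled[[1]]$maps == 0.7))
})

test_that("C1 matches the brute-force neighborhood/scale max on random
           inputs", {
  set.seed(99)
  for (i in 1:100) {
    H <- sample(6:12, 1)
    pool <- sample(2:4, 1)
    stride <- sample(1:3, 1)
    s1 <- list(array(runif(H * H * 2), c(H, H, 2)),
               array(runif(H * H * 2), c(H, H, 2)))
    bank <- list(bands = list(list(size_idx = c(1L, 2L),
                                   pool_size = pool, stride = stride)))
    c1 <- c1_response(s1, bank)
    expect_identical(c1[[1]]$maps, oracle_pool_max(s1, pool, stride))
  }
})

test_that("gaussian tuning matches its closed form and is monotone", {
  expect_identical(gaussian_tuning(c(1, 2), c(1, 2), 0.3), 1)
  expect_equal(gaussian_tuning(c(1, 1), c(0, 0), 0.5), exp(-1),
               tolerance = 1e-12)
  set.seed(3)
  for (i in 1:50) {
    w <- runif(6); x <- runif(6); g <- runif(1, 0.01, 2)
    expect_equal(gaussian_tuning(x, w, g), exp(-g * sum((w - x)^2)),
                 tolerance = 1e-12)
  }
  # strictly decreasing in the distance
  w <- rep(0, 4)
  d <- seq(0.1, 2, by = 0.1)
  resp <- vapply(d, function(s) gaussian_tuning(rep(s / 2, 4), w, 0.7),
                 numeric(1))
  expect_true(all(diff(resp) < 0))
  expect_error(gaussian_tuning(1:3, 1:4, 1), "equal length")
})

test_that("imprinting stores the local C1 pattern and reproduces a perfect
           self-match", {
  model <- tiny_model()
  img <- tiny_image()
  c1 <- c1_response(s1_response(img, model$bank), model$bank)
  pr <- imprint_prototype(c1, band = 1L, position = c(3L, 4L),
                          patch_size = 4L, source = "tiny")
  expect_length(pr$w, 4L * 4L * 4L)
  s2 <- s2_response(c1, pr, model)
  expect_equal(s2[[1]][3, 4], 1, tolerance = 1e-12)
  expect_equal(c2_response(s2), 1, tolerance = 1e-9)

  pr2 <- imprint_prototype(c1, band = 1L, position = c(1L, 1L),
                           patch_size = 4L)
  expect_false(identical(pr$w, pr2$w))
  expect_error(imprint_prototype(c1, band = 1L, position = c(100L, 1L),
                                 patch_size = 4L), "out of bounds")
})

test_that("S2 maps equal a brute-force loop of gaussian_tuning over
           patches", {
  model <- tiny_model()
  img <- tiny_image()
  c1 <- c1_response(s1_response(img, model$bank), model$bank)
  pr <- imprint_prototype(c1, band = 1L, position = c(2L, 5L),
                          patch_size = 4L)
  s2 <- s2_response(c1, pr, model)
  gamma <- model$gamma[["4"]] / sum(pr$w^2)   # energy-relative sharpness
  maps <- c1[[1]]$maps
  H <- dim(maps)[1]; W <- dim(maps)[2]
  for (r in seq_len(H - 3L)) {
    for (cc in seq_len(W - 3L)) {
      x <- as.vector(maps[r:(r + 3L), cc:(cc + 3L), , drop = FALSE])
      expect_equal(s2[[1]][r, cc], gaussian_tuning(x, pr$w, gamma),
                   tolerance = 1e-12)
    }
  }
  expect_true(all(unlist(s2) > 0 & unlist(s2) <= 1))
})

test_that("C2 is the global max and batch encoding equals the per-prototype
           path", {
  model <- tiny_model()
  img <- tiny_image()
  c1 <- c1_response(s1_response(img, model$bank), model$bank)
  protos <- list(
    imprint_prototype(c1, 1L, c(2L, 2L), 4L),
    imprint_prototype(c1, 1L, c(6L, 3L), 2L),
    imprint_prototype(c1, 1L, c(4L, 8L), 4L))
  v <- encode(img, protos, model)
  expect_length(v, 3L)
  for (i in seq_along(protos)) {
    s2 <- s2_response(c1, protos[[i]], model)
    expect_equal(unname(v[i]), max(unlist(lapply(s2, max))),
                 tolerance = 1e-9)
  }
  expect_true(all(v > 0 & v <= 1))
  # purity: identical images give identical vectors
  expect_identical(v, encode(img, protos, model))
})

test_that("C2 responses tolerate small translations of the input", {
  model <- tiny_model()
  img <- tiny_image()
  c1 <- c1_response(s1_response(img, model$bank), model$bank)
  protos <- lapply(list(c(3L, 3L), c(5L, 7L), c(8L, 4L)), function(pos) {
    imprint_prototype(c1, 1L, pos, 4L)
  })
  v0 <- encode(img, protos, model)
  shifts <- list(c(2L, 0L), c(0L, 3L), c(-2L, 2L))
  deltas <- vapply(shifts, function(d) {
    vs <- encode(shift_image(img, d[1], d[2], fill = 0.5), protos, model)
    mean(abs(vs - v0))
  }, numeric(1))
  expect_lt(mean(deltas), 0.05)
})
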