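test_that("coordinate grids follow the pixel-centre formula", {
  g <- dsnt_grids(3, 2)
  expect_equal(g$X[1, ], c(-0.5, 0.5))
  expect_equal(g$Y[, 1], c(-2 / 3, 0, 2 / 3))
  # X constant down columns, Y constant along rows
  expect_true(all(apply(g$X, 2, function(col) length(unique(col)) == 1)))
  expect_true(all(apply(g$Y, 1, function(row) length(unique(row)) == 1)))
  # entries strictly inside (-1, 1) and centred on zero
  expect_lt(max(abs(g$X)), 1)
  expect_equal(mean(g$X), 0)
  expect_equal(mean(g$Y), 0)
})

test_that("the endpoint grid convention reaches the boundary exactly", {
  g <- dsnt_grids(4, 5, convention = "endpoint")
  expect_equal(g$X[1, ], seq(-1, 1, length.out = 5))
  expect_equal(range(g$Y), c(-1, 1))
  expect_error(dsnt_grids(0, 3), "positive")
})

test_that("the spatial softmax has a closed-form value on a known channel", {
  z <- matrix(c(log(3), 0, 0, 0), 2, 2)
  zn <- normalize_heatmaps(z)
  expect_equal(zn[, , 1], matrix(c(0.5, 1 / 6, 1 / 6, 1 / 6), 2, 2),
               tolerance = 1e-14)
  ex <- dsnt_expectation(zn)
  expect_equal(ex$x, -1 / 6, tolerance = 1e-14)
  expect_equal(ex$y, -1 / 6, tolerance = 1e-14)
})

test_that("soft-argmax outputs stay strictly inside the open unit square", {
  set.seed(31)
  z <- array(rnorm(16 * 12 * 5, sd = 4), c(16, 12, 5))
  ex <- dsnt_expectation(normalize_heatmaps(z))
  expect_true(all(abs(ex$x) < 1 & abs(ex$y) < 1))
})

test_that("a sharply peaked heatmap soft-decodes to the peak's grid value", {
  z <- array(0, c(9, 9, 1))
  z[3, 7, 1] <- 60 # overwhelming logit
  g <- dsnt_grids(9, 9)
  ex <- dsnt_expectation(normalize_heatmaps(z))
  expect_equal(ex$x, g$X[3, 7], tolerance = 1e-12)
  expect_equal(ex$y, g$Y[3, 7], tolerance = 1e-12)
})

test_that("the analytic softmax-expectation gradient matches its definition", {
  set.seed(5)
  z <- array(rnorm(6 * 5 * 2), c(6, 5, 2))
  gx <- rnorm(2); gy <- rnorm(2)
  ana <- dsnt_expectation_backward(z, gx, gy)
  f <- function(zz) {
    ex <- dsnt_expectation(normalize_heatmaps(array(zz, dim(z))))
    sum(gx * ex$x + gy * ex$y)
  }
  fd <- num_grad(f, z)
  expect_lt(rel_err(ana, fd), 1e-6)
})

test_that("the distribution regulariser vanishes only at the target blob", {
  m <- 11; n <- 11
  xy <- c(0.2, -0.3)
  q <- shellmark:::target_gaussian(xy[1], xy[2], m, n, sigma_t = 1)
  zn <- array(q, c(m, n, 1))
  expect_equal(dsnt_regularizer(zn, matrix(xy, 1)), 0, tolerance = 1e-12)
  # any other distribution is penalised, bounded by log(2)
  u <- array(1 / (m * n), c(m, n, 1))
  r <- dsnt_regularizer(u, matrix(xy, 1))
  expect_gt(r, 0)
  expect_lt(r, log(2) + 1e-12)
  expect_error(dsnt_regularizer(zn, matrix(xy, 1), sigma_t = 0), "positive")
})

test_that("rendered target heatmaps peak at one on the landmark pixel", {
  co <- rbind(c(10.0, 4.0), c(2.6, 7.2))
  hm <- render_target_heatmaps(co, sigma = 1.5, height = 12, width = 16)
  expect_equal(dim(hm), c(12L, 16L, 2L))
  expect_equal(hm[5, 11, 1], 1) # row y+1, col x+1
  expect_equal(max(hm[, , 2]), hm[8, 4, 2]) # peak at round(2.6), round(7.2)
  # out-of-frame landmark gives an all-zero channel
  hm0 <- render_target_heatmaps(rbind(c(-5, 3)), sigma = 1.5,
                                height = 12, width = 16)
  expect_equal(sum(hm0), 0)
})

test_that("argmax decoding breaks ties by row-major scan order", {
  z <- array(0, c(4, 4, 1))
  expect_equal(decode_argmax(z)[, c("x", "y")],
               tibble::tibble(x = 0, y = 0))
  z[2, 3, 1] <- 1
  z[3, 1, 1] <- 1 # same value, later in row-major scan
  d <- decode_argmax(z)
  expect_equal(c(d$x, d$y), c(2, 1))
})
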