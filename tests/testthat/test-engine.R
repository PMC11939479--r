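# Direct numerical checks of the compiled engine on hand-built graphs.

node_input <- function(C, H, W) {
  list(type = "input", C = C, H = H, W = W, block = "input")
}

test_that("a freshly initialised GDConv layer performs average pooling", {
  C <- 3L; H <- 5L; W <- 4L
  nodes <- list(node_input(C, H, W),
                list(type = "gdconv", `in` = 1L, C = C, H = 1L, W = 1L,
                     block = "gd"))
  net <- nn_build(nodes, seed = 1L)
  set.seed(1)
  x <- matrix(rnorm(C * H * W), ncol = 1)
  out <- nn_forward(net, x, FALSE)$output
  # activation layout: element (i * W + j) * C + c
  ch <- matrix(x, nrow = C) # one column per spatial site
  expect_equal(as.numeric(out), rowMeans(ch), tolerance = 1e-6)
})

test_that("the fully-connected layer computes W x + b in declared layout", {
  nodes <- list(node_input(1L, 2L, 2L),
                list(type = "flatten", `in` = 1L, C = 4L, H = 1L, W = 1L,
                     block = "fl"),
                list(type = "fc", `in` = 2L, nin = 4L, nout = 2L, C = 2L,
                     H = 1L, W = 1L, block = "fc"))
  net <- nn_build(nodes, seed = 1L)
  Wm <- matrix(c(1, -1, 0.5, 2, -0.25, 3, 1.5, 0), 2, 4)
  b <- c(0.1, -0.2)
  nn_set_params(net, c(as.numeric(Wm), b))
  x <- matrix(c(1, 2, 3, 4), ncol = 1)
  out <- nn_forward(net, x, FALSE)$output
  expect_equal(as.numeric(out), as.numeric(Wm %*% x + b), tolerance = 1e-6)
})

test_that("bilinear upsampling preserves constants and the value range", {
  nodes <- list(node_input(1L, 2L, 2L),
                list(type = "upsample", `in` = 1L, C = 1L, H = 6L, W = 6L,
                     block = "up"))
  net <- nn_build(nodes, seed = 1L)
  out <- nn_forward(net, matrix(3.5, 4, 1), FALSE)$output
  expect_equal(as.numeric(out), rep(3.5, 36), tolerance = 1e-6)
  x <- matrix(c(0, 1, 2, 4), ncol = 1)
  out2 <- as.numeric(nn_forward(net, x, FALSE)$output)
  expect_gte(min(out2), 0)
  expect_lte(max(out2), 4)
})

test_that("batch normalisation at initialisation is the identity in eval mode", {
  nodes <- list(node_input(2L, 3L, 3L),
                list(type = "bn", `in` = 1L, C = 2L, H = 3L, W = 3L,
                     block = "bn"))
  net <- nn_build(nodes, seed = 1L)
  set.seed(2)
  x <- matrix(rnorm(18), ncol = 1)
  out <- nn_forward(net, x, FALSE)$output
  expect_equal(as.numeric(out), as.numeric(x), tolerance = 1e-3)
})

test_that("an unbiased convolution acts linearly on its input", {
  nodes <- list(node_input(2L, 6L, 6L),
                list(type = "conv", `in` = 1L, cin = 2L, cout = 3L, k = 3L,
                     stride = 1L, pad = 1L, groups = 1L, bias = FALSE,
                     C = 3L, H = 6L, W = 6L, block = "c"))
  net <- nn_build(nodes, seed = 4L)
  set.seed(3)
  x <- matrix(rnorm(72), ncol = 1)
  y <- matrix(rnorm(72), ncol = 1)
  fx <- as.numeric(nn_forward(net, x, FALSE)$output)
  fy <- as.numeric(nn_forward(net, y, FALSE)$output)
  f2x <- as.numeric(nn_forward(net, 2 * x, FALSE)$output)
  fxy <- as.numeric(nn_forward(net, x + y, FALSE)$output)
  expect_equal(f2x, 2 * fx, tolerance = 1e-5)
  expect_equal(fxy, fx + fy, tolerance = 1e-5)
})

test_that("grouped and depthwise convolutions preserve channel independence", {
  # depthwise 3x3: zeroing channel 1 of the input leaves output channel 2
  # untouched
  nodes <- list(node_input(2L, 5L, 5L),
                list(type = "conv", `in` = 1L, cin = 2L, cout = 2L, k = 3L,
                     stride = 1L, pad = 1L, groups = 2L, bias = FALSE,
                     C = 2L, H = 5L, W = 5L, block = "dw"))
  net <- nn_build(nodes, seed = 5L)
  set.seed(6)
  x <- matrix(rnorm(50), ncol = 1)
  x0 <- x
  x0[seq(1, 50, by = 2)] <- 0 # channel 1 occupies even positions 0-based
  a <- matrix(as.numeric(nn_forward(net, x, FALSE)$output), nrow = 2)
  b <- matrix(as.numeric(nn_forward(net, x0, FALSE)$output), nrow = 2)
  expect_equal(a[2, ], b[2, ], tolerance = 1e-6)
  expect_false(isTRUE(all.equal(a[1, ], b[1, ], tolerance = 1e-6)))
})

test_that("parameter get/set round-trips through the engine", {
  spec <- spec_dsnt_network(64L, preset = "compact")
  net <- build_landmark_network(spec, seed = 8L)
  p <- nn_get_params(net$ptr)
  expect_equal(length(p), nn_num_params(net$ptr))
  q <- p * 0.5
  nn_set_params(net$ptr, q)
  expect_equal(nn_get_params(net$ptr), q, tolerance = 1e-7)
  expect_error(nn_set_params(net$ptr, q[-1]), "mismatch")
})
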