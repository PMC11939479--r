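test_that("global depthwise convolution is a per-channel inner product", {
  set.seed(21)
  f <- array(rnorm(5 * 4 * 3), c(5, 4, 3))
  k <- array(rnorm(5 * 4 * 3), c(5, 4, 3))
  g <- gdconv(f, k)
  expect_length(g, 3L)
  expect_equal(g[2], sum(f[, , 2] * k[, , 2]))
})

test_that("the uniform kernel turns GDConv into global average pooling", {
  set.seed(22)
  h <- 6L; w <- 5L; c <- 4L
  f <- array(rnorm(h * w * c), c(h, w, c))
  k <- array(1 / (w * h), c(h, w, c))
  expect_equal(gdconv(f, k), apply(f, 3, mean), tolerance = 1e-12)
})

test_that("GDConv gradients match finite differences", {
  set.seed(23)
  f <- array(rnorm(4 * 3 * 2), c(4, 3, 2))
  k <- array(rnorm(4 * 3 * 2), c(4, 3, 2))
  dg <- rnorm(2)
  bk <- gdconv_backward(f, k, dg)
  fd_f <- num_grad(function(x) sum(dg * gdconv(array(x, dim(f)), k)), f)
  fd_k <- num_grad(function(x) sum(dg * gdconv(f, array(x, dim(k)))), k)
  expect_lt(rel_err(bk$df, fd_f), 1e-7)
  expect_lt(rel_err(bk$dk, fd_k), 1e-7)
})

test_that("convolution output geometry follows the stride arithmetic", {
  nb <- nb_new(64L)
  nb <- nb_conv(nb, 8L, k = 3L, stride = 2L)
  expect_equal(unlist(nb_dim(nb)), c(C = 8L, H = 32L, W = 32L))
  nb <- nb_conv(nb, 8L, k = 5L, stride = 4L)
  expect_equal(unlist(nb_dim(nb)), c(C = 8L, H = 8L, W = 8L))
})

test_that("parameter counting matches hand counts for simple layers", {
  # FC 10 -> 5: 10 * 5 weights + 5 biases = 55
  nb <- nb_new(2L, channels = 1L)
  nb <- nb_flatten(nb)
  nb <- nb_fc(nb, 5L)
  fc_node <- nb$nodes[[length(nb$nodes)]]
  expect_equal(shellmark:::node_params(fc_node), 4L * 5L + 5L)
  # GDConv kernel over 128 x 32 x 32 features: one weight per cell
  nb2 <- nb_new(64L)
  nb2 <- nb_conv(nb2, 128L, k = 3L, stride = 2L, bn = FALSE, act = "linear")
  nb2 <- nb_gdconv(nb2, bn = FALSE)
  gd <- shellmark:::fill_gd_size(nb2$nodes)
  expect_equal(shellmark:::node_params(gd[[length(gd)]]), 128L * 32L * 32L)
})

test_that("inverted residual blocks add a skip only at matching geometry", {
  nb <- nb_new(32L, channels = 16L)
  n0 <- length(nb$nodes)
  nb <- nb_invres(nb, 16L, expand = 32L, dw_num = 1L, stride = 1L)
  types <- vapply(nb$nodes[-seq_len(n0)], `[[`, "", "type")
  expect_true("add" %in% types)
  nb2 <- nb_new(32L, channels = 16L)
  nb2 <- nb_invres(nb2, 24L, expand = 32L, dw_num = 1L, stride = 1L)
  types2 <- vapply(nb2$nodes[-1], `[[`, "", "type")
  expect_false("add" %in% types2)
})

test_that("resource accounting agrees with the compiled engine", {
  for (mk in list(spec_fc_network, spec_heatmap_network, spec_dsnt_network)) {
    spec <- mk(input_size = 64L, preset = "compact")
    res <- count_resources(spec)
    net <- build_landmark_network(spec, seed = 1L)
    expect_equal(res$params, nn_num_params(net$ptr))
  }
})

test_that("network specs survive a YAML round trip", {
  spec <- spec_dsnt_network(input_size = 64L, preset = "compact")
  path <- tempfile(fileext = ".yaml")
  write_network_spec(spec, path)
  back <- read_network_spec(path)
  expect_equal(count_resources(back)$params, count_resources(spec)$params)
  a <- build_landmark_network(spec, seed = 3L)
  b <- build_landmark_network(back, seed = 3L)
  expect_equal(nn_get_params(a$ptr), nn_get_params(b$ptr))
  unlink(path)
})
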