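test_that("compact specs build and expose head-specific geometry", {
  size <- 64L
  img <- demo_sample()$image
  img64 <- img[1:64, 1:64, , drop = FALSE]

  fc <- build_landmark_network(spec_fc_network(size, preset = "compact"),
                               seed = 1L)
  v <- network_forward(fc, img64)
  expect_length(v, 78L)
  expect_equal(names(v)[1:4], c("x1", "y1", "x2", "y2"))

  hm <- build_landmark_network(spec_heatmap_network(size, preset = "compact"),
                               seed = 1L)
  hv <- network_forward(hm, img64)
  expect_equal(dim(hv)[3], 39L)

  ds_spec <- spec_dsnt_network(size, preset = "compact")
  ds <- build_landmark_network(ds_spec, seed = 1L)
  dv <- network_forward(ds, img64)
  expect_equal(nrow(dv$coords), 39L)
  expect_equal(dim(dv$heatmaps),
               c(ds_spec$heatmap_size, ds_spec$heatmap_size, 39L))
  expect_true(all(abs(dv$coords$x) < 1))
})

test_that("the engine's DSNT head agrees with the reference transform", {
  size <- 64L
  img <- demo_sample()$image[1:64, 1:64, , drop = FALSE]
  spec <- spec_dsnt_network(size, preset = "compact")
  net <- build_landmark_network(spec, seed = 2L)
  fwd <- network_forward(net, img)
  # heatmaps returned by the engine are already softmax-normalised
  expect_equal(apply(fwd$heatmaps, 3, sum), rep(1, 39), tolerance = 1e-5)
  ex <- dsnt_expectation(fwd$heatmaps)
  expect_equal(fwd$coords$x, ex$x, tolerance = 1e-5)
  expect_equal(fwd$coords$y, ex$y, tolerance = 1e-5)
})

test_that("prediction decodes every head to a pixel-frame landmark set", {
  size <- 64L
  img <- demo_sample()$image[1:64, 1:64, , drop = FALSE]
  for (mk in list(spec_fc_network, spec_heatmap_network, spec_dsnt_network)) {
    net <- build_landmark_network(mk(size, preset = "compact"), seed = 1L)
    lm <- predict_landmarks(net, img)
    expect_s3_class(lm, "landmark_set")
    expect_equal(lm_frame(lm), "pixel")
    expect_equal(nrow(lm), 39L)
  }
  # heatmap-family predictions carry per-point confidences in (0, 1]
  net <- build_landmark_network(
    spec_heatmap_network(size, preset = "compact"), seed = 1L)
  lm <- predict_landmarks(net, img)
  expect_true(all(lm$confidence > 0 & lm$confidence <= 1))
})

test_that("weight initialisation is seed-deterministic", {
  spec <- spec_dsnt_network(64L, preset = "compact")
  a <- nn_get_params(build_landmark_network(spec, seed = 9L)$ptr)
  b <- nn_get_params(build_landmark_network(spec, seed = 9L)$ptr)
  c <- nn_get_params(build_landmark_network(spec, seed = 10L)$ptr)
  expect_identical(a, b)
  expect_false(identical(a, c))
})

test_that("resource accounting covers params, flops and model size", {
  rep_ <- resource_report()
  expect_s3_class(rep_, "tbl_df")
  expect_setequal(rep_$network,
                  c("fully_connected", "gaussian_heatmap", "dsnt"))
  expect_true(all(rep_$params > 0))
  expect_true(all(rep_$flops > rep_$params)) # conv nets reuse weights
  expect_equal(rep_$params_m, round(rep_$params / 1e6, 2))
  expect_true(all(rep_$model_size_mb >= rep_$params * 4 / 2^20))
})

test_that("the default loss configuration tracks the head and resolution", {
  cfg512 <- loss_cfg_for(spec_heatmap_network(512L))
  expect_equal(cfg512$hm_sigma, 7)
  cfg_dsnt <- loss_cfg_for(spec_dsnt_network(128L, preset = "compact"),
                           loss = "dsnt_combined")
  expect_equal(cfg_dsnt$head, "dsnt")
})
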