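test_that("the design table matches the seven-group parallel protocol", {
  g <- experiment_groups()
  expect_equal(nrow(g), 7L)
  expect_equal(g$loss, c("l1", "smooth_l1", "wing", "l1", "l1", "l1",
                         "dsnt_combined"))
  expect_equal(g$dataset, c(rep("source", 3), rep("augmented", 4)))
  expect_equal(g$head, c(rep("fc", 5), "hm", "dsnt"))
  # groups 4 and 5 are replicates differing only by seed
  c4 <- make_group_config(4L); c5 <- make_group_config(5L)
  expect_false(c4$seed == c5$seed)
  drop <- c("group", "seed")
  expect_equal(unclass(c4)[setdiff(names(c4), drop)],
               unclass(c5)[setdiff(names(c5), drop)])
})

test_that("configuration overrides are applied and typos rejected", {
  cfg <- make_group_config(7L, epochs = 30L, input_size = 128L,
                           preset = "compact", batch_size = 64L)
  expect_equal(cfg$epochs, 30L)
  expect_equal(cfg$head, "dsnt")
  expect_equal(cfg$loss, "dsnt_combined")
  expect_error(make_group_config(8L), "1..7")
  expect_error(make_group_config(1L, epoch = 5), "unknown config fields")
  expect_error(make_group_config(1L, threshold = 0), "positive")
})

test_that("the train/test split is disjoint, exhaustive and seeded", {
  man <- tibble::tibble(sample = 1:50)
  sp <- split_dataset(man, test_fraction = 0.1, seed = 4L)
  expect_equal(nrow(sp$test), 5L)
  expect_equal(sort(c(sp$train$sample, sp$test$sample)), 1:50)
  sp2 <- split_dataset(man, test_fraction = 0.1, seed = 4L)
  expect_identical(sp$test$sample, sp2$test$sample)
  expect_error(split_dataset(man, test_fraction = 0), "test_fraction")
  expect_error(split_dataset(man[0, ], 0.1), "empty")
})

test_that("a short training run learns and records its trace", {
  cfg <- make_group_config(7L, epochs = 4L, input_size = 64L,
                           preset = "compact", batch_size = 16L,
                           n_train_metrics = 48L)
  d <- shellmark:::simulate_carapace_dataset(48, seed = 2, size = 64L,
                                             augment = TRUE)
  dte <- shellmark:::simulate_carapace_dataset(12, seed = 3, size = 64L,
                                               augment = TRUE)
  fit <- train_landmark_model(cfg, d, dte)
  expect_s3_class(fit, "landmark_fit")
  expect_equal(nrow(fit$trace), 4L)
  expect_true(all(is.finite(fit$trace$loss)))
  # the optimiser makes progress on its own objective
  expect_lt(fit$trace$loss[4], fit$trace$loss[1])
  # broom-style accessors
  gl <- glance(fit)
  expect_equal(gl$epochs_run, 4L)
  expect_true("test_r2" %in% names(gl))
  td <- tidy(fit)
  expect_setequal(unique(td$metric),
                  setdiff(names(fit$trace), "epoch"))
  # training is deterministic given the configuration
  fit2 <- train_landmark_model(cfg, d, dte)
  expect_equal(fit$trace$loss, fit2$trace$loss)
  expect_identical(fit$params, fit2$params)
})

test_that("training validates its inputs", {
  cfg <- make_group_config(1L, input_size = 128L, preset = "compact")
  d <- shellmark:::simulate_carapace_dataset(4, seed = 2, size = 64L)
  expect_error(train_landmark_model(cfg, d), "resolution")
})

test_that("evaluation, prediction and checkpoints are consistent", {
  cfg <- make_group_config(6L, epochs = 2L, input_size = 64L,
                           preset = "compact", batch_size = 8L,
                           n_train_metrics = 16L, hm_sigma = 2)
  d <- shellmark:::simulate_carapace_dataset(16, seed = 5, size = 64L,
                                             augment = TRUE)
  fit <- train_landmark_model(cfg, d)
  ev <- evaluate_landmark_model(fit, d)
  expect_true(all(c("mae", "mse", "r_squared") %in% names(ev)))
  expect_identical(ev, evaluate_landmark_model(fit, d)) # deterministic
  # matrix predictions: 78 coordinate rows, one column per sample
  pr <- predict(fit, d)
  expect_equal(dim(pr), c(78L, 16L))
  # single-image prediction decodes to a pixel-frame landmark set
  img <- make_carapace_sample(77, size = 64L)$image
  lm <- predict(fit, img)
  expect_s3_class(lm, "landmark_set")
  # float32 checkpoint round trip preserves params and predictions
  path <- tempfile(fileext = ".bin")
  save_model(fit, path)
  expect_equal(file.size(path),
               4 * (length(fit$params) + length(fit$buffers)))
  back <- load_model(path)
  expect_equal(back$params, fit$params, tolerance = 1e-7)
  ev2 <- evaluate_landmark_model(back, d)
  expect_equal(ev2$mae, ev$mae, tolerance = 1e-6)
  unlink(c(path, paste0(path, ".json")))
})

test_that("experiment reports combine metrics with resource accounting", {
  cfg <- make_group_config(7L, epochs = 1L, input_size = 64L,
                           preset = "compact", batch_size = 8L,
                           n_train_metrics = 8L)
  d <- shellmark:::simulate_carapace_dataset(8, seed = 6, size = 64L,
                                             augment = TRUE)
  fit <- train_landmark_model(cfg, d, d)
  rep_ <- experiment_report(list(fit))
  expect_equal(nrow(rep_), 1L)
  expect_true(all(c("group", "head", "test_r2", "params_m", "flops_g",
                    "model_size_mb") %in% names(rep_)))
  dir <- tempfile("rep")
  write_report(rep_, dir)
  expect_true(file.exists(file.path(dir, "report.csv")))
  expect_true(file.exists(file.path(dir, "report.json")))
  unlink(dir, recursive = TRUE)
})
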