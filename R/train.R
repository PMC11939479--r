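#' The seven-group parallel experiment design
#'
#' Groups 1--3 compare the three losses (L1, Smooth L1, Wing) on the
#' un-augmented source dataset with the fully-connected network; Groups 4--5
#' are replicate runs of L1 on the augmented dataset (identical settings,
#' different seed); Group 6 is the Gaussian-heatmap network and Group 7 the
#' DSNT network with its combined coordinate/regulariser loss, both on the
#' augmented dataset. All groups are evaluated on one shared augmented test
#' set.
#'
#' @return A 7-row tibble: `group`, `loss`, `dataset`, `head`.
#' @export
experiment_groups <- function() {
  tibble::tibble(
    group = 1:7,
    loss = c("l1", "smooth_l1", "wing", "l1", "l1", "l1", "dsnt_combined"),
    dataset = c("source", "source", "source", rep("augmented", 4)),
    head = c(rep("fc", 5), "hm", "dsnt"))
}

#' Build the configuration for one experiment group
#'
#' Returns the full training configuration for a group: head, loss and
#' dataset variant from the design table plus training hyperparameters.
#' Group 5 is a replicate of Group 4 and differs only by its seed. Training
#' stops early once the mean epoch training loss falls below `threshold`
#' (default 0.001), otherwise after `epochs` epochs.
#'
#' @param group_id integer 1..7.
#' @param ... overrides for any configuration field, e.g. `epochs = 30`,
#'   `input_size = 128L`, `preset = "compact"`, `batch_size = 64`,
#'   `seed = 11`.
#' @return A list of class `experiment_config`.
#' @export
make_group_config <- function(group_id, ...) {
  if (!is.numeric(group_id) || length(group_id) != 1 ||
      !group_id %in% 1:7) stop("group_id must be an integer in 1..7")
  row <- experiment_groups()[group_id, ]
  cfg <- list(
    group = as.integer(group_id), head = row$head, loss = row$loss,
    dataset = row$dataset,
    epochs = 300L, threshold = 1e-3, lr = 1e-3, batch_size = 16L,
    input_size = 512L, preset = "full", n_points = 39L,
    seed = if (group_id == 5L) 1001L else 1L,
    lambda = 1, sigma_t = 1, hm_sigma = NULL,
    wing_w = 10 / 256, wing_eps = 2 / 256, beta = 1,
    n_train_metrics = 200L)
  over <- list(...)
  bad <- setdiff(names(over), names(cfg))
  if (length(bad)) stop("unknown config fields: ", paste(bad, collapse = ", "))
  cfg <- modifyList(cfg, over)
  if (cfg$threshold <= 0) stop("threshold must be positive")
  class(cfg) <- "experiment_config"
  cfg
}

#' Deterministic train/test split of a manifest
#'
#' Seeded shuffle, then the first fraction becomes the test set. All seven
#' experiment groups share one test set (drawn from the augmented pool), so
#' source-trained groups are evaluated on augmented samples too.
#'
#' @param manifest a tibble with one row per sample.
#' @param test_fraction fraction of samples held out, in (0, 1).
#' @param seed shuffle seed.
#' @return List with tibbles `train` and `test`.
#' @export
split_dataset <- function(manifest, test_fraction = 0.1, seed = 1L) {
  n <- nrow(manifest)
  if (n == 0) stop("empty manifest")
  if (test_fraction <= 0 || test_fraction >= 1)
    stop("test_fraction must lie in (0, 1)")
  ord <- with_seed(seed, sample.int(n))
  n_test <- max(1L, floor(n * test_fraction))
  list(train = manifest[sort(ord[(n_test + 1):n]), ],
       test = manifest[sort(ord[seq_len(n_test)]), ])
}

#' Source/augmented dataset pair plus the shared test set
#'
#' @param n_train,n_test split sizes.
#' @param seed master seed (test samples use an offset stream).
#' @param size working resolution in pixels.
#' @param config augmentation configuration for the augmented variants.
#' @return List with `carapace_dataset`s `source`, `augmented` and `test`
#'   (the test set is augmented, hence contains rotated samples).
#' @export
experiment_datasets <- function(n_train, n_test, seed = 1L, size = 128L,
                                config = augmentation_config()) {
  pair <- simulate_carapace_pair(n_train, seed, size = size, config = config)
  list(
    source = pair$source,
    augmented = pair$augmented,
    test = simulate_carapace_dataset(n_test, seed + 7919L, size = size,
                                     augment = TRUE, config = config))
}

dataset_engine <- function(data) {
  if (!inherits(data, "carapace_dataset")) stop("expected a carapace_dataset")
  ds_new(data$images, data$coords)
}

#' Train a landmark network
#'
#' Runs up to `config$epochs` epochs of Adam over shuffled mini-batches,
#' stopping early once the mean epoch training loss drops below
#' `config$threshold`. Every source of randomness (weight initialisation,
#' batch order) flows from `config$seed`. Per-epoch MAE/MSE/R-squared are
#' recorded in the normalized coordinate frame on a fixed training subsample
#' and on the test set; the heatmap head is decoded by argmax and the DSNT
#' head by its expectation before computing metrics, so all heads are
#' measured on the same scale.
#'
#' @param config an [make_group_config()] configuration.
#' @param train_data,test_data `carapace_dataset`s at `config$input_size`.
#' @return An object of class `landmark_fit`: configuration, network spec,
#'   trained parameters, the per-epoch `trace` tibble, and convergence
#'   information.
#' @export
train_landmark_model <- function(config, train_data, test_data = NULL) {
  stopifnot(inherits(config, "experiment_config"))
  if (train_data$n < 2) stop("need at least two training samples")
  if (train_data$size != config$input_size)
    stop("training data resolution does not match the configuration")
  # engine datasets are large native allocations invisible to R's heap
  # accounting; collect dropped ones before allocating new copies
  gc(FALSE)
  spec <- spec_for_config(config)
  net <- build_landmark_network(spec, seed = config$seed)
  cfg <- loss_cfg_for(spec, loss = config$loss, beta = config$beta,
                      wing_w = config$wing_w, wing_eps = config$wing_eps,
                      lambda = config$lambda, sigma_t = config$sigma_t,
                      hm_sigma = config$hm_sigma, lr = config$lr)
  dtr <- dataset_engine(train_data)
  dte <- if (!is.null(test_data)) dataset_engine(test_data)
  n <- train_data$n
  idx_eval <- seq_len(min(config$n_train_metrics, n)) - 1L
  t0 <- proc.time()[["elapsed"]]
  set.seed(config$seed)
  rows <- list()
  converged <- FALSE
  for (epoch in seq_len(config$epochs)) {
    ord <- sample.int(n) - 1L
    loss <- nn_train_epoch(net$ptr, dtr, ord, config$batch_size, cfg)
    m_tr <- eval_metrics(net, dtr, idx_eval, cfg,
                         train_data$coords[, idx_eval + 1L, drop = FALSE])
    row <- tibble::tibble(epoch = epoch, loss = loss,
                          train_mae = m_tr$mae, train_mse = m_tr$mse,
                          train_r2 = m_tr$r_squared)
    if (!is.null(test_data)) {
      m_te <- eval_metrics(net, dte, seq_len(test_data$n) - 1L, cfg,
                           test_data$coords)
      row$test_mae <- m_te$mae; row$test_mse <- m_te$mse
      row$test_r2 <- m_te$r_squared
    }
    rows[[epoch]] <- row
    if (loss < config$threshold) { converged <- TRUE; break }
  }
  trace <- dplyr::bind_rows(rows)
  structure(list(
    config = config, spec = spec,
    params = nn_get_params(net$ptr), buffers = nn_get_buffers(net$ptr),
    trace = trace, converged = converged,
    converged_epoch = if (converged) nrow(trace) else NA_integer_,
    n_params = nn_num_params(net$ptr),
    elapsed = proc.time()[["elapsed"]] - t0),
    class = "landmark_fit")
}

spec_for_config <- function(config) {
  f <- switch(config$head, fc = spec_fc_network, hm = spec_heatmap_network,
              dsnt = spec_dsnt_network)
  f(input_size = config$input_size, n_points = config$n_points,
    preset = config$preset)
}

eval_metrics <- function(net, ds, idx, cfg, target) {
  pred <- nn_predict(net$ptr, ds, idx, cfg)
  evaluate_coords(pred, target)
}

#' Pooled metrics from coordinate matrices
#'
#' @param pred,target matrices of normalized coordinates (2 n_points rows,
#'   one column per sample).
#' @return One-row tibble: `mae`, `mse`, `r_squared`.
#' @export
evaluate_coords <- function(pred, target) {
  p <- as.numeric(pred); t0 <- as.numeric(target)
  m <- metric_mae_mse(p, t0)
  m$r_squared <- metric_r_squared(p, t0)
  m
}

# rebuild the engine network for a fit (cached on the fit's environment)
fit_network <- function(fit) {
  cache <- attr(fit, "net_cache")
  if (is.environment(cache) && !is.null(cache$net)) return(cache$net)
  net <- build_landmark_network(fit$spec, seed = fit$config$seed)
  nn_set_params(net$ptr, fit$params)
  nn_set_buffers(net$ptr, fit$buffers)
  env <- new.env(parent = emptyenv())
  env$net <- net
  attr(fit, "net_cache") <- env
  net
}

#' Evaluate a trained model on a dataset
#'
#' Decodes predictions to normalized coordinates (fully-connected: direct;
#' heatmap: argmax; DSNT: expectation) and reports the pooled metrics.
#' Deterministic: repeated calls give identical results.
#'
#' @param fit a [train_landmark_model()] result.
#' @param data a `carapace_dataset` at the fitted resolution.
#' @return One-row tibble: `mae`, `mse`, `r_squared`.
#' @export
evaluate_landmark_model <- function(fit, data) {
  gc(FALSE) # release dropped engine datasets before allocating a new one
  net <- fit_network(fit)
  cfg <- loss_cfg_for(fit$spec, loss = fit$config$loss,
                      lambda = fit$config$lambda,
                      sigma_t = fit$config$sigma_t,
                      hm_sigma = fit$config$hm_sigma)
  ds <- dataset_engine(data)
  eval_metrics(net, ds, seq_len(data$n) - 1L, cfg, data$coords)
}

#' @export
predict.landmark_fit <- function(object, newdata, ...) {
  net <- fit_network(object)
  if (inherits(newdata, "carapace_dataset")) {
    cfg <- loss_cfg_for(object$spec, loss = object$config$loss)
    ds <- dataset_engine(newdata)
    return(nn_predict(net$ptr, ds, seq_len(newdata$n) - 1L, cfg))
  }
  predict_landmarks(net, newdata)
}

#' @export
print.landmark_fit <- function(x, ...) {
  fin <- x$trace[nrow(x$trace), ]
  cat(sprintf(
    "<landmark_fit: group %d (%s head, %s loss), %d epoch(s)%s>\n",
    x$config$group, x$config$head, x$config$loss, nrow(x$trace),
    if (x$converged) sprintf(", converged at epoch %d", x$converged_epoch)
    else ""))
  if (!is.null(fin$test_r2))
    cat(sprintf("  final test MAE %.4f  MSE %.5f  R2 %.4f\n",
                fin$test_mae, fin$test_mse, fin$test_r2))
  invisible(x)
}

#' Broom-style accessors for fitted landmark models
#'
#' `tidy()` returns the per-epoch training trace in long format; `glance()`
#' a one-row model summary.
#'
#' @param x a `landmark_fit`.
#' @param ... unused.
#' @return A tibble.
#' @export
tidy.landmark_fit <- function(x, ...) {
  tidyr::pivot_longer(x$trace, -"epoch", names_to = "metric",
                      values_to = "value")
}

#' @rdname tidy.landmark_fit
#' @export
glance.landmark_fit <- function(x, ...) {
  fin <- x$trace[nrow(x$trace), ]
  out <- tibble::tibble(
    group = x$config$group, head = x$config$head, loss = x$config$loss,
    dataset = x$config$dataset, epochs_run = nrow(x$trace),
    converged = x$converged, final_loss = fin$loss,
    params = x$n_params, params_m = round(x$n_params / 1e6, 2),
    elapsed_s = x$elapsed)
  if (!is.null(fin$test_r2)) {
    out$test_mae <- fin$test_mae
    out$test_mse <- fin$test_mse
    out$test_r2 <- fin$test_r2
  }
  out
}

#' Summary tables across experiment groups
#'
#' Combines `glance()` rows of several fits with the per-network resource
#' accounting: test-set R-squared per group plus parameters (M), FLOPs (G)
#' and model size (MB). The elapsed training time is reported as measured on
#' the current machine and is not comparable across hardware.
#'
#' @param fits list of `landmark_fit` objects.
#' @return A tibble with one row per fit.
#' @export
experiment_report <- function(fits) {
  stopifnot(length(fits) >= 1)
  res <- dplyr::bind_rows(lapply(fits, function(f) {
    g <- glance(f)
    r <- count_resources(f$spec)
    g$flops_g <- r$flops_g
    g$model_size_mb <- r$model_size_mb
    g
  }))
  res
}

#' @rdname experiment_report
#' @param report tibble from `experiment_report()`.
#' @param dir output directory; writes `report.csv` and `report.json`.
#' @export
write_report <- function(report, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(report, file.path(dir, "report.csv"), row.names = FALSE)
  jsonlite::write_json(report, file.path(dir, "report.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(report)
}

#' Save / load a trained model as a float32 checkpoint
#'
#' `save_model()` writes the trainable parameters followed by the
#' batch-normalisation running statistics as little-endian float32 to
#' `<path>` and the configuration to `<path>.json`; the binary file size in
#' bytes is exactly 4 x (parameters + buffers), which is what
#' [count_resources()] reports as the model size.
#'
#' @param fit a `landmark_fit`.
#' @param path checkpoint path (binary file).
#' @return `load_model()` returns the restored `landmark_fit` (without the
#'   training trace).
#' @export
save_model <- function(fit, path) {
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(c(fit$params, fit$buffers), con, size = 4L, endian = "little")
  meta <- list(config = unclass(fit$config), n_params = length(fit$params),
               n_buffers = length(fit$buffers))
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  cfg <- meta$config
  class(cfg) <- "experiment_config"
  vals <- readBin(path, "numeric", n = meta$n_params + meta$n_buffers,
                  size = 4L, endian = "little")
  structure(list(config = cfg, spec = spec_for_config(cfg),
                 params = vals[seq_len(meta$n_params)],
                 buffers = vals[meta$n_params + seq_len(meta$n_buffers)],
                 trace = tibble::tibble(), converged = NA,
                 converged_epoch = NA_integer_, n_params = meta$n_params,
                 elapsed = NA_real_),
            class = "landmark_fit")
}
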