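#' Coordinate regression losses
#'
#' The loss suite used by the parallel experiments, all means over the
#' elementwise differences `d = pred - target`:
#' \describe{
#' \item{`loss_l1()`}{mean absolute error `|d|`.}
#' \item{`loss_smooth_l1()`}{quadratic `0.5 d^2 / beta` for `|d| < beta`,
#'   linear `|d| - beta/2` beyond; continuous at the junction.}
#' \item{`loss_wing()`}{logarithmic `w log(1 + |d|/eps)` for `|d| < w`,
#'   linear `|d| - C` beyond, with `C = w - w log(1 + w/eps)` so the branches
#'   meet; amplifies the gradient of small and medium errors, which is what
#'   makes it attractive for landmark regression.}
#' }
#' All are non-negative, zero exactly at equality, and symmetric in the sign
#' of the error. Coordinates are expected in the normalized frame, hence the
#' wing defaults `w = 10/256` and `eps = 2/256` (the customary pixel values
#' rescaled to a (-1, 1) axis).
#'
#' @param pred,target numeric vectors of equal length.
#' @param beta smooth-L1 transition point (> 0).
#' @param w wing width: the error size where the loss switches from
#'   logarithmic to linear (> 0, normalized units).
#' @param eps wing curvature parameter (> 0).
#' @return Scalar loss value.
#' @examples
#' loss_l1(c(1, -1), c(0, 0)) # 1
#' loss_wing(0.2, 0, w = 10 / 256, eps = 2 / 256)
#' @export
loss_l1 <- function(pred, target) {
  check_lengths(pred, target)
  mean(abs(pred - target))
}

#' @rdname loss_l1
#' @export
loss_smooth_l1 <- function(pred, target, beta = 1) {
  check_lengths(pred, target)
  if (beta <= 0) stop("beta must be positive")
  a <- abs(pred - target)
  mean(ifelse(a < beta, 0.5 * a^2 / beta, a - 0.5 * beta))
}

#' @rdname loss_l1
#' @export
loss_wing <- function(pred, target, w = 10 / 256, eps = 2 / 256) {
  check_lengths(pred, target)
  if (w <= 0 || eps <= 0) stop("w and eps must be positive")
  a <- abs(pred - target)
  C <- w - w * log(1 + w / eps)
  mean(ifelse(a < w, w * log(1 + a / eps), a - C))
}

check_lengths <- function(pred, target) {
  if (length(pred) != length(target)) stop("pred and target lengths differ")
  invisible(TRUE)
}

#' Combined coordinate / heatmap-distribution loss for the DSNT head
#'
#' The mean squared error between predicted and target coordinates plus
#' `lambda` times the heatmap-distribution regulariser
#' ([dsnt_regularizer()]). With `lambda = 0` this is exactly the coordinate
#' MSE; it reaches (near) zero only when the coordinates match and the
#' normalised heatmaps equal the target Gaussians.
#'
#' @param pred_coords,target_coords numeric vectors (interleaved x, y,
#'   normalized frame) or k x 2 matrices.
#' @param heatmaps normalised heatmap stack `(m, n, k)` from the forward
#'   pass.
#' @param lambda regulariser weight (>= 0, default 1).
#' @param sigma_t target-Gaussian standard deviation in grid cells.
#' @return Scalar loss.
#' @export
loss_dsnt_combined <- function(pred_coords, target_coords, heatmaps,
                               lambda = 1, sigma_t = 1) {
  if (is.matrix(pred_coords)) pred_coords <- as.numeric(t(pred_coords))
  if (is.matrix(target_coords)) tmat <- target_coords
  else tmat <- matrix(target_coords, ncol = 2, byrow = TRUE)
  target_coords <- as.numeric(t(tmat))
  check_lengths(pred_coords, target_coords)
  if (missing(heatmaps) || is.null(heatmaps)) stop("heatmaps are required")
  mse <- mean((pred_coords - target_coords)^2)
  if (lambda == 0) return(mse)
  mse + lambda * dsnt_regularizer(heatmaps, tmat, sigma_t = sigma_t)
}

#' Pooled evaluation metrics for coordinate predictions
#'
#' All heads are compared in the same normalized coordinate frame after
#' decoding, pooling over samples, landmarks and both axes: `metric_mae_mse()`
#' returns the mean absolute and mean squared coordinate error, and
#' `metric_r_squared()` the coefficient of determination
#' `1 - sum((t - p)^2) / sum((t - mean(t))^2)`. R-squared is at most 1, is 0
#' for a predictor fixed at the target mean, and can be negative; it is
#' invariant under a common affine rescaling of predictions and targets.
#'
#' @param pred,target numeric vectors of pooled coordinate values.
#' @return `metric_mae_mse()`: tibble with `mae` and `mse`;
#'   `metric_r_squared()`: scalar.
#' @examples
#' metric_r_squared(c(0, 1, 2, 5), c(0, 1, 2, 3)) # 0.2
#' @export
metric_r_squared <- function(pred, target) {
  check_lengths(pred, target)
  if (length(target) < 2) stop("need at least two values")
  ss_tot <- sum((target - mean(target))^2)
  if (ss_tot == 0) stop("target variance is zero")
  1 - sum((target - pred)^2) / ss_tot
}

#' @rdname metric_r_squared
#' @export
metric_mae_mse <- function(pred, target) {
  check_lengths(pred, target)
  d <- pred - target
  tibble::tibble(mae = mean(abs(d)), mse = mean(d^2))
}
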