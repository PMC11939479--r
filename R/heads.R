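#' Signed coordinate grids for the spatial-to-numerical transform
#'
#' Two m x n matrices serving as one-dimensional reference axes: `X` varies
#' only with the column index and `Y` only with the row index. Under the
#' default pixel-centre convention `X[i, j] = (2j - (n + 1))/n` and
#' `Y[i, j] = (2i - (m + 1))/m` (1-based indices), so entries are centred on
#' 0 and lie strictly inside (-1, 1). The `"endpoint"` convention
#' `2(j - 1)/(n - 1) - 1` pins the boundary entries to exactly -1 and 1 and
#' is provided as an alternative, not the default.
#'
#' @param m,n grid height and width (rows, columns).
#' @param convention `"pixel_center"` (default) or `"endpoint"`.
#' @return List with matrices `X` and `Y`, both m x n.
#' @examples
#' dsnt_grids(1, 2)$X # -0.5, 0.5
#' @export
dsnt_grids <- function(m, n, convention = c("pixel_center", "endpoint")) {
  convention <- match.arg(convention)
  if (m < 1 || n < 1) stop("grid dimensions must be positive")
  j <- seq_len(n); i <- seq_len(m)
  if (convention == "pixel_center") {
    xv <- (2 * j - (n + 1)) / n
    yv <- (2 * i - (m + 1)) / m
  } else {
    xv <- if (n == 1) 0 else 2 * (j - 1) / (n - 1) - 1
    yv <- if (m == 1) 0 else 2 * (i - 1) / (m - 1) - 1
  }
  list(X = matrix(xv, m, n, byrow = TRUE), Y = matrix(yv, m, n))
}

#' Per-channel spatial softmax of a heatmap stack
#'
#' Each channel of the raw stack is normalised with a spatial softmax so it
#' becomes a discrete probability distribution: all entries positive, summing
#' to one. Invariant to adding a constant to a channel.
#'
#' @param z array dim `(m, n, k)`: k raw heatmap channels.
#' @return Array of the same shape; each channel sums to 1.
#' @export
normalize_heatmaps <- function(z) {
  if (length(dim(z)) == 2L) z <- array(z, c(dim(z), 1L))
  out <- z
  for (k in seq_len(dim(z)[3])) {
    ch <- z[, , k]
    e <- exp(ch - max(ch))
    out[, , k] <- e / sum(e)
  }
  out
}

#' Soft-argmax: expectation of the coordinate grids under the heatmaps
#'
#' For each normalised channel the predicted coordinates are the Frobenius
#' inner products `x_k = <Z'_k, X>` and `y_k = <Z'_k, Y>`. Being a weighted
#' average of grid values, outputs lie strictly inside (-1, 1), and the map
#' is differentiable in the heatmap — the property that lets the DSNT head
#' train end to end, unlike argmax decoding.
#'
#' @param zn normalised heatmap stack, array `(m, n, k)` (see
#'   [normalize_heatmaps()]).
#' @param grids coordinate grids from [dsnt_grids()]; defaults to the
#'   pixel-centre grids of matching size.
#' @return Tibble with columns `point`, `x`, `y`.
#' @export
dsnt_expectation <- function(zn, grids = NULL) {
  if (length(dim(zn)) == 2L) zn <- array(zn, c(dim(zn), 1L))
  d <- dim(zn)
  if (is.null(grids)) grids <- dsnt_grids(d[1], d[2])
  if (!all(dim(grids$X) == d[1:2])) stop("grid and heatmap shapes differ")
  k <- d[3]
  tibble::tibble(
    point = seq_len(k),
    x = vapply(seq_len(k), function(i) sum(zn[, , i] * grids$X), numeric(1)),
    y = vapply(seq_len(k), function(i) sum(zn[, , i] * grids$Y), numeric(1)))
}

#' Gradient of a coordinate loss through softmax and expectation
#'
#' Analytic gradient of `sum(gx * x_k + gy * y_k)` with respect to the raw
#' logits, where `(x_k, y_k)` are the soft-argmax outputs of the
#' softmax-normalised logits. Used for gradient verification against finite
#' differences, mirroring the engine's backward pass in double precision.
#'
#' @param z raw logits, array `(m, n, k)`.
#' @param gx,gy upstream gradients, length-k vectors.
#' @inheritParams dsnt_expectation
#' @return Array `(m, n, k)`: the gradient with respect to `z`.
#' @export
dsnt_expectation_backward <- function(z, gx, gy, grids = NULL) {
  if (length(dim(z)) == 2L) z <- array(z, c(dim(z), 1L))
  d <- dim(z)
  if (is.null(grids)) grids <- dsnt_grids(d[1], d[2])
  zn <- normalize_heatmaps(z)
  out <- z
  for (k in seq_len(d[3])) {
    t_k <- gx[k] * grids$X + gy[k] * grids$Y
    p <- zn[, , k]
    out[, , k] <- p * (t_k - sum(t_k * p))
  }
  out
}

#' Heatmap-distribution regulariser for the DSNT head
#'
#' The mean, over channels, of the Jensen-Shannon divergence between each
#' normalised heatmap and a unit-mass Gaussian of standard deviation
#' `sigma_t` (in grid cells) centred at the target coordinate. Zero exactly
#' when every channel coincides with its target Gaussian; bounded above by
#' log(2) per channel. Encourages the spatial softmax to stay a compact,
#' unimodal blob rather than any distribution with the right mean.
#'
#' @param zn normalised heatmap stack `(m, n, k)`.
#' @param target k x 2 matrix of normalized-frame target coordinates
#'   (columns x, y), or a [landmark_set()] in the normalized frame.
#' @param sigma_t Gaussian standard deviation in grid cells (default 1).
#' @return Mean Jensen-Shannon divergence (natural log), a scalar >= 0.
#' @export
dsnt_regularizer <- function(zn, target, sigma_t = 1) {
  if (sigma_t <= 0) stop("sigma_t must be positive")
  if (inherits(target, "landmark_set")) {
    if (lm_frame(target) != "normalized")
      stop("target landmarks must be in the normalized frame")
    target <- cbind(target$x, target$y)
  }
  d <- dim(zn)
  if (nrow(target) != d[3]) stop("one target per channel required")
  js <- vapply(seq_len(d[3]), function(k) {
    q <- target_gaussian(target[k, 1], target[k, 2], d[1], d[2], sigma_t)
    p <- zn[, , k]
    m0 <- (p + q) / 2
    0.5 * sum(ifelse(p > 0, p * log(p / m0), 0)) +
      0.5 * sum(ifelse(q > 0, q * log(q / m0), 0))
  }, numeric(1))
  mean(js)
}

# unit-mass Gaussian on the m x n grid, centre given in normalized coords
# (clamped into the grid)
target_gaussian <- function(xn, yn, m, n, sigma_t) {
  cx <- min(max((xn * n + n - 1) / 2, 0), n - 1)
  cy <- min(max((yn * m + m - 1) / 2, 0), m - 1)
  jj <- matrix(0:(n - 1), m, n, byrow = TRUE)
  ii <- matrix(0:(m - 1), m, n)
  g <- exp(-((jj - cx)^2 + (ii - cy)^2) / (2 * sigma_t^2))
  g / sum(g)
}

#' Render Gaussian target heatmaps for landmark positions
#'
#' One channel per landmark: an unnormalised Gaussian
#' `exp(-((r - y)^2 + (c - x)^2) / (2 sigma^2))` with peak value 1 at the
#' landmark position. Landmarks outside the frame give all-zero channels.
#' These are the regression targets for the Gaussian-heatmap head.
#'
#' @param lm a [landmark_set()] in the pixel frame, or an n x 2 matrix of
#'   pixel coordinates (x, y).
#' @param sigma Gaussian standard deviation in pixels.
#' @param height,width heatmap dimensions; default: the landmark frame.
#' @return Array `(height, width, n)`.
#' @export
render_target_heatmaps <- function(lm, sigma, height = NULL, width = NULL) {
  if (sigma <= 0) stop("sigma must be positive")
  if (inherits(lm, "landmark_set")) {
    if (lm_frame(lm) != "pixel") stop("landmarks must be in the pixel frame")
    height <- height %||% lm_height(lm)
    width <- width %||% lm_width(lm)
    co <- cbind(lm$x, lm$y)
  } else co <- lm
  render_heatmaps_cpp(co, as.integer(height), as.integer(width), sigma)
}

#' Decode heatmaps to pixel coordinates by argmax
#'
#' The position of each channel's maximum, as 0-based pixel coordinates
#' (x = column, y = row). Ties are broken by the first occurrence in a
#' row-major scan (left to right, then top to bottom), so a constant channel
#' decodes to (0, 0). This is the non-differentiable decoder of the
#' Gaussian-heatmap strategy; its outputs are quantised to whole pixels.
#'
#' @param z heatmap stack, array `(h, w, k)`.
#' @return Tibble with columns `point`, `x`, `y` (pixel frame).
#' @export
decode_argmax <- function(z) {
  if (length(dim(z)) == 2L) z <- array(z, c(dim(z), 1L))
  d <- dim(z)
  k <- d[3]
  xy <- vapply(seq_len(k), function(p) {
    idx0 <- which.max(t(z[, , p])) - 1L # row-major scan
    c(idx0 %% d[2], idx0 %/% d[2])
  }, numeric(2))
  tibble::tibble(point = seq_len(k), x = xy[1, ], y = xy[2, ])
}
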