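#' Network specifications for the three coordinate-regression strategies
#'
#' All three networks share one lightweight backbone in the MobileNetV2 /
#' MobileFaceNet lineage: four strided convolution blocks (the last three
#' grouped, groups = 4) that downsample the input by a factor of 16, followed
#' by three inverted-residual blocks (1x1 expand to 920 channels, two
#' depthwise 3x3 stages, 1x1 project back to 128). At the canonical 512 x 512
#' working resolution the backbone output is a 128 x 32 x 32 feature map.
#' Convolutions carry batch normalisation and ReLU6; head outputs are linear.
#'
#' The heads differ:
#' \describe{
#' \item{fc}{a global depthwise convolution (GDConv) summarises the feature
#'   map into a 128-vector, which is concatenated with the flattened feature
#'   map and regressed through a three-layer fully-connected stage
#'   (205 and 237 hidden units) to the 78 coordinate values of the 39
#'   points. Nearly all of this network's parameters sit in the wide
#'   fully-connected stage -- the structural reason for its weak spatial
#'   generalization.}
#' \item{hm}{three semantic embedding blocks (SEB) decode the backbone
#'   features back to full resolution, multiplying upsampled deep features
#'   with 1x1-projected encoder features, ending in one Gaussian-heatmap
#'   channel per landmark at the input resolution. Coordinates are read off
#'   by per-channel argmax.}
#' \item{dsnt}{a 1x1 convolution maps the backbone features to one channel
#'   per landmark at 1/16 resolution (39 x 32 x 32 at 512 input); a spatial
#'   softmax and an expectation over signed coordinate grids turn each
#'   channel into continuous (x, y) coordinates, differentiably.}
#' }
#'
#' The hidden widths of the canonical (`preset = "full"`) networks are fixed
#' so that their trainable-parameter counts are 27.93 M (fc), 0.97 M (hm) and
#' 0.84 M (dsnt). The `"compact"` preset keeps the same topology at roughly
#' 1/16 the channel width for CPU-scale experiments; its heatmap decoder
#' stops at 1/4 resolution.
#'
#' @param input_size working resolution (pixels, square). Default 512.
#' @param n_points number of landmark channels / coordinate pairs (39).
#' @param preset `"full"` (canonical widths) or `"compact"`.
#' @return An object of class `network_spec`: a list with `name`, `head`,
#'   `input_size`, `n_points`, `heatmap_size` (hm/dsnt) and the flat `nodes`
#'   graph consumed by the engine and by [count_resources()].
#' @export
spec_fc_network <- function(input_size = 512L, n_points = 39L,
                            preset = c("full", "compact")) {
  preset <- match.arg(preset)
  nb <- spec_backbone(input_size, preset)
  backbone_out <- nb$last
  nb <- nb_gdconv(nb, in_ = backbone_out)
  gd <- nb$last
  nb <- nb_flatten(nb, in_ = backbone_out)
  nb <- nb_concat(nb, nb$last, gd)
  if (preset == "full") {
    nb <- nb_fc(nb, 205L, act = "relu6", block = "fc_hidden1")
    nb <- nb_fc(nb, 237L, act = "relu6", block = "fc_hidden2")
  } else {
    nb <- nb_fc(nb, 128L, act = "relu6", block = "fc_hidden1")
  }
  nb <- nb_fc(nb, 2L * n_points, act = "linear", block = "fc_out")
  new_network_spec("fc", nb, input_size, n_points, preset)
}

#' @rdname spec_fc_network
#' @export
spec_heatmap_network <- function(input_size = 512L, n_points = 39L,
                                 preset = c("full", "compact")) {
  preset <- match.arg(preset)
  nb <- spec_backbone(input_size, preset)
  taps <- attr(nb, "taps")
  if (preset == "full") {
    s <- input_size %/% 16L
    nb <- nb_seb(nb, nb$last, taps[3], 72L, 2L * s, 2L * s, block = "seb1")
    nb <- nb_seb(nb, nb$last, taps[2], 40L, 4L * s, 4L * s, block = "seb2")
    nb <- nb_seb(nb, nb$last, taps[1], 32L, 8L * s, 8L * s, block = "seb3")
    nb <- nb_conv(nb, n_points, k = 1L, bias = TRUE, bn = FALSE,
                  act = "linear", block = "hm_out")
    nb <- nb_add(nb, list(type = "upsample", C = n_points, H = input_size,
                          W = input_size, block = "hm_out"))
  } else {
    s <- input_size %/% 16L
    # the final 1x1 projection mixes the last SEB's channels into one map per
    # landmark, so that SEB must carry at least as many channels as there are
    # landmarks for the per-pixel linear map to have full rank
    nb <- nb_seb(nb, nb$last, taps[2], 16L, 2L * s, 2L * s, block = "seb1")
    nb <- nb_seb(nb, nb$last, taps[1], 40L, 4L * s, 4L * s, block = "seb2")
    nb <- nb_conv(nb, n_points, k = 1L, bias = TRUE, bn = FALSE,
                  act = "linear", block = "hm_out")
  }
  new_network_spec("hm", nb, input_size, n_points, preset)
}

#' @rdname spec_fc_network
#' @export
spec_dsnt_network <- function(input_size = 512L, n_points = 39L,
                              preset = c("full", "compact")) {
  preset <- match.arg(preset)
  nb <- spec_backbone(input_size, preset)
  nb <- nb_conv(nb, n_points, k = 1L, bias = TRUE, bn = FALSE,
                act = "linear", block = "point_conv")
  nb <- nb_dsnt(nb, n_points)
  new_network_spec("dsnt", nb, input_size, n_points, preset)
}

# shared encoder; attr "taps" = node indices of the three stage outputs
# (after activation) at 1/2, 1/4 and 1/8 resolution, used by the SEB decoder
spec_backbone <- function(input_size, preset) {
  if (preset == "full") {
    nb <- nb_new(input_size)
    nb <- nb_conv(nb, 32L, k = 3L, stride = 2L, block = "conv1")
    t1 <- nb$last
    nb <- nb_conv(nb, 64L, k = 3L, stride = 2L, groups = 4L, block = "conv2")
    t2 <- nb$last
    nb <- nb_conv(nb, 128L, k = 3L, stride = 2L, groups = 4L, block = "conv3")
    t3 <- nb$last
    nb <- nb_conv(nb, 128L, k = 3L, stride = 2L, groups = 4L, block = "conv4")
    for (b in 1:3)
      nb <- nb_invres(nb, 128L, expand = 920L, dw_num = 2L,
                      block = paste0("invres", b))
  } else {
    nb <- nb_new(input_size)
    nb <- nb_conv(nb, 8L, k = 5L, stride = 4L, block = "conv1")
    t1 <- nb$last
    nb <- nb_conv(nb, 16L, k = 3L, stride = 2L, block = "conv2")
    t2 <- nb$last
    nb <- nb_conv(nb, 32L, k = 3L, stride = 2L, block = "conv3")
    t3 <- nb$last
    nb <- nb_invres(nb, 32L, expand = 64L, dw_num = 2L, block = "invres1")
  }
  attr(nb, "taps") <- c(t1, t2, t3)
  nb
}

new_network_spec <- function(head, nb, input_size, n_points, preset) {
  hm_size <- NULL
  for (nd in nb$nodes)
    if (nd$type == "dsnt") hm_size <- nd$m
  if (head == "hm") hm_size <- nb$nodes[[nb$last]]$H
  spec <- list(
    name = c(fc = "fully_connected", hm = "gaussian_heatmap", dsnt = "dsnt")[[head]],
    head = head, input_size = as.integer(input_size),
    n_points = as.integer(n_points), preset = preset,
    heatmap_size = hm_size, nodes = nb$nodes)
  class(spec) <- "network_spec"
  spec
}

#' @export
print.network_spec <- function(x, ...) {
  cat(sprintf("<network_spec: %s head, %d nodes, input %dx%d, %s preset>\n",
              x$head, length(x$nodes), x$input_size, x$input_size, x$preset))
  print(count_resources(x))
  invisible(x)
}

#' Instantiate a network
#'
#' Builds the single-precision engine network for a specification and
#' initialises its weights deterministically from `seed` (He-scaled normal
#' draws; GDConv kernels start at global average pooling; batch-norm at
#' identity).
#'
#' @param spec a `network_spec`.
#' @param seed integer seed for weight initialisation.
#' @return An object of class `landmark_network` holding the specification
#'   and the engine handle.
#' @export
build_landmark_network <- function(spec, seed = 1L) {
  ptr <- nn_build(unname(spec$nodes), as.integer(seed))
  structure(list(spec = spec, ptr = ptr, seed = seed),
            class = "landmark_network")
}

#' @export
print.landmark_network <- function(x, ...) {
  cat(sprintf("<landmark_network: %s head, %.0f parameters>\n",
              x$spec$head, nn_num_params(x$ptr)))
  invisible(x)
}

loss_cfg_for <- function(spec, loss = "l1", beta = 1, wing_w = 10 / 256,
                         wing_eps = 2 / 256, lambda = 1, sigma_t = 1,
                         hm_sigma = NULL, lr = 1e-3) {
  if (is.null(hm_sigma))
    hm_sigma <- 7 * (spec$heatmap_size %||% spec$input_size) / 512
  list(head = spec$head, loss = loss, beta = beta, wing_w = wing_w,
       wing_eps = wing_eps, lambda = lambda, sigma_t = sigma_t,
       hm_sigma = hm_sigma, n_points = spec$n_points, lr = lr,
       beta1 = 0.9, beta2 = 0.999, adam_eps = 1e-8)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Pack an image array into an engine column
#'
#' Engine activations store one image per column with element order
#' `(row * width + col) * channels + channel`. Values are scaled to `[0, 1]`.
#'
#' @param image array dim `(h, w, 3)`, values 0--255.
#' @return Numeric matrix with one column.
#' @keywords internal
pack_image <- function(image) {
  matrix(as.numeric(aperm(image, c(3, 2, 1))) / 255, ncol = 1L)
}

#' Run a network forward on one image
#'
#' Returns the raw head output: a 78-vector of normalized coordinates for the
#' fc head, an `(h, w, n_points)` heatmap array for the hm head, and a list
#' with the coordinate tibble plus normalised heatmaps for the dsnt head.
#' Node output shapes from the actual engine pass are attached as attribute
#' `"shapes"`.
#'
#' @param net a [build_landmark_network()] object.
#' @param image array dim `(h, w, 3)`, values 0--255, at the spec's input
#'   size.
#' @return Head-dependent output, see Details.
#' @export
network_forward <- function(net, image) {
  spec <- net$spec
  res <- nn_forward(net$ptr, pack_image(image), train = FALSE)
  shapes <- dplyr::bind_rows(lapply(res$shapes, tibble::as_tibble))
  out <- res$output
  value <- switch(spec$head,
    fc = {
      v <- as.numeric(out)
      names(v) <- paste0(rep(c("x", "y"), spec$n_points),
                         rep(seq_len(spec$n_points), each = 2L))
      v
    },
    hm = unpack_heatmaps(out[, 1L], spec$n_points,
                         shapes$H[nrow(shapes)], shapes$W[nrow(shapes)]),
    dsnt = {
      co <- matrix(as.numeric(out), nrow = 2L)
      hm <- unpack_heatmaps(nn_heatmaps(net$ptr)[, 1L], spec$n_points,
                            spec$heatmap_size, spec$heatmap_size)
      list(coords = tibble::tibble(point = seq_len(spec$n_points),
                                   x = co[1L, ], y = co[2L, ]),
           heatmaps = hm)
    })
  attr(value, "shapes") <- shapes
  value
}

# engine activation layout ((i*W+j)*C + c) -> R array (H, W, C)
unpack_heatmaps <- function(v, n_ch, h, w) {
  aperm(array(v, dim = c(n_ch, w, h)), c(3, 2, 1))
}

#' Predict landmark positions on an image
#'
#' Runs the network and decodes to a pixel-frame [landmark_set()]: the fc
#' head's coordinates are taken directly, the hm head is decoded by
#' per-channel argmax, and the dsnt head by the soft-argmax expectation. For
#' the heatmap-based heads each point carries the maximum (normalised)
#' heatmap value as a confidence score.
#'
#' @inheritParams network_forward
#' @return A 39-point [landmark_set()] in the pixel frame, with a
#'   `confidence` column for the heatmap-based heads.
#' @export
predict_landmarks <- function(net, image) {
  spec <- net$spec
  cfg <- loss_cfg_for(spec)
  co <- nn_predict_mat(net$ptr, pack_image(image), cfg)
  m <- matrix(as.numeric(co), nrow = 2L)
  lmn <- landmark_set(m[1L, ], m[2L, ], frame = "normalized",
                      width = dim(image)[2], height = dim(image)[1])
  lm <- landmarks_to_pixel(lmn)
  if (spec$head %in% c("hm", "dsnt")) {
    fwd <- network_forward(net, image)
    hm <- if (spec$head == "hm") normalize_heatmaps(fwd) else fwd$heatmaps
    lm$confidence <- apply(hm, 3L, max)
  }
  lm
}
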