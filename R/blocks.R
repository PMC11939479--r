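#' Global depthwise convolution (reference implementation)
#'
#' A per-channel spatial inner product between a feature map and a learnable
#' kernel of the same size: `G[1,1,k] = sum_{i,j} F[i,j,k] * K[i,j,k]`. With a
#' constant kernel `1/(w*h)` it reduces exactly to global average pooling;
#' with learned weights every spatial position gets its own importance. Used
#' in place of global average pooling at the end of the fully-connected
#' network (MobileFaceNet-style).
#'
#' This is the double-precision reference used in tests and documentation;
#' the training engine has its own single-precision implementation.
#'
#' @param f input feature map, array of dim `(h, w, m)`.
#' @param k kernel, array of the same dim.
#' @return Numeric vector of length `m` (the 1 x 1 x m output).
#' @examples
#' f <- array(1:8, c(2, 2, 2))
#' gdconv(f, array(1 / 4, c(2, 2, 2))) # global average pooling
#' @export
gdconv <- function(f, k) {
  if (!identical(dim(f), dim(k))) stop("feature map and kernel shapes differ")
  apply(f * k, 3L, sum)
}

#' @rdname gdconv
#' @param dg upstream gradient, numeric vector of length `m`.
#' @return `gdconv_backward()`: list with `df` and `dk`, the gradients of
#'   `sum(dg * gdconv(f, k))` with respect to `f` and `k`.
#' @export
gdconv_backward <- function(f, k, dg) {
  m <- dim(f)[3]
  scale <- array(rep(dg, each = prod(dim(f)[1:2])), dim(f))
  list(df = scale * k, dk = scale * f)
}

# --- network graph builder --------------------------------------------------
# Networks are flat lists of primitive nodes (conv/bn/relu6/add/mul/upsample/
# flatten/concat/fc/gdconv/dsnt). The R side computes every node's output
# shape; the engine re-derives and cross-checks them.

nb_new <- function(input_size, channels = 3L) {
  list(nodes = list(list(type = "input", C = channels,
                         H = input_size, W = input_size, block = "input")),
       last = 1L)
}

nb_add <- function(nb, node) {
  if (is.null(node$in_)) node$in_ <- nb$last
  names(node)[names(node) == "in_"] <- "in"
  nb$nodes[[length(nb$nodes) + 1L]] <- node
  nb$last <- length(nb$nodes)
  nb
}

nb_dim <- function(nb, i = nb$last) nb$nodes[[i]][c("C", "H", "W")]

conv_out_dim <- function(x, k, stride, pad) (x + 2L * pad - k) %/% stride + 1L

nb_conv <- function(nb, cout, k = 3L, stride = 1L, groups = 1L,
                    bias = FALSE, bn = TRUE, act = "relu6",
                    in_ = nb$last, block = "conv") {
  d <- nb_dim(nb, in_)
  oh <- conv_out_dim(d$H, k, stride, (k - 1L) %/% 2L)
  ow <- conv_out_dim(d$W, k, stride, (k - 1L) %/% 2L)
  nb <- nb_add(nb, list(type = "conv", in_ = in_, cin = d$C, cout = cout,
                        k = k, stride = stride, pad = (k - 1L) %/% 2L,
                        groups = groups, bias = bias,
                        C = cout, H = oh, W = ow, block = block))
  if (bn) nb <- nb_add(nb, list(type = "bn", C = cout, H = oh, W = ow,
                                block = block))
  if (act == "relu6") nb <- nb_add(nb, list(type = "relu6", C = cout, H = oh,
                                            W = ow, block = block))
  nb
}

# inverted residual: 1x1 expand -> dw_num depthwise 3x3 -> 1x1 project,
# with a skip connection when stride 1 and matching channels
nb_invres <- function(nb, cout, expand, dw_num = 2L, stride = 1L,
                      block = "invres") {
  d_in <- nb_dim(nb)
  skip_from <- nb$last
  nb <- nb_conv(nb, expand, k = 1L, block = paste0(block, "_expand"))
  for (t in seq_len(dw_num)) {
    s <- if (t == 1L) stride else 1L
    nb <- nb_conv(nb, expand, k = 3L, stride = s, groups = expand,
                  block = paste0(block, "_dw", t))
  }
  nb <- nb_conv(nb, cout, k = 1L, act = "linear",
                block = paste0(block, "_project"))
  if (stride == 1L && d_in$C == cout) {
    d <- nb_dim(nb)
    nb <- nb_add(nb, list(type = "add", in_ = c(skip_from, nb$last),
                          C = d$C, H = d$H, W = d$W, block = block))
  }
  nb
}

# semantic embedding block: (3x3 conv -> bilinear upsample)(high) multiplied
# elementwise by (1x1 conv -> bilinear upsample)(low), both at (out_h, out_w).
# The branch convolutions are batch-normalised but linear: with two clipped
# non-negative branches the product has an exact dead stationary point
# (disjoint supports make both factors' gradients vanish identically), which
# pixelwise losses reliably fall into; signed branches remove it.
nb_seb <- function(nb, high, low, cout, out_h, out_w, block = "seb") {
  nb <- nb_conv(nb, cout, k = 3L, in_ = high, act = "linear",
                block = paste0(block, "_high"))
  nb <- nb_add(nb, list(type = "upsample", C = cout, H = out_h, W = out_w,
                        block = paste0(block, "_high")))
  hi <- nb$last
  nb <- nb_conv(nb, cout, k = 1L, in_ = low, act = "linear",
                block = paste0(block, "_low"))
  nb <- nb_add(nb, list(type = "upsample", C = cout, H = out_h, W = out_w,
                        block = paste0(block, "_low")))
  nb <- nb_add(nb, list(type = "mul", in_ = c(hi, nb$last), C = cout,
                        H = out_h, W = out_w, block = block))
  nb
}

nb_gdconv <- function(nb, bn = TRUE, in_ = nb$last, block = "gdconv") {
  d <- nb_dim(nb, in_)
  nb <- nb_add(nb, list(type = "gdconv", in_ = in_, C = d$C, H = 1L, W = 1L,
                        block = block))
  if (bn) nb <- nb_add(nb, list(type = "bn", C = d$C, H = 1L, W = 1L,
                                block = block))
  nb
}

nb_flatten <- function(nb, in_ = nb$last, block = "flatten") {
  d <- nb_dim(nb, in_)
  nb_add(nb, list(type = "flatten", in_ = in_, C = d$C * d$H * d$W,
                  H = 1L, W = 1L, block = block))
}

nb_concat <- function(nb, a, b, block = "concat") {
  da <- nb_dim(nb, a); db <- nb_dim(nb, b)
  stopifnot(da$H == 1L, db$H == 1L)
  nb_add(nb, list(type = "concat", in_ = c(a, b), C = da$C + db$C,
                  H = 1L, W = 1L, block = block))
}

nb_fc <- function(nb, nout, act = "linear", block = "fc") {
  d <- nb_dim(nb)
  nin <- d$C * d$H * d$W
  nb <- nb_add(nb, list(type = "fc", nin = nin, nout = nout, C = nout,
                        H = 1L, W = 1L, block = block))
  if (act == "relu6") nb <- nb_add(nb, list(type = "relu6", C = nout, H = 1L,
                                            W = 1L, block = block))
  nb
}

nb_dsnt <- function(nb, n_points, block = "dsnt") {
  d <- nb_dim(nb)
  stopifnot(d$C == n_points)
  nb_add(nb, list(type = "dsnt", npoints = n_points, m = d$H, n = d$W,
                  C = 2L * n_points, H = 1L, W = 1L, block = block))
}

# --- resource accounting ----------------------------------------------------

node_params <- function(nd) {
  switch(nd$type,
    conv = {
      kg <- (nd$cin %/% nd$groups) * nd$k * nd$k
      nd$cout * kg + if (isTRUE(nd$bias)) nd$cout else 0L
    },
    bn = 2L * nd$C,
    fc = nd$nin * nd$nout + nd$nout,
    gdconv = nd$gd_size,
    0L)
}

node_flops <- function(nd) {
  # 2 x multiply-accumulate convention for conv/fc/gdconv; elementwise and
  # normalisation ops are not counted
  switch(nd$type,
    conv = {
      kg <- (nd$cin %/% nd$groups) * nd$k * nd$k
      2 * kg * nd$cout * nd$H * nd$W
    },
    fc = 2 * nd$nin * nd$nout,
    gdconv = 2 * nd$gd_size,
    0)
}

fill_gd_size <- function(nodes) {
  for (i in seq_along(nodes)) {
    if (nodes[[i]]$type == "gdconv") {
      src <- nodes[[nodes[[i]]$`in`]]
      nodes[[i]]$gd_size <- src$C * src$H * src$W
    }
  }
  nodes
}

#' Resource accounting for a network specification
#'
#' Counts trainable parameters, forward-pass floating-point operations
#' (2 operations per multiply--accumulate, convolution/fully-connected/GDConv
#' layers only) and the serialised checkpoint size (trainable parameters plus
#' batch-normalisation running statistics, 4 bytes each, as written by
#' [save_model()]). A pure function of the specification.
#'
#' @param spec a network specification from [spec_fc_network()],
#'   [spec_heatmap_network()] or [spec_dsnt_network()].
#' @return One-row tibble: `network`, `params`, `params_m` (millions, 2 dp),
#'   `flops`, `flops_g`, `model_size_mb` (MiB, 2 dp).
#' @examples
#' count_resources(spec_dsnt_network())
#' @export
count_resources <- function(spec) {
  nodes <- fill_gd_size(spec$nodes)
  params <- sum(vapply(nodes, node_params, numeric(1)))
  flops <- sum(vapply(nodes, node_flops, numeric(1)))
  buffers <- 2 * sum(vapply(nodes, function(nd)
    if (nd$type == "bn") nd$C else 0L, numeric(1)))
  tibble::tibble(
    network = spec$name,
    params = params,
    params_m = round(params / 1e6, 2),
    flops = flops,
    flops_g = round(flops / 1e9, 2),
    model_size_mb = round((params + buffers) * 4 / 2^20, 2))
}

#' @rdname count_resources
#' @param specs list of network specifications (default: the three canonical
#'   networks at 512 x 512).
#' @return `resource_report()`: one tibble row per network.
#' @export
resource_report <- function(specs = list(spec_fc_network(),
                                         spec_heatmap_network(),
                                         spec_dsnt_network())) {
  dplyr::bind_rows(lapply(specs, count_resources))
}

#' Serialise a network specification to YAML
#'
#' @param spec a network specification.
#' @param path output file.
#' @return `read_network_spec()` returns the specification.
#' @export
write_network_spec <- function(spec, path) {
  yaml::write_yaml(spec, path)
  invisible(path)
}

#' @rdname write_network_spec
#' @export
read_network_spec <- function(path) {
  spec <- yaml::read_yaml(path)
  class(spec) <- "network_spec"
  spec
}
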