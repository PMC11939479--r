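# Procedural synthetic carapaces: a super-ellipse-like rim carrying 12
# triangular teeth in fixed angular sectors (frontal on the top arc, lateral
# on the upper-left/right arcs), a flat rear edge and an M-shaped groove
# polyline near the vertical midline. Landmarks are placed analytically, so
# ground truth is exact by construction.

#' Jitter ranges for sampling carapace parameters
#'
#' Fractions are relative to the template value (or to the image side for the
#' centre). All ranges are symmetric uniform draws. Zero everywhere gives the
#' fixed template.
#'
#' @param center_frac centre offset, fraction of image side (default 0.03).
#' @param axis_frac semi-axis scaling (default 0.08).
#' @param orient_deg orientation range in degrees (default 10).
#' @param amp_frac per-tooth amplitude scaling (default 0.3).
#' @param groove_frac groove geometry scaling (default 0.15).
#' @param color brightness offset of carapace/background base colours,
#'   0--255 scale (default 12).
#' @return A named list of class `jitter_config`.
#' @export
jitter_config <- function(center_frac = 0.03, axis_frac = 0.08,
                          orient_deg = 10, amp_frac = 0.3,
                          groove_frac = 0.15, color = 12) {
  cfg <- list(center_frac = center_frac, axis_frac = axis_frac,
              orient_deg = orient_deg, amp_frac = amp_frac,
              groove_frac = groove_frac, color = color)
  if (any(unlist(cfg) < 0)) stop("jitter ranges must be non-negative")
  class(cfg) <- "jitter_config"
  cfg
}

# fixed angular sectors (degrees clockwise from the frontal direction)
tooth_angles <- function() {
  list(frontal = seq(-40, 40, length.out = 9),
       left = seq(-50, -122, length.out = 9),
       right = seq(50, 122, length.out = 9),
       rear = c(162, 180, 198))
}

carapace_template <- function(size) {
  s <- size
  list(size = as.integer(size),
       center = c(s / 2, s / 2),
       a = 0.34 * s,            # horizontal semi-axis
       b_front = 0.30 * s,      # vertical semi-axis, frontal half
       b_rear = 0.26 * s,       # vertical semi-axis, rear half (narrower)
       exponent = 2.5,          # super-ellipse exponent (> 2: squarish)
       orientation = 0,
       tooth_amp = rep(0.022 * s, 12L), # radial peak displacement, px
       groove = list(offset_y = -0.06 * s, width = 0.30 * s,
                     depth = 0.05 * s, upturn = 0.3, darkness = 0.45),
       carapace_rgb = c(112, 96, 64),
       background_rgb = c(196, 193, 186),
       noise_amp = 9, noise_sigma_frac = 0.02,
       illum_angle = 0.6, illum_strength = 0.10,
       texture_seed = 1L, background_seed = 2L)
}

#' Sample carapace parameters
#'
#' Draws one parameter set around the fixed template, deterministically for a
#' given seed. Errors if the configured ranges could push the carapace rim
#' (including tooth peaks) outside the image.
#'
#' @param seed integer seed; `NULL` uses the current RNG state.
#' @param size image side in pixels (default 512).
#' @param jitter a [jitter_config()].
#' @return A named list of class `carapace_params`.
#' @export
sample_carapace_params <- function(seed = NULL, size = 512L,
                                   jitter = jitter_config()) {
  draw <- function() {
    p <- carapace_template(size)
    u <- function(r) runif(1, -r, r)
    p$center <- p$center + c(u(jitter$center_frac * size),
                             u(jitter$center_frac * size))
    p$a <- p$a * (1 + u(jitter$axis_frac))
    p$b_front <- p$b_front * (1 + u(jitter$axis_frac))
    p$b_rear <- p$b_rear * (1 + u(jitter$axis_frac))
    p$orientation <- u(jitter$orient_deg) * pi / 180
    p$tooth_amp <- p$tooth_amp * (1 + runif(12, -jitter$amp_frac,
                                            jitter$amp_frac))
    g <- 1 + u(jitter$groove_frac)
    p$groove$width <- p$groove$width * g
    p$groove$depth <- p$groove$depth * (1 + u(jitter$groove_frac))
    p$carapace_rgb <- p$carapace_rgb + u(jitter$color)
    p$background_rgb <- p$background_rgb + u(jitter$color)
    p$illum_angle <- runif(1, 0, 2 * pi)
    p$texture_seed <- sample.int(.Machine$integer.max, 1)
    p$background_seed <- sample.int(.Machine$integer.max, 1)
    class(p) <- "carapace_params"
    p
  }
  p <- if (is.null(seed)) draw() else with_seed(seed, draw())
  validate_carapace_params(p, jitter)
  p
}

validate_carapace_params <- function(p, jitter = NULL) {
  if (any(c(p$a, p$b_front, p$b_rear) <= 0)) stop("semi-axes must be positive")
  if (any(p$tooth_amp < 0)) stop("tooth amplitudes must be non-negative")
  s <- p$size
  reach <- max(p$a, p$b_front, p$b_rear) + max(p$tooth_amp)
  slack <- if (is.null(jitter)) 0 else jitter$center_frac * s
  if (reach + slack + max(abs(p$center - s / 2)) >= s / 2)
    stop("parameter ranges allow the carapace to leave the image")
  invisible(p)
}

# rim radius at model angle theta (radians clockwise from frontal direction)
rim_radius <- function(p, theta) {
  dx <- sin(theta); dy <- -cos(theta)
  b <- ifelse(dy < 0, p$b_front, p$b_rear)
  (abs(dx / p$a)^p$exponent + abs(dy / b)^p$exponent)^(-1 / p$exponent)
}

# model-frame point at angle theta and radial offset amp, then rotated by the
# orientation and translated to the centre
rim_point <- function(p, theta, amp = 0) {
  r <- rim_radius(p, theta) + amp
  mx <- r * sin(theta); my <- -r * cos(theta)
  rotate_about(cbind(mx, my), p$orientation, c(0, 0)) +
    matrix(p$center, length(theta), 2, byrow = TRUE)
}

rotate_about <- function(xy, angle, center) {
  ca <- cos(angle); sa <- sin(angle)
  dx <- xy[, 1] - center[1]; dy <- xy[, 2] - center[2]
  cbind(center[1] + ca * dx - sa * dy, center[2] + sa * dx + ca * dy)
}

#' Analytic landmark positions for a parameter set
#'
#' Places the 37 carapace points on the rim and groove: per tooth group, the
#' nine points at evenly spaced angles with peaks displaced radially outward
#' by the tooth amplitude (so shared junction points are equal exactly, by
#' construction); three rear-edge points on the lower arc; seven groove
#' points tracing the M-shaped polyline.
#'
#' @param params a [sample_carapace_params()] object.
#' @return A 37-point [landmark_set()] in the pixel frame.
#' @export
carapace_landmarks <- function(params) {
  p <- validate_carapace_params(params)
  ang <- tooth_angles()
  amps <- function(group_idx) {
    a <- numeric(9)
    a[c(2, 4, 6, 8)] <- p$tooth_amp[(group_idx - 1) * 4 + 1:4]
    a
  }
  fr <- rim_point(p, ang$frontal * pi / 180, amps(1))
  le <- rim_point(p, ang$left * pi / 180, amps(2))
  ri <- rim_point(p, ang$right * pi / 180, amps(3))
  re <- rim_point(p, ang$rear * pi / 180, 0)
  g <- p$groove
  gx <- g$width * seq(-0.5, 0.5, length.out = 7)
  gy <- g$offset_y + g$depth * c(0, 1, g$upturn, 1, g$upturn, 1, 0)
  gr <- rotate_about(cbind(gx, gy), p$orientation, c(0, 0)) +
    matrix(p$center, 7, 2, byrow = TRUE)
  xy <- rbind(fr, le, ri, re, gr)
  landmark_set(xy[, 1], xy[, 2], frame = "pixel",
               width = p$size, height = p$size)
}

# closed rim polygon: tooth landmarks as vertices plus base-rim samples in
# the tooth-free arcs, ordered clockwise
rim_polygon <- function(p) {
  ang <- tooth_angles()
  amps <- function(group_idx) {
    a <- numeric(9)
    a[c(2, 4, 6, 8)] <- p$tooth_amp[(group_idx - 1) * 4 + 1:4]
    a
  }
  seg <- list(
    list(th = ang$frontal, amp = amps(1)),
    list(th = seq(43, 47, by = 2), amp = 0),
    list(th = ang$right, amp = amps(3)),
    list(th = seq(127, 157, by = 6), amp = 0),
    list(th = ang$rear, amp = 0),
    list(th = seq(203, 233, by = 6), amp = 0),
    list(th = rev(ang$left) + 360, amp = rev(amps(2))),
    list(th = seq(313, 317, by = 2), amp = 0))
  do.call(rbind, lapply(seg, function(s)
    rim_point(p, s$th * pi / 180, s$amp)))
}

smooth_noise <- function(h, w, sigma) {
  n <- matrix(runif(h * w, -1, 1), h, w)
  b <- gaussian_blur_cpp(array(n, c(h, w, 1L)), sigma)[, , 1]
  s <- sd(b)
  if (s < 1e-12) matrix(0, h, w) else b / s
}

#' Render a synthetic annotated carapace image
#'
#' Deterministically renders the filled carapace polygon (rim interpolated
#' through the tooth landmarks, so the outline passes through every tooth
#' point) over a textured background, adds the groove as a soft dark stroke
#' through the seven groove points, smooth noise textures and a linear
#' illumination gradient.
#'
#' @param params a [sample_carapace_params()] object.
#' @param size output image side; defaults to `params$size`.
#' @return An object of class `annotated_image`: list with `image` (array
#'   `(size, size, 3)`, values 0--255), `landmarks` (the 39-point
#'   [landmark_set()], bbox corners included) and `params`.
#' @export
render_carapace <- function(params, size = params$size) {
  p <- validate_carapace_params(params)
  if (size < 64) stop("size must be at least 64")
  if (size != p$size) stop("size must match params$size")
  h <- w <- as.integer(size)
  nsig <- max(1, p$noise_sigma_frac * size)
  bg_tex <- with_seed(p$background_seed, smooth_noise(h, w, nsig))
  car_tex <- with_seed(p$texture_seed, smooth_noise(h, w, nsig))
  poly <- rim_polygon(p)
  mask <- rasterize_polygon_cpp(h, w, poly[, 1], poly[, 2])
  lm <- carapace_landmarks(p)
  groove_pts <- lm[lm$group == "neck_groove", ]
  gd <- polyline_distance_cpp(h, w, groove_pts$x, groove_pts$y, 5)
  groove_fac <- 1 - p$groove$darkness * exp(-(gd / 1.4)^2)
  xg <- matrix((0:(w - 1)) / w - 0.5, h, w, byrow = TRUE)
  yg <- matrix((0:(h - 1)) / h - 0.5, h, w)
  illum <- p$illum_strength * 255 *
    (cos(p$illum_angle) * xg + sin(p$illum_angle) * yg)
  img <- array(0, c(h, w, 3L))
  for (c0 in 1:3) {
    plane <- p$background_rgb[c0] + p$noise_amp * bg_tex
    car <- p$carapace_rgb[c0] + p$noise_amp * car_tex
    plane[mask] <- car[mask]
    plane <- plane * groove_fac + illum
    img[, , c0] <- pmin(255, pmax(0, plane))
  }
  structure(list(image = img, landmarks = landmarks_with_bbox(lm),
                 params = p),
            class = "annotated_image")
}

#' Generate one synthetic sample (optionally augmented)
#'
#' A pure function of the seed: parameter sampling, rendering and any
#' augmentation draws all run under the given seed.
#'
#' @param seed integer seed.
#' @param size image side in pixels.
#' @param jitter a [jitter_config()].
#' @param augment apply [augment_sample()]?
#' @param config an [augmentation_config()] used when `augment = TRUE`.
#' @return An `annotated_image`.
#' @export
make_carapace_sample <- function(seed, size = 512L, jitter = jitter_config(),
                                 augment = FALSE,
                                 config = augmentation_config()) {
  with_seed(seed, {
    params <- sample_carapace_params(seed = NULL, size = size, jitter = jitter)
    sample <- render_carapace(params)
    if (augment) sample <- augment_sample(sample, config)
    sample
  })
}

#' Simulate an in-memory annotated dataset
#'
#' Renders `n` samples with disjoint per-sample seeds derived from `seed` and
#' packs them in the engine's column layout. The `augment = TRUE` variant
#' draws the same underlying carapaces as `augment = FALSE` for the same
#' seed, then applies the stochastic augmentation protocol -- the
#' "source" vs "augmented" dataset pair of the parallel experiments.
#'
#' @inheritParams make_carapace_sample
#' @param n number of samples.
#' @param seed master seed; per-sample seeds are drawn from it.
#' @return An object of class `carapace_dataset`: list with `images` (raw
#'   matrix, one packed image per column), `coords` (78 x n normalized
#'   coordinates), `valid` (39 x n), `size`, `n`, `seeds`, `augmented`.
#' @export
simulate_carapace_dataset <- function(n, seed, size = 128L,
                                      augment = FALSE,
                                      jitter = jitter_config(),
                                      config = augmentation_config()) {
  stopifnot(n >= 1)
  seeds <- with_seed(seed, sample.int(.Machine$integer.max, n))
  images <- matrix(as.raw(0), nrow = 3L * size * size, ncol = n)
  coords <- matrix(0, nrow = 78L, ncol = n)
  valid <- matrix(TRUE, nrow = 39L, ncol = n)
  for (i in seq_len(n)) {
    s <- make_carapace_sample(seeds[i], size = size, jitter = jitter,
                              augment = augment, config = config)
    images[, i] <- pack_image_raw(s$image)
    coords[, i] <- landmarks_flatten(landmarks_normalize(s$landmarks))
    valid[, i] <- s$landmarks$valid
  }
  structure(list(images = images, coords = coords, valid = valid,
                 size = as.integer(size), n = as.integer(n), seeds = seeds,
                 augmented = augment),
            class = "carapace_dataset")
}

#' Simulate a source/augmented dataset pair sharing one set of renders
#'
#' Equivalent to calling [simulate_carapace_dataset()] twice with
#' `augment = FALSE` and `augment = TRUE` and the same seed -- the per-sample
#' RNG protocol is identical, so the results are bit-for-bit the same --
#' but each carapace is rendered only once and the augmentation protocol is
#' applied to that render, which is also how the augmented training set is
#' defined: the source images with stochastic transforms applied.
#'
#' @inheritParams simulate_carapace_dataset
#' @return A list with elements `source` and `augmented`, both
#'   `carapace_dataset`s.
#' @export
simulate_carapace_pair <- function(n, seed, size = 128L,
                                   jitter = jitter_config(),
                                   config = augmentation_config()) {
  stopifnot(n >= 1)
  seeds <- with_seed(seed, sample.int(.Machine$integer.max, n))
  img_src <- matrix(as.raw(0), nrow = 3L * size * size, ncol = n)
  img_aug <- img_src
  crd_src <- matrix(0, nrow = 78L, ncol = n)
  crd_aug <- crd_src
  val_src <- matrix(TRUE, nrow = 39L, ncol = n)
  val_aug <- val_src
  for (i in seq_len(n)) {
    pair <- with_seed(seeds[i], {
      params <- sample_carapace_params(seed = NULL, size = size,
                                       jitter = jitter)
      base <- render_carapace(params)
      list(base = base, aug = augment_sample(base, config))
    })
    img_src[, i] <- pack_image_raw(pair$base$image)
    crd_src[, i] <- landmarks_flatten(landmarks_normalize(pair$base$landmarks))
    val_src[, i] <- pair$base$landmarks$valid
    img_aug[, i] <- pack_image_raw(pair$aug$image)
    crd_aug[, i] <- landmarks_flatten(landmarks_normalize(pair$aug$landmarks))
    val_aug[, i] <- pair$aug$landmarks$valid
  }
  mk <- function(images, coords, valid, augment) {
    structure(list(images = images, coords = coords, valid = valid,
                   size = as.integer(size), n = as.integer(n), seeds = seeds,
                   augmented = augment),
              class = "carapace_dataset")
  }
  list(source = mk(img_src, crd_src, val_src, FALSE),
       augmented = mk(img_aug, crd_aug, val_aug, TRUE))
}

pack_image_raw <- function(image) {
  as.raw(pmax(0, pmin(255, round(as.numeric(aperm(image, c(3, 2, 1)))))))
}

#' Write a synthetic dataset to disk
#'
#' PNG images plus one annotation JSON per image (see [write_annotation()])
#' and a JSON-lines manifest with one record per sample (`file`,
#' `annotation`, `split`, `seed`). Reproducible end to end: the same seed
#' yields identical files.
#'
#' @inheritParams simulate_carapace_dataset
#' @param out_dir output directory (created if needed).
#' @param n_train,n_test split sizes.
#' @return The manifest as a tibble (invisibly also written to
#'   `manifest.jsonl`).
#' @export
generate_carapace_dataset <- function(out_dir, n_train, n_test, seed,
                                      size = 512L, augment = FALSE,
                                      jitter = jitter_config(),
                                      config = augmentation_config()) {
  stopifnot(n_train >= 1, n_test >= 1)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  n <- n_train + n_test
  seeds <- with_seed(seed, sample.int(.Machine$integer.max, n))
  split <- rep(c("train", "test"), c(n_train, n_test))
  rows <- vector("list", n)
  for (i in seq_len(n)) {
    s <- make_carapace_sample(seeds[i], size = size, jitter = jitter,
                              augment = augment, config = config)
    stem <- sprintf("%s_%05d", split[i], i)
    img_file <- file.path(out_dir, paste0(stem, ".png"))
    ann_file <- file.path(out_dir, paste0(stem, ".json"))
    png::writePNG(s$image / 255, img_file)
    write_annotation(s$landmarks, ann_file, image = basename(img_file),
                     augment = s$augment)
    rows[[i]] <- tibble::tibble(file = basename(img_file),
                                annotation = basename(ann_file),
                                split = split[i], seed = seeds[i])
  }
  manifest <- dplyr::bind_rows(rows)
  writeLines(vapply(seq_len(n), function(i)
    jsonlite::toJSON(as.list(manifest[i, ]), auto_unbox = TRUE),
    character(1)), file.path(out_dir, "manifest.jsonl"))
  manifest
}

#' @rdname generate_carapace_dataset
#' @param path a `manifest.jsonl` file.
#' @return `read_manifest()`: the manifest tibble.
#' @export
read_manifest <- function(path) {
  dplyr::bind_rows(lapply(readLines(path), function(l)
    tibble::as_tibble(jsonlite::fromJSON(l))))
}

#' One-tenth test-set convention
#'
#' @param n_total total number of samples.
#' @return Number of test samples (`n_total %/% 10`).
#' @examples
#' default_test_count(4600) # 460
#' @export
default_test_count <- function(n_total) n_total %/% 10L

# evaluate a block with a temporary RNG seed, restoring the caller's state
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}
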