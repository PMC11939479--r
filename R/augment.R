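#' Augmentation configuration
#'
#' The four stochastic augmentations -- Gaussian blur, brightness/contrast,
#' rotation and rectangular occlusion -- are each applied independently with
#' probability 0.5 by default. Ranges are uniform draws.
#'
#' @param p_blur,p_brightness_contrast,p_rotation,p_occlusion per-transform
#'   apply probabilities, each in `[0, 1]`.
#' @param blur_sigma blur standard-deviation range in pixels.
#' @param brightness additive brightness-shift range (0--255 scale).
#' @param contrast multiplicative contrast-factor range (about the mid-grey
#'   value 128).
#' @param rotation rotation-angle range in degrees.
#' @param occlusion_count range of the number of occluding rectangles.
#' @param occlusion_frac per-rectangle area fraction range, in (0, 1).
#' @return A named list of class `augmentation_config`.
#' @export
augmentation_config <- function(p_blur = 0.5, p_brightness_contrast = 0.5,
                                p_rotation = 0.5, p_occlusion = 0.5,
                                blur_sigma = c(0.5, 3),
                                brightness = c(-40, 40),
                                contrast = c(0.7, 1.3),
                                rotation = c(-30, 30),
                                occlusion_count = c(1, 3),
                                occlusion_frac = c(0.02, 0.10)) {
  probs <- c(blur = p_blur, brightness_contrast = p_brightness_contrast,
             rotation = p_rotation, occlusion = p_occlusion)
  if (any(probs < 0 | probs > 1)) stop("probabilities must lie in [0, 1]")
  ranges <- list(blur_sigma = blur_sigma, brightness = brightness,
                 contrast = contrast, rotation = rotation,
                 occlusion_count = occlusion_count,
                 occlusion_frac = occlusion_frac)
  ok <- vapply(ranges, function(r) length(r) == 2 && r[1] <= r[2], logical(1))
  if (!all(ok)) stop("ranges must be ordered length-2 vectors")
  if (any(occlusion_frac <= 0 | occlusion_frac >= 1))
    stop("occlusion area fractions must lie in (0, 1)")
  structure(c(list(probs = probs), ranges), class = "augmentation_config")
}

#' Photometric augmentation: Gaussian blur, brightness and contrast
#'
#' Blurs with standard deviation `sigma` (separable Gaussian, reflective
#' boundaries), then maps every pixel value to
#' `clip(contrast * (v - 128) + 128 + brightness)`. Landmark positions are
#' untouched by photometric changes.
#'
#' @param image array `(h, w, 3)`, values 0--255.
#' @param sigma blur standard deviation in pixels (0 = no blur).
#' @param brightness additive shift.
#' @param contrast multiplicative factor (> 0).
#' @return The transformed image.
#' @export
apply_photometric <- function(image, sigma = 0, brightness = 0, contrast = 1) {
  if (sigma < 0) stop("sigma must be non-negative")
  if (contrast <= 0) stop("contrast must be positive")
  if (sigma > 0) image <- gaussian_blur_cpp(image, sigma)
  if (contrast != 1 || brightness != 0) {
    image <- contrast * (image - 128) + 128 + brightness
    image[] <- pmin(255, pmax(0, image))
  }
  image
}

#' Rotation augmentation with exact landmark remapping
#'
#' Rotates the image about its centre `((w-1)/2, (h-1)/2)` on a fixed canvas
#' with bilinear resampling, filling exposed canvas with `fill` (default: the
#' per-channel median of the border pixels, a cheap background estimate).
#' Every landmark is mapped by the same rotation; points leaving the frame
#' keep their coordinates but are flagged invalid, so the coordinate vector
#' keeps its fixed length. Bounding-box corners are recomputed from the
#' rotated carapace points when any remain in frame.
#'
#' @param image array `(h, w, 3)`.
#' @param landmarks a [landmark_set()] in the pixel frame.
#' @param angle_deg rotation angle in degrees (positive rotates landmark
#'   content clockwise on screen).
#' @param fill length-3 fill colour, or `NULL` for the border median.
#' @return List with `image` and `landmarks`.
#' @export
apply_rotation <- function(image, landmarks, angle_deg, fill = NULL) {
  if (lm_frame(landmarks) != "pixel") stop("landmarks must be in pixel frame")
  h <- dim(image)[1]; w <- dim(image)[2]
  if (is.null(fill)) {
    border <- rbind(image[1, , ], image[h, , ], image[, 1, ], image[, w, ])
    fill <- apply(border, 2, stats::median)
  }
  ang <- angle_deg * pi / 180
  out_img <- rotate_image_cpp(image, ang, fill)
  ctr <- c((w - 1) / 2, (h - 1) / 2)
  core <- landmarks[landmarks$id <= 37L, ]
  xy <- rotate_about(cbind(core$x, core$y), ang, ctr)
  lm <- landmark_set(xy[, 1], xy[, 2], frame = "pixel", width = w, height = h)
  lm <- if (any(lm$valid)) landmarks_with_bbox(lm) else {
    bb <- rotate_about(cbind(landmarks$x[38:39], landmarks$y[38:39]), ang, ctr)
    landmark_set(c(xy[, 1], bb[, 1]), c(xy[, 2], bb[, 2]), frame = "pixel",
                 width = w, height = h)
  }
  list(image = out_img, landmarks = lm)
}

#' Occlusion augmentation
#'
#' Fills 1..k axis-aligned rectangles (drawn wholly inside the frame) with
#' random uniform colours. Labels are unchanged: landmarks keep their true
#' positions underneath the occluders, which is exactly what forces a
#' detector to learn context.
#'
#' @param image array `(h, w, 3)`.
#' @param config an [augmentation_config()] providing count and area ranges.
#' @return List with `image` and `rects` (one row per rectangle:
#'   `x0, y0, width, height`, 0-based pixel indices).
#' @export
apply_occlusion <- function(image, config = augmentation_config()) {
  h <- dim(image)[1]; w <- dim(image)[2]
  cr <- config$occlusion_count
  n_rect <- if (cr[1] == cr[2]) cr[1] else sample(cr[1]:cr[2], 1)
  rects <- vector("list", n_rect)
  for (r in seq_len(n_rect)) {
    frac <- runif(1, config$occlusion_frac[1], config$occlusion_frac[2])
    aspect <- exp(runif(1, log(0.5), log(2)))
    rw <- max(1L, min(w, round(sqrt(frac * w * h * aspect))))
    rh <- max(1L, min(h, round(sqrt(frac * w * h / aspect))))
    x0 <- sample.int(w - rw + 1L, 1) - 1L
    y0 <- sample.int(h - rh + 1L, 1) - 1L
    col <- runif(3, 0, 255)
    for (c0 in 1:3)
      image[(y0 + 1):(y0 + rh), (x0 + 1):(x0 + rw), c0] <- col[c0]
    rects[[r]] <- tibble::tibble(x0 = x0, y0 = y0, width = rw, height = rh)
  }
  list(image = image, rects = dplyr::bind_rows(rects))
}

#' Apply the stochastic augmentation protocol to one sample
#'
#' Each of blur, brightness/contrast, rotation and occlusion is applied
#' independently with its configured probability, in that order, drawing all
#' parameters from the current RNG state (seed the RNG for reproducibility).
#' The applied transforms and their parameters are stored in the returned
#' sample's `augment` record.
#'
#' @param sample an `annotated_image` (see [render_carapace()]).
#' @param config an [augmentation_config()].
#' @return The augmented `annotated_image`; `$augment` lists the applied
#'   transforms.
#' @export
augment_sample <- function(sample, config = augmentation_config()) {
  img <- sample$image
  lm <- sample$landmarks
  rec <- list()
  if (runif(1) < config$probs[["blur"]]) {
    sigma <- runif(1, config$blur_sigma[1], config$blur_sigma[2])
    img <- apply_photometric(img, sigma = sigma)
    rec$blur <- list(sigma = sigma)
  }
  if (runif(1) < config$probs[["brightness_contrast"]]) {
    b <- runif(1, config$brightness[1], config$brightness[2])
    co <- runif(1, config$contrast[1], config$contrast[2])
    img <- apply_photometric(img, brightness = b, contrast = co)
    rec$brightness_contrast <- list(brightness = b, contrast = co)
  }
  if (runif(1) < config$probs[["rotation"]]) {
    ang <- runif(1, config$rotation[1], config$rotation[2])
    rot <- apply_rotation(img, lm, ang)
    img <- rot$image
    lm <- rot$landmarks
    rec$rotation <- list(angle_deg = ang)
  }
  if (runif(1) < config$probs[["occlusion"]]) {
    occ <- apply_occlusion(img, config)
    img <- occ$image
    rec$occlusion <- list(rects = occ$rects)
  }
  out <- sample
  out$image <- img
  out$landmarks <- lm
  out$augment <- rec
  out
}
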