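test_that("configuration ranges and probabilities are validated", {
  expect_s3_class(augmentation_config(), "augmentation_config")
  expect_error(augmentation_config(p_blur = 1.2), "probabilities")
  expect_error(augmentation_config(contrast = c(1.3, 0.7)), "ordered")
  expect_error(augmentation_config(occlusion_frac = c(0, 0.5)), "fractions")
})

test_that("photometric transforms clip to the valid pixel range", {
  img <- array(runif(20 * 20 * 3, 0, 255), c(20, 20, 3))
  out <- apply_photometric(img, brightness = 300)
  expect_true(all(out == 255))
  out <- apply_photometric(img, brightness = -300)
  expect_true(all(out == 0))
  # identity parameters leave the image untouched
  expect_identical(apply_photometric(img), img)
  expect_error(apply_photometric(img, sigma = -1), "non-negative")
  expect_error(apply_photometric(img, contrast = 0), "positive")
})

test_that("Gaussian blur preserves a constant image and smooths edges", {
  img <- array(100, c(16, 16, 3))
  expect_equal(apply_photometric(img, sigma = 2), img, tolerance = 1e-4)
  step <- array(0, c(16, 16, 3)); step[, 9:16, ] <- 255
  sm <- apply_photometric(step, sigma = 2)
  expect_gt(sm[8, 8, 1], 0)
  expect_lt(sm[8, 9, 1], 255)
})

test_that("rotation maps landmarks with the exact rotation matrix", {
  s <- demo_sample()
  ang <- 25
  rot <- apply_rotation(s$image, s$landmarks, ang)
  h <- dim(s$image)[1]; w <- dim(s$image)[2]
  ctr <- c((w - 1) / 2, (h - 1) / 2)
  th <- ang * pi / 180
  R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)
  expected <- t(R %*% t(cbind(s$landmarks$x[1:37], s$landmarks$y[1:37]) -
                          matrix(ctr, 37, 2, byrow = TRUE))) +
    matrix(ctr, 37, 2, byrow = TRUE)
  expect_equal(rot$landmarks$x[1:37], expected[, 1], tolerance = 1e-9)
  expect_equal(rot$landmarks$y[1:37], expected[, 2], tolerance = 1e-9)
  expect_equal(dim(rot$image), dim(s$image))
})

test_that("image content moves consistently with the landmarks", {
  # a bright dot placed at a landmark position is found near the rotated
  # landmark position after rotation
  img <- array(0, c(64, 64, 3))
  img[41, 21, ] <- 255 # pixel (x = 20, y = 40)
  x <- rep(20, 39); y <- rep(40, 39)
  lm <- landmark_set(x, y, frame = "pixel", width = 64, height = 64)
  rot <- apply_rotation(img, lm, 30, fill = c(0, 0, 0))
  peak <- which(rot$image[, , 1] == max(rot$image[, , 1]), arr.ind = TRUE)[1, ]
  expect_lt(abs(peak["col"] - 1 - rot$landmarks$x[1]), 1.5)
  expect_lt(abs(peak["row"] - 1 - rot$landmarks$y[1]), 1.5)
})

test_that("rotation flags points that leave the frame as invalid", {
  img <- array(128, c(32, 32, 3))
  x <- rep(16, 39); y <- rep(16, 39)
  x[1] <- 31; y[1] <- 0 # top-right corner: a 90-degree turn pushes it out
  lm <- landmark_set(x, y, frame = "pixel", width = 32, height = 32)
  rot <- apply_rotation(img, lm, 45)
  expect_false(rot$landmarks$valid[1])
  expect_length(rot$landmarks$x, 39L)
})

test_that("occluders stay inside the frame and cover what they claim", {
  set.seed(60)
  img <- array(128, c(40, 40, 3))
  occ <- apply_occlusion(img, augmentation_config(occlusion_count = c(2, 2)))
  expect_equal(nrow(occ$rects), 2L)
  r <- occ$rects
  expect_true(all(r$x0 >= 0 & r$x0 + r$width <= 40))
  expect_true(all(r$y0 >= 0 & r$y0 + r$height <= 40))
  # with a single occluder (no overlap possible) its patch is one flat colour
  occ1 <- apply_occlusion(img, augmentation_config(occlusion_count = c(1, 1)))
  r1 <- occ1$rects
  patch <- occ1$image[(r1$y0 + 1):(r1$y0 + r1$height),
                      (r1$x0 + 1):(r1$x0 + r1$width), 1]
  expect_equal(length(unique(as.numeric(patch))), 1L)
})

test_that("the augmentation protocol is seed-reproducible and recorded", {
  s <- demo_sample()
  a <- shellmark:::with_seed(9, augment_sample(s))
  b <- shellmark:::with_seed(9, augment_sample(s))
  expect_identical(a$image, b$image)
  expect_identical(a$augment, b$augment)
  expect_true(is.list(a$augment))
  # with all probabilities zero, the sample passes through unchanged
  off <- augmentation_config(p_blur = 0, p_brightness_contrast = 0,
                             p_rotation = 0, p_occlusion = 0)
  untouched <- shellmark:::with_seed(9, augment_sample(s, off))
  expect_identical(untouched$image, s$image)
  expect_length(untouched$augment, 0L)
})

test_that("each transform leaves its parameters in the augment record", {
  s <- demo_sample()
  always <- augmentation_config(p_blur = 1, p_brightness_contrast = 1,
                                p_rotation = 1, p_occlusion = 1)
  a <- shellmark:::with_seed(123, augment_sample(s, always))
  expect_setequal(names(a$augment),
                  c("blur", "brightness_contrast", "rotation", "occlusion"))
  expect_true(a$augment$blur$sigma >= 0.5 && a$augment$blur$sigma <= 3)
  expect_true(abs(a$augment$rotation$angle_deg) <= 30)
})
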