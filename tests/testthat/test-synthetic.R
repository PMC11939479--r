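test_that("parameter sampling is a pure function of the seed", {
  a <- sample_carapace_params(seed = 99, size = 128L)
  b <- sample_carapace_params(seed = 99, size = 128L)
  expect_identical(a, b)
  c <- sample_carapace_params(seed = 100, size = 128L)
  expect_false(identical(a$center, c$center))
})

test_that("sampling under a seed leaves the caller's RNG state untouched", {
  set.seed(1); before <- .Random.seed
  invisible(sample_carapace_params(seed = 5, size = 64L))
  expect_identical(.Random.seed, before)
})

test_that("the template places twelve teeth in four fixed sectors", {
  ang <- tooth_angles()
  expect_length(ang$frontal, 9L)
  expect_length(ang$left, 9L)
  expect_length(ang$right, 9L)
  expect_length(ang$rear, 3L)
  tpl <- carapace_template(128L)
  expect_length(tpl$tooth_amp, 12L)
  expect_true(tpl$a > tpl$b_front) # wider than tall
})

test_that("rim landmarks lie on the rim and groove points inside it", {
  p <- sample_carapace_params(seed = 17, size = 128L)
  lm <- shellmark:::carapace_landmarks(p)
  expect_equal(nrow(lm), 37L)
  # rear-edge points carry no tooth displacement: exactly on the base rim
  # undo the orientation to work in the template frame, where the rim
  # direction at angle theta is (sin theta, -cos theta)
  to_model <- function(pts) {
    d <- cbind(pts$x - p$center[1], pts$y - p$center[2])
    shellmark:::rotate_about(d, -p$orientation, c(0, 0))
  }
  re <- to_model(lm[lm$group == "rear_edge", ])
  th <- atan2(re[, 1], -re[, 2])
  r <- sqrt(rowSums(re^2))
  expect_equal(r, shellmark:::rim_radius(p, th), tolerance = 1e-9)
  # groove points sit strictly inside the rim
  gr <- to_model(lm[lm$group == "neck_groove", ])
  thg <- atan2(gr[, 1], -gr[, 2])
  rg <- sqrt(rowSums(gr^2))
  expect_true(all(rg < shellmark:::rim_radius(p, thg)))
})

test_that("rendering yields an annotated image with in-frame landmarks", {
  s <- demo_sample()
  expect_s3_class(s$landmarks, "landmark_set")
  d <- dim(s$image)
  expect_equal(d[3], 3L)
  expect_true(all(s$image >= 0 & s$image <= 255))
  expect_equal(nrow(s$landmarks), 39L)
  expect_true(all(s$landmarks$valid))
  # the carapace body is darker than the background corner
  cx <- round(mean(s$landmarks$x[1:37])) + 1L
  cy <- round(mean(s$landmarks$y[1:37])) + 1L
  expect_lt(mean(s$image[cy, cx, ]), mean(s$image[1, 1, ]))
})

test_that("rendering is reproducible and seeds decorrelate samples", {
  a <- make_carapace_sample(7, size = 64L)
  b <- make_carapace_sample(7, size = 64L)
  expect_identical(a$image, b$image)
  expect_identical(a$landmarks$x, b$landmarks$x)
  c <- make_carapace_sample(8, size = 64L)
  expect_false(identical(a$image, c$image))
})

test_that("off-image carapace parameters are rejected", {
  p <- sample_carapace_params(seed = 1, size = 128L)
  p$center <- c(-50, -50)
  expect_error(shellmark:::validate_carapace_params(p))
})

test_that("simulated datasets have the documented engine layout", {
  d <- shellmark:::simulate_carapace_dataset(3, seed = 5, size = 64L)
  expect_s3_class(d, "carapace_dataset")
  expect_equal(dim(d$images), c(3L * 64L * 64L, 3L))
  expect_equal(dim(d$coords), c(78L, 3L))
  expect_equal(dim(d$valid), c(39L, 3L))
  expect_true(all(abs(d$coords) <= 1))
  # column i reproduces sample i exactly
  s1 <- make_carapace_sample(d$seeds[2], size = 64L)
  expect_identical(d$images[, 2],
                   shellmark:::pack_image_raw(s1$image))
})

test_that("the dataset pair shares renders with the two-call protocol", {
  p <- simulate_carapace_pair(3, seed = 31, size = 64L)
  src <- shellmark:::simulate_carapace_dataset(3, 31, size = 64L,
                                               augment = FALSE)
  aug <- shellmark:::simulate_carapace_dataset(3, 31, size = 64L,
                                               augment = TRUE)
  expect_identical(p$source$images, src$images)
  expect_identical(p$augmented$images, aug$images)
  expect_identical(p$augmented$coords, aug$coords)
  expect_false(p$source$augmented)
  expect_true(p$augmented$augmented)
})

test_that("on-disk datasets round-trip through PNG, JSON and manifest", {
  dir <- tempfile("ds")
  man <- generate_carapace_dataset(dir, n_train = 2, n_test = 1, seed = 44,
                                   size = 64L)
  expect_equal(nrow(man), 3L)
  expect_equal(sum(man$split == "test"), 1L)
  expect_true(all(file.exists(file.path(dir, man$file))))
  back <- read_manifest(file.path(dir, "manifest.jsonl"))
  expect_equal(back$file, man$file)
  ann <- read_annotation(file.path(dir, man$annotation[1]))
  img <- png::readPNG(file.path(dir, man$file[1]))
  expect_equal(dim(img)[1:2], c(64L, 64L))
  expect_equal(nrow(ann), 39L)
  unlink(dir, recursive = TRUE)
})

test_that("the held-out split is one tenth of the pool", {
  expect_equal(default_test_count(4600L), 460L)
  expect_equal(default_test_count(95L), 9L)
})
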