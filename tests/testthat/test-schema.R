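test_that("the schema enumerates 37 carapace points plus two bbox corners", {
  sch <- carapace_schema()
  expect_equal(nrow(sch), 39L)
  expect_equal(nrow(carapace_schema(bbox = FALSE)), 37L)
  counts <- table(sch$group)
  expect_equal(as.integer(counts[c("frontal_teeth", "left_teeth",
                                   "right_teeth", "rear_edge", "neck_groove",
                                   "bbox")]),
               c(9L, 9L, 9L, 3L, 7L, 2L))
  expect_equal(sch$id, 1:39)
  expect_false(anyDuplicated(sch$name) > 0)
})

test_that("adjacent teeth share their junction point", {
  sh <- attr(carapace_schema(), "sharing")
  expect_equal(nrow(sh), 9L)
  # junction of teeth t and t+1 sits at offset + 2t + 1 within its group
  expect_equal(unname(sh$id[sh$group == "frontal_teeth"]), c(3L, 5L, 7L))
  expect_equal(unname(sh$id[sh$group == "left_teeth"]), c(12L, 14L, 16L))
  expect_equal(unname(sh$id[sh$group == "right_teeth"]), c(21L, 23L, 25L))
  sch <- carapace_schema()
  expect_true(all(sch$role[sh$id] == "junction"))
})

test_that("landmark sets validate their length and carry frame metadata", {
  lm <- landmark_set(runif(39, 0, 31), runif(39, 0, 31),
                     frame = "pixel", width = 32, height = 32)
  expect_s3_class(lm, "landmark_set")
  expect_equal(lm_frame(lm), "pixel")
  expect_equal(lm_width(lm), 32L)
  expect_true(all(lm$valid))
  expect_error(landmark_set(1:5, 1:5, width = 8, height = 8), "37")
  expect_error(landmark_set(1:39, 1:38, width = 8, height = 8), "lengths")
})

test_that("out-of-frame points are flagged invalid", {
  x <- rep(5, 39); y <- rep(5, 39)
  x[4] <- -2; y[9] <- 40
  lm <- landmark_set(x, y, frame = "pixel", width = 32, height = 32)
  expect_equal(which(!lm$valid), c(4L, 9L))
})

test_that("flatten and unflatten are exact inverses in interleaved order", {
  lm <- landmark_set(seq(0, 38), seq(38, 0), frame = "pixel",
                     width = 64, height = 64)
  v <- landmarks_flatten(lm)
  expect_length(v, 78L)
  expect_equal(unname(v[1:4]), c(0, 38, 1, 37)) # x1, y1, x2, y2
  back <- landmarks_unflatten(v, frame = "pixel", width = 64, height = 64)
  expect_equal(back$x, lm$x)
  expect_equal(back$y, lm$y)
})

test_that("pixel-centre normalization maps known points exactly", {
  # x' = (2(x + 1) - (W + 1)) / W: pixel 0 of a 32-wide axis -> -31/32
  x <- rep(0, 39); y <- rep(31, 39)
  lm <- landmark_set(x, y, frame = "pixel", width = 32, height = 32)
  nm <- landmarks_normalize(lm)
  expect_equal(lm_frame(nm), "normalized")
  expect_equal(nm$x[1], -31 / 32)
  expect_equal(nm$y[1], 31 / 32)
  # centre of a 33-wide axis maps to 0 exactly
  lm2 <- landmark_set(rep(16, 39), rep(16, 39), frame = "pixel",
                      width = 33, height = 33)
  expect_equal(landmarks_normalize(lm2)$x[1], 0)
})

test_that("normalization round-trips through the pixel frame", {
  set.seed(7)
  lm <- landmark_set(runif(39, 0, 63), runif(39, 0, 47), frame = "pixel",
                     width = 64, height = 48)
  for (conv in c("pixel_center", "endpoint")) {
    back <- landmarks_to_pixel(landmarks_normalize(lm, conv), conv)
    expect_equal(back$x, lm$x, tolerance = 1e-12)
    expect_equal(back$y, lm$y, tolerance = 1e-12)
  }
})

test_that("the endpoint convention pins frame borders to -1 and 1", {
  lm <- landmark_set(c(0, rep(1, 37), 31), c(0, rep(1, 37), 31),
                     frame = "pixel", width = 32, height = 32)
  nm <- landmarks_normalize(lm, "endpoint")
  expect_equal(nm$x[1], -1)
  expect_equal(nm$x[39], 1)
})

test_that("the bounding box encloses all valid points", {
  s <- demo_sample()
  lm <- s$landmarks
  core37 <- restore_lm(lm[lm$id <= 37L, ], lm)
  bb <- landmark_bbox(core37)
  core <- lm[lm$id <= 37L & lm$valid, ]
  expect_lte(bb$x[1], min(core$x))
  expect_gte(bb$x[2], max(core$x))
  expect_lte(bb$y[1], min(core$y))
  wb <- landmarks_with_bbox(core37)
  expect_equal(nrow(wb), 39L)
  expect_equal(wb$x[38], bb$x[1])
  expect_equal(wb$y[39], bb$y[2])
})

test_that("annotations survive a JSON round trip", {
  s <- demo_sample()
  path <- tempfile(fileext = ".json")
  write_annotation(s$landmarks, path, image = "sample.png")
  back <- read_annotation(path)
  expect_s3_class(back, "landmark_set")
  expect_equal(back$x, s$landmarks$x, tolerance = 1e-9)
  expect_equal(back$y, s$landmarks$y, tolerance = 1e-9)
  expect_equal(lm_width(back), lm_width(s$landmarks))
  expect_equal(attr(back, "image"), "sample.png")
  unlink(path)
})
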