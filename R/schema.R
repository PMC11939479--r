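#' The canonical carapace landmark schema
#'
#' The carapace rim carries twelve teeth: four frontal, four left-lateral and
#' four right-lateral. Each tooth is described by a start point, a peak and an
#' end point, and adjacent teeth within a group share their junction point, so
#' each group of four teeth needs 4 x 3 - 3 = 9 points. Together with the
#' three-point rear edge and the seven-point M-shaped neck groove this gives
#' 37 carapace points; the upper-left and lower-right corners of the bounding
#' rectangle are appended as points 38 and 39 for the regression heads.
#'
#' Ordering is fixed: P1--P9 frontal teeth left to right, P10--P18 left
#' lateral front to rear, P19--P27 right lateral front to rear, P28--P30 rear
#' edge left to right, P31--P37 groove left to right, P38/P39 bounding box.
#'
#' @param bbox if `TRUE` (default) include the two bounding-box corner points
#'   (39 rows); otherwise only the 37 carapace points.
#' @return A tibble with columns `id`, `name`, `group` and `role`, and a
#'   `sharing` attribute listing the point shared by each pair of adjacent
#'   teeth.
#' @examples
#' sch <- carapace_schema()
#' nrow(carapace_schema(bbox = FALSE)) # 37
#' table(sch$group)
#' @export
carapace_schema <- function(bbox = TRUE) {
  tooth_group <- function(prefix) {
    name <- character(9)
    role <- character(9)
    k <- 1L
    for (t in 1:4) {
      if (t == 1L) {
        name[k] <- paste0(prefix, "_t1_start"); role[k] <- "start"; k <- k + 1L
      }
      name[k] <- paste0(prefix, "_t", t, "_peak"); role[k] <- "peak"; k <- k + 1L
      name[k] <- if (t < 4L) paste0(prefix, "_t", t, "t", t + 1L) else
        paste0(prefix, "_t4_end")
      role[k] <- if (t < 4L) "junction" else "end"
      k <- k + 1L
    }
    tibble::tibble(name = name, role = role)
  }
  groups <- list(
    frontal_teeth = tooth_group("frontal"),
    left_teeth    = tooth_group("left"),
    right_teeth   = tooth_group("right"),
    rear_edge     = tibble::tibble(
      name = c("rear_left", "rear_mid", "rear_right"),
      role = "edge"),
    neck_groove   = tibble::tibble(
      name = paste0("groove_", 1:7),
      role = "groove")
  )
  sch <- dplyr::bind_rows(groups, .id = "group")
  if (bbox) {
    sch <- dplyr::bind_rows(sch, tibble::tibble(
      group = "bbox",
      name = c("bbox_upper_left", "bbox_lower_right"),
      role = "bbox"))
  }
  sch <- dplyr::mutate(sch, id = dplyr::row_number(), .before = 1)
  # junction of tooth t and t+1 within each tooth group (shared point)
  offsets <- c(frontal_teeth = 0L, left_teeth = 9L, right_teeth = 18L)
  sharing <- tidyr::expand_grid(
    group = names(offsets), tooth_a = 1:3) |>
    dplyr::mutate(tooth_b = .data$tooth_a + 1L,
                  id = offsets[.data$group] + 2L * .data$tooth_a + 1L)
  attr(sch, "sharing") <- sharing
  sch
}

#' Construct a landmark set
#'
#' A landmark set is a tibble of named 2-D points tied to a coordinate frame.
#' In the pixel frame coordinates are 0-based and continuous with the origin
#' at the top-left pixel centre: the centre of pixel (row r, column c) has
#' coordinates (x = c, y = r), x growing rightwards and y downwards. In the
#' normalized frame both axes lie in roughly (-1, 1) (see
#' [landmarks_normalize()]).
#'
#' @param x,y numeric vectors of length 37 or 39 in schema order.
#' @param frame `"pixel"` or `"normalized"`.
#' @param width,height image dimensions in pixels the coordinates refer to.
#' @param valid logical vector of per-point validity (in-frame) flags;
#'   computed from the coordinates when `NULL`.
#' @return A tibble of class `landmark_set` with columns `id`, `name`,
#'   `group`, `x`, `y`, `valid` and attributes `frame`, `width`, `height`.
#' @export
landmark_set <- function(x, y, frame = c("pixel", "normalized"),
                         width, height, valid = NULL) {
  frame <- match.arg(frame)
  n <- length(x)
  if (length(y) != n) stop("x and y lengths differ")
  if (!n %in% c(37L, 39L))
    stop("a landmark set has 37 carapace points or 39 points with bbox corners")
  sch <- carapace_schema(bbox = n == 39L)
  if (is.null(valid)) {
    valid <- if (frame == "pixel")
      x >= 0 & x <= width - 1 & y >= 0 & y <= height - 1
    else abs(x) <= 1 & abs(y) <= 1
  }
  out <- tibble::tibble(id = sch$id, name = sch$name, group = sch$group,
                        x = as.numeric(x), y = as.numeric(y),
                        valid = as.logical(valid))
  attr(out, "frame") <- frame
  attr(out, "width") <- as.integer(width)
  attr(out, "height") <- as.integer(height)
  class(out) <- c("landmark_set", class(out))
  out
}

lm_frame <- function(lm) attr(lm, "frame", exact = TRUE)
lm_width <- function(lm) attr(lm, "width", exact = TRUE)
lm_height <- function(lm) attr(lm, "height", exact = TRUE)

restore_lm <- function(df, template, frame = lm_frame(template)) {
  attr(df, "frame") <- frame
  attr(df, "width") <- lm_width(template)
  attr(df, "height") <- lm_height(template)
  if (!inherits(df, "landmark_set")) class(df) <- c("landmark_set", class(df))
  df
}

#' Validate a landmark set against the canonical schema
#'
#' @param lm a [landmark_set()].
#' @return `lm`, invisibly; errors describe the first violated invariant.
#' @export
validate_landmarks <- function(lm) {
  if (!inherits(lm, "landmark_set")) stop("not a landmark_set")
  n <- nrow(lm)
  if (!n %in% c(37L, 39L)) stop("landmark set must have 37 or 39 points")
  sch <- carapace_schema(bbox = n == 39L)
  if (!identical(lm$id, sch$id) || !identical(lm$name, sch$name))
    stop("point ids/names do not match the canonical schema order")
  if (anyNA(lm$x) || anyNA(lm$y) || any(!is.finite(lm$x)) || any(!is.finite(lm$y)))
    stop("landmark coordinates must be finite")
  if (!lm_frame(lm) %in% c("pixel", "normalized")) stop("unknown frame")
  invisible(lm)
}

#' Flatten a 39-point landmark set to a 78-vector (and back)
#'
#' Coordinates are interleaved as (x1, y1, x2, y2, ..., x39, y39), the layout
#' the fully-connected head regresses directly.
#'
#' @param lm a 39-point [landmark_set()].
#' @return `landmarks_flatten()`: a numeric vector of length 78.
#' @export
landmarks_flatten <- function(lm) {
  if (nrow(lm) != 39L)
    stop("flatten requires the 39-point set (37 carapace + 2 bbox points)")
  v <- as.numeric(rbind(lm$x, lm$y))
  names(v) <- paste0(rep(c("x", "y"), 39L), rep(lm$id, each = 2L))
  v
}

#' @rdname landmarks_flatten
#' @param v numeric vector of length 78, interleaved (x, y) pairs.
#' @inheritParams landmark_set
#' @return `landmarks_unflatten()`: the reconstructed 39-point set.
#' @export
landmarks_unflatten <- function(v, frame = c("pixel", "normalized"),
                                width, height) {
  if (length(v) != 78L) stop("expected 78 values (39 interleaved (x,y) pairs)")
  m <- matrix(v, nrow = 2L)
  landmark_set(m[1, ], m[2, ], frame = match.arg(frame),
               width = width, height = height)
}

#' Map landmark coordinates between the pixel and normalized frames
#'
#' The default `"pixel_center"` convention places the n pixel centres of an
#' axis of length n at (2j - (n + 1))/n for j = 1..n, i.e. x' =
#' (2(x + 1) - (w + 1))/w for a 0-based pixel coordinate x. This matches the
#' signed coordinate grids used by the DSNT head, so a normalized landmark and
#' the soft-argmax expectation live on the same scale. The `"endpoint"`
#' convention 2x/(w - 1) - 1, which pins the outermost pixel centres to
#' exactly -1 and 1, is provided as an alternative but is not the default.
#' Both maps are exactly invertible.
#'
#' @param lm a [landmark_set()].
#' @param convention `"pixel_center"` (default) or `"endpoint"`.
#' @return The landmark set in the other frame; `width`/`height` are kept so
#'   the mapping can be undone.
#' @examples
#' p <- landmark_set(rep(0, 37), rep(0, 37), "pixel", 32, 32)
#' landmarks_normalize(p)$x[1] # -31/32
#' @export
landmarks_normalize <- function(lm, convention = c("pixel_center", "endpoint")) {
  convention <- match.arg(convention)
  if (lm_frame(lm) != "pixel") stop("landmarks are not in the pixel frame")
  w <- lm_width(lm); h <- lm_height(lm)
  if (is.null(w) || w <= 0 || is.null(h) || h <= 0)
    stop("positive width and height are required")
  out <- lm
  if (convention == "pixel_center") {
    out$x <- (2 * (lm$x + 1) - (w + 1)) / w
    out$y <- (2 * (lm$y + 1) - (h + 1)) / h
  } else {
    out$x <- 2 * lm$x / (w - 1) - 1
    out$y <- 2 * lm$y / (h - 1) - 1
  }
  restore_lm(out, lm, frame = "normalized")
}

#' @rdname landmarks_normalize
#' @export
landmarks_to_pixel <- function(lm, convention = c("pixel_center", "endpoint")) {
  convention <- match.arg(convention)
  if (lm_frame(lm) != "normalized") stop("landmarks are not in the normalized frame")
  w <- lm_width(lm); h <- lm_height(lm)
  out <- lm
  if (convention == "pixel_center") {
    out$x <- (w * lm$x + w - 1) / 2
    out$y <- (h * lm$y + h - 1) / 2
  } else {
    out$x <- (lm$x + 1) * (w - 1) / 2
    out$y <- (lm$y + 1) * (h - 1) / 2
  }
  restore_lm(out, lm, frame = "pixel")
}

#' Bounding box of the carapace points
#'
#' The tight min/max box over the (in-frame) carapace points, expanded by
#' `margin` pixels and clamped to the image bounds. The box corners become
#' schema points 38 and 39.
#'
#' @param lm a [landmark_set()] in the pixel frame.
#' @param margin expansion in pixels (default 0).
#' @return A tibble with rows `upper_left` and `lower_right` and columns
#'   `corner`, `x`, `y`.
#' @export
landmark_bbox <- function(lm, margin = 0) {
  if (lm_frame(lm) != "pixel") stop("bounding box requires the pixel frame")
  pts <- lm[lm$id <= 37L & lm$valid, ]
  if (nrow(pts) == 0L) stop("no in-frame points to bound")
  w <- lm_width(lm); h <- lm_height(lm)
  x0 <- max(0, min(pts$x) - margin); y0 <- max(0, min(pts$y) - margin)
  x1 <- min(w - 1, max(pts$x) + margin); y1 <- min(h - 1, max(pts$y) + margin)
  tibble::tibble(corner = c("upper_left", "lower_right"),
                 x = c(x0, x1), y = c(y0, y1))
}

#' @rdname landmark_bbox
#' @return `landmarks_with_bbox()`: the 39-point set with the two box corners
#'   appended (an existing pair is recomputed).
#' @export
landmarks_with_bbox <- function(lm, margin = 0) {
  bb <- landmark_bbox(lm, margin = margin)
  core <- lm[lm$id <= 37L, ]
  landmark_set(c(core$x, bb$x), c(core$y, bb$y), frame = "pixel",
               width = lm_width(lm), height = lm_height(lm),
               valid = c(core$valid, TRUE, TRUE))
}

#' Read and write per-image landmark annotations (JSON)
#'
#' One JSON file per image: `{"image", "width", "height", "frame", "points":
#' [{"id", "name", "x", "y"}, ...]}` with an optional `"augment"` record.
#' Files with only the 37 carapace points are accepted; the bounding-box
#' corners are then computed on read.
#'
#' @param lm a [landmark_set()] in the pixel frame.
#' @param path file path.
#' @param image image file name stored alongside the points.
#' @param augment optional named list describing applied augmentations.
#' @return `read_annotation()` returns a 39-point [landmark_set()] with the
#'   image name and any augmentation record as attributes.
#' @export
write_annotation <- function(lm, path, image = "", augment = NULL) {
  obj <- list(
    image = image, width = lm_width(lm), height = lm_height(lm),
    frame = lm_frame(lm),
    points = purrr::pmap(list(lm$id, lm$name, lm$x, lm$y),
                         function(id, name, x, y)
                           list(id = id, name = name, x = x, y = y)))
  if (!is.null(augment)) obj$augment <- augment
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_annotation
#' @export
read_annotation <- function(path) {
  obj <- jsonlite::read_json(path)
  pts <- dplyr::bind_rows(purrr::map(obj$points, tibble::as_tibble))
  pts <- pts[order(pts$id), ]
  lm <- landmark_set(pts$x, pts$y, frame = obj$frame,
                     width = obj$width, height = obj$height)
  if (nrow(lm) == 37L) lm <- landmarks_with_bbox(lm)
  attr(lm, "image") <- obj$image
  attr(lm, "augment") <- obj$augment
  validate_landmarks(lm)
  lm
}
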