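#' Pixel-scale calibration
#'
#' A TEM image's physical calibration, expressed in microns per pixel. All
#' physical measurements in the package (areas in um^2, perimeters in um)
#' are pixel measurements multiplied by powers of this factor.
#'
#' @param microns_per_pixel Positive, finite scalar: physical side length of
#'   one pixel in microns.
#' @return An object of class `pixel_scale`.
#' @examples
#' pixel_scale(0.02)
#' @export
pixel_scale <- function(microns_per_pixel) {
  if (!is.numeric(microns_per_pixel) || length(microns_per_pixel) != 1L ||
      !is.finite(microns_per_pixel) || microns_per_pixel <= 0) {
    stop("`microns_per_pixel` must be a single finite value > 0", call. = FALSE)
  }
  structure(list(microns_per_pixel = as.numeric(microns_per_pixel)),
            class = "pixel_scale")
}

#' @export
print.pixel_scale <- function(x, ...) {
  cat(sprintf("<pixel_scale> %g um/px\n", x$microns_per_pixel))
  invisible(x)
}

.as_pixel_matrix <- function(pixels, what = "pixels") {
  if (is.null(pixels)) return(NULL)
  pixels <- as.matrix(pixels)
  if (ncol(pixels) != 2L) stop(what, " must be a 2-column (x, y) matrix", call. = FALSE)
  storage.mode(pixels) <- "integer"
  colnames(pixels) <- c("x", "y")
  pixels
}

# Frame-independent pixel key; coordinates are bounded well below 2^15 in
# practice (images up to 2048 px), so x + y * 2^16 is collision-free.
.pix_key <- function(pixels) {
  if (is.null(pixels) || nrow(pixels) == 0L) return(integer(0))
  pixels[, 1L] + pixels[, 2L] * 65536L
}

#' One annotated mitochondrion instance
#'
#' Holds the pixel support of a single mitochondrion in one TEM field,
#' optionally together with the polygon it was rasterized from, a prediction
#' confidence score, a cristae sub-mask, an outer-mitochondrial-membrane
#' (OMM) integrity flag and a human-assigned cristae-type label.
#'
#' Pixel coordinates are 1-based `(x, y)` pairs, origin at the top-left of
#' the image, y growing downwards. Polygons are in the COCO convention:
#' continuous coordinates with the origin at the top-left *corner* of the
#' image, so pixel `(x, y)` has its center at `(x - 0.5, y - 0.5)`.
#'
#' @param instance_id Integer id, unique within its image.
#' @param pixels Integer matrix with columns x, y (1-based). If `NULL`, a
#'   `polygon` and `frame` must be supplied and the mask is rasterized by
#'   center sampling.
#' @param polygon Optional k x 2 numeric matrix of polygon vertices (one
#'   simple ring).
#' @param score Optional prediction confidence in \[0, 1\]; ground-truth
#'   instances carry no score.
#' @param cristae_pixels Optional pixel matrix of the cristae sub-mask; must
#'   be a subset of `pixels`.
#' @param omm_intact Optional logical: OMM judged intact.
#' @param mrc_type Optional integer 1..3: human-assigned cristae type.
#' @param frame Optional `c(width, height)` used to rasterize `polygon` when
#'   `pixels` is absent.
#' @return An object of class `mito_instance`.
#' @export
mito_instance <- function(instance_id, pixels = NULL, polygon = NULL,
                          score = NULL, cristae_pixels = NULL,
                          omm_intact = NULL, mrc_type = NULL, frame = NULL) {
  instance_id <- as.integer(instance_id)
  if (length(instance_id) != 1L || is.na(instance_id)) {
    stop("`instance_id` must be a single integer", call. = FALSE)
  }
  if (!is.null(polygon)) {
    polygon <- as.matrix(polygon)
    if (ncol(polygon) != 2L || nrow(polygon) < 3L) {
      stop("`polygon` must be a k x 2 matrix with k >= 3", call. = FALSE)
    }
    storage.mode(polygon) <- "double"
  }
  if (is.null(pixels)) {
    if (is.null(polygon) || is.null(frame)) {
      stop("either `pixels`, or `polygon` plus `frame`, must be given", call. = FALSE)
    }
    pixels <- rasterize_polygon(polygon, frame[1L], frame[2L])
  }
  pixels <- .as_pixel_matrix(pixels)
  if (nrow(pixels) == 0L) {
    stop("instance ", instance_id, " has an empty mask", call. = FALSE)
  }
  if (!is.null(score)) {
    score <- as.numeric(score)
    if (length(score) != 1L || is.na(score) || score < 0 || score > 1) {
      stop("`score` must be a single value in [0, 1]", call. = FALSE)
    }
  }
  if (!is.null(cristae_pixels)) {
    cristae_pixels <- .as_pixel_matrix(cristae_pixels, "cristae_pixels")
    if (nrow(cristae_pixels) > 0L &&
        !all(.pix_key(cristae_pixels) %in% .pix_key(pixels))) {
      stop("cristae mask of instance ", instance_id,
           " is not contained in the mitochondrion mask", call. = FALSE)
    }
  }
  if (!is.null(omm_intact)) omm_intact <- isTRUE(as.logical(omm_intact))
  if (!is.null(mrc_type)) {
    mrc_type <- as.integer(mrc_type)
    if (!mrc_type %in% 1:3) stop("`mrc_type` must be 1, 2 or 3", call. = FALSE)
  }
  structure(list(instance_id = instance_id, pixels = pixels, polygon = polygon,
                 score = score, cristae_pixels = cristae_pixels,
                 omm_intact = omm_intact, mrc_type = mrc_type),
            class = "mito_instance")
}

#' @export
print.mito_instance <- function(x, ...) {
  cat(sprintf("<mito_instance %d> %d px%s%s\n", x$instance_id, nrow(x$pixels),
              if (!is.null(x$score)) sprintf(", score %.3f", x$score) else "",
              if (!is.null(x$cristae_pixels))
                sprintf(", %d cristae px", nrow(x$cristae_pixels)) else ""))
  invisible(x)
}

#' A cell region within a TEM field
#'
#' The outline of one tumor cell with an intact membrane; per-cell indices
#' (mitochondrial density, area ratio) are computed over this region.
#'
#' @param cell_id Integer id, unique within its image.
#' @param polygon Optional k x 2 vertex matrix of the membrane outline.
#' @param pixels Optional pixel support; rasterized from `polygon` when
#'   absent and `frame` is given.
#' @param frame Optional `c(width, height)` for rasterization.
#' @return An object of class `cell_region` with an `area_px` field.
#' @export
cell_region <- function(cell_id, polygon = NULL, pixels = NULL, frame = NULL) {
  cell_id <- as.integer(cell_id)
  if (!is.null(polygon)) {
    polygon <- as.matrix(polygon)
    storage.mode(polygon) <- "double"
    if (ncol(polygon) != 2L || nrow(polygon) < 3L) {
      stop("cell `polygon` must be a k x 2 matrix with k >= 3", call. = FALSE)
    }
  }
  if (is.null(pixels) && !is.null(polygon) && !is.null(frame)) {
    pixels <- rasterize_polygon(polygon, frame[1L], frame[2L])
  }
  if (is.null(pixels)) {
    if (is.null(polygon)) {
      stop("either `pixels`, or a `polygon`, must be given", call. = FALSE)
    }
    area_px <- poly_area(polygon)
  } else {
    pixels <- .as_pixel_matrix(pixels)
    if (nrow(pixels) == 0L) stop("cell ", cell_id, " has empty support", call. = FALSE)
    area_px <- nrow(pixels)
  }
  if (area_px <= 0) stop("cell ", cell_id, " has zero area", call. = FALSE)
  structure(list(cell_id = cell_id, polygon = polygon, pixels = pixels,
                 area_px = area_px),
            class = "cell_region")
}

#' One annotated TEM field
#'
#' Container for a single image's cell outlines and mitochondrion instances,
#' its pixel-scale calibration and its role (manual ground truth or model
#' prediction), plus an optional WHO grade (1--4) inherited by all its
#' instances.
#'
#' @param image_id Character id, unique within a dataset.
#' @param width,height Image size in pixels.
#' @param scale A [pixel_scale()].
#' @param cells List of [cell_region()] objects.
#' @param instances List of [mito_instance()] objects with unique ids.
#' @param role `"ground_truth"` or `"prediction"`.
#' @param grade Optional WHO grade, integer 1..4.
#' @return An object of class `annotated_image`.
#' @export
annotated_image <- function(image_id, width, height, scale,
                            cells = list(), instances = list(),
                            role = c("ground_truth", "prediction"),
                            grade = NULL) {
  role <- match.arg(role)
  image_id <- as.character(image_id)
  width <- as.integer(width); height <- as.integer(height)
  if (width <= 0L || height <= 0L) stop("image size must be positive", call. = FALSE)
  if (!inherits(scale, "pixel_scale")) stop("`scale` must be a pixel_scale", call. = FALSE)
  if (!is.null(grade)) {
    grade <- as.integer(grade)
    if (!grade %in% 1:4) stop("`grade` must be in 1..4", call. = FALSE)
  }
  ids <- vapply(instances, function(i) i$instance_id, integer(1))
  if (anyDuplicated(ids)) {
    stop("duplicate instance ids in image ", image_id, call. = FALSE)
  }
  for (inst in instances) {
    p <- inst$pixels
    if (nrow(p) && (min(p) < 1L || max(p[, 1L]) > width || max(p[, 2L]) > height)) {
      stop("instance ", inst$instance_id, " has pixels outside image ",
           image_id, " bounds", call. = FALSE)
    }
  }
  structure(list(image_id = image_id, width = width, height = height,
                 scale = scale, cells = cells, instances = instances,
                 role = role, grade = grade),
            class = "annotated_image")
}

#' @export
print.annotated_image <- function(x, ...) {
  cat(sprintf("<annotated_image '%s'> %dx%d px, %s, %d cell(s), %d instance(s)%s\n",
              x$image_id, x$width, x$height, x$role, length(x$cells),
              length(x$instances),
              if (!is.null(x$grade)) sprintf(", grade %d", x$grade) else ""))
  invisible(x)
}
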