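# Annotation I/O: label images (TIFF/PNG) and a COCO-instance JSON dialect.

.label_matrix_from_file <- function(path) {
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("tif", "tiff")) {
    read_tiff_gray(path)
  } else if (ext == "png") {
    img <- png::readPNG(path)
    if (length(dim(img)) == 3L) {
      if (dim(img)[3L] > 1L && !all(img[, , 1L] == img[, , -1L])) {
        stop("PNG label image must be single-channel: ", path, call. = FALSE)
      }
      img <- img[, , 1L]
    }
    # png scales to [0,1]; recover integer labels at the stored bit depth
    for (denom in c(255, 65535)) {
      v <- img * denom
      if (max(abs(v - round(v))) < 1e-6) return(matrix(as.integer(round(v)),
                                                       nrow(img), ncol(img)))
    }
    stop("PNG does not contain integer labels: ", path, call. = FALSE)
  } else {
    stop("unsupported label-image format '", ext, "' (use TIFF or PNG)", call. = FALSE)
  }
}

#' Read a label image as an annotated TEM field
#'
#' Loads a single-channel integer label image (uncompressed TIFF or PNG;
#' 0 = background) and turns every nonzero label into one mitochondrion
#' instance. Labels cannot overlap by construction, so this path is the
#' natural carrier for manual ground truth; an all-zero image yields a valid
#' image with zero instances.
#'
#' @param path Path to the label image.
#' @param scale A [pixel_scale()].
#' @param role `"ground_truth"` (default) or `"prediction"`.
#' @param image_id Image identifier; defaults to the file name without
#'   extension.
#' @param grade Optional WHO grade 1..4.
#' @return An [annotated_image()] without cell outlines.
#' @seealso [write_label_mask()], [load_coco_annotations()]
#' @export
load_label_mask <- function(path, scale, role = c("ground_truth", "prediction"),
                            image_id = NULL, grade = NULL) {
  role <- match.arg(role)
  m <- .label_matrix_from_file(path)
  if (is.null(image_id)) image_id <- tools::file_path_sans_ext(basename(path))
  labels <- sort(unique(m[m != 0L]))
  instances <- lapply(labels, function(lb) {
    mito_instance(lb, pixels = mask_to_pixels(m == lb))
  })
  annotated_image(image_id, width = ncol(m), height = nrow(m), scale = scale,
                  instances = instances, role = role, grade = grade)
}

#' Write an annotated image (or label matrix) as a label TIFF
#'
#' Instances are burned into a uint16 label image using their instance ids.
#' Overlapping instances cannot be represented in a label image and raise an
#' error; use the COCO JSON writer for overlapping predictions.
#'
#' @param x An [annotated_image()] or an integer label matrix.
#' @param path Output path (`.tif`).
#' @return The path, invisibly.
#' @export
write_label_mask <- function(x, path) {
  if (inherits(x, "annotated_image")) {
    m <- matrix(0L, nrow = x$height, ncol = x$width)
    for (inst in x$instances) {
      idx <- cbind(inst$pixels[, 2L], inst$pixels[, 1L])
      if (any(m[idx] != 0L)) {
        stop("overlapping instances cannot be written as a label image ",
             "(image ", x$image_id, ")", call. = FALSE)
      }
      m[idx] <- inst$instance_id
    }
  } else {
    m <- x
  }
  write_tiff_gray(m, path)
}

# --- COCO-style JSON ---------------------------------------------------------

# Dialect: top level {images, annotations, categories}. Category 1 =
# mitochondrion, category 2 = cell outline. "segmentation" is either a list
# of flat polygon rings [x0,y0,x1,y1,...] or an uncompressed RLE object
# {"counts": [...], "size": [h, w]} (column-major, starting with background,
# as in the COCO API). Optional extension fields: per-image
# "microns_per_pixel" and "grade"; per-annotation "score", "omm_intact",
# "mrc_type" and "cristae_segmentation" (an RLE).

.rle_decode <- function(rle) {
  counts <- as.numeric(unlist(rle$counts))
  h <- as.integer(rle$size[[1L]]); w <- as.integer(rle$size[[2L]])
  v <- rep(rep(c(0L, 1L), length.out = length(counts)), counts)
  if (length(v) != h * w) stop("RLE length does not match its size field", call. = FALSE)
  m <- matrix(v, nrow = h, ncol = w)  # column-major fill == COCO order
  mask_to_pixels(m)
}

.rle_encode <- function(pixels, width, height) {
  m <- matrix(0L, nrow = height, ncol = width)
  m[cbind(pixels[, 2L], pixels[, 1L])] <- 1L
  v <- as.vector(m)                   # column-major == COCO order
  r <- rle(v)
  counts <- r$lengths
  if (r$values[1L] == 1L) counts <- c(0L, counts)
  list(counts = as.integer(counts), size = c(height, width))
}

.seg_to_pixels <- function(seg, width, height, what) {
  if (!is.null(seg$counts)) return(list(pixels = .rle_decode(seg), polygon = NULL))
  rings <- seg
  pixels <- NULL; polygon <- NULL
  for (ring in rings) {
    ring <- as.numeric(unlist(ring))
    if (length(ring) < 6L) {
      warning(what, ": degenerate polygon (<3 vertices) skipped", call. = FALSE)
      next
    }
    poly <- matrix(ring, ncol = 2L, byrow = TRUE)
    if (is.null(polygon)) polygon <- poly  # first ring kept as the outline
    pixels <- rbind(pixels, rasterize_polygon(poly, width, height))
  }
  if (!is.null(pixels)) pixels <- unique(pixels)
  list(pixels = pixels, polygon = polygon)
}

#' Load COCO-style instance annotations
#'
#' Parses the package's COCO dialect (see Details) into a list of
#' [annotated_image()] objects. Polygons are rasterized by pixel-center
#' sampling at the image resolution; uncompressed RLE is decoded exactly.
#' Annotations carrying `"score"` are predictions in spirit, but the role of
#' the whole file is set explicitly or inferred: if any annotation has a
#' score the default role is `"prediction"`, otherwise `"ground_truth"`.
#'
#' @details
#' Expected structure: `images` (id, width, height, optionally
#' `microns_per_pixel` and `grade`), `annotations` (id, image_id,
#' category_id 1 = mitochondrion / 2 = cell, `segmentation`, optional
#' `score`, `omm_intact`, `mrc_type`, `cristae_segmentation`), `categories`.
#' An annotation referencing an unknown image id is a structural error;
#' degenerate polygons (< 3 vertices) are skipped with a warning.
#'
#' @param path Path to the JSON file.
#' @param scale Optional [pixel_scale()]; overrides per-image
#'   `microns_per_pixel` fields and is required when those are absent.
#' @param role Optional role override (`"ground_truth"` / `"prediction"`).
#' @return List of [annotated_image()], in file order of `images`.
#' @export
load_coco_annotations <- function(path, scale = NULL, role = NULL) {
  doc <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  if (is.null(doc$images)) stop("COCO file has no `images` list: ", path, call. = FALSE)
  anns <- doc$annotations %||% list()
  has_score <- any(vapply(anns, function(a) !is.null(a$score), logical(1)))
  if (is.null(role)) role <- if (has_score) "prediction" else "ground_truth"
  img_ids <- vapply(doc$images, function(im) as.character(im$id), character(1))
  by_image <- split(anns, vapply(anns, function(a) as.character(a$image_id),
                                 character(1)))
  unknown <- setdiff(names(by_image), img_ids)
  if (length(unknown)) {
    stop("annotations reference unknown image id(s): ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  lapply(doc$images, function(im) {
    w <- as.integer(im$width); h <- as.integer(im$height)
    sc <- if (!is.null(scale)) scale else if (!is.null(im$microns_per_pixel)) {
      pixel_scale(im$microns_per_pixel)
    } else stop("no pixel scale for image ", im$id,
                " (supply `scale` or a per-image microns_per_pixel)", call. = FALSE)
    cells <- list(); instances <- list()
    for (a in by_image[[as.character(im$id)]] %||% list()) {
      cat_id <- as.integer(a$category_id %||% 1L)
      dec <- .seg_to_pixels(a$segmentation, w, h,
                            paste0("annotation ", a$id))
      if (is.null(dec$pixels) || nrow(dec$pixels) == 0L) next
      if (cat_id == 2L) {
        cells[[length(cells) + 1L]] <-
          cell_region(a$id, polygon = dec$polygon, pixels = dec$pixels)
      } else {
        cr <- if (!is.null(a$cristae_segmentation)) {
          .rle_decode(a$cristae_segmentation)
        }
        instances[[length(instances) + 1L]] <- mito_instance(
          a$id, pixels = dec$pixels, polygon = dec$polygon,
          score = a$score, cristae_pixels = cr,
          omm_intact = a$omm_intact, mrc_type = a$mrc_type)
      }
    }
    annotated_image(as.character(im$id), w, h, sc, cells = cells,
                    instances = instances, role = role,
                    grade = if (!is.null(im$grade)) as.integer(im$grade))
  })
}

#' Write annotated images as COCO-style JSON
#'
#' Inverse of [load_coco_annotations()]: polygons are written when an
#' instance carries one (rasterization on re-read reproduces the pixel set
#' exactly, since both sides use center sampling); instances without a
#' polygon are written as uncompressed RLE. Output is deterministic for a
#' given input, byte for byte.
#'
#' @param images List of [annotated_image()] (or a single one).
#' @param path Output JSON path.
#' @return The path, invisibly.
#' @export
write_coco_annotations <- function(images, path) {
  if (inherits(images, "annotated_image")) images <- list(images)
  imgs <- list(); anns <- list(); next_id <- 1L
  for (img in images) {
    rec <- list(id = img$image_id, width = img$width, height = img$height,
                microns_per_pixel = img$scale$microns_per_pixel)
    if (!is.null(img$grade)) rec$grade <- img$grade
    imgs[[length(imgs) + 1L]] <- rec
    for (cl in img$cells) {
      seg <- if (!is.null(cl$polygon)) {
        list(as.vector(t(cl$polygon)))
      } else .rle_encode(cl$pixels, img$width, img$height)
      anns[[length(anns) + 1L]] <- list(
        id = cl$cell_id, image_id = img$image_id, category_id = 2L,
        segmentation = seg, area = cl$area_px)
      next_id <- next_id + 1L
    }
    for (inst in img$instances) {
      seg <- if (!is.null(inst$polygon)) {
        list(as.vector(t(inst$polygon)))
      } else .rle_encode(inst$pixels, img$width, img$height)
      a <- list(id = inst$instance_id, image_id = img$image_id,
                category_id = 1L, segmentation = seg,
                area = nrow(inst$pixels))
      if (!is.null(inst$score)) a$score <- inst$score
      if (!is.null(inst$omm_intact)) a$omm_intact <- inst$omm_intact
      if (!is.null(inst$mrc_type)) a$mrc_type <- inst$mrc_type
      if (!is.null(inst$cristae_pixels)) {
        a$cristae_segmentation <- .rle_encode(inst$cristae_pixels,
                                              img$width, img$height)
      }
      anns[[length(anns) + 1L]] <- a
    }
  }
  doc <- list(images = imgs, annotations = anns,
              categories = list(list(id = 1L, name = "mitochondrion"),
                                list(id = 2L, name = "cell")))
  json <- jsonlite::toJSON(doc, auto_unbox = TRUE, digits = NA)
  writeLines(json, path, useBytes = TRUE)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write per-mitochondrion measurement records to CSV
#'
#' One row per mitochondrion; UTF-8, `.` decimal separator, full double
#' precision so a write/read round trip is lossless to well below 1e-9.
#'
#' @param records Data frame of morphometry records (see [measure_dataset()]).
#' @param path Output CSV path.
#' @return The path, invisibly.
#' @export
write_measurements_csv <- function(records, path) {
  stopifnot(is.data.frame(records))
  old <- options(digits = 15); on.exit(options(old))
  write.csv(records, path, row.names = FALSE, fileEncoding = "UTF-8", na = "")
  invisible(path)
}

#' Read a measurements CSV written by [write_measurements_csv()]
#' @param path CSV path.
#' @return Data frame of records.
#' @export
read_measurements_csv <- function(path) {
  read.csv(path, stringsAsFactors = FALSE, fileEncoding = "UTF-8")
}
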