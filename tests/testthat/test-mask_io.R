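test_that("label-mask round trip preserves the per-label pixel multiset", {
  set.seed(11)
  m <- matrix(0L, 32, 48)
  m[3:8, 4:10] <- 1L
  m[15:25, 20:30] <- 2L
  m[28:30, 40:44] <- 7L          # labels need not be consecutive
  f <- withr::local_tempfile(fileext = ".tif")
  write_label_mask(m, f)
  img <- load_label_mask(f, pixel_scale(0.02))
  expect_s3_class(img, "annotated_image")
  expect_equal(img$width, 48)
  expect_equal(img$height, 32)
  counts <- vapply(img$instances, function(i) nrow(i$pixels), integer(1))
  ids <- vapply(img$instances, function(i) i$instance_id, integer(1))
  expect_equal(sort(ids), c(1L, 2L, 7L))
  expect_equal(counts[order(ids)],
               unname(c(table(m[m != 0L])[c("1", "2", "7")])))
  # full round trip through an annotated_image is pixel-exact
  f2 <- withr::local_tempfile(fileext = ".tif")
  write_label_mask(img, f2)
  expect_identical(read_tiff_gray(f2), m)
})

test_that("label loading handles empty images and rejects bad input", {
  f <- withr::local_tempfile(fileext = ".tif")
  write_label_mask(matrix(0L, 8, 8), f)
  img <- load_label_mask(f, pixel_scale(0.01))
  expect_length(img$instances, 0)
  expect_error(write_label_mask(matrix(-1L, 2, 2), f), "label values")
  expect_error(load_label_mask("nope.xyz", pixel_scale(1)), "format")
  # overlap cannot be represented as labels
  ov <- annotated_image("x", 8, 8, pixel_scale(1), instances = list(
    mito_instance(1, pixels = px_rect(1, 1, 3, 3)),
    mito_instance(2, pixels = px_rect(2, 2, 3, 3))), role = "prediction")
  expect_error(write_label_mask(ov, f), "overlap")
})

test_that("8-bit PNG label images load", {
  f <- withr::local_tempfile(fileext = ".png")
  m <- matrix(0L, 10, 10); m[2:4, 2:4] <- 3L
  png::writePNG(m / 255, f)
  img <- load_label_mask(f, pixel_scale(0.02))
  expect_length(img$instances, 1)
  expect_equal(img$instances[[1]]$instance_id, 3L)
  expect_equal(nrow(img$instances[[1]]$pixels), 9)
})

test_that("COCO polygons rasterize by pixel-center sampling", {
  # 10x10 square with corners on pixel boundaries -> exactly 100 pixels
  doc <- list(
    images = list(list(id = "a", width = 20, height = 20,
                       microns_per_pixel = 0.05)),
    annotations = list(
      list(id = 1, image_id = "a", category_id = 1,
           segmentation = list(c(0, 0, 10, 0, 10, 10, 0, 10))),
      list(id = 2, image_id = "a", category_id = 1,
           segmentation = list(c(12, 12, 19, 12, 19, 18, 12, 18)),
           score = 0.9)),
    categories = list(list(id = 1, name = "mitochondrion")))
  f <- withr::local_tempfile(fileext = ".json")
  jsonlite::write_json(doc, f, auto_unbox = TRUE)
  imgs <- load_coco_annotations(f)
  expect_length(imgs, 1)
  inst <- imgs[[1]]$instances
  expect_equal(nrow(inst[[1]]$pixels), 100)
  # agreement with an independent brute-force rasterizer
  sq <- matrix(c(0, 0, 10, 0, 10, 10, 0, 10), ncol = 2, byrow = TRUE)
  expect_setequal(paste(inst[[1]]$pixels[, 1], inst[[1]]$pixels[, 2]),
                  paste(oracle_rasterize(sq, 20, 20)[, 1],
                        oracle_rasterize(sq, 20, 20)[, 2]))
  # score passthrough and role inference
  expect_equal(inst[[2]]$score, 0.9)
  expect_equal(imgs[[1]]$role, "prediction")
})

test_that("COCO loading flags structural errors and degenerate polygons", {
  doc <- list(images = list(list(id = "a", width = 8, height = 8,
                                 microns_per_pixel = 1)),
              annotations = list(list(id = 1, image_id = "ghost",
                                      category_id = 1,
                                      segmentation = list(c(0, 0, 4, 0, 4, 4)))),
              categories = list())
  f <- withr::local_tempfile(fileext = ".json")
  jsonlite::write_json(doc, f, auto_unbox = TRUE)
  expect_error(load_coco_annotations(f), "unknown image")
  doc$annotations[[1]]$image_id <- "a"
  doc$annotations[[1]]$segmentation <- list(c(0, 0, 4, 0))  # 2 vertices
  jsonlite::write_json(doc, f, auto_unbox = TRUE)
  expect_warning(imgs <- load_coco_annotations(f), "degenerate")
  expect_length(imgs[[1]]$instances, 0)
  # empty annotation list is a valid image with zero instances
  doc$annotations <- list()
  jsonlite::write_json(doc, f, auto_unbox = TRUE)
  expect_length(load_coco_annotations(f)[[1]]$instances, 0)
})

test_that("COCO write/read round trip is lossless and order-independent", {
  gt <- small_gt()[[1]]
  f <- withr::local_tempfile(fileext = ".json")
  write_coco_annotations(gt, f)
  back <- load_coco_annotations(f)[[1]]
  expect_equal(length(back$instances), length(gt$instances))
  expect_equal(back$grade, gt$grade)
  for (k in seq_along(gt$instances)) {
    a <- gt$instances[[k]]; b <- back$instances[[k]]
    expect_setequal(paste(a$pixels[, 1], a$pixels[, 2]),
                    paste(b$pixels[, 1], b$pixels[, 2]))
    expect_equal(nrow(a$cristae_pixels), nrow(b$cristae_pixels))
    expect_equal(a$omm_intact, b$omm_intact)
  }
  # permuting annotation order yields the same image up to instance order
  doc <- jsonlite::fromJSON(f, simplifyVector = FALSE)
  set.seed(5)
  doc$annotations <- doc$annotations[sample(length(doc$annotations))]
  f2 <- withr::local_tempfile(fileext = ".json")
  writeLines(jsonlite::toJSON(doc, auto_unbox = TRUE, digits = NA), f2)
  perm <- load_coco_annotations(f2)[[1]]
  ids <- function(im) sort(vapply(im$instances, `[[`, integer(1), "instance_id"))
  expect_equal(ids(perm), ids(back))
  npx <- function(im) {
    v <- vapply(im$instances, function(i) nrow(i$pixels), integer(1))
    v[order(vapply(im$instances, `[[`, integer(1), "instance_id"))]
  }
  expect_equal(npx(perm), npx(back))
})

test_that("rasterized polygon area approaches analytic area", {
  # relative error < 2% for squares of side >= 50 px, anywhere in the frame
  set.seed(7)
  for (side in c(50, 80, 120)) {
    off <- runif(2, 0.1, 0.9)
    poly <- square_poly(off[1], off[2], side)
    px <- rasterize_polygon(poly, side + 2, side + 2)
    expect_lt(abs(nrow(px) - side^2) / side^2, 0.02)
  }
})

test_that("measurements CSV round trips", {
  res <- measure_dataset(small_gt()[1:2])
  f <- withr::local_tempfile(fileext = ".csv")
  write_measurements_csv(res$records, f)
  back <- read_measurements_csv(f)
  expect_equal(nrow(back), nrow(res$records))
  for (col in c("area_um2", "perimeter_um", "circularity", "cristae_occupancy")) {
    expect_equal(back[[col]], res$records[[col]], tolerance = 1e-9)
  }
  # empty records -> header only
  f2 <- withr::local_tempfile(fileext = ".csv")
  write_measurements_csv(res$records[0, ], f2)
  expect_length(readLines(f2), 1)
  # 3 records -> 4 lines
  write_measurements_csv(res$records[1:3, ], f2)
  expect_length(readLines(f2), 4)
})
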