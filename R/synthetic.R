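# Synthetic TEM annotation generator.
#
# Generates ground-truth annotated images whose mitochondrial populations
# follow per-grade profiles (count, lognormal area, beta-like circularity,
# cristae type mixture), plus perturbed "prediction" sets with controllable
# drop/spurious rates, target IoU, perimeter and area biases and score
# draws. Shapes are ellipses with low-order radial Fourier wobble, sampled
# as 72-gon polygons and rasterized by the package's center-sampling
# convention, so they span the circularity range of real sections without
# self-intersection. Everything is a pure function of (spec, seed).

# ellipse circularity 4*pi*A/P^2 via Ramanujan's perimeter approximation
.ellipse_circ <- function(k) {
  a <- 1; b <- k
  p <- pi * (3 * (a + b) - sqrt((3 * a + b) * (a + 3 * b)))
  4 * pi * (pi * a * b) / p^2
}

.aspect_for_circ <- function(circ) {
  if (circ >= 1) return(1)
  uniroot(function(k) .ellipse_circ(k) - circ, c(0.01, 1),
          tol = 1e-6)$root
}

# Star-shaped blob polygon around (cx, cy) with target pixel area and
# circularity; `wobble` adds organic low-order radial noise.
.blob_polygon <- function(cx, cy, area_px, circ, rotation = runif(1, 0, pi),
                          wobble = 0.03, n_vert = 72L) {
  k <- .aspect_for_circ(min(circ, 0.995))
  a <- sqrt(area_px / (pi * k)); b <- k * a
  theta <- seq(0, 2 * pi, length.out = n_vert + 1L)[-(n_vert + 1L)]
  t0 <- theta - rotation
  r <- a * b / sqrt((b * cos(t0))^2 + (a * sin(t0))^2)
  if (wobble > 0) {
    for (m in 3:6) {
      amp <- rnorm(1, 0, wobble / (m - 2))
      r <- r * (1 + amp * cos(m * theta + runif(1, 0, 2 * pi)))
    }
  }
  r <- pmax(r, 0.8)
  cbind(cx + r * cos(theta), cy + r * sin(theta))
}

# Interior stripe pattern with a controlled pixel fraction: threshold a
# sinusoidal field over the instance pixels at the (1 - occupancy) sample
# quantile, so the realized fraction tracks the request to within a pixel.
.cristae_pixels <- function(pixels, occupancy) {
  if (occupancy <= 0) {
    return(matrix(integer(0), 0L, 2L, dimnames = list(NULL, c("x", "y"))))
  }
  if (occupancy >= 1) return(pixels)
  alpha <- runif(1, 0, pi)
  lambda <- runif(1, 3, 5)
  v <- sin(2 * pi * (pixels[, 1L] * cos(alpha) + pixels[, 2L] * sin(alpha)) /
             lambda) + 1e-9 * pixels[, 1L]  # tie-break deterministically
  q <- quantile(v, 1 - occupancy, names = FALSE, type = 7)
  pixels[v >= q, , drop = FALSE]
}

# Type-conditional cristae/OMM tables for the type-driven sampling mode:
# healthy Type 1 has dense cristae and an almost always intact OMM, Type 3
# nearly vanished cristae and a mostly ruptured OMM.
.TYPE_OCC_SHAPE1 <- c(12, 5, 0.8)
.TYPE_OCC_SHAPE2 <- c(6, 9, 14)
.TYPE_P_OMM <- c(0.97, 0.60, 0.12)

#' Grade profile for the synthetic generator
#'
#' Distribution parameters of the mitochondrial population of one WHO
#' grade. Counts per cell are negative binomial (`mito_count_mean`,
#' dispersion `mito_count_size`; larger size = closer to Poisson), areas
#' lognormal (`area_um2_median`, log-sd `area_um2_sigma`), circularities
#' beta-distributed on (0, 1\] with mean `circularity_mean` and
#' concentration `circularity_conc`. Cristae state is drawn either
#' type-first (`type_mixture` over Types 1--3, then type-conditional
#' occupancy/OMM tables) or, when `type_mixture` is `NULL`,
#' occupancy-first from a beta with mean `cristae_occupancy_mean` and the
#' OMM flag as Bernoulli(`p_omm_intact`).
#'
#' @param grade WHO grade 1..4.
#' @param mito_count_mean,mito_count_size Negative-binomial count
#'   parameters.
#' @param area_um2_median,area_um2_sigma Lognormal area parameters (um^2).
#' @param circularity_mean,circularity_conc Beta circularity parameters.
#' @param cristae_occupancy_mean,cristae_occupancy_conc Beta occupancy
#'   parameters (occupancy-first mode).
#' @param p_omm_intact OMM-intact probability (occupancy-first mode).
#' @param type_mixture Probabilities of Types 1..3 summing to 1, or `NULL`
#'   for occupancy-first sampling.
#' @return An object of class `grade_profile`.
#' @export
grade_profile <- function(grade, mito_count_mean, mito_count_size = 20,
                          area_um2_median, area_um2_sigma = 0.45,
                          circularity_mean, circularity_conc = 25,
                          cristae_occupancy_mean = 0.4,
                          cristae_occupancy_conc = 10,
                          p_omm_intact = 0.6, type_mixture = NULL) {
  stopifnot(grade %in% 1:4, mito_count_mean > 0, mito_count_size > 0,
            area_um2_median > 0, area_um2_sigma > 0,
            circularity_mean > 0, circularity_mean <= 1,
            cristae_occupancy_mean >= 0, cristae_occupancy_mean <= 1,
            p_omm_intact >= 0, p_omm_intact <= 1)
  if (!is.null(type_mixture)) {
    stopifnot(length(type_mixture) == 3L, all(type_mixture >= 0),
              abs(sum(type_mixture) - 1) < 1e-8)
  }
  structure(list(grade = as.integer(grade),
                 mito_count_mean = mito_count_mean,
                 mito_count_size = mito_count_size,
                 area_um2_median = area_um2_median,
                 area_um2_sigma = area_um2_sigma,
                 circularity_mean = circularity_mean,
                 circularity_conc = circularity_conc,
                 cristae_occupancy_mean = cristae_occupancy_mean,
                 cristae_occupancy_conc = cristae_occupancy_conc,
                 p_omm_intact = p_omm_intact,
                 type_mixture = type_mixture),
            class = "grade_profile")
}

#' Default per-grade profiles
#'
#' Invented magnitudes encoding only the qualitative low- versus high-grade
#' contrasts seen in TEM morphometry of glioma: towards high grade,
#' mitochondria are smaller, denser per cell, rounder, and richer in
#' healthy Type-1 cristae. These are placeholders for pipeline testing, not
#' estimates of any clinical distribution.
#'
#' @return Named list (grades `"1"`..`"4"`) of [grade_profile()] objects.
#' @export
default_grade_profiles <- function() {
  list(
    "1" = grade_profile(1, mito_count_mean = 8,  area_um2_median = 0.40,
                        circularity_mean = 0.62, p_omm_intact = 0.55,
                        type_mixture = c(0.20, 0.40, 0.40)),
    "2" = grade_profile(2, mito_count_mean = 10, area_um2_median = 0.35,
                        circularity_mean = 0.68, p_omm_intact = 0.60,
                        type_mixture = c(0.25, 0.40, 0.35)),
    "3" = grade_profile(3, mito_count_mean = 15, area_um2_median = 0.25,
                        circularity_mean = 0.78, p_omm_intact = 0.72,
                        type_mixture = c(0.45, 0.33, 0.22)),
    "4" = grade_profile(4, mito_count_mean = 18, area_um2_median = 0.20,
                        circularity_mean = 0.84, p_omm_intact = 0.78,
                        type_mixture = c(0.55, 0.27, 0.18)))
}

#' Specification of a synthetic dataset
#'
#' @param n_images Number of images (>= 1).
#' @param cells_per_image Cells per image.
#' @param image_size_px Square image side in pixels.
#' @param scale A [pixel_scale()]; default 0.02 um/px.
#' @param profiles Map grade -> [grade_profile()]; default
#'   [default_grade_profiles()].
#' @param grades Optional integer vector (length `n_images`) fixing each
#'   image's grade; by default the profile grades are cycled.
#' @param seed Integer RNG seed; the whole dataset is a pure function of
#'   (spec, seed).
#' @return An object of class `synthetic_dataset_spec`.
#' @export
synthetic_dataset_spec <- function(n_images = 8L, cells_per_image = 1L,
                                   image_size_px = 512L,
                                   scale = pixel_scale(0.02),
                                   profiles = default_grade_profiles(),
                                   grades = NULL, seed = 1L) {
  stopifnot(n_images >= 1L, cells_per_image >= 1L, image_size_px >= 64L,
            inherits(scale, "pixel_scale"), length(profiles) >= 1L)
  prof_grades <- vapply(profiles, function(p) p$grade, integer(1))
  if (is.null(grades)) {
    grades <- rep_len(prof_grades, n_images)
  } else {
    stopifnot(length(grades) == n_images, all(grades %in% prof_grades))
  }
  structure(list(n_images = as.integer(n_images),
                 cells_per_image = as.integer(cells_per_image),
                 image_size_px = as.integer(image_size_px), scale = scale,
                 profiles = profiles, grades = as.integer(grades),
                 seed = as.integer(seed)),
            class = "synthetic_dataset_spec")
}

.draw_instance_state <- function(profile) {
  if (!is.null(profile$type_mixture)) {
    type <- sample.int(3L, 1L, prob = profile$type_mixture)
    occ <- rbeta(1, .TYPE_OCC_SHAPE1[type], .TYPE_OCC_SHAPE2[type])
    omm <- runif(1) < .TYPE_P_OMM[type]
    list(mrc_type = type, occupancy = occ, omm_intact = omm)
  } else {
    mu <- profile$cristae_occupancy_mean; cc <- profile$cristae_occupancy_conc
    occ <- if (mu <= 0) 0 else if (mu >= 1) 1 else
      rbeta(1, mu * cc, (1 - mu) * cc)
    list(mrc_type = NULL, occupancy = occ,
         omm_intact = runif(1) < profile$p_omm_intact)
  }
}

#' Generate ground-truth annotated images
#'
#' Places `cells_per_image` wobbly elliptical cells per image and packs
#' each with a grade-profiled population of non-overlapping mitochondrion
#' blobs, each carrying a cristae sub-mask at its drawn occupancy, an OMM
#' flag and (in type-driven mode) its cristae-type label. Identical
#' (spec, seed) inputs produce identical output, down to the bytes of the
#' written annotation JSON.
#'
#' @param spec A [synthetic_dataset_spec()].
#' @param max_tries Placement attempts per mitochondrion before the packing
#'   is declared infeasible.
#' @return List of ground-truth [annotated_image()] objects.
#' @export
generate_ground_truth <- function(spec, max_tries = 250L) {
  stopifnot(inherits(spec, "synthetic_dataset_spec"))
  set.seed(spec$seed)
  subseeds <- sample.int(2147483646L, spec$n_images)
  prof_by_grade <- stats::setNames(
    spec$profiles, vapply(spec$profiles, function(p) p$grade, integer(1)))
  lapply(seq_len(spec$n_images), function(i) {
    set.seed(subseeds[i])
    side <- spec$image_size_px
    grade <- spec$grades[i]
    profile <- prof_by_grade[[as.character(grade)]]
    s <- spec$scale$microns_per_pixel
    ncell <- spec$cells_per_image
    gr <- ceiling(sqrt(ncell)); gc <- ceiling(ncell / gr)
    sw <- side / gc; sh <- side / gr
    cells <- list(); instances <- list(); occupied <- integer(0)
    inst_id <- 0L
    for (ci in seq_len(ncell)) {
      row <- (ci - 1L) %/% gc; col <- (ci - 1L) %% gc
      cx <- (col + 0.5) * sw + runif(1, -0.03, 0.03) * sw
      cy <- (row + 0.5) * sh + runif(1, -0.03, 0.03) * sh
      rx <- 0.41 * sw * runif(1, 0.88, 1); ry <- 0.41 * sh * runif(1, 0.88, 1)
      cell_poly <- .blob_polygon(cx, cy, pi * rx * ry,
                                 .ellipse_circ(min(ry, rx) / max(rx, ry)),
                                 wobble = 0.015, n_vert = 96L)
      cell <- cell_region(ci, polygon = cell_poly, frame = c(side, side))
      cells[[length(cells) + 1L]] <- cell
      n_mito <- rnbinom(1, mu = profile$mito_count_mean,
                        size = profile$mito_count_size)
      for (mi in seq_len(n_mito)) {
        area_um2 <- rlnorm(1, log(profile$area_um2_median),
                           profile$area_um2_sigma)
        area_px <- area_um2 / s^2
        circ <- rbeta(1, profile$circularity_mean * profile$circularity_conc,
                      (1 - profile$circularity_mean) * profile$circularity_conc)
        circ <- min(max(circ, 0.15), 0.995)
        placed <- FALSE
        for (try in seq_len(max_tries)) {
          ctr <- cell$pixels[sample.int(nrow(cell$pixels), 1L), ]
          poly <- .blob_polygon(ctr[1L] - 0.5, ctr[2L] - 0.5, area_px, circ)
          if (!all(point_in_polygon(poly[, 1L], poly[, 2L], cell_poly))) next
          px <- rasterize_polygon(poly, side, side)
          if (nrow(px) == 0L) next
          keys <- .pix_key(px)
          if (any(keys %in% occupied)) next
          st <- .draw_instance_state(profile)
          inst_id <- inst_id + 1L
          instances[[length(instances) + 1L]] <- mito_instance(
            inst_id, pixels = px, polygon = poly,
            cristae_pixels = .cristae_pixels(px, st$occupancy),
            omm_intact = st$omm_intact, mrc_type = st$mrc_type)
          occupied <- c(occupied, keys)
          placed <- TRUE
          break
        }
        if (!placed) {
          stop("packing failed: cannot place mitochondrion ", mi,
               " of cell ", ci, " in image img", i,
               " without overlap after ", max_tries, " tries", call. = FALSE)
        }
      }
    }
    annotated_image(sprintf("img%03d", i), side, side, spec$scale,
                    cells = cells, instances = instances,
                    role = "ground_truth", grade = grade)
  })
}

#' Perturbation configuration for synthetic predictions
#'
#' @param drop_rate Probability that a ground-truth instance has no
#'   corresponding prediction (creates false negatives).
#' @param spurious_rate Expected number of spurious predictions per image
#'   (creates false positives; placed with IoU < 0.5 against every ground
#'   truth by construction).
#' @param jitter_iou_target Expected IoU of surviving predictions against
#'   their ground truth; 1 = no positional jitter.
#' @param perimeter_bias,area_bias Signed relative biases applied to each
#'   surviving prediction's perimeter/area (e.g. `+0.10` inflates
#'   perimeters by 10 percent).
#' @param score_distribution Either a scalar score given to every
#'   prediction or a `function(n)` drawing scores in \[0, 1\]; the default
#'   Beta(8, 2) concentrates around 0.8.
#' @param seed Integer RNG seed.
#' @return An object of class `perturbation_config`.
#' @export
perturbation_config <- function(drop_rate = 0, spurious_rate = 0,
                                jitter_iou_target = 1, perimeter_bias = 0,
                                area_bias = 0,
                                score_distribution = function(n) rbeta(n, 8, 2),
                                seed = 1L) {
  stopifnot(drop_rate >= 0, drop_rate <= 1, spurious_rate >= 0,
            jitter_iou_target > 0, jitter_iou_target <= 1,
            area_bias > -1, perimeter_bias > -1)
  structure(list(drop_rate = drop_rate, spurious_rate = spurious_rate,
                 jitter_iou_target = jitter_iou_target,
                 perimeter_bias = perimeter_bias, area_bias = area_bias,
                 score_distribution = score_distribution,
                 seed = as.integer(seed)),
            class = "perturbation_config")
}

.draw_score <- function(cfg, n = 1L) {
  sd_ <- cfg$score_distribution
  v <- if (is.function(sd_)) sd_(n) else rep(sd_, n)
  pmin(pmax(v, 0), 1)
}

# Adjust a star-shaped polygon's perimeter towards `target`: high-frequency
# radial ripple to lengthen, radial moving-average smoothing to shorten.
.tune_perimeter <- function(poly, target) {
  cur <- poly_perimeter(poly)
  if (abs(cur / target - 1) < 2e-3) return(poly)
  ctr <- colMeans(poly)
  dx <- poly[, 1L] - ctr[1L]; dy <- poly[, 2L] - ctr[2L]
  theta <- atan2(dy, dx); r <- sqrt(dx^2 + dy^2)
  rebuild <- function(rr) cbind(ctr[1L] + rr * cos(theta),
                                ctr[2L] + rr * sin(theta))
  if (cur < target) {
    psi <- runif(1, 0, 2 * pi)
    perim_at <- function(a) poly_perimeter(rebuild(r * (1 + a * cos(16 * theta + psi))))
    hi <- 0.8
    if (perim_at(hi) < target) {
      warning("perimeter bias beyond ripple range; using maximum", call. = FALSE)
      return(rebuild(r * (1 + hi * cos(16 * theta + psi))))
    }
    a <- uniroot(function(a) perim_at(a) - target, c(0, hi), tol = 1e-5)$root
    rebuild(r * (1 + a * cos(16 * theta + psi)))
  } else {
    rs <- r
    for (it in 1:100) {
      rs <- (rs + (rs[c(length(rs), seq_len(length(rs) - 1L))] +
                     rs[c(2:length(rs), 1L)]) / 2) / 2
      if (poly_perimeter(rebuild(rs)) <= target) break
    }
    if (poly_perimeter(rebuild(rs)) > target) {
      warning("could not shorten perimeter to target; using smoothest shape",
              call. = FALSE)
      return(rebuild(rs))
    }
    a <- uniroot(function(a) poly_perimeter(rebuild((1 - a) * r + a * rs)) - target,
                 c(0, 1), tol = 1e-5)$root
    rebuild((1 - a) * r + a * rs)
  }
}

# Shift a polygon so its raster IoU against the ground-truth pixels hits
# `target` (approximately; IoU is piecewise constant in the shift).
.tune_iou_shift <- function(poly, gt_keys, target, width, height) {
  iou_at <- function(d, dir) {
    p <- poly + rep(d * dir, each = nrow(poly))
    px <- rasterize_polygon(p, width, height)
    if (nrow(px) == 0L) return(0)
    k <- .pix_key(px)
    i <- sum(k %in% gt_keys)
    i / (length(k) + length(gt_keys) - i)
  }
  phi <- runif(1, 0, 2 * pi); dir <- c(cos(phi), sin(phi))
  if (iou_at(0, dir) <= target) return(poly)
  dmax <- 2
  while (iou_at(dmax, dir) > target && dmax < 4 * (max(poly) - min(poly))) {
    dmax <- dmax * 2
  }
  d <- uniroot(function(d) iou_at(d, dir) - target, c(0, dmax), tol = 0.15)$root
  poly + rep(d * dir, each = nrow(poly))
}

#' Generate a perturbed prediction set from ground truth
#'
#' Each retained ground-truth instance yields one prediction: its polygon
#' is scaled about the centroid by `sqrt(1 + area_bias)`, its perimeter is
#' then tuned to `(1 + perimeter_bias)` times the ground-truth perimeter by
#' radial ripple/smoothing, it is translated until the raster IoU against
#' its ground truth reaches `jitter_iou_target`, and it receives a score
#' draw. Dropped instances yield nothing; spurious blobs are added away
#' from all ground truth (IoU < 0.5 by construction). Requires polygonal
#' ground truth (as produced by [generate_ground_truth()]) whenever a
#' non-identity shape transform is requested.
#'
#' @param gt List of ground-truth [annotated_image()] objects.
#' @param cfg A [perturbation_config()].
#' @return List of prediction [annotated_image()] objects, parallel to `gt`.
#' @export
generate_predictions <- function(gt, cfg = perturbation_config()) {
  stopifnot(inherits(cfg, "perturbation_config"))
  if (inherits(gt, "annotated_image")) gt <- list(gt)
  set.seed(cfg$seed)
  subseeds <- sample.int(2147483646L, length(gt))
  f <- sqrt(1 + cfg$area_bias)
  identity_shape <- abs(cfg$area_bias) < 1e-12 && abs(cfg$perimeter_bias) < 1e-12
  lapply(seq_along(gt), function(i) {
    set.seed(subseeds[i])
    img <- gt[[i]]
    instances <- list()
    for (inst in img$instances) {
      if (runif(1) < cfg$drop_rate) next
      no_jitter <- cfg$jitter_iou_target >= 0.995
      if (identity_shape && no_jitter) {
        instances[[length(instances) + 1L]] <- mito_instance(
          inst$instance_id, pixels = inst$pixels, polygon = inst$polygon,
          score = .draw_score(cfg))
        next
      }
      if (is.null(inst$polygon)) {
        stop("instance ", inst$instance_id, " in image ", img$image_id,
             " has no polygon; shape perturbations need polygonal ground truth",
             call. = FALSE)
      }
      poly <- inst$polygon
      ctr <- colMeans(poly)
      poly <- cbind(ctr[1L] + f * (poly[, 1L] - ctr[1L]),
                    ctr[2L] + f * (poly[, 2L] - ctr[2L]))
      target_p <- poly_perimeter(inst$polygon) * (1 + cfg$perimeter_bias)
      poly <- .tune_perimeter(poly, target_p)
      if (!no_jitter) {
        poly <- .tune_iou_shift(poly, .pix_key(inst$pixels),
                                cfg$jitter_iou_target, img$width, img$height)
      }
      px <- rasterize_polygon(poly, img$width, img$height)
      if (nrow(px) == 0L) {
        warning("prediction for instance ", inst$instance_id,
                " left the frame; dropped", call. = FALSE)
        next
      }
      instances[[length(instances) + 1L]] <- mito_instance(
        inst$instance_id, pixels = px, polygon = poly,
        score = .draw_score(cfg))
    }
    n_sp <- rpois(1, cfg$spurious_rate)
    if (n_sp > 0L) {
      gt_sets <- lapply(img$instances, function(x) .pix_key(x$pixels))
      base_area <- if (length(img$instances)) {
        median(vapply(img$instances, function(x) nrow(x$pixels), numeric(1)))
      } else 600
      next_id <- if (length(img$instances)) {
        max(vapply(img$instances, function(x) x$instance_id, integer(1)))
      } else 0L
      for (k in seq_len(n_sp)) {
        for (try in 1:100) {
          cx <- runif(1, 10, img$width - 10); cy <- runif(1, 10, img$height - 10)
          poly <- .blob_polygon(cx, cy, base_area * runif(1, 0.6, 1.4), 0.8)
          px <- rasterize_polygon(poly, img$width, img$height)
          if (nrow(px) == 0L) next
          keys <- .pix_key(px)
          worst <- if (length(gt_sets)) {
            max(vapply(gt_sets, function(g) {
              ii <- sum(keys %in% g); ii / (length(keys) + length(g) - ii)
            }, numeric(1)))
          } else 0
          if (worst < 0.25) {
            next_id <- next_id + 1L
            instances[[length(instances) + 1L]] <- mito_instance(
              next_id, pixels = px, polygon = poly, score = .draw_score(cfg))
            break
          }
        }
      }
    }
    annotated_image(img$image_id, img$width, img$height, img$scale,
                    instances = instances, role = "prediction",
                    grade = img$grade)
  })
}

.square_poly <- function(x0, y0, side) {
  rbind(c(x0, y0), c(x0 + side, y0), c(x0 + side, y0 + side), c(x0, y0 + side))
}

#' Tiny hand-constructed evaluation fixture
#'
#' Two 64 x 64 images of axis-aligned squares with known matching outcome
#' at the default thresholds: image 1 has two true positives (one exact,
#' one at IoU 2/3), one false positive and one false negative; image 2 has
#' a single clean true positive. All matched squares share their ground
#' truth's dimensions, so the image-1 signed perimeter and area error
#' contributions are exactly zero. Used for exact metric tests.
#'
#' @return List with elements `gt` and `pred`, each a list of two
#'   [annotated_image()] objects.
#' @export
reference_fixture <- function() {
  s <- pixel_scale(0.1)
  frame <- c(64L, 64L)
  mk <- function(id, x0, y0, side, score = NULL) {
    mito_instance(id, polygon = .square_poly(x0, y0, side), frame = frame,
                  score = score)
  }
  cell1 <- cell_region(1L, polygon = .square_poly(1, 1, 62), frame = frame)
  gt1 <- annotated_image("fix1", 64, 64, s, cells = list(cell1),
                         instances = list(mk(1L, 5, 5, 10), mk(2L, 30, 30, 10),
                                          mk(3L, 48, 8, 8)))
  pr1 <- annotated_image("fix1", 64, 64, s, role = "prediction",
                         instances = list(mk(1L, 5, 5, 10, score = 0.9),
                                          mk(2L, 32, 30, 10, score = 0.8),
                                          mk(3L, 10, 45, 9, score = 0.95)))
  cell2 <- cell_region(1L, polygon = .square_poly(1, 1, 62), frame = frame)
  gt2 <- annotated_image("fix2", 64, 64, s, cells = list(cell2),
                         instances = list(mk(1L, 20, 20, 12)))
  pr2 <- annotated_image("fix2", 64, 64, s, role = "prediction",
                         instances = list(mk(1L, 20, 20, 12, score = 1)))
  list(gt = list(gt1, gt2), pred = list(pr1, pr2))
}
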