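test_that("generation is a pure function of (spec, seed)", {
  spec <- synthetic_dataset_spec(n_images = 2, image_size_px = 256, seed = 7)
  g1 <- generate_ground_truth(spec)
  g2 <- generate_ground_truth(spec)
  f1 <- withr::local_tempfile(fileext = ".json")
  f2 <- withr::local_tempfile(fileext = ".json")
  write_coco_annotations(g1, f1)
  write_coco_annotations(g2, f2)
  expect_identical(readBin(f1, "raw", file.size(f1)),
                   readBin(f2, "raw", file.size(f2)))  # byte-identical
  # different seed differs
  g3 <- generate_ground_truth(synthetic_dataset_spec(n_images = 2,
                                                     image_size_px = 256,
                                                     seed = 8))
  expect_false(identical(
    vapply(g1[[1]]$instances, function(i) nrow(i$pixels), integer(1)),
    vapply(g3[[1]]$instances, function(i) nrow(i$pixels), integer(1))))
})

test_that("ground-truth instances never overlap and stay inside the frame", {
  for (img in small_gt()) {
    keys <- lapply(img$instances, function(i) mitomorph:::.pix_key(i$pixels))
    all_keys <- unlist(keys)
    expect_equal(anyDuplicated(all_keys), 0)  # pairwise intersection empty
    for (inst in img$instances) {
      expect_true(all(inst$pixels >= 1) &&
                    all(inst$pixels[, 1] <= img$width) &&
                    all(inst$pixels[, 2] <= img$height))
    }
  }
})

test_that("drawn counts, areas and occupancies are recovered by measurement", {
  # one grade, many cells -> check the generator against the morphometry
  # module at a few hundred instances
  prof <- list("2" = grade_profile(2, mito_count_mean = 12,
                                   area_um2_median = 0.3,
                                   circularity_mean = 0.75,
                                   type_mixture = NULL,
                                   cristae_occupancy_mean = 0.4,
                                   p_omm_intact = 0.6))
  spec <- synthetic_dataset_spec(n_images = 12, image_size_px = 384,
                                 profiles = prof, seed = 33)
  gt <- generate_ground_truth(spec)
  res <- measure_dataset(gt)
  r <- res$records
  n <- nrow(r)
  expect_gt(n, 80)
  # counts: mean within 3 SE of the requested mean
  counts <- res$cells$mito_count
  se <- sd(counts) / sqrt(length(counts))
  expect_lt(abs(mean(counts) - 12), 3 * se + 1e-9)
  # areas: measured median within 15% of the lognormal median
  expect_lt(abs(median(r$area_um2) / 0.3 - 1), 0.15)
  # occupancy: mean measured occupancy within 0.05 of the beta mean
  expect_lt(abs(mean(r$cristae_occupancy) - 0.4), 0.05)
  # circularity: analytic-path mean within 0.05 of the requested mean
  # (radial wobble costs a couple of points, documented)
  expect_lt(abs(mean(r$circularity) - 0.75), 0.05)
})

test_that("a circularity profile concentrated near 1 yields round blobs", {
  prof <- list("4" = grade_profile(4, mito_count_mean = 10,
                                   area_um2_median = 0.3,
                                   circularity_mean = 0.97,
                                   circularity_conc = 200,
                                   type_mixture = c(1, 0, 0)))
  spec <- synthetic_dataset_spec(n_images = 4, image_size_px = 384,
                                 profiles = prof, seed = 5)
  r <- measure_dataset(generate_ground_truth(spec))$records
  expect_gt(mean(r$circularity), 0.9)
})

test_that("identity perturbation reproduces the ground truth with scores", {
  gt <- small_gt()[1:2]
  pred <- generate_predictions(gt, perturbation_config(
    drop_rate = 0, spurious_rate = 0, jitter_iou_target = 1,
    score_distribution = 0.9, seed = 2))
  for (k in seq_along(gt)) {
    expect_equal(length(pred[[k]]$instances), length(gt[[k]]$instances))
    for (j in seq_along(gt[[k]]$instances)) {
      expect_identical(pred[[k]]$instances[[j]]$pixels,
                       gt[[k]]$instances[[j]]$pixels)
      expect_equal(pred[[k]]$instances[[j]]$score, 0.9)
    }
  }
  rep <- evaluate_predictions(pred, gt)
  expect_equal(rep$macro$precision, 1)
  expect_equal(rep$macro$recall, 1)
  expect_equal(rep$macro$f1, 1)
  expect_equal(rep$macro$perimeter_error_rate, 0)
  expect_equal(rep$macro$area_error_rate, 0)
})

test_that("drop_rate 1 removes all predictions; recall is zero", {
  gt <- small_gt()[1]
  pred <- generate_predictions(gt, perturbation_config(drop_rate = 1, seed = 3))
  expect_length(pred[[1]]$instances, 0)
  prf <- precision_recall_f1(match_instances(pred[[1]], gt[[1]]))
  expect_equal(unname(prf$macro["recall"]), 0)
  expect_true(is.na(prf$macro["precision"]))  # no retained predictions
})

test_that("jitter drives the realized IoU towards its target", {
  gt <- small_gt()[1:2]
  tgt <- 0.7
  pred <- generate_predictions(gt, perturbation_config(
    jitter_iou_target = tgt, seed = 11))
  ious <- unlist(lapply(seq_along(gt), function(k) {
    match_instances(pred[[k]], gt[[k]], score_thr = 0, iou_thr = 0.1)$tp_pairs$iou
  }))
  expect_gt(length(ious), 10)
  expect_lt(abs(mean(ious) - tgt), 0.05)
})

test_that("spurious blobs are FPs away from all ground truth", {
  gt <- small_gt()[1]
  pred <- generate_predictions(gt, perturbation_config(
    spurious_rate = 4, score_distribution = 0.9, seed = 13))
  extra <- length(pred[[1]]$instances) - length(gt[[1]]$instances)
  expect_gt(extra, 0)
  m <- match_instances(pred[[1]], gt[[1]])
  expect_equal(length(m$fp_ids), extra)  # all spurious, no stolen matches
  expect_length(m$fn_ids, 0)
})

test_that("infeasible packing raises a packing error naming the image", {
  prof <- list("4" = grade_profile(4, mito_count_mean = 60,
                                   mito_count_size = 1e6,
                                   area_um2_median = 1.5,
                                   circularity_mean = 0.9))
  spec <- synthetic_dataset_spec(n_images = 1, image_size_px = 128,
                                 profiles = prof, seed = 1)
  expect_error(generate_ground_truth(spec, max_tries = 20), "packing.*img")
})

test_that("the reference fixture has its stated matching outcome", {
  fx <- reference_fixture()
  m1 <- match_instances(fx$pred[[1]], fx$gt[[1]])
  expect_equal(nrow(m1$tp_pairs), 2)
  expect_length(m1$fp_ids, 1)
  expect_length(m1$fn_ids, 1)
  m2 <- match_instances(fx$pred[[2]], fx$gt[[2]])
  expect_equal(nrow(m2$tp_pairs), 1)
  expect_length(m2$fp_ids, 0)
  expect_length(m2$fn_ids, 0)
  # brute-force IoU check of every pair against the matcher's decisions
  for (img in 1:2) {
    for (p in fx$pred[[img]]$instances) {
      for (g in fx$gt[[img]]$instances) {
        expect_equal(compute_iou(p, g), oracle_iou(p$pixels, g$pixels))
      }
    }
  }
  # all scores forced to 0.4 -> everything discarded, zero TP everywhere
  low <- lapply(fx$pred, function(img) {
    img$instances <- lapply(img$instances, function(i) { i$score <- 0.4; i })
    img
  })
  for (img in 1:2) {
    m <- match_instances(low[[img]], fx$gt[[img]])
    expect_equal(nrow(m$tp_pairs), 0)
    expect_length(m$fp_ids, 0)
  }
})
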