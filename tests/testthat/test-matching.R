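mk_img <- function(id, insts, role = "ground_truth", wh = 64) {
  annotated_image(id, wh, wh, pixel_scale(0.1), instances = insts, role = role)
}

test_that("compute_iou matches brute-force pixel enumeration", {
  a <- px_rect(1, 1, 2, 2); b <- px_rect(2, 1, 2, 2)  # 1x2 strip overlap
  expect_equal(compute_iou(a, b), 2 / 6)
  expect_equal(compute_iou(a, b), oracle_iou(a, b))
  expect_equal(compute_iou(a, a), 1)
  expect_equal(compute_iou(a, px_rect(10, 10, 2, 2)), 0)
  expect_error(compute_iou(matrix(integer(0), 0, 2), matrix(integer(0), 0, 2)),
               "undefined")
  set.seed(21)
  for (i in 1:20) {
    p <- px_rect(sample(1:6, 1), sample(1:6, 1), sample(2:5, 1), sample(2:5, 1))
    q <- px_rect(sample(1:6, 1), sample(1:6, 1), sample(2:5, 1), sample(2:5, 1))
    expect_equal(compute_iou(p, q), oracle_iou(p, q))
  }
})

test_that("identity predictions give perfect matching", {
  gt <- mk_img("i", list(mito_instance(1, pixels = px_rect(3, 3, 6, 6)),
                         mito_instance(2, pixels = px_rect(20, 20, 8, 5))))
  pred <- mk_img("i", list(
    mito_instance(1, pixels = px_rect(3, 3, 6, 6), score = 0.9),
    mito_instance(2, pixels = px_rect(20, 20, 8, 5), score = 0.9)),
    role = "prediction")
  m <- match_instances(pred, gt)
  expect_equal(nrow(m$tp_pairs), 2)
  expect_length(m$fp_ids, 0)
  expect_length(m$fn_ids, 0)
  expect_equal(m$tp_pairs$iou, c(1, 1))
})

test_that("score filter discards low-confidence predictions", {
  gt <- mk_img("i", list(mito_instance(1, pixels = px_rect(3, 3, 6, 6))))
  pred <- mk_img("i", list(mito_instance(1, pixels = px_rect(3, 3, 6, 6),
                                         score = 0.4)), role = "prediction")
  m <- match_instances(pred, gt)
  expect_equal(nrow(m$tp_pairs), 0)
  expect_length(m$fp_ids, 0)           # discarded, not a false positive
  expect_equal(m$fn_ids, 1L)
  expect_equal(m$n_discarded_low_score, 1)
  # boundary: score exactly 0.5 is retained
  pred2 <- mk_img("i", list(mito_instance(1, pixels = px_rect(3, 3, 6, 6),
                                          score = 0.5)), role = "prediction")
  expect_equal(nrow(match_instances(pred2, gt)$tp_pairs), 1)
})

test_that("two predictions on one GT: best IoU wins, other is FP", {
  gt <- mk_img("i", list(mito_instance(1, pixels = px_rect(10, 10, 10, 10))))
  pred <- mk_img("i", list(
    mito_instance(1, pixels = px_rect(10, 11, 10, 10), score = 0.9),  # IoU 9/11
    mito_instance(2, pixels = px_rect(10, 13, 10, 10), score = 0.9)), # IoU 7/13
    role = "prediction")
  m <- match_instances(pred, gt)
  expect_equal(m$tp_pairs$prediction_id, 1L)
  expect_equal(m$fp_ids, 2L)
  expect_length(m$fn_ids, 0)
})

test_that("frame or id mismatch is an error", {
  gt <- mk_img("i", list(mito_instance(1, pixels = px_rect(3, 3, 4, 4))))
  expect_error(match_instances(mk_img("j", list(), role = "prediction"), gt),
               "different images")
  bad <- annotated_image("i", 32, 32, pixel_scale(0.1), role = "prediction")
  expect_error(match_instances(bad, gt), "frame mismatch")
})

test_that("counting identities hold on randomized inputs", {
  set.seed(31)
  for (rep in 1:10) {
    gt_i <- lapply(seq_len(sample(0:4, 1)), function(k) {
      mito_instance(k, pixels = px_rect(sample(1:50, 1), sample(1:50, 1),
                                        sample(3:8, 1), sample(3:8, 1)))
    })
    pr_i <- lapply(seq_len(sample(0:5, 1)), function(k) {
      mito_instance(k, pixels = px_rect(sample(1:50, 1), sample(1:50, 1),
                                        sample(3:8, 1), sample(3:8, 1)),
                    score = runif(1))
    })
    m <- match_instances(mk_img("r", pr_i, role = "prediction"),
                         mk_img("r", gt_i))
    expect_equal(nrow(m$tp_pairs) + length(m$fn_ids), length(gt_i))
    expect_equal(nrow(m$tp_pairs) + length(m$fp_ids) +
                   m$n_discarded_low_score, length(pr_i))
  }
})

test_that("greedy matcher agrees with exhaustive optimal assignment", {
  # random mask instances up to 6 predictions x 6 ground truths, with
  # non-overlapping ground truth (as in label images): at IoU threshold 0.5
  # each prediction can clear the threshold against at most one disjoint
  # ground truth, so greedy matching must equal the exhaustive optimum in
  # both pair count and total IoU
  set.seed(42)
  for (rep in 1:150) {
    case <- random_matching_case(ng = sample(1:6, 1), np = sample(1:6, 1))
    g <- mitomorph:::greedy_match_iou(case$iou, iou_thr = 0.5)
    best <- oracle_best_assignment(case$iou, 0.5)
    expect_equal(nrow(g), best[1L])
    expect_equal(if (nrow(g)) sum(g[, "iou"]) else 0, best[2L])
  }
})

test_that("precision/recall/F1 follow the printed per-image formulas", {
  fabricate <- function(id, tp, fp, fn) {
    structure(list(image_id = id,
                   tp_pairs = data.frame(prediction_id = seq_len(tp),
                                         gt_id = seq_len(tp),
                                         iou = rep(0.9, tp)),
                   fp_ids = if (fp) 1000L + seq_len(fp) else integer(0),
                   fn_ids = if (fn) 2000L + seq_len(fn) else integer(0),
                   n_discarded_low_score = 0L, n_gt = tp + fn,
                   n_retained = tp + fp), class = "match_result")
  }
  r <- precision_recall_f1(list(fabricate("a", 2, 1, 1)))
  expect_equal(unname(r$macro["precision"]), 2 / 3)
  expect_equal(unname(r$macro["recall"]), 2 / 3)
  expect_equal(unname(r$macro["f1"]), 2 / 3)   # 2/(2 + (1+1)/2)
  # macro mean over images
  r2 <- precision_recall_f1(list(fabricate("a", 2, 0, 0),
                                 fabricate("b", 1, 1, 0)))
  expect_equal(unname(r2$macro["precision"]), 0.75)
  # per-image f1 equals 2PR/(P+R) wherever both P and R are defined
  set.seed(13)
  for (i in 1:30) {
    tp <- sample(0:5, 1); fp <- sample(0:3, 1); fn <- sample(0:3, 1)
    per <- precision_recall_f1(list(fabricate("x", tp, fp, fn)))$per_image
    if (!is.na(per$precision) && !is.na(per$recall) &&
        per$precision + per$recall > 0) {
      expect_equal(per$f1, 2 * per$precision * per$recall /
                     (per$precision + per$recall))
    }
  }
  # undefined ratios are excluded from the macro mean and counted
  r3 <- precision_recall_f1(list(fabricate("a", 0, 0, 2),
                                 fabricate("b", 2, 0, 0)))
  expect_equal(unname(r3$macro["precision"]), 1)
  expect_equal(unname(r3$n_images_used["precision"]), 1)
  expect_equal(unname(r3$macro["recall"]), 0.5)
  expect_equal(unname(r3$n_images_used["recall"]), 2)
})

test_that("monotonicity: spurious predictions and dropped matches", {
  gt <- mk_img("i", list(mito_instance(1, pixels = px_rect(3, 3, 6, 6)),
                         mito_instance(2, pixels = px_rect(30, 30, 6, 6))))
  base_insts <- list(mito_instance(1, pixels = px_rect(3, 3, 6, 6), score = 0.9),
                     mito_instance(2, pixels = px_rect(30, 30, 6, 6), score = 0.9))
  base <- precision_recall_f1(match_instances(
    mk_img("i", base_insts, role = "prediction"), gt))
  with_spur <- precision_recall_f1(match_instances(
    mk_img("i", c(base_insts, list(mito_instance(3, pixels = px_rect(50, 50, 5, 5),
                                                 score = 0.9))),
           role = "prediction"), gt))
  expect_lte(with_spur$macro["precision"], base$macro["precision"])
  dropped <- precision_recall_f1(match_instances(
    mk_img("i", base_insts[1], role = "prediction"), gt))
  expect_lte(dropped$macro["recall"], base$macro["recall"])
})

test_that("error rates: trivial arithmetic and missing-measurement errors", {
  m <- structure(list(image_id = "a",
                      tp_pairs = data.frame(prediction_id = 1L, gt_id = 1L,
                                            iou = 1),
                      fp_ids = integer(0), fn_ids = integer(0),
                      n_discarded_low_score = 0L, n_gt = 1L, n_retained = 1L),
                 class = "match_result")
  meas <- function(p, a) data.frame(image_id = "a", instance_id = 1L,
                                    perimeter_um = p, area_um2 = a)
  pe <- perimeter_error_rate(m, meas(11, 5), meas(10, 5))
  expect_equal(pe$signed_macro, 0.1)
  ae <- area_error_rate(m, meas(10, 90), meas(10, 100))
  expect_equal(ae$signed_macro, -0.1)
  same <- perimeter_error_rate(m, meas(10, 5), meas(10, 5))
  expect_identical(same$signed_macro, 0)
  expect_error(perimeter_error_rate(m, meas(10, 5)[0, ], meas(10, 5)),
               "missing perimeter")
})
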