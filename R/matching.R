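# Prediction--ground-truth matching and the four evaluation statistics.
#
# Matching rule: predictions with score < 0.5 are discarded; the retained
# ones are matched one-to-one to ground truths greedily in descending IoU
# (ties: higher score, then lower prediction id); a matched pair with
# IoU >= 0.5 is a TP, an unmatched retained prediction is an FP, an
# unmatched ground truth an FN. Metrics follow the macro-averaged form
#   Precision = (1/N) sum_images TP/(TP+FP)
#   Recall    = (1/N) sum_images TP/(TP+FN)
#   F1        = (1/N) sum_images TP/(TP+(FN+FP)/2)
# and the error rates are signed mean relative differences over TP pairs,
# per image, macro-averaged over images. Note the published area-error
# display equation degenerates to zero by an evident typo ((A_pred -
# A_pred)/A_pred); this package implements the perimeter-analogous form
# (A_pred - A_gt)/A_gt.

# Greedy one-to-one matching on a precomputed IoU matrix (rows =
# predictions, cols = ground truths). Only pairs with IoU >= iou_thr are
# eligible. Returns a matrix with columns pred, gt, iou.
greedy_match_iou <- function(iou, scores = NULL, iou_thr = 0.5) {
  cand <- which(iou >= iou_thr, arr.ind = TRUE)
  out <- matrix(numeric(0), 0L, 3L, dimnames = list(NULL, c("pred", "gt", "iou")))
  if (!nrow(cand)) return(out)
  v <- iou[cand]
  sc <- if (is.null(scores)) rep(0, nrow(cand)) else scores[cand[, 1L]]
  ord <- order(-v, -sc, cand[, 1L], cand[, 2L])
  cand <- cand[ord, , drop = FALSE]; v <- v[ord]
  used_p <- logical(nrow(iou)); used_g <- logical(ncol(iou))
  keep <- logical(nrow(cand))
  for (k in seq_len(nrow(cand))) {
    p <- cand[k, 1L]; g <- cand[k, 2L]
    if (!used_p[p] && !used_g[g]) {
      used_p[p] <- TRUE; used_g[g] <- TRUE; keep[k] <- TRUE
    }
  }
  cbind(pred = cand[keep, 1L], gt = cand[keep, 2L], iou = v[keep])
}

#' Match predicted instances to ground truth in one image
#'
#' Applies the score filter (predictions with score below `score_thr` are
#' discarded and counted), computes all pairwise IoUs and matches retained
#' predictions one-to-one to ground truths greedily in descending IoU.
#' Pairs at or above `iou_thr` are true positives; leftover retained
#' predictions are false positives and leftover ground truths false
#' negatives. A prediction without a score is retained (the filter applies
#' to predictions that carry scores; ground truth never does).
#'
#' @param pred,gt [annotated_image()] objects for the same image id and
#'   raster frame, with roles prediction and ground truth.
#' @param score_thr Score threshold, default 0.5.
#' @param iou_thr IoU threshold, default 0.5.
#' @return A `match_result`: `image_id`, `tp_pairs` (data frame
#'   `prediction_id`, `gt_id`, `iou`), `fp_ids`, `fn_ids`,
#'   `n_discarded_low_score`, `n_gt`, `n_retained`.
#' @export
match_instances <- function(pred, gt, score_thr = 0.5, iou_thr = 0.5) {
  if (!identical(pred$image_id, gt$image_id)) {
    stop("prediction and ground truth refer to different images (",
         pred$image_id, " vs ", gt$image_id, ")", call. = FALSE)
  }
  if (pred$width != gt$width || pred$height != gt$height) {
    stop("raster frame mismatch for image ", gt$image_id, call. = FALSE)
  }
  scores <- vapply(pred$instances,
                   function(i) if (is.null(i$score)) NA_real_ else i$score,
                   numeric(1))
  retained <- is.na(scores) | scores >= score_thr
  n_discarded <- sum(!retained)
  preds <- pred$instances[retained]
  pscores <- scores[retained]
  np <- length(preds); ng <- length(gt$instances)
  iou <- matrix(0, np, ng)
  if (np && ng) {
    gt_keys <- lapply(gt$instances, function(i) .pix_key(i$pixels))
    gt_len <- lengths(gt_keys)
    for (i in seq_len(np)) {
      k <- .pix_key(preds[[i]]$pixels)
      for (j in seq_len(ng)) {
        inter <- sum(k %in% gt_keys[[j]])
        iou[i, j] <- inter / (length(k) + gt_len[j] - inter)
      }
    }
  }
  m <- greedy_match_iou(iou, scores = ifelse(is.na(pscores), 1, pscores),
                        iou_thr = iou_thr)
  pred_ids <- vapply(preds, function(i) i$instance_id, integer(1))
  gt_ids <- vapply(gt$instances, function(i) i$instance_id, integer(1))
  tp <- data.frame(prediction_id = pred_ids[m[, "pred"]],
                   gt_id = gt_ids[m[, "gt"]], iou = m[, "iou"])
  res <- structure(list(
    image_id = gt$image_id,
    tp_pairs = tp,
    fp_ids = setdiff(pred_ids, tp$prediction_id),
    fn_ids = setdiff(gt_ids, tp$gt_id),
    n_discarded_low_score = n_discarded,
    n_gt = ng, n_retained = np), class = "match_result")
  # counting identities hold by construction; assert them on every result
  stopifnot(nrow(res$tp_pairs) + length(res$fn_ids) == res$n_gt,
            nrow(res$tp_pairs) + length(res$fp_ids) == res$n_retained)
  res
}

#' @export
print.match_result <- function(x, ...) {
  cat(sprintf("<match_result '%s'> TP %d, FP %d, FN %d (%d low-score discarded)\n",
              x$image_id, nrow(x$tp_pairs), length(x$fp_ids),
              length(x$fn_ids), x$n_discarded_low_score))
  invisible(x)
}

.as_match_list <- function(matches) {
  if (inherits(matches, "match_result")) list(matches) else matches
}

#' Macro-averaged Precision, Recall and F1
#'
#' Per image: `TP/(TP+FP)`, `TP/(TP+FN)` and `TP/(TP+(FN+FP)/2)`. The macro
#' value of each metric is the plain mean over the images where its ratio
#' is defined (nonzero denominator); the number of images entering each
#' mean is reported. The per-image F1 equals the harmonic mean of per-image
#' precision and recall whenever both are defined.
#'
#' @param matches A `match_result` or list of them (one per image).
#' @return List with `per_image` (data frame `image_id`, `tp`, `fp`, `fn`,
#'   `precision`, `recall`, `f1`), `macro` (named vector) and
#'   `n_images_used` (named vector).
#' @export
precision_recall_f1 <- function(matches) {
  matches <- .as_match_list(matches)
  if (!length(matches)) stop("at least one image is required", call. = FALSE)
  per <- do.call(rbind, lapply(matches, function(m) {
    tp <- nrow(m$tp_pairs); fp <- length(m$fp_ids); fn <- length(m$fn_ids)
    data.frame(image_id = m$image_id, tp = tp, fp = fp, fn = fn,
               precision = if (tp + fp > 0) tp / (tp + fp) else NA_real_,
               recall = if (tp + fn > 0) tp / (tp + fn) else NA_real_,
               f1 = if (tp + (fn + fp) / 2 > 0) tp / (tp + (fn + fp) / 2)
                    else NA_real_,
               stringsAsFactors = FALSE)
  }))
  macro <- vapply(c("precision", "recall", "f1"), function(col) {
    v <- per[[col]]
    if (all(is.na(v))) NA_real_ else mean(v, na.rm = TRUE)
  }, numeric(1))
  used <- vapply(c("precision", "recall", "f1"),
                 function(col) sum(!is.na(per[[col]])), numeric(1))
  list(per_image = per, macro = macro, n_images_used = used)
}

.relative_error_rate <- function(matches, pred_measurements, gt_measurements,
                                 column, what) {
  matches <- .as_match_list(matches)
  lookup <- function(df, image_id, instance_id, side) {
    i <- which(df$image_id == image_id & df$instance_id == instance_id)
    if (length(i) != 1L) {
      stop("missing ", what, " measurement for ", side, " instance ",
           instance_id, " in image ", image_id, call. = FALSE)
    }
    df[[column]][i]
  }
  per <- do.call(rbind, lapply(matches, function(m) {
    if (!nrow(m$tp_pairs)) {
      return(data.frame(image_id = m$image_id, n_tp = 0L,
                        signed = NA_real_, abs = NA_real_))
    }
    err <- vapply(seq_len(nrow(m$tp_pairs)), function(k) {
      pv <- lookup(pred_measurements, m$image_id,
                   m$tp_pairs$prediction_id[k], "predicted")
      gv <- lookup(gt_measurements, m$image_id, m$tp_pairs$gt_id[k],
                   "ground-truth")
      (pv - gv) / gv
    }, numeric(1))
    data.frame(image_id = m$image_id, n_tp = nrow(m$tp_pairs),
               signed = mean(err), abs = mean(abs(err)))
  }))
  used <- sum(!is.na(per$signed))
  list(signed_macro = if (used) mean(per$signed, na.rm = TRUE) else NA_real_,
       abs_macro = if (used) mean(per$abs, na.rm = TRUE) else NA_real_,
       per_image = per, n_images_used = used)
}

#' Perimeter error rate between matched predictions and ground truth
#'
#' For every TP pair the signed relative perimeter error
#' `(P_pred - P_gt) / P_gt`; the per-image value is the mean over that
#' image's TP pairs and the macro value the mean over images with at least
#' one TP. Since signed errors can cancel, the mean absolute companion is
#' always reported alongside.
#'
#' @param matches A `match_result` or list of them.
#' @param pred_measurements,gt_measurements Data frames from
#'   [measure_instances()] covering every TP member.
#' @return List: `signed_macro`, `abs_macro`, `per_image`, `n_images_used`.
#' @export
perimeter_error_rate <- function(matches, pred_measurements, gt_measurements) {
  .relative_error_rate(matches, pred_measurements, gt_measurements,
                       "perimeter_um", "perimeter")
}

#' Area error rate between matched predictions and ground truth
#'
#' Signed relative area error `(A_pred - A_gt) / A_gt` over TP pairs,
#' aggregated exactly like [perimeter_error_rate()]. (The perimeter-
#' analogous definition is used; a literal reading of the published area
#' formula is identically zero due to a typo.)
#'
#' @inheritParams perimeter_error_rate
#' @return List: `signed_macro`, `abs_macro`, `per_image`, `n_images_used`.
#' @export
area_error_rate <- function(matches, pred_measurements, gt_measurements) {
  .relative_error_rate(matches, pred_measurements, gt_measurements,
                       "area_um2", "area")
}

#' End-to-end evaluation of predicted against ground-truth images
#'
#' Pairs prediction and ground-truth images by image id, matches instances,
#' and assembles per-image and macro-averaged Precision, Recall, F1 and
#' signed perimeter/area error rates into one report.
#'
#' @param pred_images,gt_images Lists of [annotated_image()].
#' @param score_thr,iou_thr Matching thresholds, both default 0.5.
#' @param method Measurement path for the error rates ("auto", "polygon",
#'   "raster"); see [measure_instance()].
#' @return A `metrics_report`: `per_image` data frame, `macro` named list,
#'   `n_images_used`, and the underlying `matches`.
#' @export
evaluate_predictions <- function(pred_images, gt_images, score_thr = 0.5,
                                 iou_thr = 0.5, method = "auto") {
  if (inherits(pred_images, "annotated_image")) pred_images <- list(pred_images)
  if (inherits(gt_images, "annotated_image")) gt_images <- list(gt_images)
  gt_ids <- vapply(gt_images, function(i) i$image_id, character(1))
  pred_ids <- vapply(pred_images, function(i) i$image_id, character(1))
  if (!setequal(gt_ids, pred_ids)) {
    stop("prediction and ground-truth image ids do not match", call. = FALSE)
  }
  matches <- lapply(gt_ids, function(id) {
    match_instances(pred_images[[match(id, pred_ids)]],
                    gt_images[[match(id, gt_ids)]],
                    score_thr = score_thr, iou_thr = iou_thr)
  })
  prf <- precision_recall_f1(matches)
  pm <- measure_instances(pred_images, method = method)
  gm <- measure_instances(gt_images, method = method)
  per_err <- perimeter_error_rate(matches, pm, gm)
  area_err <- area_error_rate(matches, pm, gm)
  per_image <- prf$per_image
  per_image$perimeter_error_rate <- per_err$per_image$signed[
    match(per_image$image_id, per_err$per_image$image_id)]
  per_image$area_error_rate <- area_err$per_image$signed[
    match(per_image$image_id, area_err$per_image$image_id)]
  structure(list(
    per_image = per_image,
    macro = list(precision = unname(prf$macro["precision"]),
                 recall = unname(prf$macro["recall"]),
                 f1 = unname(prf$macro["f1"]),
                 perimeter_error_rate = per_err$signed_macro,
                 perimeter_error_rate_abs = per_err$abs_macro,
                 area_error_rate = area_err$signed_macro,
                 area_error_rate_abs = area_err$abs_macro),
    n_images_used = c(prf$n_images_used,
                      perimeter_error_rate = per_err$n_images_used,
                      area_error_rate = area_err$n_images_used),
    matches = matches), class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, ...) {
  cat("<metrics_report>", nrow(x$per_image), "image(s)\n")
  m <- x$macro
  cat(sprintf("  Precision %.4f  Recall %.4f  F1 %.4f\n",
              m$precision, m$recall, m$f1))
  cat(sprintf("  Perimeter error rate %+.4f (|.| %.4f)  Area error rate %+.4f (|.| %.4f)\n",
              m$perimeter_error_rate, m$perimeter_error_rate_abs,
              m$area_error_rate, m$area_error_rate_abs))
  invisible(x)
}
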