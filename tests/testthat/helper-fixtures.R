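# Shared helpers: tiny deterministic fixtures and independent oracles.

# pixel block helper: all pixels of an axis-aligned rectangle (1-based)
px_rect <- function(x0, y0, w, h) {
  m <- as.matrix(expand.grid(x = x0:(x0 + w - 1L), y = y0:(y0 + h - 1L)))
  storage.mode(m) <- "integer"
  m
}

square_poly <- function(x0, y0, side) {
  rbind(c(x0, y0), c(x0 + side, y0), c(x0 + side, y0 + side), c(x0, y0 + side))
}

# brute-force even-odd point-in-polygon rasterizer, written independently of
# the package implementation (angle-summation test instead of ray crossing)
oracle_rasterize <- function(poly, width, height) {
  inside_one <- function(x, y) {
    dx <- poly[, 1L] - x; dy <- poly[, 2L] - y
    dx2 <- c(dx[-1L], dx[1L]); dy2 <- c(dy[-1L], dy[1L])
    ang <- atan2(dx * dy2 - dy * dx2, dx * dx2 + dy * dy2)
    abs(sum(ang)) > pi  # winding ~ 2*pi inside, ~0 outside
  }
  out <- NULL
  for (yy in seq_len(height)) {
    for (xx in seq_len(width)) {
      if (inside_one(xx - 0.5, yy - 0.5)) out <- rbind(out, c(xx, yy))
    }
  }
  if (is.null(out)) matrix(integer(0), 0, 2) else out
}

# brute-force IoU by pixel enumeration on character keys
oracle_iou <- function(a, b) {
  ka <- paste(a[, 1L], a[, 2L]); kb <- paste(b[, 1L], b[, 2L])
  length(intersect(ka, kb)) / length(union(ka, kb))
}

# exhaustive optimal one-to-one assignment on an IoU matrix: maximize the
# number of matched pairs with IoU >= thr, then the total IoU of the
# matching; returns c(n_pairs, total_iou)
oracle_best_assignment <- function(iou, thr) {
  np <- nrow(iou); ng <- ncol(iou)
  best <- c(0, 0)
  recurse <- function(p, used_g, n, tot) {
    if (p > np) {
      if (n > best[1L] || (n == best[1L] && tot > best[2L])) {
        best <<- c(n, tot)
      }
      return(invisible())
    }
    recurse(p + 1L, used_g, n, tot)  # leave prediction p unmatched
    for (g in seq_len(ng)) {
      if (!used_g[g] && iou[p, g] >= thr) {
        used_g[g] <- TRUE
        recurse(p + 1L, used_g, n + 1L, tot + iou[p, g])
        used_g[g] <- FALSE
      }
    }
  }
  recurse(1L, logical(ng), 0L, 0)
  best
}

# hand-rolled Kruskal-Wallis H with mid-rank ties, independent of stats::
oracle_kruskal_h <- function(values, groups) {
  r <- rank(values)  # mid-ranks
  n <- length(values)
  h <- 12 / (n * (n + 1)) *
    sum(tapply(r, groups, function(x) length(x) * mean(x)^2)) - 3 * (n + 1)
  ties <- table(values)
  h / (1 - sum(ties^3 - ties) / (n^3 - n))
}

# one random matching scenario: `ng` non-overlapping ground-truth rectangles
# on a grid and `np` predictions jittered off them (or placed anywhere);
# returns the pixel sets and their IoU matrix (rows = predictions)
random_matching_case <- function(ng, np, frame = 60L) {
  slots <- expand.grid(x = c(1L, 21L, 41L), y = c(1L, 21L, 41L))
  slots <- slots[sample(nrow(slots), ng), , drop = FALSE]
  gts <- lapply(seq_len(ng), function(k) {
    px_rect(slots$x[k] + sample(0:4, 1), slots$y[k] + sample(0:4, 1),
            sample(5:12, 1), sample(5:12, 1))
  })
  preds <- lapply(seq_len(np), function(k) {
    if (ng && runif(1) < 0.7) {   # jitter off a ground truth
      base <- gts[[sample(ng, 1)]]
      pmin(pmax(base + matrix(sample(-4:4, 2), nrow(base), 2, byrow = TRUE),
                1L), frame)
    } else {
      px_rect(sample(1:45, 1), sample(1:45, 1), sample(4:10, 1),
              sample(4:10, 1))
    }
  })
  iou <- matrix(0, np, ng)
  for (i in seq_len(np)) for (j in seq_len(ng)) {
    iou[i, j] <- compute_iou(preds[[i]], gts[[j]])
  }
  list(gts = gts, preds = preds, iou = iou)
}

# small synthetic dataset shared by several tests (cached per session)
small_gt <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      spec <- synthetic_dataset_spec(n_images = 4, image_size_px = 384,
                                     seed = 101)
      cache <<- generate_ground_truth(spec)
    }
    cache
  }
})
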