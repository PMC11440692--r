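# Group-wise statistics and dataset summaries.

#' Compare a morphometric metric between groups
#'
#' Nonparametric or parametric comparison of one measurement column across
#' WHO grades or the LGG/HGG dichotomy: Kruskal--Wallis or ordinary one-way
#' ANOVA for more than two groups, Mann--Whitney U (Wilcoxon rank-sum, with
#' mid-rank tie handling) or the unpaired two-tailed Student t test for two
#' groups. `test = "auto"` picks Kruskal--Wallis / Mann--Whitney by group
#' count. The statistical unit defaults to the mitochondrion; set
#' `unit = "cell"` or `"image"` to aggregate (mean) per cell or image
#' first, which avoids pseudoreplication at the cost of power.
#'
#' @param records Data frame with the metric column, `grade`, and (for
#'   non-instance units) `image_id` / `cell_id`.
#' @param metric Name of the measurement column.
#' @param grouping `"group"` (LGG/HGG) or `"grade"`.
#' @param test `"auto"`, `"kruskal_wallis"`, `"one_way_anova"`,
#'   `"mann_whitney"`, or `"t_test"`.
#' @param unit `"instance"`, `"cell"`, or `"image"`.
#' @return A `group_comparison`: `metric_name`, `groups` (label, n, mean,
#'   sd, median), `test`, `statistic`, `p_value`, `unit`.
#' @export
compare_groups <- function(records, metric, grouping = c("group", "grade"),
                           test = c("auto", "kruskal_wallis", "one_way_anova",
                                    "mann_whitney", "t_test"),
                           unit = c("instance", "cell", "image")) {
  grouping <- match.arg(grouping); test <- match.arg(test)
  unit <- match.arg(unit)
  if (!metric %in% names(records)) {
    stop("no column `", metric, "` in records", call. = FALSE)
  }
  df <- records[!is.na(records[[metric]]) & !is.na(records$grade), ]
  if (unit != "instance") {
    keycols <- if (unit == "cell") c("image_id", "cell_id") else "image_id"
    df <- aggregate(df[metric],
                    by = c(df[keycols], list(grade = df$grade)), FUN = mean)
  }
  key <- if (grouping == "grade") factor(df$grade) else
    assign_grade_group(df$grade)
  key <- droplevels(key)
  values <- df[[metric]]
  if (nlevels(key) < 2L) stop("need >= 2 non-empty groups", call. = FALSE)
  k <- nlevels(key)
  if (test == "auto") test <- if (k > 2L) "kruskal_wallis" else "mann_whitney"
  if (k != 2L && test %in% c("mann_whitney", "t_test")) {
    stop("`", test, "` requires exactly 2 groups (got ", k, ")", call. = FALSE)
  }
  if (test %in% c("one_way_anova", "t_test")) {
    sizes <- table(key)
    if (any(sizes < 2L)) {
      stop("variance-based tests need n >= 2 per group", call. = FALSE)
    }
  }
  res <- switch(test,
    kruskal_wallis = {
      h <- kruskal.test(values, key)
      list(statistic = unname(h$statistic), p = h$p.value)
    },
    one_way_anova = {
      h <- oneway.test(values ~ key, var.equal = TRUE)
      list(statistic = unname(h$statistic), p = h$p.value)
    },
    mann_whitney = {
      h <- wilcox.test(values[key == levels(key)[1L]],
                       values[key == levels(key)[2L]], exact = FALSE)
      list(statistic = unname(h$statistic), p = h$p.value)
    },
    t_test = {
      h <- t.test(values[key == levels(key)[1L]],
                  values[key == levels(key)[2L]], var.equal = TRUE)
      list(statistic = unname(h$statistic), p = h$p.value)
    })
  groups <- do.call(rbind, lapply(levels(key), function(lv) {
    v <- values[key == lv]
    data.frame(label = lv, n = length(v), mean = mean(v), sd = sd(v),
               median = median(v), stringsAsFactors = FALSE)
  }))
  structure(list(metric_name = metric, groups = groups, test = test,
                 statistic = res$statistic, p_value = res$p, unit = unit),
            class = "group_comparison")
}

#' @export
print.group_comparison <- function(x, ...) {
  cat(sprintf("<group_comparison> %s by %s (%s unit)\n", x$metric_name,
              paste(x$groups$label, collapse = "/"), x$unit))
  print(x$groups, row.names = FALSE)
  cat(sprintf("  %s: statistic %.4g, p = %.4g\n", x$test, x$statistic,
              x$p_value))
  invisible(x)
}

#' Compare several metrics at once
#'
#' Convenience wrapper running [compare_groups()] per metric and returning
#' a flat table of statistics and raw p-values, optionally with a Holm
#' adjustment column (off by default; source panels report raw p-values).
#'
#' @inheritParams compare_groups
#' @param metrics Character vector of measurement columns.
#' @param adjust Add a Holm-adjusted `p_holm` column.
#' @return Data frame: `metric`, `test`, `statistic`, `p_value`
#'   (, `p_holm`).
#' @export
compare_groups_table <- function(records, metrics, grouping = "group",
                                 test = "auto", unit = "instance",
                                 adjust = FALSE) {
  out <- do.call(rbind, lapply(metrics, function(m) {
    cmp <- compare_groups(records, m, grouping = grouping, test = test,
                          unit = unit)
    data.frame(metric = m, test = cmp$test, statistic = cmp$statistic,
               p_value = cmp$p_value, stringsAsFactors = FALSE)
  }))
  if (adjust) out$p_holm <- p.adjust(out$p_value, method = "holm")
  out
}

#' Dataset-level counts
#'
#' Totals over a measured dataset: images, cells, mitochondria, and
#' per-grade mitochondrion counts. When every instance carries a grade the
#' per-grade counts are checked to sum exactly to the total (integer
#' arithmetic).
#'
#' @param records Per-instance data frame ([measure_dataset()] `$records`).
#' @param cells Optional per-cell data frame.
#' @param n_patients Optional patient count carried through.
#' @return A `dataset_summary` list: `n_patients`, `n_images`, `n_cells`,
#'   `n_instances_total`, `n_instances_per_grade`.
#' @export
summarize_dataset <- function(records, cells = NULL, n_patients = NA_integer_) {
  per_grade <- table(factor(records$grade, levels = 1:4))
  total <- nrow(records)
  if (total && !anyNA(records$grade)) {
    stopifnot(sum(per_grade) == total)
  }
  structure(list(
    n_patients = n_patients,
    n_images = length(unique(records$image_id)),
    n_cells = if (!is.null(cells)) nrow(cells) else if ("cell_id" %in% names(records)) {
      ok <- !is.na(records$cell_id)
      length(unique(paste(records$image_id[ok], records$cell_id[ok])))
    } else 0L,
    n_instances_total = total,
    n_instances_per_grade = as.integer(per_grade)),
    class = "dataset_summary")
}

#' @export
print.dataset_summary <- function(x, ...) {
  cat(sprintf("<dataset_summary> %s patients, %d images, %d cells, %d mitochondria\n",
              ifelse(is.na(x$n_patients), "?", x$n_patients), x$n_images,
              x$n_cells, x$n_instances_total))
  cat("  per grade:", paste(sprintf("g%d=%d", 1:4, x$n_instances_per_grade),
                            collapse = ", "), "\n")
  invisible(x)
}

#' Min--max normalized group means for a radar display
#'
#' Computes the LGG/HGG group mean of each metric and rescales each metric
#' across groups to \[0, 1\] by min--max over the group means (so with two
#' groups the smaller mean maps to 0 and the larger to 1). A metric whose
#' group means coincide is mapped to 0.5 and listed in the
#' `"constant_metrics"` attribute. Optionally draws a simple base-graphics
#' radar chart.
#'
#' @param records Per-instance data frame with `grade`.
#' @param cells Optional per-cell data frame (contributes
#'   `density_per_um2` and `area_ratio`).
#' @param metrics Metrics to include; defaults to the five indices that are
#'   available in the inputs.
#' @param plot Draw the radar chart.
#' @return Data frame: `metric`, one raw-mean and one normalized column per
#'   group.
#' @export
radar_summary <- function(records, cells = NULL, metrics = NULL, plot = FALSE) {
  sources <- list(instance = records)
  if (!is.null(cells)) sources$cell <- cells
  candidates <- c(area_um2 = "instance", perimeter_um = "instance",
                  circularity = "instance", cristae_occupancy = "instance",
                  density_per_um2 = "cell", area_ratio = "cell")
  if (is.null(metrics)) {
    metrics <- names(candidates)[vapply(names(candidates), function(m) {
      src <- sources[[candidates[[m]]]]
      !is.null(src) && m %in% names(src) && any(!is.na(src[[m]]))
    }, logical(1))]
  }
  if (!length(metrics)) stop("no usable metrics", call. = FALSE)
  constant <- character(0)
  rows <- lapply(metrics, function(m) {
    src <- sources[[candidates[[m]] %||% "instance"]]
    grp <- assign_grade_group(src$grade)
    ok <- !is.na(grp) & !is.na(src[[m]])
    if (!any(ok)) stop("metric `", m, "` has no graded values", call. = FALSE)
    means <- tapply(src[[m]][ok], droplevels(grp[ok]), mean)
    if (length(means) < 2L) stop("need records in both groups", call. = FALSE)
    rng <- range(means)
    norm <- if (diff(rng) == 0) {
      constant <<- c(constant, m)
      stats::setNames(rep(0.5, length(means)), names(means))
    } else (means - rng[1L]) / diff(rng)
    data.frame(metric = m, mean_LGG = means[["LGG"]], mean_HGG = means[["HGG"]],
               norm_LGG = unname(norm["LGG"]), norm_HGG = unname(norm["HGG"]),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "constant_metrics") <- constant
  if (plot) .radar_plot(out)
  out
}

.radar_plot <- function(tab) {
  k <- nrow(tab)
  ang <- seq(0, 2 * pi, length.out = k + 1L)[-(k + 1L)] + pi / 2
  graphics::plot.new()
  graphics::plot.window(c(-1.4, 1.4), c(-1.4, 1.4), asp = 1)
  for (r in c(0.5, 1)) {
    graphics::polygon(r * cos(ang), r * sin(ang), border = "grey80")
  }
  cols <- c(norm_LGG = "#2166ac", norm_HGG = "#b2182b")
  for (g in names(cols)) {
    v <- tab[[g]]
    graphics::polygon(v * cos(ang), v * sin(ang), border = cols[[g]],
                      col = grDevices::adjustcolor(cols[[g]], 0.2))
  }
  graphics::text(1.25 * cos(ang), 1.25 * sin(ang), tab$metric, cex = 0.8)
  graphics::legend("topright", legend = c("LGG", "HGG"), col = cols, lwd = 2,
                   bty = "n")
  invisible(tab)
}
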