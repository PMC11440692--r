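# Three-type cristae-health classification and LGG/HGG grade grouping.
#
# The three types describe mitochondrial respiratory cristae (MRC) and
# outer-membrane (OMM) state: Type 1 = dense, orderly cristae with intact
# OMM; Type 2 = sparse or disorganized cristae, possibly with a disrupted
# OMM; Type 3 = vanished cristae, often with a ruptured OMM. Human typing
# is visual; the thresholded proxy below operationalizes it for synthetic
# pipelines from cristae occupancy and the OMM flag, and human-assigned
# labels always take precedence when present.

#' Rule-based proxy for the three-type MRC classification
#'
#' Decision table (defaults `t_low = 0.10`, `t_high = 0.50`; boundary values
#' classify upward, i.e. toward the healthier type):
#' \itemize{
#'   \item occupancy `< t_low` -> `TYPE3`;
#'   \item occupancy `>= t_high` with OMM intact (or unknown) -> `TYPE1`;
#'   \item anything else with occupancy present -> `TYPE2`;
#'   \item occupancy absent: OMM intact -> `TYPE2` (dense cristae cannot be
#'     confirmed), OMM ruptured -> `TYPE3`; both absent -> `NA`.
#' }
#' The rule is deterministic and monotone in occupancy for a fixed OMM
#' state. These thresholds are a package-level operationalization, not a
#' clinically validated criterion.
#'
#' @param occupancy Numeric vector of cristae occupancies in \[0, 1\]
#'   (`NA` = not annotated).
#' @param omm_intact Logical vector (`NA` = not annotated); recycled.
#' @param t_low,t_high Thresholds with `0 <= t_low < t_high <= 1`.
#' @return Factor with levels `TYPE1`, `TYPE2`, `TYPE3` (NA when neither
#'   input is available).
#' @examples
#' classify_mrc_type(c(0.8, 0.05), c(TRUE, FALSE))
#' @export
classify_mrc_type <- function(occupancy, omm_intact = NA,
                              t_low = 0.10, t_high = 0.50) {
  if (!is.numeric(c(t_low, t_high)) || is.na(t_low) || is.na(t_high) ||
      t_low < 0 || t_high > 1 || t_low >= t_high) {
    stop("thresholds must satisfy 0 <= t_low < t_high <= 1", call. = FALSE)
  }
  n <- max(length(occupancy), length(omm_intact))
  occupancy <- rep_len(as.numeric(occupancy), n)
  omm_intact <- rep_len(as.logical(omm_intact), n)
  if (any(occupancy < 0 | occupancy > 1, na.rm = TRUE)) {
    stop("occupancy must lie in [0, 1]", call. = FALSE)
  }
  out <- character(n)
  has_occ <- !is.na(occupancy)
  out[has_occ & occupancy < t_low] <- "TYPE3"
  out[has_occ & occupancy >= t_high &
        (is.na(omm_intact) | omm_intact)] <- "TYPE1"
  out[has_occ & out == ""] <- "TYPE2"
  out[!has_occ & !is.na(omm_intact) & omm_intact] <- "TYPE2"
  out[!has_occ & !is.na(omm_intact) & !omm_intact] <- "TYPE3"
  out[out == ""] <- NA_character_
  factor(out, levels = c("TYPE1", "TYPE2", "TYPE3"))
}

#' Attach MRC types to a measurement table
#'
#' Human-assigned labels in a `mrc_type` column override the proxy; records
#' without a label are typed from `cristae_occupancy` and `omm_intact` via
#' [classify_mrc_type()].
#'
#' @param records Data frame from [measure_instances()]/[measure_dataset()].
#' @param t_low,t_high Proxy thresholds.
#' @return `records` with a factor column `mrc_type_label`.
#' @export
classify_instances <- function(records, t_low = 0.10, t_high = 0.50) {
  proxy <- classify_mrc_type(records$cristae_occupancy, records$omm_intact,
                             t_low = t_low, t_high = t_high)
  lv <- levels(proxy)
  manual <- if ("mrc_type" %in% names(records)) records$mrc_type else
    rep(NA_integer_, nrow(records))
  out <- ifelse(!is.na(manual), lv[manual], as.character(proxy))
  records$mrc_type_label <- factor(out, levels = lv)
  records
}

#' Map WHO grade to the LGG/HGG dichotomy
#'
#' Grades 1 and 2 are low-grade glioma (LGG); grades 3 and 4 high-grade
#' glioma (HGG). Any other grade is an error.
#'
#' @param grade Integer vector of WHO grades.
#' @return Factor with levels `LGG`, `HGG` (`NA` passes through as `NA`).
#' @examples
#' assign_grade_group(c(1, 2, 3, 4))
#' @export
assign_grade_group <- function(grade) {
  g <- as.integer(grade)
  bad <- !is.na(g) & !g %in% 1:4
  if (any(bad)) {
    stop("invalid WHO grade(s): ", paste(unique(g[bad]), collapse = ", "),
         call. = FALSE)
  }
  factor(ifelse(is.na(g), NA_character_, ifelse(g <= 2L, "LGG", "HGG")),
         levels = c("LGG", "HGG"))
}

#' Per-group composition of the three MRC types
#'
#' Proportions of Types 1--3 per WHO grade or per LGG/HGG group; rows sum
#' to 1. Groups without typed records are excluded and listed in the
#' `"excluded"` attribute.
#'
#' @param records Data frame with a `mrc_type_label` column (see
#'   [classify_instances()]) and a `grade` column.
#' @param by `"grade"` or `"group"` (LGG/HGG).
#' @return Data frame with columns `group`, `n`, `TYPE1`, `TYPE2`, `TYPE3`.
#' @export
type_composition <- function(records, by = c("group", "grade")) {
  by <- match.arg(by)
  if (!"mrc_type_label" %in% names(records)) {
    stop("records lack `mrc_type_label`; run classify_instances() first",
         call. = FALSE)
  }
  key <- if (by == "grade") factor(records$grade, levels = 1:4) else
    assign_grade_group(records$grade)
  keep <- !is.na(key) & !is.na(records$mrc_type_label)
  tab <- table(key[keep], records$mrc_type_label[keep])
  n <- rowSums(tab)
  excluded <- rownames(tab)[n == 0]
  tab <- tab[n > 0, , drop = FALSE]
  out <- data.frame(group = rownames(tab), n = as.integer(rowSums(tab)),
                    as.data.frame.matrix(tab / rowSums(tab)),
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  attr(out, "excluded") <- excluded
  out
}
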