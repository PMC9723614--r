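#' Empirical false discovery rate as a function of call threshold
#'
#' On control material known to be unmodified, every call is a false call, so
#' the fraction of statistics falling below a threshold is the empirical
#' false discovery rate of calling at that threshold. Evaluated on a grid,
#' this gives the calibration curve used to pick an operating threshold.
#'
#' @param control A [stat_matrix()] of control (unmodified) reads.
#' @param thresholds Numeric grid in `[0, 1]`.
#' @return A tibble with columns `threshold` and `fdr`, ordered by threshold;
#'   `fdr` is monotone non-decreasing.
#' @examples
#' ctrl <- stat_matrix(matrix(runif(200), 10, 20))
#' fdr_curve(ctrl, seq(0.05, 0.5, by = 0.05))
#' @export
fdr_curve <- function(control, thresholds = seq(0.05, 0.95, by = 0.05)) {
  stopifnot(inherits(control, "stat_matrix"))
  stopifnot(all(thresholds >= 0), all(thresholds <= 1))
  stats_vec <- unclass(control)[!is.na(unclass(control))]
  if (!length(stats_vec)) {
    abort("control matrix has no non-missing statistics",
          class = "smstruct_value_error")
  }
  thresholds <- sort(unique(thresholds))
  tibble(
    threshold = thresholds,
    fdr = vapply(thresholds, function(t) mean(stats_vec < t), 0)
  )
}

#' Select the operating threshold from an FDR curve
#'
#' Returns the largest grid threshold whose empirical FDR does not exceed the
#' target (no interpolation between grid points).
#'
#' @param curve Tibble from [fdr_curve()].
#' @param target_fdr Acceptable false discovery rate; default `0.15`.
#' @return Numeric threshold.
#' @export
select_threshold <- function(curve, target_fdr = 0.15) {
  stopifnot(is.data.frame(curve), nrow(curve) >= 1)
  ok <- curve$fdr <= target_fdr
  if (!any(ok)) {
    abort(sprintf(
      "no grid threshold achieves FDR <= %.3g (smallest achievable FDR is %.3g at threshold %.3g)",
      target_fdr, min(curve$fdr), curve$threshold[which.min(curve$fdr)]
    ), class = "smstruct_value_error")
  }
  max(curve$threshold[ok])
}

#' Call per-read modifications from continuous statistics
#'
#' A base on a read is called modified when its statistic is strictly below
#' the threshold; missing statistics propagate to missing calls.
#'
#' @param stats A [stat_matrix()].
#' @param threshold Call threshold in `(0, 1]`; default `0.2`.
#' @return A [mod_matrix()] with `threshold_used` recorded.
#' @export
call_modifications <- function(stats, threshold = 0.2) {
  stopifnot(inherits(stats, "stat_matrix"))
  stopifnot(is.numeric(threshold), length(threshold) == 1,
            threshold > 0, threshold <= 1)
  calls <- (unclass(stats) < threshold) * 1
  m <- mod_matrix(calls, reference = attr(stats, "reference"),
                  threshold_used = threshold)
  m
}

#' Filter reads by modification count
#'
#' Reads with too few modifications carry little structural signal; reads
#' with too many are over-modified. Default bounds (keep 4-18, inclusive)
#' are calibrated for a short hairpin construct and should be adjusted to
#' the probed molecule.
#'
#' @param m A [mod_matrix()].
#' @param min_mods,max_mods Inclusive bounds on the per-read count.
#' @return Filtered [mod_matrix()]; warns (does not error) when no read
#'   survives.
#' @export
filter_reads <- function(m, min_mods = 4L, max_mods = 18L) {
  stopifnot(inherits(m, "mod_matrix"))
  stopifnot(min_mods >= 0, max_mods >= min_mods)
  counts <- modification_counts(m)
  keep <- counts >= min_mods & counts <= max_mods
  if (!any(keep)) {
    warn("all reads removed by modification-count filter")
  }
  m[keep, , drop = FALSE]
}

#' Per-position consensus modification frequency
#'
#' Mean call over non-missing cells at each position — the population-average
#' reactivity profile that consensus methods report.
#'
#' @param m A [mod_matrix()].
#' @return A tibble with columns `position`, `frequency` (NA where no read
#'   covers the position) and `n_reads`.
#' @export
consensus_frequency <- function(m) {
  stopifnot(inherits(m, "mod_matrix"), nrow(m) >= 1)
  x <- unclass(m)
  n <- colSums(!is.na(x))
  freq <- ifelse(n > 0, colMeans(x, na.rm = TRUE), NA_real_)
  tibble(position = seq_len(ncol(x)), frequency = as.numeric(freq),
         n_reads = as.integer(n))
}

#' Correct an observed modification rate for false calls
#'
#' With an empirical false-call fraction `fdr`, the estimated real rate is
#' `observed_rate * (1 - fdr)`.
#'
#' @param observed_rate,fdr Proportions in `[0, 1]`.
#' @return Corrected rate.
#' @examples
#' corrected_rate(0.31, 0.15)  # 0.2635, reported as ~26%
#' @export
corrected_rate <- function(observed_rate, fdr) {
  stopifnot(all(observed_rate >= 0 & observed_rate <= 1),
            all(fdr >= 0 & fdr <= 1))
  observed_rate * (1 - fdr)
}

#' ROC curve and AUC
#'
#' AUC is the probability that a randomly chosen positive outranks a randomly
#' chosen negative, with ties credited one half (equivalently the trapezoidal
#' area under the ROC curve).
#'
#' @param scores Numeric scores.
#' @param labels Binary truth (0/1 or logical), same length.
#' @param higher_is_modified If `FALSE` (default here is `TRUE`), low scores
#'   indicate the positive class and scores are negated internally.
#' @return An object of class `sms_roc`: list with `points` (tibble of `fpr`,
#'   `tpr`, `threshold`) and `auc`.
#' @export
roc_auc <- function(scores, labels, higher_is_modified = TRUE) {
  stopifnot(length(scores) == length(labels))
  keep <- !is.na(scores) & !is.na(labels)
  scores <- scores[keep]
  labels <- as.integer(labels[keep])
  stopifnot(all(labels %in% 0:1))
  if (length(unique(labels)) < 2L) {
    abort("both classes must be present", class = "smstruct_value_error")
  }
  if (!higher_is_modified) scores <- -scores
  # rank-sum AUC with midranks handles ties at half credit
  r <- rank(scores, ties.method = "average")
  n_pos <- as.numeric(sum(labels == 1))
  n_neg <- as.numeric(sum(labels == 0))
  auc <- (sum(r[labels == 1]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
  ord <- order(scores, decreasing = TRUE)
  tp <- cumsum(labels[ord] == 1)
  fp <- cumsum(labels[ord] == 0)
  uniq <- c(which(diff(scores[ord]) != 0), length(scores))
  points <- tibble(
    threshold = c(Inf, scores[ord][uniq]),
    tpr = c(0, tp[uniq] / n_pos),
    fpr = c(0, fp[uniq] / n_neg)
  )
  structure(list(points = points, auc = auc), class = "sms_roc")
}

#' @export
print.sms_roc <- function(x, ...) {
  cat(sprintf("<sms_roc> AUC = %.4f (%d operating points)\n",
              x$auc, nrow(x$points)))
  invisible(x)
}

#' Read-level sensitivity and specificity against a known structure
#'
#' Treats the structure's open positions as the positive class and evaluates
#' every non-missing read-by-position cell within the probed-base mask:
#' sensitivity is the fraction of open cells called modified, specificity the
#' fraction of paired cells called unmodified.
#'
#' @param m A [mod_matrix()].
#' @param truth An [rna_structure][parse_dotbracket] of the same length.
#' @param base_mask Positions to evaluate (default: adenosines of the
#'   structure's sequence if available, otherwise all positions).
#' @return A tibble with one row: `sensitivity`, `specificity`, `n_open`,
#'   `n_paired` (cell counts evaluated).
#' @export
read_level_confusion <- function(m, truth, base_mask = NULL) {
  stopifnot(inherits(m, "mod_matrix"), inherits(truth, "rna_structure"))
  if (ncol(m) != length(truth)) {
    abort("matrix width and structure length differ",
          class = "smstruct_value_error")
  }
  if (is.null(base_mask)) {
    base_mask <- if (!is.null(truth$sequence)) {
      adenosine_positions(truth$sequence)
    } else {
      seq_len(ncol(m))
    }
  }
  if (!length(base_mask)) {
    abort("base mask is empty", class = "smstruct_value_error")
  }
  open_cols <- intersect(base_mask, truth$open_set)
  paired_cols <- setdiff(base_mask, truth$open_set)
  x <- unclass(m)
  open_cells <- as.vector(x[, open_cols, drop = FALSE])
  paired_cells <- as.vector(x[, paired_cols, drop = FALSE])
  open_cells <- open_cells[!is.na(open_cells)]
  paired_cells <- paired_cells[!is.na(paired_cells)]
  tibble(
    sensitivity = if (length(open_cells)) mean(open_cells == 1) else NA_real_,
    specificity = if (length(paired_cells)) mean(paired_cells == 0) else NA_real_,
    n_open = length(open_cells),
    n_paired = length(paired_cells)
  )
}

#' @export
#' @method autoplot sms_roc
autoplot.sms_roc <- function(object, ...) {
  ggplot2::ggplot(object$points, ggplot2::aes(x = .data$fpr, y = .data$tpr)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dotted") +
    ggplot2::geom_step() +
    ggplot2::coord_equal() +
    ggplot2::labs(
      x = "False positive rate", y = "True positive rate",
      title = sprintf("ROC (AUC = %.3f)", object$auc)
    ) +
    ggplot2::theme_minimal()
}
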