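#' Log2 fold change in accessibility between two conditions
#'
#' Haldane-Anscombe-smoothed log ratio of per-position modification rates:
#' `log2(((kA + pseudo) / (nA + 2 pseudo)) / ((kB + pseudo) / (nB + 2 pseudo)))`.
#'
#' @param kA,nA Modified and total read counts in condition A (vectorized).
#' @param kB,nB Same for condition B.
#' @param pseudo Pseudocount, default 0.5.
#' @return Numeric log2 fold change(s); `NA` where either condition has no
#'   coverage.
#' @export
log2_fold_accessibility <- function(kA, nA, kB, nB, pseudo = 0.5) {
  stopifnot(all(kA <= nA, na.rm = TRUE), all(kB <= nB, na.rm = TRUE))
  out <- log2(((kA + pseudo) / (nA + 2 * pseudo)) /
                ((kB + pseudo) / (nB + 2 * pseudo)))
  out[nA == 0 | nB == 0] <- NA_real_
  out
}

#' Cochran-Mantel-Haenszel test for stratified 2x2 tables
#'
#' Tests association between modification state and condition across strata
#' (replicates), without continuity correction: the statistic is
#' `(sum_k (a_k - E_k))^2 / sum_k V_k` with hypergeometric mean `E_k` and
#' variance `V_k` per stratum, referred to chi-square with 1 df. For a
#' single stratum this equals `(N - 1) / N` times the Pearson chi-square.
#'
#' @param tables A 2x2xK array, or a list of 2x2 matrices (rows: modified /
#'   unmodified; columns: condition A / B).
#' @return A one-row tibble with `statistic`, `p.value`, `df`, `n_strata`;
#'   `p.value` is `NA` when the total variance is zero.
#' @export
cmh_test <- function(tables) {
  if (is.list(tables)) {
    tables <- array(unlist(tables), dim = c(2, 2, length(tables)))
  }
  stopifnot(length(dim(tables)) == 3, all(dim(tables)[1:2] == 2))
  if (any(tables < 0)) abort("counts must be non-negative",
                             class = "smstruct_value_error")
  K <- dim(tables)[3]
  dev <- 0
  v <- 0
  informative <- 0L
  for (k in seq_len(K)) {
    t2 <- tables[, , k]
    N <- sum(t2)
    if (N < 2) next
    informative <- informative + 1L
    r1 <- sum(t2[1, ]); r2 <- sum(t2[2, ])
    c1 <- sum(t2[, 1]); c2 <- sum(t2[, 2])
    dev <- dev + t2[1, 1] - r1 * c1 / N
    v <- v + r1 * r2 * c1 * c2 / (N^2 * (N - 1))
  }
  if (informative == 0L) {
    abort("no informative stratum (need a stratum with N >= 2)",
          class = "smstruct_value_error")
  }
  if (v == 0) {
    return(tibble(statistic = NA_real_, p.value = NA_real_, df = 1L,
                  n_strata = informative))
  }
  stat <- dev^2 / v
  tibble(statistic = stat, p.value = pchisq(stat, df = 1, lower.tail = FALSE),
         df = 1L, n_strata = informative)
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up FDR adjustment; a thin validated wrapper over
#' `stats::p.adjust(method = "BH")` so that all q-values in the package flow
#' through one audited entry point.
#'
#' @param pvalues Numeric vector in `[0, 1]` (`NA` allowed, left `NA`).
#' @return q-values, same length; each `q >= p` and `q <= 1`.
#' @export
bh_adjust <- function(pvalues) {
  ok <- pvalues[!is.na(pvalues)]
  if (length(ok) && (min(ok) < 0 || max(ok) > 1)) {
    abort("p-values must lie in [0, 1]", class = "smstruct_value_error")
  }
  p.adjust(pvalues, method = "BH")
}

#' Per-position differential accessibility scan between two conditions
#'
#' For every probed position, counts modified vs unmodified reads in each
#' condition within each replicate, tests association with the
#' Cochran-Mantel-Haenszel test using replicates as strata, attaches the
#' pooled log2 fold change and adjusts p-values across positions with
#' Benjamini-Hochberg.
#'
#' @param mods_a,mods_b Lists of [mod_matrix()] replicates (same width); the
#'   k-th matrices of the two lists form stratum k.
#' @param positions Positions to test (default: positions covered in every
#'   replicate of both conditions).
#' @param q_cut Significance cutoff on the q-value, default 0.1.
#' @param pseudo Pseudocount for the fold change.
#' @return An object of classes `sms_diff` and `tbl_df`: one row per tested
#'   position with `position`, `log2fc`, `statistic`, `p`, `q`,
#'   `significant`, plus the pooled counts.
#' @export
differential_scan <- function(mods_a, mods_b, positions = NULL, q_cut = 0.1,
                              pseudo = 0.5) {
  if (inherits(mods_a, "mod_matrix")) mods_a <- list(mods_a)
  if (inherits(mods_b, "mod_matrix")) mods_b <- list(mods_b)
  stopifnot(length(mods_a) >= 1, length(mods_a) == length(mods_b))
  widths <- vapply(c(mods_a, mods_b), ncol, 0L)
  if (length(unique(widths)) != 1L) {
    abort("all matrices must share the reference width",
          class = "smstruct_value_error")
  }
  L <- widths[1]
  covered <- function(m) colSums(!is.na(unclass(m))) > 0
  if (is.null(positions)) {
    cov_all <- Reduce(`&`, lapply(c(mods_a, mods_b), covered))
    positions <- which(cov_all)
  }
  if (!length(positions)) {
    abort("no shared covered positions to test", class = "smstruct_value_error")
  }
  K <- length(mods_a)
  count_pos <- function(m, pos) {
    x <- unclass(m)[, pos, drop = FALSE]
    list(k = colSums(x == 1, na.rm = TRUE), n = colSums(!is.na(x)))
  }
  ca <- lapply(mods_a, count_pos, pos = positions)
  cb <- lapply(mods_b, count_pos, pos = positions)
  res <- purrr::map_dfr(seq_along(positions), function(idx) {
    tabs <- lapply(seq_len(K), function(k) {
      matrix(c(ca[[k]]$k[idx], ca[[k]]$n[idx] - ca[[k]]$k[idx],
               cb[[k]]$k[idx], cb[[k]]$n[idx] - cb[[k]]$k[idx]), nrow = 2)
    })
    test <- cmh_test(tabs)
    kA <- sum(vapply(ca, function(z) z$k[idx], 0))
    nA <- sum(vapply(ca, function(z) z$n[idx], 0))
    kB <- sum(vapply(cb, function(z) z$k[idx], 0))
    nB <- sum(vapply(cb, function(z) z$n[idx], 0))
    tibble(
      position = positions[idx],
      k_a = kA, n_a = nA, k_b = kB, n_b = nB,
      log2fc = log2_fold_accessibility(kA, nA, kB, nB, pseudo = pseudo),
      statistic = test$statistic, p = test$p.value
    )
  })
  res$q <- bh_adjust(res$p)
  res$significant <- !is.na(res$q) & res$q < q_cut
  class(res) <- c("sms_diff", class(res))
  attr(res, "q_cut") <- q_cut
  res
}

#' @export
#' @method autoplot sms_diff
autoplot.sms_diff <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$position, y = .data$log2fc,
                                       fill = .data$significant)) +
    ggplot2::geom_col() +
    ggplot2::scale_fill_manual(values = c(`FALSE` = "grey60",
                                          `TRUE` = "firebrick")) +
    ggplot2::labs(x = "position", y = "log2 fold change in accessibility",
                  fill = sprintf("q < %.2g", attr(object, "q_cut") %||% 0.1)) +
    ggplot2::theme_minimal()
}
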