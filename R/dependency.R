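#' Joint modification counts for a pair of positions
#'
#' Counts the four joint states over reads where both positions are
#' non-missing. `n11` counts reads modified at both, `n10` modified at `i`
#' only, `n01` at `j` only, `n00` at neither; `n` is their sum.
#'
#' @param m A [mod_matrix()].
#' @param i,j Distinct positions (1-based).
#' @return A one-row tibble `n11, n10, n01, n00, n`.
#' @export
pair_counts <- function(m, i, j) {
  stopifnot(inherits(m, "mod_matrix"), i != j)
  x <- unclass(m)
  u <- x[, i]
  v <- x[, j]
  keep <- !is.na(u) & !is.na(v)
  u <- u[keep]
  v <- v[keep]
  tibble(
    n11 = sum(u == 1 & v == 1), n10 = sum(u == 1 & v == 0),
    n01 = sum(u == 0 & v == 1), n00 = sum(u == 0 & v == 0),
    n = length(u)
  )
}

#' Mutual information of a 2x2 contingency table
#'
#' MI between the two binary modification-state partitions, in nats:
#' `sum over cells of (n_ab/N) * log(N * n_ab / (n_a. * n_.b))` over non-zero
#' cells. Natural logarithm throughout.
#'
#' @param counts One-row tibble or list with `n11, n10, n01, n00` (a
#'   [pair_counts()] row).
#' @return MI in nats (non-negative).
#' @export
mutual_information <- function(counts) {
  tab <- pc_table(counts)
  N <- sum(tab)
  stopifnot(N >= 1)
  rs <- rowSums(tab)
  cs <- colSums(tab)
  mi <- 0
  for (a in 1:2) for (b in 1:2) {
    nab <- tab[a, b]
    if (nab > 0) mi <- mi + (nab / N) * log(N * nab / (rs[a] * cs[b]))
  }
  max(mi, 0)
}

pc_table <- function(counts) {
  if (is.data.frame(counts)) counts <- as.list(counts[1, ])
  matrix(c(counts$n11, counts$n01, counts$n10, counts$n00), nrow = 2,
         dimnames = list(U = c("1", "0"), V = c("1", "0")))
}

#' Expected mutual information under the permutation (hypergeometric) null
#'
#' Expectation of [mutual_information()] over all 2x2 tables with the
#' observed margins, where the joint cell count follows the hypergeometric
#' distribution induced by randomly permuting one column against the other.
#' This is the chance-agreement term of the adjusted mutual information.
#'
#' @inheritParams mutual_information
#' @return Expected MI in nats.
#' @export
expected_mi <- function(counts) {
  tab <- pc_table(counts)
  N <- sum(tab)
  stopifnot(N >= 1)
  rs <- rowSums(tab)
  cs <- colSums(tab)
  emi <- 0
  for (a in 1:2) for (b in 1:2) {
    ra <- rs[a]
    cb <- cs[b]
    if (ra == 0 || cb == 0) next
    lo <- max(1, ra + cb - N)
    hi <- min(ra, cb)
    if (lo > hi) next
    k <- lo:hi
    term <- (k / N) * log(N * k / (ra * cb))
    emi <- emi + sum(term * dhyper(k, cb, N - cb, ra))
  }
  emi
}

#' Shannon entropy of a binary partition, in nats
#' @noRd
binary_entropy <- function(n1, n0) {
  N <- n1 + n0
  p <- c(n1, n0) / N
  p <- p[p > 0]
  -sum(p * log(p))
}

#' Adjusted mutual information of a 2x2 contingency table
#'
#' Chance-corrected MI: `(MI - E[MI]) / (avg(H(U), H(V)) - E[MI])`, entropies
#' in nats. Equals 1 for identical non-constant columns and concentrates near
#' 0 for independent columns. By convention a pair where either column is
#' constant scores 0 (the denominator degenerates; zero information is the
#' honest value).
#'
#' @inheritParams mutual_information
#' @return AMI (dimensionless, at most 1).
#' @export
adjusted_mi <- function(counts) {
  tab <- pc_table(counts)
  N <- sum(tab)
  stopifnot(N >= 1)
  rs <- rowSums(tab)
  cs <- colSums(tab)
  hu <- binary_entropy(rs[1], rs[2])
  hv <- binary_entropy(cs[1], cs[2])
  if (hu == 0 || hv == 0) return(0)
  mi <- mutual_information(counts)
  emi <- expected_mi(counts)
  denom <- (hu + hv) / 2 - emi
  # guard against cancellation when the mean entropy is at chance level
  eps <- .Machine$double.eps
  denom <- if (denom < 0) min(denom, -eps) else max(denom, eps)
  (mi - emi) / denom
}

#' Co-openness and co-agreement of a position pair
#'
#' `co_openness()` is the probability that both bases are modified given
#' that at least one is: `n11 / (n11 + n10 + n01)` — a symmetric realization
#' of "one base is modified given that the other is". The directional
#' conditionals are available via `directional = TRUE`. `co_agreement()` is
#' the fraction of reads in which the pair share the same state:
#' `(n11 + n00) / n`.
#'
#' @inheritParams mutual_information
#' @param directional If `TRUE`, return a tibble with the two directional
#'   conditionals `p_j_given_i`, `p_i_given_j` alongside the symmetric value.
#' @return Numeric scalar (or tibble when `directional = TRUE`); `NA` when no
#'   read has either base modified.
#' @export
co_openness <- function(counts, directional = FALSE) {
  if (is.data.frame(counts)) counts <- as.list(counts[1, ])
  any_mod <- counts$n11 + counts$n10 + counts$n01
  sym <- if (any_mod >= 1) counts$n11 / any_mod else NA_real_
  if (!directional) return(sym)
  ni <- counts$n11 + counts$n10
  nj <- counts$n11 + counts$n01
  tibble(
    co_open = sym,
    p_j_given_i = if (ni >= 1) counts$n11 / ni else NA_real_,
    p_i_given_j = if (nj >= 1) counts$n11 / nj else NA_real_
  )
}

#' @rdname co_openness
#' @export
co_agreement <- function(counts) {
  if (is.data.frame(counts)) counts <- as.list(counts[1, ])
  N <- counts$n11 + counts$n10 + counts$n01 + counts$n00
  stopifnot(N >= 1)
  (counts$n11 + counts$n00) / N
}

#' Z-score a pairwise statistic within each pair distance
#'
#' Bases in close proximity share signal for technical reasons (the pore
#' reads several bases at once), so raw pairwise statistics are normalized
#' within each distance class `d = |i - j|`: each value is replaced by its
#' z-score against the mean and population standard deviation of all
#' non-missing values at the same distance. Distances with fewer than
#' `min_pairs` values, or zero spread, map to 0.
#'
#' @param values Symmetric numeric matrix with `NA` allowed; the diagonal is
#'   ignored.
#' @param min_pairs Minimum number of pairs per distance class (default 2).
#' @return Matrix of the same shape; `NA` cells stay `NA`.
#' @export
distance_zscore <- function(values, min_pairs = 2L) {
  stopifnot(is.matrix(values), nrow(values) == ncol(values))
  n <- nrow(values)
  out <- matrix(NA_real_, n, n, dimnames = dimnames(values))
  if (n < 2) return(out)
  idx <- which(upper.tri(values), arr.ind = TRUE)
  d <- idx[, 2] - idx[, 1]
  v <- values[idx]
  for (dist in unique(d)) {
    sel <- d == dist & !is.na(v)
    if (!any(sel)) next
    xs <- v[sel]
    mu <- mean(xs)
    sigma <- sqrt(mean((xs - mu)^2))  # population sd
    z <- if (length(xs) < min_pairs || sigma == 0) {
      rep(0, length(xs))
    } else {
      (xs - mu) / sigma
    }
    ii <- idx[sel, , drop = FALSE]
    out[ii] <- z
    out[ii[, c(2, 1), drop = FALSE]] <- z
  }
  out
}

#' Pairwise co-dependency map of a modification matrix
#'
#' Computes, for every eligible position pair, the adjusted mutual
#' information, co-openness and co-agreement, plus their distance-z-scored
#' forms (`dami`, `z_co_open`, `z_co_agree`). A pair is eligible when at
#' least `min_reads` reads cover both positions; the distance-normalized AMI
#' (dAMI) additionally excludes pairs where either column is constant, since
#' those carry no information to normalize.
#'
#' @param m A [mod_matrix()].
#' @param min_reads Minimum joint coverage per pair (default 10).
#' @param positions Positions to include (default: all with any coverage).
#' @param min_pairs_per_distance Passed to [distance_zscore()].
#' @return An object of class `sms_depmap`: list of symmetric matrices
#'   (`ami`, `co_open`, `co_agree`, `dami`, `z_co_open`, `z_co_agree`, `n`)
#'   over `positions`. Use [tidy()] for the long tibble form and
#'   [autoplot()] for a heatmap.
#' @export
dependency_map <- function(m, min_reads = 10L, positions = NULL,
                           min_pairs_per_distance = 2L) {
  stopifnot(inherits(m, "mod_matrix"))
  x <- unclass(m)
  if (is.null(positions)) {
    positions <- which(colSums(!is.na(x)) > 0)
  }
  if (length(positions) < 2L) {
    abort("need at least two positions with coverage",
          class = "smstruct_value_error")
  }
  p <- length(positions)
  xm <- x[, positions, drop = FALSE]
  obs <- !is.na(xm)
  xz <- xm
  xz[!obs] <- 0
  # joint-count matrices by cross products of indicator matrices
  N <- crossprod(obs * 1)             # reads covering both
  n11 <- crossprod(xz)                # both modified
  ni <- crossprod(xz, obs * 1)        # i modified, j covered
  n10 <- ni - n11
  n01 <- t(ni) - n11
  n00 <- N - n11 - n10 - n01

  dimn <- list(positions, positions)
  mk <- function() matrix(NA_real_, p, p, dimnames = dimn)
  ami <- mk(); co_open <- mk(); co_agree <- mk()
  constant_pair <- matrix(FALSE, p, p)
  for (a in seq_len(p - 1)) {
    for (b in (a + 1):p) {
      if (N[a, b] < min_reads) next
      pc <- list(n11 = n11[a, b], n10 = n10[a, b],
                 n01 = n01[a, b], n00 = n00[a, b])
      const <- (pc$n11 + pc$n10) %in% c(0, N[a, b]) ||
        (pc$n11 + pc$n01) %in% c(0, N[a, b])
      constant_pair[a, b] <- constant_pair[b, a] <- const
      ami[a, b] <- ami[b, a] <- if (const) 0 else adjusted_mi(pc)
      co_open[a, b] <- co_open[b, a] <- co_openness(pc)
      co_agree[a, b] <- co_agree[b, a] <- co_agreement(pc)
    }
  }
  ami_for_z <- ami
  ami_for_z[constant_pair] <- NA_real_
  res <- list(
    positions = positions,
    ami = ami, co_open = co_open, co_agree = co_agree,
    dami = distance_zscore(ami_for_z, min_pairs = min_pairs_per_distance),
    z_co_open = distance_zscore(co_open, min_pairs = min_pairs_per_distance),
    z_co_agree = distance_zscore(co_agree, min_pairs = min_pairs_per_distance),
    n = matrix(N, p, p, dimnames = dimn),
    min_reads = min_reads
  )
  class(res) <- "sms_depmap"
  res
}

#' @export
print.sms_depmap <- function(x, ...) {
  n_elig <- sum(!is.na(x$ami[upper.tri(x$ami)]))
  cat(sprintf("<sms_depmap> %d positions, %d eligible pairs (min %d joint reads)\n",
              length(x$positions), n_elig, x$min_reads))
  invisible(x)
}

#' @describeIn dependency_map long tibble with one row per ordered pair
#'   `i < j`: positions, distance, joint coverage and all six statistics.
#' @param x An `sms_depmap`.
#' @param ... Unused.
#' @export
#' @method tidy sms_depmap
tidy.sms_depmap <- function(x, ...) {
  ut <- which(upper.tri(x$ami), arr.ind = TRUE)
  pos <- x$positions
  out <- tibble(
    i = pos[ut[, 1]], j = pos[ut[, 2]],
    distance = pos[ut[, 2]] - pos[ut[, 1]],
    n = as.integer(x$n[ut]),
    ami = x$ami[ut], dami = x$dami[ut],
    co_open = x$co_open[ut], z_co_open = x$z_co_open[ut],
    co_agree = x$co_agree[ut], z_co_agree = x$z_co_agree[ut]
  )
  dplyr::arrange(out, .data$i, .data$j)
}

#' @export
#' @method autoplot sms_depmap
autoplot.sms_depmap <- function(object, statistic = "dami", ...) {
  stopifnot(statistic %in% c("ami", "dami", "co_open", "z_co_open",
                             "co_agree", "z_co_agree"))
  df <- tidy(object)
  df <- df[!is.na(df[[statistic]]), , drop = FALSE]
  ggplot2::ggplot(df, ggplot2::aes(x = .data$i, y = .data$j,
                                   fill = .data[[statistic]])) +
    ggplot2::geom_tile() +
    ggplot2::geom_tile(ggplot2::aes(x = .data$j, y = .data$i)) +
    ggplot2::scale_fill_gradient2(low = "steelblue", mid = "white",
                                  high = "firebrick") +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "position", y = "position", fill = statistic) +
    ggplot2::theme_minimal()
}
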