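#' Anchor-aligned metaprofile of per-gene accessibility
#'
#' Each gene's per-position rate profile is z-scored against its own covered
#' positions (population standard deviation; a flat profile maps to zeros),
#' aligned so its anchor sits at offset 0, and averaged per offset across
#' genes. Offsets covered by fewer than `min_genes` genes are dropped to
#' `NA`.
#'
#' @param rate_profiles Named list of numeric per-position rate vectors
#'   (`NA` allowed), one per gene — e.g. the `frequency` column of
#'   [consensus_frequency()].
#' @param anchors Named numeric vector of anchor positions (same names).
#' @param window Length-2 vector `c(up, down)`: offsets `-up .. +down` are
#'   reported. Default `c(100, 100)`.
#' @param min_genes Minimum genes per offset (default 10).
#' @return An object of classes `sms_metaplot`/`tbl_df`: columns `offset`,
#'   `z` (mean z-score across genes), `n_genes`.
#' @export
metaplot <- function(rate_profiles, anchors, window = c(100, 100),
                     min_genes = 10L) {
  if (!length(rate_profiles)) {
    abort("no gene profiles supplied", class = "smstruct_value_error")
  }
  genes <- intersect(names(rate_profiles), names(anchors))
  genes <- genes[!is.na(anchors[genes])]
  if (!length(genes)) {
    abort("no gene has both a profile and an anchor",
          class = "smstruct_value_error")
  }
  offsets <- seq(-window[1], window[2])
  acc <- matrix(NA_real_, nrow = length(genes), ncol = length(offsets),
                dimnames = list(genes, offsets))
  for (g in genes) {
    prof <- rate_profiles[[g]]
    z <- zscore_profile(prof)
    pos <- anchors[[g]] + offsets
    ok <- pos >= 1 & pos <= length(z)
    acc[g, ok] <- z[pos[ok]]
  }
  n_genes <- colSums(!is.na(acc))
  z_mean <- ifelse(n_genes >= min_genes, colMeans(acc, na.rm = TRUE), NA_real_)
  out <- tibble(offset = offsets, z = as.numeric(z_mean),
                n_genes = as.integer(n_genes))
  class(out) <- c("sms_metaplot", class(out))
  out
}

# z-score a profile over its covered positions with population sd
zscore_profile <- function(prof) {
  ok <- !is.na(prof)
  if (!any(ok)) return(prof)
  mu <- mean(prof[ok])
  sigma <- sqrt(mean((prof[ok] - mu)^2))
  z <- prof
  z[ok] <- if (sigma == 0) 0 else (prof[ok] - mu) / sigma
  z
}

#' @export
#' @method autoplot sms_metaplot
autoplot.sms_metaplot <- function(object, ...) {
  ggplot2::ggplot(object[!is.na(object$z), ],
                  ggplot2::aes(x = .data$offset, y = .data$z)) +
    ggplot2::geom_hline(yintercept = 0, linetype = "dotted") +
    ggplot2::geom_vline(xintercept = 0, colour = "grey50") +
    ggplot2::geom_line() +
    ggplot2::labs(x = "offset from anchor (nt)", y = "mean per-gene z-score") +
    ggplot2::theme_minimal()
}

#' Mean modification rate per annotated region
#'
#' For each gene, averages the per-position consensus frequency within the
#' 5'UTR, CDS and 3'UTR intervals; regions absent from the annotation are
#' `NA`. `region_rate_tests()` compares regions across genes with Welch
#' t-tests.
#'
#' @param mods Named list of [mod_matrix()] objects, one per gene.
#' @param annotations Named list of [annotation()] objects (same names).
#' @return A tibble with one row per gene: `gene`, `utr5`, `cds`, `utr3`.
#' @export
region_rates <- function(mods, annotations) {
  genes <- intersect(names(mods), names(annotations))
  if (!length(genes)) {
    abort("no gene has both data and annotation",
          class = "smstruct_value_error")
  }
  purrr::map_dfr(genes, function(g) {
    freq <- consensus_frequency(mods[[g]])$frequency
    a <- annotations[[g]]
    rate_in <- function(iv) {
      if (is.null(iv)) return(NA_real_)
      v <- freq[iv[1]:min(iv[2], length(freq))]
      if (all(is.na(v))) NA_real_ else mean(v, na.rm = TRUE)
    }
    tibble(gene = g, utr5 = rate_in(a$utr5), cds = rate_in(a$cds),
           utr3 = rate_in(a$utr3))
  })
}

#' @rdname region_rates
#' @param rates Output of `region_rates()`.
#' @export
region_rate_tests <- function(rates) {
  pairs <- list(c("utr5", "cds"), c("utr3", "cds"), c("utr5", "utr3"))
  purrr::map_dfr(pairs, function(pr) {
    x <- rates[[pr[1]]]
    y <- rates[[pr[2]]]
    ok <- sum(!is.na(x)) >= 2 && sum(!is.na(y)) >= 2
    tt <- if (ok) t.test(x, y) else NULL
    tibble(
      region_a = pr[1], region_b = pr[2],
      mean_a = mean(x, na.rm = TRUE), mean_b = mean(y, na.rm = TRUE),
      statistic = if (ok) unname(tt$statistic) else NA_real_,
      p.value = if (ok) tt$p.value else NA_real_
    )
  })
}

#' Stop-codon-grouped metaprofiles around the termination site
#'
#' Splits genes by stop-codon identity (UAA / UGA / UAG) and computes the
#' anchor-aligned metaprofile of [metaplot()] separately per group.
#'
#' @inheritParams metaplot
#' @param stop_codon_ids Named character vector of codon labels per gene.
#' @return Tibble with columns `stop_codon`, `offset`, `z`, `n_genes`.
#' @export
grouped_stop_profiles <- function(rate_profiles, anchors, stop_codon_ids,
                                  window = c(100, 100), min_genes = 3L) {
  bad <- setdiff(unique(stop_codon_ids), c("UAA", "UGA", "UAG", NA))
  if (length(bad)) {
    abort(sprintf("unknown stop codon label '%s'", bad[1]),
          class = "smstruct_value_error")
  }
  groups <- split(names(stop_codon_ids), stop_codon_ids)
  purrr::map_dfr(names(groups), function(codon) {
    genes <- groups[[codon]]
    genes <- intersect(genes, names(rate_profiles))
    if (!length(genes)) return(tibble())
    mp <- metaplot(rate_profiles[genes], anchors[genes], window = window,
                   min_genes = min_genes)
    dplyr::mutate(tibble::as_tibble(mp), stop_codon = codon, .before = 1)
  })
}

#' Mean modification rate around sequence-motif occurrences
#'
#' Averages the raw (not z-scored) rate profile across motif hits at each
#' offset from the motif start; window edges beyond a gene's profile are
#' simply not counted for that hit.
#'
#' @param rate_profiles Named list of per-position rate vectors.
#' @param motif_hits Tibble with columns `gene`, `motif`, `start`.
#' @param up,down Window size upstream / downstream of the motif start
#'   (defaults 50 and 20 nt).
#' @return Tibble with `motif`, `offset`, `rate`, `n_hits`.
#' @export
motif_profile <- function(rate_profiles, motif_hits, up = 50L, down = 20L) {
  stopifnot(all(c("gene", "motif", "start") %in% names(motif_hits)))
  offsets <- seq(-up, down)
  purrr::map_dfr(split(motif_hits, motif_hits$motif), function(hits) {
    acc <- matrix(NA_real_, nrow = nrow(hits), ncol = length(offsets))
    for (h in seq_len(nrow(hits))) {
      prof <- rate_profiles[[hits$gene[h]]]
      if (is.null(prof)) next
      pos <- hits$start[h] + offsets
      ok <- pos >= 1 & pos <= length(prof)
      acc[h, ok] <- prof[pos[ok]]
    }
    n_hits <- colSums(!is.na(acc))
    if (!any(n_hits > 0)) return(tibble())
    tibble(
      motif = hits$motif[1], offset = offsets,
      rate = ifelse(n_hits > 0, colMeans(acc, na.rm = TRUE), NA_real_),
      n_hits = as.integer(n_hits)
    )
  })
}

#' Rank genes by average modification rate
#'
#' Mean call over all probed, non-missing cells per gene, ranked descending;
#' ties keep a stable order by gene id.
#'
#' @param mods Named list of [mod_matrix()] objects.
#' @return Tibble `gene`, `rate`, `n_cells`, `rank`.
#' @export
gene_rank <- function(mods) {
  stopifnot(length(mods) >= 1)
  out <- purrr::map_dfr(names(mods), function(g) {
    x <- unclass(mods[[g]])
    tibble(gene = g, rate = mean(x, na.rm = TRUE),
           n_cells = sum(!is.na(x)))
  })
  out <- dplyr::arrange(out, dplyr::desc(.data$rate), .data$gene)
  out$rank <- seq_len(nrow(out))
  out
}
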