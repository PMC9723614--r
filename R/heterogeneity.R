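#' Fold every read and group reads by resulting structure
#'
#' Each read is folded with its called-modified positions banned from
#' pairing (hard constraints); reads yielding the exact same dot-bracket are
#' pooled. The group table mirrors the heterogeneity view of a probed
#' ensemble: a dominant structure plus lower-abundance alternatives.
#'
#' @param m A [mod_matrix()].
#' @param sequence RNA sequence matching the matrix width.
#' @param engine Folding engine, see [constrained_fold()].
#' @return An object of class `sms_structure_groups`: tibble with one row
#'   per distinct structure — `dotbracket`, `read_count`, `fraction`,
#'   `energy_score`, `member_read_ids` (list-column) — sorted by
#'   `read_count` descending (ties by energy, then dot-bracket).
#' @export
group_reads_by_structure <- function(m, sequence, engine = "builtin") {
  stopifnot(inherits(m, "mod_matrix"))
  sequence <- toupper(gsub("T", "U", sequence, fixed = TRUE))
  if (nchar(sequence) != ncol(m)) {
    abort("sequence length and matrix width differ",
          class = "smstruct_value_error")
  }
  x <- unclass(m)
  banned_sets <- lapply(seq_len(nrow(x)), function(r) {
    which(!is.na(x[r, ]) & x[r, ] == 1)
  })
  # identical constraint sets fold identically; fold each distinct set once
  keys <- vapply(banned_sets, function(b) paste(b, collapse = ","), "")
  uniq <- !duplicated(keys)
  folded <- lapply(banned_sets[uniq], function(b) {
    constrained_fold(sequence, banned = b, engine = engine)
  })
  idx <- match(keys, keys[uniq])
  db <- vapply(folded[idx], function(s) s$dotbracket, "")
  energy <- vapply(folded[idx], function(s) attr(s, "energy_score"), 0)
  groups <- tibble(
    read_id = rownames(x), dotbracket = unname(db), energy_score = unname(energy)
  ) |>
    dplyr::group_by(.data$dotbracket) |>
    dplyr::summarise(
      read_count = dplyr::n(),
      energy_score = min(.data$energy_score),
      member_read_ids = list(.data$read_id),
      .groups = "drop"
    ) |>
    dplyr::mutate(fraction = .data$read_count / nrow(x)) |>
    dplyr::arrange(dplyr::desc(.data$read_count), .data$energy_score,
                   .data$dotbracket) |>
    dplyr::select("dotbracket", "read_count", "fraction", "energy_score",
                  "member_read_ids")
  class(groups) <- c("sms_structure_groups", class(groups))
  groups
}

#' @export
#' @method autoplot sms_structure_groups
autoplot.sms_structure_groups <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$energy_score,
                                       y = .data$read_count)) +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::labs(x = "energy score", y = "reads folding to structure") +
    ggplot2::theme_minimal()
}

#' Is a read's modification pattern compatible with a structure?
#'
#' A read is compatible when none of its called-modified positions falls on
#' a paired base of the structure (modified implies accessible/open).
#'
#' @param read_calls Binary vector with `NA` allowed (one read's row).
#' @param s An [rna_structure][parse_dotbracket] of matching length.
#' @return Logical scalar.
#' @export
is_compatible <- function(read_calls, s) {
  stopifnot(inherits(s, "rna_structure"))
  if (length(read_calls) != length(s)) {
    abort("read length and structure length differ",
          class = "smstruct_value_error")
  }
  modified <- which(!is.na(read_calls) & read_calls == 1)
  all(modified %in% s$open_set)
}

#' Binary (Jaccard) distance between a read and a structure
#'
#' `1 - |M intersect O| / |M union O|` where `M` is the read's set of
#' called-modified positions and `O` the structure's open positions, both
#' restricted to `positions` (typically the probed adenosines) and to cells
#' the read actually covers. Two empty sets give distance 0.
#'
#' @param read_calls Binary vector with `NA` allowed.
#' @param s An [rna_structure][parse_dotbracket].
#' @param positions Positions compared (default all).
#' @return Distance in `[0, 1]`.
#' @export
read_structure_distance <- function(read_calls, s, positions = NULL) {
  stopifnot(inherits(s, "rna_structure"))
  if (length(read_calls) != length(s)) {
    abort("read length and structure length differ",
          class = "smstruct_value_error")
  }
  if (is.null(positions)) positions <- seq_along(read_calls)
  covered <- intersect(positions, which(!is.na(read_calls)))
  M <- covered[read_calls[covered] == 1]
  O <- intersect(s$open_set, covered)
  u <- length(union(M, O))
  if (u == 0) return(0)
  1 - length(intersect(M, O)) / u
}

# vectorized distances: reads x structures Jaccard distance over a mask
distance_matrix <- function(x, structures, positions) {
  obs <- !is.na(x[, positions, drop = FALSE])
  calls <- x[, positions, drop = FALSE]
  calls[!obs] <- 0
  open_ind <- vapply(structures, function(s) {
    as.numeric(positions %in% s$open_set)
  }, numeric(length(positions)))
  open_ind <- matrix(open_ind, ncol = length(structures))
  inter <- calls %*% open_ind                      # |M ∩ O|
  size_m <- rowSums(calls)
  size_o <- (obs * 1) %*% open_ind                 # |O ∩ covered|
  uni <- size_m + size_o - inter
  d <- 1 - inter / uni
  d[uni == 0] <- 0
  d
}

#' Assign reads to their nearest candidate structure
#'
#' Each read goes to the structure minimizing the binary distance of
#' [read_structure_distance()]; ties break toward the lowest structure
#' index.
#'
#' @param m A [mod_matrix()].
#' @param structures List of [rna_structure][parse_dotbracket] objects of
#'   matching length.
#' @param positions Positions compared; default: adenosines of the first
#'   structure's sequence when available, otherwise all positions.
#' @return An object of class `sms_cluster`: list with `assignment`
#'   (integer vector), `distances` (reads x structures matrix) and
#'   `positions`. [tidy()] gives the per-read table.
#' @export
assign_reads <- function(m, structures, positions = NULL) {
  stopifnot(inherits(m, "mod_matrix"), length(structures) >= 1)
  lens <- vapply(structures, length, 0L)
  if (any(lens != ncol(m))) {
    abort("all structures must match the matrix width",
          class = "smstruct_value_error")
  }
  if (is.null(positions)) {
    seq1 <- structures[[1]]$sequence
    positions <- if (!is.null(seq1)) adenosine_positions(seq1) else seq_len(ncol(m))
    if (!length(positions)) positions <- seq_len(ncol(m))
  }
  d <- distance_matrix(unclass(m), structures, positions)
  rownames(d) <- rownames(m)
  assignment <- apply(d, 1, which.min)  # which.min takes the first minimum
  res <- list(assignment = setNames(as.integer(assignment), rownames(m)),
              distances = d, positions = positions)
  class(res) <- "sms_cluster"
  res
}

#' @export
print.sms_cluster <- function(x, ...) {
  tab <- table(factor(x$assignment, levels = seq_len(ncol(x$distances))))
  cat(sprintf("<sms_cluster> %d reads over %d structures (%s)\n",
              nrow(x$distances), ncol(x$distances),
              paste(as.integer(tab), collapse = "/")))
  invisible(x)
}

#' @describeIn assign_reads one row per read: `read_id`, `structure`
#'   (assigned index) and `distance` to it.
#' @param x An `sms_cluster`.
#' @param ... Unused.
#' @export
#' @method tidy sms_cluster
tidy.sms_cluster <- function(x, ...) {
  tibble(
    read_id = rownames(x$distances),
    structure = x$assignment,
    distance = x$distances[cbind(seq_along(x$assignment), x$assignment)]
  )
}

#' Permutation test of read-structure concordance
#'
#' Do reads sit closer to the candidate structures than chance allows? Each
#' permutation shuffles every structure's open/paired labels across
#' positions (independently per structure, preserving the open-set size) and
#' records each read's minimum distance to the permuted set. The observed
#' minimum distances are compared to the permuted ones with a Welch
#' two-sample t-test.
#'
#' @param m A [mod_matrix()].
#' @param structures Candidate structures.
#' @param n_perm Number of permutations (default 10000).
#' @param seed Integer seed (recorded in the result).
#' @param positions As in [assign_reads()].
#' @return An object of class `sms_permtest`: list with `p_value`,
#'   `statistic`, `mean_observed`, `mean_permuted`, `n_permutations`,
#'   `seed`. [glance()] gives the one-row summary.
#' @export
structure_permutation_test <- function(m, structures, n_perm = 10000L,
                                       seed = 1L, positions = NULL) {
  stopifnot(inherits(m, "mod_matrix"), length(structures) >= 1)
  if (n_perm < 1) {
    abort("n_perm must be at least 1", class = "smstruct_value_error")
  }
  if (is.null(positions)) {
    seq1 <- structures[[1]]$sequence
    positions <- if (!is.null(seq1)) adenosine_positions(seq1) else seq_len(ncol(m))
    if (!length(positions)) positions <- seq_len(ncol(m))
  }
  x <- unclass(m)
  obs_min <- apply(distance_matrix(x, structures, positions), 1, min)

  # permuting open/paired labels only matters within the compared mask;
  # shuffle the mask-restricted open indicator of each structure
  open_ind <- vapply(structures, function(s) {
    as.numeric(positions %in% s$open_set)
  }, numeric(length(positions)))
  open_ind <- matrix(open_ind, ncol = length(structures))
  obs <- !is.na(x[, positions, drop = FALSE])
  calls <- x[, positions, drop = FALSE]
  calls[!obs] <- 0
  obs1 <- obs * 1
  size_m <- rowSums(calls)

  old_seed <- get0(".Random.seed", envir = globalenv())
  on.exit({
    if (!is.null(old_seed)) assign(".Random.seed", old_seed, envir = globalenv())
  })
  set.seed(seed)
  k <- ncol(open_ind)
  np <- nrow(open_ind)
  perm_min <- matrix(NA_real_, nrow(x), n_perm)
  for (b in seq_len(n_perm)) {
    perm_open <- apply(open_ind, 2, function(o) o[sample.int(np)])
    inter <- calls %*% perm_open
    uni <- size_m + obs1 %*% perm_open - inter
    d <- 1 - inter / uni
    d[uni == 0] <- 0
    perm_min[, b] <- do.call(pmin, lapply(seq_len(k), function(s) d[, s]))
  }
  tt <- t.test(obs_min, as.vector(perm_min))
  res <- list(
    p_value = tt$p.value,
    statistic = unname(tt$statistic),
    mean_observed = mean(obs_min),
    mean_permuted = mean(perm_min),
    n_permutations = as.integer(n_perm),
    seed = as.integer(seed),
    n_reads = nrow(x)
  )
  class(res) <- "sms_permtest"
  res
}

#' @export
print.sms_permtest <- function(x, ...) {
  cat(sprintf(
    "<sms_permtest> %d reads, %d permutations\n  mean distance observed %.4f vs permuted %.4f, Welch t = %.2f, p = %.3g\n",
    x$n_reads, x$n_permutations, x$mean_observed, x$mean_permuted,
    x$statistic, x$p_value))
  invisible(x)
}

#' @describeIn structure_permutation_test one-row tibble of the test summary.
#' @param x An `sms_permtest`.
#' @param ... Unused.
#' @export
#' @method glance sms_permtest
glance.sms_permtest <- function(x, ...) {
  tibble(
    statistic = x$statistic, p.value = x$p_value,
    mean_observed = x$mean_observed, mean_permuted = x$mean_permuted,
    n_permutations = x$n_permutations, n_reads = x$n_reads, seed = x$seed
  )
}
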