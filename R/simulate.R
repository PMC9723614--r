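#' Statistic emission distribution for the simulator
#'
#' Piecewise-uniform distribution on `[0, 1]` parameterized by the
#' probability mass below a breakpoint: a draw falls uniformly in
#' `[0, breakpoint)` with probability `p_below`, otherwise uniformly in
#' `[breakpoint, 1]`. With breakpoint 0.2 this pins the distribution's mass
#' at the call threshold: the default alternative distribution has 95% mass
#' below 0.2 (modified bases usually called) and the default null has 15%
#' (the empirical false-call floor of the assay).
#'
#' @param p_below Mass below the breakpoint.
#' @param breakpoint Breakpoint, default 0.2.
#' @return An object of class `sms_stat_dist` with fields `p_below`,
#'   `breakpoint`, and functions `sample(n)` and `cdf(x)`.
#' @export
stat_distribution <- function(p_below, breakpoint = 0.2) {
  stopifnot(p_below >= 0, p_below <= 1, breakpoint > 0, breakpoint < 1)
  force(p_below); force(breakpoint)
  structure(
    list(
      p_below = p_below, breakpoint = breakpoint,
      sample = function(n) {
        low <- runif(n) < p_below
        ifelse(low, runif(n, 0, breakpoint), runif(n, breakpoint, 1))
      },
      cdf = function(x) {
        ifelse(x <= breakpoint,
               p_below * x / breakpoint,
               p_below + (1 - p_below) * (x - breakpoint) / (1 - breakpoint))
      }
    ),
    class = "sms_stat_dist"
  )
}

#' Describe a synthetic structure ensemble
#'
#' An ensemble specification drives the simulator: reads are drawn from a
#' weighted mixture of structures; probed positions that are open in the
#' read's structure are modified with probability `p_open`, probed paired
#' positions with probability `p_closed` (the false-call floor, default
#' 0.15), unprobed positions are never modified, and the trailing
#' `missing_tail` positions carry no statistic at all (the upstream caller
#' emits nothing for the last bases of a read).
#'
#' @param structures List of [rna_structure][parse_dotbracket] objects of a
#'   common length.
#' @param weights Mixture weights (non-negative, normalized to sum 1).
#' @param p_open,p_closed Modification probabilities for open and paired
#'   probed positions; scalars or per-position vectors.
#' @param probed Probed positions; default: adenosines of the first
#'   structure's sequence, or all positions when no sequence is attached.
#' @param stat_alt,stat_null [stat_distribution()]s for modified and
#'   unmodified cells.
#' @param missing_tail Number of trailing positions with missing statistics
#'   (default 13: the 10 uncalled bases at the read end plus 3 lost to
#'   statistic context smoothing).
#' @param seed Default seed used by the simulator.
#' @return An object of class `sms_ensemble_spec`.
#' @export
ensemble_spec <- function(structures, weights = NULL, p_open = 0.5,
                          p_closed = 0.15, probed = NULL,
                          stat_alt = stat_distribution(0.95),
                          stat_null = stat_distribution(0.15),
                          missing_tail = 13L, seed = 1L) {
  if (inherits(structures, "rna_structure")) structures <- list(structures)
  stopifnot(length(structures) >= 1)
  lens <- vapply(structures, length, 0L)
  if (length(unique(lens)) != 1L) {
    abort("all structures must share a common length",
          class = "smstruct_value_error")
  }
  L <- lens[1]
  weights <- weights %||% rep(1 / length(structures), length(structures))
  if (length(weights) != length(structures) || any(weights < 0) ||
      abs(sum(weights) - 1) > 1e-8) {
    abort("weights must be non-negative and sum to 1",
          class = "smstruct_value_error")
  }
  expand <- function(p, nm) {
    if (length(p) == 1L) p <- rep(p, L)
    if (length(p) != L || any(p < 0) || any(p > 1)) {
      abort(sprintf("%s must be a probability (scalar or length-%d vector)",
                    nm, L), class = "smstruct_value_error")
    }
    p
  }
  p_open <- expand(p_open, "p_open")
  p_closed <- expand(p_closed, "p_closed")
  if (any(p_closed > p_open)) {
    abort("p_closed must not exceed p_open", class = "smstruct_value_error")
  }
  if (is.null(probed)) {
    seq1 <- structures[[1]]$sequence
    probed <- if (!is.null(seq1)) adenosine_positions(seq1) else seq_len(L)
  }
  stopifnot(all(probed >= 1), all(probed <= L))
  if (missing_tail < 0 || missing_tail >= L) {
    abort("missing_tail must be in [0, length)", class = "smstruct_value_error")
  }
  structure(
    list(structures = structures, weights = weights, length = L,
         p_open = p_open, p_closed = p_closed, probed = sort(unique(probed)),
         stat_alt = stat_alt, stat_null = stat_null,
         missing_tail = as.integer(missing_tail), seed = as.integer(seed)),
    class = "sms_ensemble_spec"
  )
}

#' @export
print.sms_ensemble_spec <- function(x, ...) {
  cat(sprintf(
    "<sms_ensemble_spec> %d structure(s) of %d nt, %d probed positions, tail %d missing\n  weights %s, p_open %s, p_closed %s\n",
    length(x$structures), x$length, length(x$probed), x$missing_tail,
    paste(signif(x$weights, 3), collapse = "/"),
    paste(range(signif(x$p_open, 3)), collapse = "-"),
    paste(range(signif(x$p_closed, 3)), collapse = "-")))
  invisible(x)
}

#' Simulate single-molecule modification calls from an ensemble
#'
#' Each read samples a structure by weight, then each probed position is
#' modified independently with `p_open` or `p_closed` according to whether
#' the position is open in that structure. Unprobed positions are 0; the
#' trailing `missing_tail` positions are missing.
#'
#' @param spec An [ensemble_spec()].
#' @param n_reads Number of reads.
#' @param seed Seed; defaults to the spec's.
#' @return A list: `mods` ([mod_matrix()]) and `truth` (integer vector of
#'   generating structure indices, one per read).
#' @export
simulate_mods <- function(spec, n_reads, seed = spec$seed) {
  stopifnot(inherits(spec, "sms_ensemble_spec"), n_reads >= 1)
  set.seed(seed)
  L <- spec$length
  truth <- sample.int(length(spec$structures), n_reads, replace = TRUE,
                      prob = spec$weights)
  open_ind <- vapply(spec$structures, function(s) {
    seq_len(L) %in% s$open_set
  }, logical(L))
  open_ind <- matrix(open_ind, nrow = L)
  calls <- matrix(0, nrow = n_reads, ncol = L)
  for (pos in spec$probed) {
    p <- ifelse(open_ind[pos, truth], spec$p_open[pos], spec$p_closed[pos])
    calls[, pos] <- rbinom(n_reads, 1L, p)
  }
  if (spec$missing_tail > 0) {
    calls[, (L - spec$missing_tail + 1L):L] <- NA_real_
  }
  rownames(calls) <- sprintf("read_%d", seq_len(n_reads))
  list(mods = mod_matrix(calls, reference = "synthetic"),
       truth = truth)
}

#' Emit continuous statistics consistent with a call matrix
#'
#' Modified cells draw from the spec's alternative distribution, unmodified
#' cells from the null distribution; missing cells stay missing. Applying
#' the caller at a threshold `t` to the result recovers each cell's state
#' with sensitivity `P_alt(x < t)` and false-call rate `P_null(x < t)`.
#'
#' @param m A [mod_matrix()] (typically from [simulate_mods()]).
#' @param spec The [ensemble_spec()] providing the distributions.
#' @param seed Seed; defaults to the spec's seed plus one (so that paired
#'   mods/stats simulations do not reuse the same stream).
#' @return A [stat_matrix()].
#' @export
simulate_stats <- function(m, spec, seed = spec$seed + 1L) {
  stopifnot(inherits(m, "mod_matrix"), inherits(spec, "sms_ensemble_spec"))
  set.seed(seed)
  x <- unclass(m)
  out <- matrix(NA_real_, nrow(x), ncol(x), dimnames = dimnames(x))
  is_mod <- !is.na(x) & x == 1
  is_unmod <- !is.na(x) & x == 0
  out[is_mod] <- spec$stat_alt$sample(sum(is_mod))
  out[is_unmod] <- spec$stat_null$sample(sum(is_unmod))
  stat_matrix(out, reference = attr(m, "reference"))
}

# ---- bundled fixtures ------------------------------------------------------

#' Bundled synthetic constructs
#'
#' Three ready-made ensemble specifications used throughout the test-suite
#' and documentation:
#'
#' * `fixture_hairpin()` — a single stable stem-loop (12 bp stem, 8 nt
#'   A-rich loop) ligated to an unstructured A/C linker, 60 nt total with
#'   the last 13 positions missing. The sequence is designed so that the
#'   builtin pair-maximization engine folds the unconstrained sequence to
#'   exactly this hairpin.
#' * `fixture_two_domain()` — a riboswitch-like construct: a constant
#'   closing stem and expression platform, and an aptamer domain that is
#'   open in conformation 1 and paired in conformation 2 (equal weights).
#'   The probed aptamer adenosines are exposed in
#'   `attr(spec, "aptamer_positions")`.
#' * `fixture_stem_flip()` — a two-conformation ensemble on the hairpin
#'   sequence whose stem is either fully formed or fully molten, with all
#'   positions probed; the joint flipping of the stem is the textbook
#'   co-dependency signal.
#' * `fixture_transcriptome()` — `n_genes` mRNA-like genes with UTR/CDS
#'   annotation, stop-codon labels, a planted accessible window upstream of
#'   both the start and the stop anchors, reduced accessibility at the
#'   start of UGA 3'UTRs and around a planted `AAUAAA` motif elevated
#'   accessibility. All positions are probed (dense-probing idealization).
#'
#' @param p_open,p_closed Modification probabilities (see [ensemble_spec()]).
#' @param seed Spec seed.
#' @return An [ensemble_spec()]; `fixture_transcriptome()` returns a list
#'   with `specs` (named list of ensemble specs) and `annotations` (named
#'   list of [annotation()] objects).
#' @export
fixture_hairpin <- function(p_open = 0.5, p_closed = 0.15, seed = 1L) {
  seq <- paste0(
    "GGAGAGGACGGA",          # stem 5' arm (G/A only)
    "AAAAAAAA",              # loop, all A
    "UCCGUCCUCUCC",          # stem 3' arm (reverse complement, C/U only)
    "ACCACAACAACCACAACAACCACAACAA"  # unstructured linker (A/C only)
  )
  db <- paste0(strrep("(", 12), strrep(".", 8), strrep(")", 12),
               strrep(".", 28))
  hp <- parse_dotbracket(db, sequence = seq, name = "hairpin")
  ensemble_spec(hp, p_open = p_open, p_closed = p_closed, seed = seed)
}

#' @rdname fixture_hairpin
#' @param bound If `TRUE`, return the ligand-bound state of the two-domain
#'   construct: accessibility at the 10 probed aptamer adenosines drops to
#'   `p_open_bound` regardless of conformation (the ligand occludes the
#'   binding pocket); everything else is unchanged.
#' @param p_open_bound Bound-state modification probability at the aptamer
#'   adenosines (default 0.1).
#' @export
fixture_two_domain <- function(p_open = 0.5, p_closed = 0.15, seed = 1L,
                               bound = FALSE, p_open_bound = 0.1) {
  # closing stem (1-24), aptamer domain (25-44), expression platform (45-60),
  # unstructured 3' tail overlapping the missing window
  seq <- paste0(
    "GGGGAGGG", "CAAACAAC", "CCCUCCCC",        # closing stem-loop, 24 nt
    "ACACACACACACACACACAC",                    # aptamer domain, 20 nt, 10 A
    "GGGAGG", "CAAC", "CCUCCC",                # expression platform, 16 nt
    strrep("A", 13)                            # tail
  )
  L <- nchar(seq)
  stem <- paste0(strrep("(", 8), strrep(".", 8), strrep(")", 8))
  platform <- paste0(strrep("(", 6), strrep(".", 4), strrep(")", 6))
  tail <- strrep(".", 13)
  apt_open <- strrep(".", 20)
  apt_paired <- paste0(strrep("(", 8), strrep(".", 4), strrep(")", 8))
  s_open <- parse_dotbracket(paste0(stem, apt_open, platform, tail),
                             sequence = seq, name = "aptamer_open")
  s_closed <- parse_dotbracket(paste0(stem, apt_paired, platform, tail),
                               sequence = seq, name = "aptamer_paired")
  aptamer <- intersect(adenosine_positions(seq), 25:44)
  p_open_vec <- rep(p_open, L)
  p_closed_vec <- rep(p_closed, L)
  if (bound) {
    p_open_vec[aptamer] <- p_open_bound
    p_closed_vec[aptamer] <- p_open_bound
  }
  spec <- ensemble_spec(list(s_open, s_closed), weights = c(0.5, 0.5),
                        p_open = p_open_vec, p_closed = p_closed_vec,
                        seed = seed)
  attr(spec, "aptamer_positions") <- aptamer
  spec
}

#' @rdname fixture_hairpin
#' @export
fixture_stem_flip <- function(p_open = 0.5, p_closed = 0.05, seed = 1L) {
  hp <- fixture_hairpin()$structures[[1]]
  molten <- parse_dotbracket(strrep(".", length(hp)), sequence = hp$sequence,
                             name = "molten")
  spec <- ensemble_spec(list(hp, molten), weights = c(0.5, 0.5),
                        p_open = p_open, p_closed = p_closed,
                        probed = seq_len(length(hp)), seed = seed)
  attr(spec, "stem_pairs") <- {
    pt <- hp$pair_table
    ii <- which(!is.na(pt) & seq_along(pt) < pt)
    cbind(i = ii, j = pt[ii])
  }
  spec
}

#' @rdname fixture_hairpin
#' @param n_genes Number of genes.
#' @param gene_length Transcript length (common to all genes).
#' @export
fixture_transcriptome <- function(n_genes = 12L, gene_length = 400L,
                                  seed = 1L) {
  stopifnot(n_genes >= 1, gene_length >= 200)
  set.seed(seed)
  L <- gene_length
  codons <- rep(c("UAA", "UGA", "UAG"), length.out = n_genes)
  specs <- list()
  annotations <- list()
  for (g in seq_len(n_genes)) {
    name <- sprintf("gene_%02d", g)
    utr5 <- c(1L, 60L)
    cds <- c(61L, L - 81L)
    utr3 <- c(L - 80L, L)
    start_anchor <- cds[1]
    stop_anchor <- cds[2] - 2L          # first base of the stop codon
    motif_start <- utr3[1] + 30L
    # region-wise probability that a position is open (accessible)
    p_open_pos <- rep(NA_real_, L)
    p_open_pos[utr5[1]:utr5[2]] <- 0.75
    p_open_pos[cds[1]:cds[2]] <- 0.40
    p_open_pos[utr3[1]:utr3[2]] <- 0.30
    # planted features: open windows upstream of the start and stop anchors
    p_open_pos[max(1, start_anchor - 20):(start_anchor - 1)] <- 0.95
    p_open_pos[max(1, stop_anchor - 20):(stop_anchor - 1)] <- 0.95
    # UGA genes: closed stretch at the beginning of the 3'UTR
    if (codons[g] == "UGA") {
      p_open_pos[utr3[1]:(utr3[1] + 19L)] <- 0.05
    }
    # accessible window around the polyadenylation motif
    p_open_pos[motif_start:(motif_start + 10L)] <- 0.95
    open <- which(runif(L) < p_open_pos)
    if ((L - length(open)) %% 2L == 1L) {       # concentric pairing needs
      open <- union(open, setdiff(seq_len(L), open)[1])  # an even closed set
    }
    st <- structure_from_open_set(L, open, name = name)
    specs[[name]] <- ensemble_spec(st, probed = seq_len(L),
                                   seed = seed + g)
    annotations[[name]] <- annotation(
      transcript = name, length = L, utr5 = utr5, cds = cds, utr3 = utr3,
      start_codon = start_anchor, stop_codon = stop_anchor,
      stop_codon_id = codons[g],
      motifs = tibble(motif = "AAUAAA", start = motif_start)
    )
  }
  list(specs = specs, annotations = annotations)
}
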