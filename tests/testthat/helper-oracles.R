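# Independent oracles used to cross-check the package's own implementations.
# Each is written as directly as possible (brute force / enumeration /
# literal resampling) and shares no code with the functions it checks.

# maximum base-pair count over ALL nested structures (min hairpin loop 3,
# Watson-Crick + GU, banned positions never paired), by plain recursion
oracle_max_pairs <- function(sequence, banned = integer(0)) {
  chars <- strsplit(toupper(gsub("T", "U", sequence)), "")[[1]]
  ok_pair <- function(a, b) {
    paste0(a, b) %in% c("AU", "UA", "GC", "CG", "GU", "UG")
  }
  allowed <- !(seq_along(chars) %in% banned)
  rec <- function(i, j) {
    if (j - i < 4) return(0L)
    best <- rec(i + 1L, j)
    if (allowed[i]) {
      for (k in (i + 4L):j) {
        if (allowed[k] && ok_pair(chars[i], chars[k])) {
          cand <- 1L + rec(i + 1L, k - 1L) + rec(k + 1L, j)
          if (cand > best) best <- cand
        }
      }
    }
    best
  }
  rec(1L, length(chars))
}

random_rna <- function(n) {
  paste(sample(c("A", "C", "G", "U"), n, replace = TRUE), collapse = "")
}

# AUC by explicit concordant-pair counting over all positive/negative pairs
oracle_auc <- function(scores, labels) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  total <- 0
  for (p in pos) {
    total <- total + sum(p > neg) + 0.5 * sum(p == neg)
  }
  total / (length(pos) * length(neg))
}

# E[MI] by literally permuting one column against the other B times
oracle_expected_mi_perm <- function(u, v, B = 10000L) {
  N <- length(u)
  n11 <- vapply(seq_len(B), function(b) sum(u[sample.int(N)] * v), 0)
  r1 <- sum(u)
  c1 <- sum(v)
  mi_cell <- function(nab, ra, cb) {
    out <- numeric(length(nab))
    nz <- nab > 0 & ra > 0 & cb > 0
    out[nz] <- (nab[nz] / N) * log(N * nab[nz] / (ra * cb))
    out
  }
  n10 <- r1 - n11
  n01 <- c1 - n11
  n00 <- N - r1 - c1 + n11
  mean(mi_cell(n11, r1, c1) + mi_cell(n10, r1, N - c1) +
         mi_cell(n01, N - r1, c1) + mi_cell(n00, N - r1, N - c1))
}

# adjusted mutual information from the reference scikit-learn implementation
# (the pre-installed python); takes a list of list(u =, v =) binary vectors
oracle_sklearn_ami <- function(cases) {
  infile <- tempfile(fileext = ".tsv")
  outfile <- tempfile(fileext = ".txt")
  lines <- unlist(lapply(cases, function(cs) {
    c(paste(cs$u, collapse = ","), paste(cs$v, collapse = ","))
  }))
  writeLines(lines, infile)
  script <- tempfile(fileext = ".py")
  writeLines(c(
    "import sys",
    "import numpy as np",
    "from sklearn.metrics import adjusted_mutual_info_score",
    "lines = open(sys.argv[1]).read().strip().split('\\n')",
    "out = []",
    "for k in range(0, len(lines), 2):",
    "    u = np.array(lines[k].split(','), int)",
    "    v = np.array(lines[k + 1].split(','), int)",
    "    out.append(repr(adjusted_mutual_info_score(u, v)))",
    "open(sys.argv[2], 'w').write('\\n'.join(out) + '\\n')"
  ), script)
  status <- system2("python", c(script, infile, outfile))
  if (status != 0) stop("python oracle failed")
  as.numeric(readLines(outfile))
}

sklearn_available <- function() {
  nzchar(Sys.which("python")) &&
    suppressWarnings(system2("python", c("-c", shQuote("import sklearn")),
                             stdout = FALSE, stderr = FALSE)) == 0
}

pair_counts_from_vectors <- function(u, v) {
  list(n11 = sum(u == 1 & v == 1), n10 = sum(u == 1 & v == 0),
       n01 = sum(u == 0 & v == 1), n00 = sum(u == 0 & v == 0))
}

random_mod_matrix <- function(n_reads, n_pos, p = 0.3, p_missing = 0,
                              reference = "ref") {
  x <- matrix(rbinom(n_reads * n_pos, 1, p), n_reads, n_pos)
  if (p_missing > 0) {
    x[matrix(runif(n_reads * n_pos) < p_missing, n_reads, n_pos)] <- NA
  }
  mod_matrix(x, reference = reference)
}
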