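#' RNA secondary structures in dot-bracket notation
#'
#' An `rna_structure` holds a nucleotide sequence together with a nested
#' secondary structure encoded in dot-bracket notation: `'('` and `')'` mark
#' the two halves of a base pair, `'.'` marks an unpaired (open) base. The
#' pair table and the open-position set are derived at construction and kept
#' in sync. Positions are 1-based throughout.
#'
#' @param dotbracket Character scalar over `(`, `)`, `.`.
#' @param sequence Optional nucleotide string (A/C/G/U/N, case-insensitive;
#'   `T` is accepted and read as `U`). Must match `dotbracket` in length when
#'   both are given.
#' @param name Optional structure name.
#'
#' @return An object of class `rna_structure`: a list with elements
#'   `name`, `sequence`, `dotbracket`, `pair_table` (integer vector; `NA`
#'   where unpaired, partner index where paired) and `open_set` (integer
#'   vector of unpaired positions).
#'
#' @examples
#' s <- parse_dotbracket("((...))")
#' s$pair_table
#' s$open_set
#' @export
parse_dotbracket <- function(dotbracket, sequence = NULL, name = NULL) {
  stopifnot(is.character(dotbracket), length(dotbracket) == 1L)
  chars <- strsplit(dotbracket, "", fixed = TRUE)[[1]]
  bad <- which(!chars %in% c("(", ")", "."))
  if (length(bad)) {
    abort(sprintf(
      "invalid dot-bracket character '%s' at position %d (only '(', ')', '.' allowed)",
      chars[bad[1]], bad[1]
    ), class = "smstruct_format_error")
  }
  n <- length(chars)
  pair_table <- rep(NA_integer_, n)
  stack <- integer(0)
  for (i in seq_len(n)) {
    if (chars[i] == "(") {
      stack <- c(stack, i)
    } else if (chars[i] == ")") {
      if (!length(stack)) {
        abort(sprintf("unmatched ')' at position %d", i),
              class = "smstruct_format_error")
      }
      j <- stack[length(stack)]
      stack <- stack[-length(stack)]
      pair_table[j] <- i
      pair_table[i] <- j
    }
  }
  if (length(stack)) {
    abort(sprintf("unmatched '(' at position %d", stack[1]),
          class = "smstruct_format_error")
  }
  if (!is.null(sequence)) {
    sequence <- toupper(gsub("T", "U", sequence, fixed = TRUE))
    if (nchar(sequence) != n) {
      abort(sprintf("sequence length (%d) != structure length (%d)",
                    nchar(sequence), n), class = "smstruct_format_error")
    }
    seq_chars <- strsplit(sequence, "", fixed = TRUE)[[1]]
    if (any(!seq_chars %in% c("A", "C", "G", "U", "N"))) {
      abort("sequence may contain only A/C/G/U/N",
            class = "smstruct_format_error")
    }
  }
  structure(
    list(
      name = name,
      sequence = sequence,
      dotbracket = dotbracket,
      pair_table = pair_table,
      open_set = which(chars == ".")
    ),
    class = "rna_structure"
  )
}

#' @rdname parse_dotbracket
#' @param x An `rna_structure`.
#' @export
render_dotbracket <- function(x) {
  stopifnot(inherits(x, "rna_structure"))
  x$dotbracket
}

#' @export
print.rna_structure <- function(x, ...) {
  cat("<rna_structure>", if (!is.null(x$name)) x$name else "", "\n")
  if (!is.null(x$sequence)) cat(" ", x$sequence, "\n")
  cat(" ", x$dotbracket, "\n")
  cat(sprintf("  %d nt, %d pairs, %d open\n",
              nchar(x$dotbracket),
              sum(!is.na(x$pair_table)) %/% 2L,
              length(x$open_set)))
  invisible(x)
}

#' @export
length.rna_structure <- function(x) nchar(x$dotbracket)

#' Build a nested structure from a prescribed open set
#'
#' Pairs the non-open positions concentrically (smallest with largest, and so
#' on inward), yielding a balanced, nested dot-bracket whose unpaired
#' positions are exactly `open`. Used by the simulator to plant arbitrary
#' accessibility patterns; complementarity is not enforced.
#'
#' @param n Structure length.
#' @param open Integer vector of positions (1-based) left unpaired.
#' @param sequence,name Passed to [parse_dotbracket()].
#' @return An `rna_structure`.
#' @export
structure_from_open_set <- function(n, open, sequence = NULL, name = NULL) {
  stopifnot(n >= 1, all(open >= 1), all(open <= n))
  paired <- sort(setdiff(seq_len(n), open))
  if (length(paired) %% 2L != 0L) {
    abort("number of paired positions must be even")
  }
  chars <- rep(".", n)
  k <- length(paired) %/% 2L
  if (k > 0) {
    chars[paired[seq_len(k)]] <- "("
    chars[paired[(k + 1L):(2L * k)]] <- ")"
  }
  parse_dotbracket(paste(chars, collapse = ""), sequence = sequence, name = name)
}

#' Read and write dot-bracket structure files
#'
#' The file format is FASTA-like: a `>name` line, the sequence line, then the
#' dot-bracket line, repeated per record.
#'
#' @param path File path.
#' @return `read_structures()` returns a list of [rna_structure][parse_dotbracket]
#'   objects; `write_structures()` returns `path` invisibly.
#' @export
read_structures <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  hdr <- grep("^>", lines)
  if (!length(hdr)) abort("no '>' records found", class = "smstruct_format_error")
  out <- vector("list", length(hdr))
  ends <- c(hdr[-1] - 1L, length(lines))
  for (k in seq_along(hdr)) {
    block <- lines[hdr[k]:ends[k]]
    if (length(block) < 3L) {
      abort(sprintf("record '%s' needs sequence and structure lines",
                    sub("^>", "", block[1])), class = "smstruct_format_error")
    }
    out[[k]] <- parse_dotbracket(trimws(block[3]),
                                 sequence = trimws(block[2]),
                                 name = sub("^>\\s*", "", block[1]))
  }
  names(out) <- vapply(out, function(s) s$name %||% "", "")
  out
}

#' @rdname read_structures
#' @param structures A list of `rna_structure` objects.
#' @export
write_structures <- function(structures, path) {
  if (inherits(structures, "rna_structure")) structures <- list(structures)
  lines <- unlist(lapply(seq_along(structures), function(k) {
    s <- structures[[k]]
    seqline <- s$sequence %||% strrep("N", nchar(s$dotbracket))
    c(paste0(">", s$name %||% paste0("structure_", k)), seqline, s$dotbracket)
  }))
  writeLines(lines, path)
  invisible(path)
}

#' Read a FASTA file of reference sequences
#'
#' Minimal single-purpose FASTA reader returning a named character vector of
#' uppercase RNA sequences (`T` converted to `U`).
#'
#' @param path FASTA file path.
#' @return Named character vector.
#' @export
read_fasta <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  hdr <- grep("^>", lines)
  if (!length(hdr)) abort("no FASTA records found", class = "smstruct_format_error")
  ends <- c(hdr[-1] - 1L, length(lines))
  seqs <- vapply(seq_along(hdr), function(k) {
    body <- if (hdr[k] + 1L > ends[k]) "" else
      paste(lines[(hdr[k] + 1L):ends[k]], collapse = "")
    gsub("T", "U", toupper(gsub("\\s", "", body)), fixed = TRUE)
  }, "")
  names(seqs) <- sub("^>\\s*", "", sub("\\s.*$", "", lines[hdr]))
  seqs
}

# positions of probed bases (DEPC modifies adenosines)
adenosine_positions <- function(sequence) {
  which(strsplit(toupper(gsub("T", "U", sequence)), "", fixed = TRUE)[[1]] == "A")
}
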