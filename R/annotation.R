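#' Transcript feature annotation
#'
#' Per-transcript 5'UTR / CDS / 3'UTR intervals in transcript coordinates
#' (1-based, inclusive), anchor positions for the translation start and stop,
#' the stop-codon identity and any motif occurrences.
#'
#' @param transcript Transcript name.
#' @param utr5,cds,utr3 Length-2 integer vectors `c(start, end)` or `NULL`
#'   when the region is absent.
#' @param length Transcript length.
#' @param start_codon,stop_codon Anchor positions (first base of the codon),
#'   or `NA`.
#' @param stop_codon_id One of `"UAA"`, `"UGA"`, `"UAG"`, or `NA`.
#' @param motifs Tibble with columns `motif` and `start`, or `NULL`.
#' @return An object of class `sms_annotation`.
#' @export
annotation <- function(transcript, length, utr5 = NULL, cds = NULL,
                       utr3 = NULL, start_codon = NA_integer_,
                       stop_codon = NA_integer_, stop_codon_id = NA_character_,
                       motifs = NULL) {
  check_interval <- function(iv, nm) {
    if (is.null(iv)) return(invisible(NULL))
    if (length(iv) != 2 || iv[1] > iv[2] || iv[1] < 1 || iv[2] > length) {
      abort(sprintf("%s interval must be within [1, %d]", nm, length),
            class = "smstruct_value_error")
    }
  }
  check_interval(utr5, "utr5"); check_interval(cds, "cds")
  check_interval(utr3, "utr3")
  ivs <- Filter(Negate(is.null), list(utr5 = utr5, cds = cds, utr3 = utr3))
  if (length(ivs) > 1) {
    ord <- order(vapply(ivs, function(iv) as.numeric(iv[1]), 0))
    sorted <- ivs[ord]
    for (k in seq_len(length(sorted) - 1)) {
      if (sorted[[k]][2] >= sorted[[k + 1]][1]) {
        abort("annotation intervals overlap", class = "smstruct_value_error")
      }
    }
  }
  for (anchor in c(start_codon, stop_codon)) {
    if (!is.na(anchor) && (anchor < 1 || anchor > length)) {
      abort("anchor outside transcript", class = "smstruct_value_error")
    }
  }
  if (!is.na(stop_codon_id) && !stop_codon_id %in% c("UAA", "UGA", "UAG")) {
    abort("stop_codon_id must be UAA, UGA or UAG",
          class = "smstruct_value_error")
  }
  structure(
    list(transcript = transcript, length = as.integer(length),
         utr5 = utr5, cds = cds, utr3 = utr3,
         start_codon = as.integer(start_codon),
         stop_codon = as.integer(stop_codon),
         stop_codon_id = stop_codon_id,
         motifs = motifs %||% tibble(motif = character(0), start = integer(0))),
    class = "sms_annotation"
  )
}

#' @export
print.sms_annotation <- function(x, ...) {
  fmt_iv <- function(iv) if (is.null(iv)) "-" else sprintf("%d-%d", iv[1], iv[2])
  cat(sprintf("<sms_annotation> %s (%d nt) utr5 %s, cds %s, utr3 %s, stop %s\n",
              x$transcript, x$length, fmt_iv(x$utr5), fmt_iv(x$cds),
              fmt_iv(x$utr3), x$stop_codon_id))
  invisible(x)
}

#' Read transcript annotations from a BED-like TSV
#'
#' Six columns: transcript, start, end, feature, score, strand. Coordinates
#' are 0-based half-open on disk (BED convention) and converted to the
#' package's 1-based inclusive intervals. Recognized features: `utr5`,
#' `cds`, `utr3`, `start_codon`, `stop_codon` (score column carries the
#' stop-codon identity for `stop_codon` rows), and `motif:<name>` rows whose
#' start gives the motif position. Strand must be `+` (transcript
#' coordinates).
#'
#' @param path TSV file path.
#' @return Named list of [annotation()] objects.
#' @export
read_annotation <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = FALSE,
                          col.names = c("transcript", "start", "end",
                                        "feature", "score", "strand"),
                          colClasses = c("character", "integer", "integer",
                                         "character", "character", "character"))
  if (any(df$strand != "+")) {
    abort("annotation strand must be '+' (transcript coordinates)",
          class = "smstruct_format_error")
  }
  out <- lapply(split(df, df$transcript), function(g) {
    len <- max(g$end)
    get_iv <- function(feat) {
      row <- g[g$feature == feat, , drop = FALSE]
      if (!nrow(row)) NULL else c(row$start[1] + 1L, row$end[1])
    }
    stop_row <- g[g$feature == "stop_codon", , drop = FALSE]
    start_row <- g[g$feature == "start_codon", , drop = FALSE]
    motif_rows <- g[startsWith(g$feature, "motif:"), , drop = FALSE]
    annotation(
      transcript = g$transcript[1], length = len,
      utr5 = get_iv("utr5"), cds = get_iv("cds"), utr3 = get_iv("utr3"),
      start_codon = if (nrow(start_row)) start_row$start[1] + 1L else NA_integer_,
      stop_codon = if (nrow(stop_row)) stop_row$start[1] + 1L else NA_integer_,
      stop_codon_id = if (nrow(stop_row)) stop_row$score[1] else NA_character_,
      motifs = if (nrow(motif_rows)) {
        tibble(motif = sub("^motif:", "", motif_rows$feature),
               start = motif_rows$start + 1L)
      } else {
        NULL
      }
    )
  })
  out
}

#' @rdname read_annotation
#' @param annotations Named list of [annotation()] objects.
#' @export
write_annotation <- function(annotations, path) {
  rows <- unlist(lapply(annotations, function(a) {
    lines <- character(0)
    add <- function(s, e, feat, score = ".") {
      sprintf("%s\t%d\t%d\t%s\t%s\t+", a$transcript, s, e, feat, score)
    }
    if (!is.null(a$utr5)) lines <- c(lines, add(a$utr5[1] - 1L, a$utr5[2], "utr5"))
    if (!is.null(a$cds)) lines <- c(lines, add(a$cds[1] - 1L, a$cds[2], "cds"))
    if (!is.null(a$utr3)) lines <- c(lines, add(a$utr3[1] - 1L, a$utr3[2], "utr3"))
    if (!is.na(a$start_codon)) {
      lines <- c(lines, add(a$start_codon - 1L, a$start_codon + 2L, "start_codon"))
    }
    if (!is.na(a$stop_codon)) {
      lines <- c(lines, add(a$stop_codon - 1L, a$stop_codon + 2L, "stop_codon",
                            a$stop_codon_id))
    }
    if (nrow(a$motifs)) {
      lines <- c(lines, vapply(seq_len(nrow(a$motifs)), function(k) {
        add(a$motifs$start[k] - 1L, a$motifs$start[k] - 1L + nchar(a$motifs$motif[k]),
            paste0("motif:", a$motifs$motif[k]))
      }, ""))
    }
    lines
  }))
  writeLines(rows, path)
  invisible(path)
}
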