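#' Read-by-position modification matrices
#'
#' Two matrix containers carry the single-molecule data. A `stat_matrix`
#' holds continuous per-read, per-base modification statistics in `[0, 1]`
#' (the semantics of a treated-vs-control current comparison: low values
#' indicate likely modification). A `mod_matrix` holds the binary calls
#' derived from it (`1` modified, `0` unmodified). Both allow `NA` cells —
#' the upstream statistic is undefined near read ends — and both are plain
#' numeric matrices with read ids as rownames plus attributes `reference`
#' (transcript name) and, for calls, `threshold_used`.
#'
#' @param x Numeric matrix (reads in rows, positions in columns). Rownames
#'   are read ids; generated as `read_1..read_n` when absent.
#' @param reference Reference/transcript name.
#' @param threshold_used Threshold the calls were made with, or `NULL`.
#' @return A `stat_matrix` or `mod_matrix` object.
#' @examples
#' m <- mod_matrix(rbind(read_a = c(1, 0, NA), read_b = c(0, 0, 1)), "tx1")
#' consensus_frequency(m)
#' @export
stat_matrix <- function(x, reference = "ref") {
  x <- as.matrix(x)
  storage.mode(x) <- "double"
  x <- validate_read_matrix(x)
  v <- x[!is.na(x)]
  if (length(v) && (min(v) < 0 || max(v) > 1)) {
    abort("statistics must lie in [0, 1]", class = "smstruct_value_error")
  }
  structure(x, reference = reference, class = c("stat_matrix", class(x)))
}

#' @rdname stat_matrix
#' @export
mod_matrix <- function(x, reference = "ref", threshold_used = NULL) {
  x <- as.matrix(x)
  storage.mode(x) <- "double"
  x <- validate_read_matrix(x)
  v <- x[!is.na(x)]
  if (length(v) && !all(v %in% c(0, 1))) {
    abort("calls must be 0, 1 or NA", class = "smstruct_value_error")
  }
  structure(x, reference = reference, threshold_used = threshold_used,
            class = c("mod_matrix", class(x)))
}

validate_read_matrix <- function(x) {
  if (nrow(x) < 1L || ncol(x) < 1L) {
    abort("matrix must have at least one read and one position",
          class = "smstruct_format_error")
  }
  if (is.null(rownames(x))) {
    rownames(x) <- paste0("read_", seq_len(nrow(x)))
  }
  if (anyDuplicated(rownames(x))) {
    abort("read ids must be unique", class = "smstruct_format_error")
  }
  x
}

#' @export
print.stat_matrix <- function(x, ...) {
  cat(sprintf("<stat_matrix> %d reads x %d positions, reference '%s' (%.1f%% missing)\n",
              nrow(x), ncol(x), attr(x, "reference"), 100 * mean(is.na(x))))
  invisible(x)
}

#' @export
print.mod_matrix <- function(x, ...) {
  thr <- attr(x, "threshold_used")
  cat(sprintf("<mod_matrix> %d reads x %d positions, reference '%s'%s\n",
              nrow(x), ncol(x), attr(x, "reference"),
              if (is.null(thr)) "" else sprintf(", threshold %.3g", thr)))
  invisible(x)
}

# subsetting keeps class and attributes when the result is still a matrix
#' @export
`[.mod_matrix` <- function(x, i, j, ..., drop = FALSE) {
  out <- NextMethod(drop = drop)
  if (is.matrix(out)) {
    out <- structure(out, reference = attr(x, "reference"),
                     threshold_used = attr(x, "threshold_used"),
                     class = class(x))
  }
  out
}

#' @export
`[.stat_matrix` <- function(x, i, j, ..., drop = FALSE) {
  out <- NextMethod(drop = drop)
  if (is.matrix(out)) {
    out <- structure(out, reference = attr(x, "reference"), class = class(x))
  }
  out
}

#' @export
#' @method as_tibble stat_matrix
as_tibble.stat_matrix <- function(x, ...) {
  read_matrix_to_tibble(x, "stat")
}

#' @export
#' @method as_tibble mod_matrix
as_tibble.mod_matrix <- function(x, ...) {
  read_matrix_to_tibble(x, "call")
}

read_matrix_to_tibble <- function(x, value_name) {
  tibble(
    read_id = rep(rownames(x), times = ncol(x)),
    position = rep(seq_len(ncol(x)), each = nrow(x)),
    !!value_name := as.vector(unclass(x)[, , drop = FALSE])
  )
}

# ---- TSV dialect -----------------------------------------------------------
# header: read_id <tab> 1 <tab> 2 ...; missing cells written as "NA"

read_matrix_tsv <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (length(lines) < 2L) {
    abort("matrix file needs a header and at least one read",
          class = "smstruct_format_error")
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  width <- length(fields[[1]])
  rag <- which(lengths(fields) != width)
  if (length(rag)) {
    abort(sprintf("ragged row at line %d (%d fields, expected %d)",
                  rag[1], lengths(fields)[rag[1]], width),
          class = "smstruct_format_error")
  }
  header <- fields[[1]]
  if (header[1] != "read_id") {
    abort("first header column must be 'read_id'", class = "smstruct_format_error")
  }
  body <- fields[-1]
  ids <- vapply(body, `[[`, "", 1L)
  cells <- vapply(body, function(f) f[-1], character(width - 1L))
  cells <- matrix(cells, ncol = width - 1L, byrow = TRUE)
  cells[cells == "" | cells == "NA"] <- NA_character_
  vals <- suppressWarnings(array(as.numeric(cells), dim = dim(cells)))
  bad <- which(is.na(vals) & !is.na(cells))
  if (length(bad)) {
    abort(sprintf("non-numeric cell '%s'", cells[bad[1]]),
          class = "smstruct_value_error")
  }
  rownames(vals) <- ids
  colnames(vals) <- header[-1]
  vals
}

write_matrix_tsv <- function(x, path) {
  header <- paste(c("read_id", seq_len(ncol(x))), collapse = "\t")
  fmt <- function(v) {
    out <- format(v, digits = 15, trim = TRUE, scientific = FALSE)
    out[is.na(v)] <- "NA"
    out
  }
  rows <- vapply(seq_len(nrow(x)), function(i) {
    paste(c(rownames(x)[i], fmt(unclass(x)[i, ])), collapse = "\t")
  }, "")
  writeLines(c(header, rows), path)
  invisible(path)
}

#' Read and write matrix TSV files
#'
#' Tab-separated dialect with header `read_id` followed by 1-based position
#' labels; missing cells are `NA`. `load(write(m))` round-trips exactly.
#'
#' @param path File path.
#' @param reference Reference name to attach (defaults to the file stem).
#' @return A [stat_matrix()] or [mod_matrix()].
#' @export
read_stat_matrix <- function(path, reference = NULL) {
  vals <- read_matrix_tsv(path)
  stat_matrix(vals, reference = reference %||% file_stem(path))
}

#' @rdname read_stat_matrix
#' @export
read_mod_matrix <- function(path, reference = NULL) {
  vals <- read_matrix_tsv(path)
  mod_matrix(vals, reference = reference %||% file_stem(path))
}

#' @rdname read_stat_matrix
#' @param x Matrix to write.
#' @export
write_stat_matrix <- function(x, path) write_matrix_tsv(x, path)

#' @rdname read_stat_matrix
#' @export
write_mod_matrix <- function(x, path) write_matrix_tsv(x, path)

file_stem <- function(path) sub("\\.[^.]*$", "", basename(path))

#' Per-read modification counts
#'
#' Number of called-modified bases per read, counted over non-missing cells.
#'
#' @param m A [mod_matrix()].
#' @return Named integer vector, one entry per read.
#' @export
modification_counts <- function(m) {
  stopifnot(inherits(m, "mod_matrix"))
  counts <- rowSums(unclass(m) == 1, na.rm = TRUE)
  setNames(as.integer(counts), rownames(m))
}
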