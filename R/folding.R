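# Constrained secondary-structure folding.
#
# The builtin engine is a Nussinov-style base-pair maximization over
# Watson-Crick (AU, GC) plus GU wobble pairs with a minimum hairpin loop of
# three unpaired bases, honoring hard constraints that forbid listed
# positions from pairing. It is deliberately not a thermodynamic model; an
# external command (e.g. a nearest-neighbor energy folder) can be plugged in
# through `engine = sms_external_engine(...)`.

can_pair_chars <- function(a, b) {
  (a == "A" & b == "U") | (a == "U" & b == "A") |
    (a == "G" & b == "C") | (a == "C" & b == "G") |
    (a == "G" & b == "U") | (a == "U" & b == "G")
}

#' Fold a sequence with hard constraints
#'
#' Predicts a nested secondary structure for `sequence` while forbidding the
#' `banned` positions from base-pairing — the in-silico counterpart of
#' folding a read with its chemically modified bases excluded from stems.
#'
#' The builtin engine maximizes the number of Watson-Crick + GU pairs with a
#' minimum hairpin loop of 3 and reports `energy_score = -pair_count`; ties
#' in the dynamic program are broken deterministically by pairing the
#' smallest opening index with its smallest admissible partner.
#'
#' @param sequence RNA sequence string.
#' @param banned Integer positions (1-based) forbidden from pairing.
#' @param engine `"builtin"` or an engine created by
#'   [sms_external_engine()].
#' @return An [rna_structure][parse_dotbracket] with attribute
#'   `energy_score`.
#' @examples
#' constrained_fold("GGGGAAAACCCC")$dotbracket  # "((((....))))"
#' @export
constrained_fold <- function(sequence, banned = integer(0), engine = "builtin") {
  sequence <- toupper(gsub("T", "U", sequence, fixed = TRUE))
  n <- nchar(sequence)
  stopifnot(all(banned >= 1), all(banned <= n))
  if (inherits(engine, "sms_external_engine")) {
    return(external_fold(sequence, banned, engine))
  }
  if (!identical(engine, "builtin")) {
    abort("engine must be \"builtin\" or an sms_external_engine()",
          class = "smstruct_config_error")
  }
  chars <- strsplit(sequence, "", fixed = TRUE)[[1]]
  allowed <- !(seq_len(n) %in% banned)
  db <- nussinov_trace(chars, allowed)
  s <- parse_dotbracket(db, sequence = sequence)
  attr(s, "energy_score") <- -(sum(!is.na(s$pair_table)) / 2)
  s
}

MIN_LOOP <- 3L

nussinov_fill <- function(chars, allowed) {
  n <- length(chars)
  M <- matrix(0L, n, n)
  if (n < MIN_LOOP + 2L) return(M)
  for (span in (MIN_LOOP + 1L):(n - 1L)) {
    for (i in seq_len(n - span)) {
      j <- i + span
      best <- M[i + 1L, j]
      if (allowed[i]) {
        ks <- (i + MIN_LOOP + 1L):j
        ks <- ks[allowed[ks] & can_pair_chars(chars[i], chars[ks])]
        if (length(ks)) {
          inner <- ifelse(ks - 1L >= i + 1L, M[cbind(i + 1L, pmax(ks - 1L, i + 1L))], 0L)
          inner[ks - 1L < i + 1L] <- 0L
          right <- ifelse(ks + 1L <= j, M[cbind(pmin(ks + 1L, j), j)], 0L)
          right[ks + 1L > j] <- 0L
          best <- max(best, max(1L + inner + right))
        }
      }
      M[i, j] <- best
    }
  }
  M
}

nussinov_trace <- function(chars, allowed) {
  n <- length(chars)
  db <- rep(".", n)
  if (n == 0) return("")
  M <- nussinov_fill(chars, allowed)
  stack <- list(c(1L, n))
  while (length(stack)) {
    ij <- stack[[length(stack)]]
    stack[[length(stack)]] <- NULL
    i <- ij[1]; j <- ij[2]
    while (i < j) {
      if (j - i <= MIN_LOOP) break
      target <- M[i, j]
      paired_here <- FALSE
      if (allowed[i]) {
        for (k in (i + MIN_LOOP + 1L):j) {    # smallest partner first
          if (!allowed[k] || !can_pair_chars(chars[i], chars[k])) next
          inner <- if (k - 1L >= i + 1L) M[i + 1L, k - 1L] else 0L
          right <- if (k + 1L <= j) M[k + 1L, j] else 0L
          if (1L + inner + right == target) {
            db[i] <- "("
            db[k] <- ")"
            if (k + 1L <= j) stack[[length(stack) + 1L]] <- c(k + 1L, j)
            j <- k - 1L
            i <- i + 1L
            paired_here <- TRUE
            break
          }
        }
      }
      if (!paired_here) i <- i + 1L
    }
  }
  paste(db, collapse = "")
}

#' Plug in an external folding engine
#'
#' Describes a shell command implementing the folding contract: the command
#' receives a FASTA record on stdin followed by a constraint line (`x` =
#' forced unpaired, `.` = free) and must print a dot-bracket line (the first
#' line of output containing only `(`, `)`, `.` is used). An optional energy
#' in trailing "( -12.3 )" notation on that line is captured as the
#' `energy_score`.
#'
#' @param command Command to run (invoked via [system2()]).
#' @param args Character vector of arguments.
#' @return An object of class `sms_external_engine`.
#' @export
sms_external_engine <- function(command, args = character(0)) {
  structure(list(command = command, args = args),
            class = "sms_external_engine")
}

external_fold <- function(sequence, banned, engine) {
  n <- nchar(sequence)
  constraint <- rep(".", n)
  constraint[banned] <- "x"
  input <- c(">query", sequence, paste(constraint, collapse = ""))
  out <- suppressWarnings(
    system2(engine$command, engine$args, input = input, stdout = TRUE)
  )
  status <- attr(out, "status") %||% 0L
  if (status != 0L) {
    abort(sprintf("external folding engine failed (exit %d)", status),
          class = "smstruct_config_error")
  }
  db_lines <- grep("^[().]+", out, value = TRUE)
  if (!length(db_lines)) {
    abort("external engine produced no dot-bracket line",
          class = "smstruct_config_error")
  }
  line <- db_lines[1]
  db <- sub("^([().]+).*$", "\\1", line)
  energy <- suppressWarnings(as.numeric(
    sub("^.*\\(\\s*(-?[0-9.]+)\\s*\\)\\s*$", "\\1", line)
  ))
  s <- parse_dotbracket(db, sequence = sequence)
  if (any(!is.na(s$pair_table[banned]))) {
    abort("external engine paired a banned position",
          class = "smstruct_config_error")
  }
  attr(s, "energy_score") <- if (is.na(energy)) -(sum(!is.na(s$pair_table)) / 2) else energy
  s
}
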