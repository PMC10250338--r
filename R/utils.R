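`%||%` <- function(x, y) if (is.null(x)) y else x

#' Signal a validation error
#'
#' Validation failures get a dedicated condition class so callers (and the
#' command-line wrapper, which maps them to exit code 2) can distinguish bad
#' input from runtime failure.
#' @param ... message parts passed to [sprintf()]-free [paste0()].
#' @keywords internal
#' @noRd
stop_validation <- function(...) {
  stop(errorCondition(paste0(...), class = c("minicircler_validation_error",
                                             "error", "condition")))
}

is_count <- function(x) {
  is.numeric(x) && length(x) == 1L && is.finite(x) && x >= 1 && x == floor(x)
}

is_fraction <- function(x, lo = 0, hi = 1) {
  is.numeric(x) && length(x) == 1L && is.finite(x) && x >= lo && x <= hi
}

DNA_LETTERS <- c("A", "C", "G", "T")

#' @noRd
check_dna <- function(x, what = "sequence", allow_n = TRUE) {
  pat <- if (allow_n) "^[ACGTN]*$" else "^[ACGT]*$"
  bad <- !grepl(pat, x)
  if (any(bad)) {
    stop_validation(what, " contains non-ACGT",
                    if (allow_n) "N" else "", " characters (first offender: ",
                    which(bad)[1L], ")")
  }
  invisible(x)
}

#' Reverse complement of character DNA sequences
#' @param x character vector of ACGTN sequences.
#' @return character vector of the same length.
#' @export
revcomp <- function(x) {
  if (length(x) == 0L) return(character())
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

#' Random DNA of a given length and GC content
#'
#' Bases are drawn i.i.d. with P(G) = P(C) = gc/2. Caller is responsible for
#' seeding the RNG.
#' @param n length in bp.
#' @param gc target GC fraction in (0, 1).
#' @return a single character string.
#' @export
random_dna <- function(n, gc = 0.5) {
  if (!is_fraction(gc) || gc <= 0 || gc >= 1) {
    stop_validation("gc must be in (0, 1)")
  }
  if (n == 0L) return("")
  p <- c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)
  paste(sample(DNA_LETTERS, n, replace = TRUE, prob = p), collapse = "")
}

# Derive a reproducible child seed (< 2^31) from a master seed and a stream
# offset, so each module draws from an independent stream.
child_seed <- function(seed, offset) {
  m <- 2147483647
  as.integer(((as.double(seed) %% m) * 48271 + 12345 + offset * 7919) %% m)
}

gc_fraction_chr <- function(seq) {
  counts <- table(factor(strsplit(seq, "", fixed = TRUE)[[1L]],
                         levels = c("A", "C", "G", "T")))
  denom <- sum(counts)
  if (denom == 0) return(NA_real_)
  unname((counts[["G"]] + counts[["C"]]) / denom)
}

#' Substring of a circular sequence
#'
#' 0-based start; the extraction wraps past the origin (and may traverse the
#' circle several times, e.g. for rolling-circle products).
#' @param seq circular DNA string.
#' @param start 0-based start offset.
#' @param len length of the extraction.
#' @return a character string of length `len`.
#' @export
circ_substr <- function(seq, start, len) {
  L <- nchar(seq)
  if (len <= 0) return("")
  start <- start %% L
  reps <- ceiling((start + len) / L)
  substr(strrep(seq, reps), start + 1L, start + len)
}
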