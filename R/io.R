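#' Read sequences from FASTA
#'
#' Gzip is handled transparently; sequences are uppercased and validated
#' against the ACGTN alphabet; record order and ids are preserved.
#'
#' @param path FASTA file.
#' @return named character vector of sequences.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop_validation("no such file: ", path)
  x <- Biostrings::readDNAStringSet(path, format = "fasta")
  if (length(x) == 0L) {
    warning("empty FASTA file: ", path)
    return(stats::setNames(character(0), character(0)))
  }
  out <- toupper(as.character(x))
  names(out) <- sub("\\s.*$", "", names(x))
  check_dna(out, "FASTA sequence")
  out
}

#' Read reads from FASTQ
#'
#' Validates the 4-line record structure first (reporting the offending
#' line number), then parses. Gzip is transparent.
#'
#' @param path FASTQ file.
#' @return data.frame: read_id, sequence, quality.
#' @export
read_fastq <- function(path) {
  if (!file.exists(path)) stop_validation("no such file: ", path)
  con <- gzfile(path, "rt")
  on.exit(close(con))
  lines <- readLines(con, warn = FALSE)
  if (length(lines) == 0L) {
    warning("empty FASTQ file: ", path)
    return(data.frame(read_id = character(), sequence = character(),
                      quality = character(), stringsAsFactors = FALSE))
  }
  if (length(lines) %% 4L != 0L) {
    stop_validation("truncated FASTQ record at line ",
                    4L * (length(lines) %/% 4L) + 1L)
  }
  hdr <- seq(1L, length(lines), by = 4L)
  bad <- hdr[!startsWith(lines[hdr], "@")]
  if (length(bad)) stop_validation("malformed FASTQ header at line ", bad[1L])
  plus <- hdr + 2L
  bad <- plus[!startsWith(lines[plus], "+")]
  if (length(bad)) stop_validation("malformed FASTQ separator at line ",
                                   bad[1L])
  seqs <- toupper(lines[hdr + 1L])
  quals <- lines[hdr + 3L]
  mism <- which(nchar(seqs) != nchar(quals))
  if (length(mism)) {
    stop_validation("quality length differs from sequence length at line ",
                    hdr[mism[1L]] + 3L)
  }
  check_dna(seqs, "FASTQ sequence")
  data.frame(read_id = sub("\\s.*$", "", sub("^@", "", lines[hdr])),
             sequence = seqs, quality = quals, stringsAsFactors = FALSE)
}

#' Write sequences to FASTA
#' @param seqs named character vector.
#' @param path output file (".gz" suffix enables compression).
#' @return the path, invisibly.
#' @export
write_fasta <- function(seqs, path) {
  x <- Biostrings::DNAStringSet(seqs)
  Biostrings::writeXStringSet(x, path, format = "fasta",
                              compress = endsWith(path, ".gz"))
  invisible(path)
}

#' Write reads to FASTQ
#' @param reads data.frame with read_id, sequence, quality.
#' @param path output file (".gz" suffix enables compression).
#' @return the path, invisibly.
#' @export
write_fastq <- function(reads, path) {
  con <- if (endsWith(path, ".gz")) gzfile(path, "wt") else file(path, "wt")
  on.exit(close(con))
  writeLines(paste0("@", reads$read_id, "\n", reads$sequence, "\n+\n",
                    reads$quality), con)
  invisible(path)
}

#' Read/write tab-separated tables
#' @param path file path.
#' @return data.frame.
#' @export
read_tsv <- function(path) {
  read.delim(path, sep = "\t", stringsAsFactors = FALSE, check.names = FALSE)
}

#' @rdname read_tsv
#' @param x data.frame to write.
#' @export
write_tsv <- function(x, path) {
  write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
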