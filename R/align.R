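#' Classifier and alignment configuration
#'
#' Thresholds mirror the read-collection filters used in the study:
#' reads are *collected* at pairwise identity >= 80% to a mitochondrial
#' gene; the *strict* filter additionally requires the hit to cover >= 80%
#' of the CDS at identity >= 90%; for intron-rich genes the coverage
#' requirement is replaced by a minimum hit length of 200 bp.
#'
#' @param match,mismatch,gap_open,gap_extend local alignment scoring. A gap
#'   of length L costs `gap_open + L * gap_extend`.
#' @param min_identity_collect,min_identity_strict identity thresholds
#'   (matches / alignment columns, gaps counted as columns).
#' @param min_cds_fraction minimum fraction of the CDS covered by the
#'   reference interval of a hit (strict mode).
#' @param min_hit_len_intron_rich minimum alignment length in bp
#'   (intron-rich mode).
#' @param score_floor minimum alignment score for a hit to be reported.
#' @param seed_k,min_seeds exact k-mer seeding used for long reads (full
#'   dynamic programming is used whenever `read length * ref length <=
#'   full_dp_max_cells`).
#' @param max_hits maximum hits reported per read/reference/strand.
#' @param max_read_overlap bp of read-interval overlap tolerated between
#'   retained hits when resolving a read into units.
#' @return a `classifier_config` list.
#' @export
classifier_config <- function(match = 2, mismatch = -3, gap_open = 5,
                              gap_extend = 2, min_identity_collect = 0.80,
                              min_identity_strict = 0.90,
                              min_cds_fraction = 0.80,
                              min_hit_len_intron_rich = 200L,
                              score_floor = 60, seed_k = 13L, min_seeds = 3L,
                              full_dp_max_cells = 3e5, max_hits = 64L,
                              max_read_overlap = 20L) {
  for (v in c(min_identity_collect, min_identity_strict, min_cds_fraction)) {
    if (!is_fraction(v) || v <= 0) stop_validation("thresholds must be in (0, 1]")
  }
  if (!is_count(min_hit_len_intron_rich)) {
    stop_validation("min_hit_len_intron_rich must be >= 1")
  }
  structure(list(match = match, mismatch = mismatch, gap_open = gap_open,
                 gap_extend = gap_extend,
                 min_identity_collect = min_identity_collect,
                 min_identity_strict = min_identity_strict,
                 min_cds_fraction = min_cds_fraction,
                 min_hit_len_intron_rich = as.integer(min_hit_len_intron_rich),
                 score_floor = score_floor, seed_k = as.integer(seed_k),
                 min_seeds = as.integer(min_seeds),
                 full_dp_max_cells = full_dp_max_cells,
                 max_hits = as.integer(max_hits),
                 max_read_overlap = as.integer(max_read_overlap)),
            class = "classifier_config")
}

as_named_seqs <- function(x, what) {
  if (is.data.frame(x)) x <- stats::setNames(x$sequence, x$read_id %||% x$id)
  if (inherits(x, "DNAStringSet")) x <- as.character(x)
  if (!is.character(x)) stop_validation(what, " must be named sequences")
  if (length(x) == 0L) return(stats::setNames(character(0), character(0)))
  if (is.null(names(x)) || any(names(x) == "")) {
    names(x) <- paste0(what, "_", seq_along(x))
  }
  x <- toupper(x)
  check_dna(x, what)
  x
}

#' Align reads locally against reference sequences
#'
#' Affine-gap Smith-Waterman on both strands. Long read/reference pairs are
#' k-mer seeded; within each candidate window the optimal local alignment is
#' taken, its read interval masked, and the flanks re-searched, so several
#' non-overlapping hits per read (concatemer units) are reported. Minus
#' strand hits are reported in forward-read coordinates. Identity is
#' matches / alignment columns with gaps counted as columns.
#'
#' @param reads named character vector (or data.frame with `read_id`,
#'   `sequence`) of reads.
#' @param refs named character vector of references.
#' @param config a [classifier_config()].
#' @return data.frame of hits: read_id, ref_id, read_start, read_end,
#'   ref_start, ref_end (0-based half-open), strand, identity, score,
#'   matches, columns.
#' @export
align_reads <- function(reads, refs, config = classifier_config()) {
  reads <- as_named_seqs(reads, "read")
  refs <- as_named_seqs(refs, "ref")
  if (length(reads) == 0L || length(refs) == 0L) {
    stop_validation("reads and refs must be non-empty")
  }
  df <- .sw_scan_batch(unname(reads), unname(refs), config$match,
                       config$mismatch, config$gap_open, config$gap_extend,
                       config$score_floor, config$seed_k, config$min_seeds,
                       config$full_dp_max_cells, config$max_hits)
  out <- data.frame(read_id = names(reads)[df$read_idx],
                    ref_id = names(refs)[df$ref_idx],
                    df[, c("read_start", "read_end", "ref_start", "ref_end",
                           "strand", "identity", "score", "matches",
                           "columns")],
                    stringsAsFactors = FALSE)
  out[order(match(out$read_id, names(reads)), out$read_start), , drop = FALSE]
}

#' @rdname align_reads
#' @param read a single sequence (optionally named).
#' @export
align_read_to_refs <- function(read, refs, config = classifier_config()) {
  align_reads(read, refs, config)
}

#' Filter alignment hits by identity, coverage or hit length
#'
#' `collect` keeps hits with identity >= `min_identity_collect`. `strict`
#' keeps hits with identity >= `min_identity_strict` whose reference
#' interval covers >= `min_cds_fraction` of the CDS. `intron_rich` keeps
#' hits with identity >= `min_identity_strict` and alignment length >=
#' `min_hit_len_intron_rich`.
#'
#' @param hits data.frame from [align_reads()].
#' @param refs named character vector of references (for CDS lengths).
#' @param config a [classifier_config()].
#' @param mode one of `"collect"`, `"strict"`, `"intron_rich"`.
#' @return the filtered hits data.frame.
#' @export
filter_hits <- function(hits, refs, config = classifier_config(),
                        mode = c("collect", "strict", "intron_rich")) {
  if (length(mode) != 1L || !mode %in% c("collect", "strict", "intron_rich")) {
    stop_validation("unknown filter mode: ", paste(mode, collapse = "/"))
  }
  if (nrow(hits) == 0L) return(hits)
  refs <- as_named_seqs(refs, "ref")
  unknown <- setdiff(unique(hits$ref_id), names(refs))
  if (length(unknown)) stop_validation("hits reference unknown refs: ",
                                       paste(unknown, collapse = ", "))
  keep <- switch(mode,
    collect = hits$identity >= config$min_identity_collect,
    strict = {
      cds_len <- nchar(refs)[hits$ref_id]
      hits$identity >= config$min_identity_strict &
        (hits$ref_end - hits$ref_start) >= config$min_cds_fraction * cds_len
    },
    intron_rich = hits$identity >= config$min_identity_strict &
      hits$columns >= config$min_hit_len_intron_rich)
  hits[keep, , drop = FALSE]
}

# Greedy score-descending selection of hits on one read, tolerating up to
# max_overlap bp of read-interval overlap (alignment end wobble).
resolve_read_hits <- function(hits, max_overlap = 20L) {
  if (nrow(hits) <= 1L) return(hits)
  ord <- order(-hits$score, hits$read_start)
  sel <- logical(nrow(hits))
  starts <- ends <- numeric(0)
  for (i in ord) {
    s <- hits$read_start[i]
    e <- hits$read_end[i]
    ov <- pmax(0, pmin(e, ends) - pmax(s, starts))
    if (all(ov <= max_overlap)) {
      sel[i] <- TRUE
      starts <- c(starts, s)
      ends <- c(ends, e)
    }
  }
  out <- hits[sel, , drop = FALSE]
  out[order(out$read_start), , drop = FALSE]
}

#' Per-gene read-length distributions
#'
#' For each gene, the full lengths of reads carrying a kept (strict-filter)
#' hit are binned; the modal bin midpoint estimates the originating circle
#' length. Reads hitting several genes contribute to each.
#'
#' @param reads named character vector or data.frame of reads.
#' @param kept_hits strict-filtered hits ([filter_hits()]).
#' @param circles optional list of `minicircle_spec`; if given, the relative
#'   deviation of the mode from the circle length is reported per gene.
#' @param binwidth histogram bin width in bp.
#' @return data.frame with one row per gene: gene, n_reads, mode_length,
#'   empty flag and (with `circles`) circle_length, rel_mode_error. The
#'   per-gene histograms are attached as attribute `"histograms"`.
#' @export
length_distribution <- function(reads, kept_hits, circles = NULL,
                                binwidth = 50L) {
  reads <- as_named_seqs(reads, "read")
  read_len <- stats::setNames(nchar(reads), names(reads))
  genes <- sort(unique(kept_hits$ref_id))
  circle_len <- NULL
  if (!is.null(circles)) {
    circle_len <- stats::setNames(
      vapply(circles, function(x) nchar(x$sequence), 1L),
      vapply(circles, `[[`, "", "gene"))
    genes <- union(genes, names(circle_len))
  }
  hists <- list()
  rows <- lapply(genes, function(g) {
    rid <- unique(kept_hits$read_id[kept_hits$ref_id == g])
    lens <- unname(read_len[rid])
    if (length(lens) == 0L) {
      hists[[g]] <<- data.frame(bin_start = integer(), count = integer())
      row <- data.frame(gene = g, n_reads = 0L, mode_length = NA_real_,
                        empty = TRUE, stringsAsFactors = FALSE)
    } else {
      bins <- floor(lens / binwidth)
      tab <- table(bins)
      modal <- as.integer(names(tab)[which.max(tab)])
      hists[[g]] <<- data.frame(bin_start = as.integer(names(tab)) * binwidth,
                                count = as.integer(tab))
      # mode = most frequent exact length within the modal bin (ties:
      # smallest), so degenerate all-equal inputs report their value exactly
      in_bin <- lens[bins == modal]
      lt <- table(in_bin)
      row <- data.frame(gene = g, n_reads = length(lens),
                        mode_length = as.numeric(names(lt)[which.max(lt)]),
                        empty = FALSE, stringsAsFactors = FALSE)
    }
    if (!is.null(circle_len) && g %in% names(circle_len)) {
      row$circle_length <- unname(circle_len[g])
      row$rel_mode_error <- abs(row$mode_length - row$circle_length) /
        row$circle_length
    } else if (!is.null(circle_len)) {
      row$circle_length <- NA_integer_
      row$rel_mode_error <- NA_real_
    }
    row
  })
  out <- do.call(rbind, rows)
  attr(out, "histograms") <- hists
  out
}
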