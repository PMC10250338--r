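#' Simulation parameters for long-read generation
#'
#' Defaults encode the stated world of the study system: read lengths peak
#' at the originating circle's length (truncated normal, sd = 10% of circle
#' length), concatemers are rare (1% of reads, split 60/40 homo/hetero), and
#' sequencing error is injected as substitutions and indels in the sequence
#' itself (qualities are a constant Q20 placeholder).
#'
#' @param n_reads number of reads.
#' @param sub_rate,indel_rate per-base error rates in \[0, 0.3\].
#' @param fraction_homo,fraction_hetero,fraction_background category mixing
#'   fractions; the remainder are single-circle reads.
#' @param length_sigma read-length sd as a fraction of circle length.
#' @param min_len minimum read length in bp.
#' @param background_gc GC of background (non-mitochondrial) reads.
#' @param allow_illegitimate if `TRUE`, hetero reads may join genes from
#'   different constant groups (off by default: recombination requires
#'   constant-region homology).
#' @param seed integer master seed.
#' @return a `simulation_params` list.
#' @export
simulation_params <- function(n_reads = 1000L, sub_rate = 0, indel_rate = 0,
                              fraction_homo = 0.006, fraction_hetero = 0.004,
                              fraction_background = 0, length_sigma = 0.10,
                              min_len = 100L, background_gc = 0.5,
                              allow_illegitimate = FALSE, seed = 1L) {
  if (!is_count(n_reads)) stop_validation("n_reads must be a positive integer")
  for (r in c(sub_rate, indel_rate)) {
    if (!is_fraction(r, 0, 0.3)) stop_validation("error rates must be in [0, 0.3]")
  }
  fr <- c(fraction_homo, fraction_hetero, fraction_background)
  if (any(!vapply(fr, is_fraction, TRUE))) {
    stop_validation("fractions must be in [0, 1]")
  }
  if (sum(fr) > 1) stop_validation("category fractions must sum to <= 1")
  structure(list(n_reads = as.integer(n_reads), sub_rate = sub_rate,
                 indel_rate = indel_rate, fraction_homo = fraction_homo,
                 fraction_hetero = fraction_hetero,
                 fraction_background = fraction_background,
                 length_sigma = length_sigma, min_len = as.integer(min_len),
                 background_gc = background_gc,
                 allow_illegitimate = isTRUE(allow_illegitimate),
                 seed = as.integer(seed)),
            class = "simulation_params")
}

#' Inject substitution and indel errors into a DNA sequence
#'
#' Each position is independently substituted with probability `sub_rate`
#' (to one of the three other bases) and receives an indel with probability
#' `indel_rate` (insertion of a random base before it, or deletion, with
#' equal probability), so the expected substitution count is
#' `sub_rate * nchar(seq)`.
#'
#' @param seq DNA string (ACGTN).
#' @param sub_rate,indel_rate per-base rates in \[0, 0.3\].
#' @param seed integer seed; the global RNG state is preserved.
#' @return the mutated sequence.
#' @export
mutate_sequence <- function(seq, sub_rate, indel_rate, seed = 1L) {
  if (!is_fraction(sub_rate, 0, 0.3) || !is_fraction(indel_rate, 0, 0.3)) {
    stop_validation("rates must be in [0, 0.3]")
  }
  check_dna(seq)
  if (sub_rate == 0 && indel_rate == 0) return(seq)
  withr::with_seed(as.integer(seed), {
    s <- strsplit(seq, "", fixed = TRUE)[[1L]]
    n <- length(s)
    if (n == 0L) return(seq)
    sub_at <- which(runif(n) < sub_rate)
    if (length(sub_at)) {
      # substitute with one of the three other bases, uniformly
      shift <- sample.int(3L, length(sub_at), replace = TRUE)
      cur <- match(s[sub_at], DNA_LETTERS, nomatch = 0L)
      repl <- ifelse(cur == 0L, sample(DNA_LETTERS, length(sub_at), TRUE),
                     DNA_LETTERS[((cur - 1L + shift) %% 4L) + 1L])
      s[sub_at] <- repl
    }
    ind_at <- runif(n) < indel_rate
    if (any(ind_at)) {
      is_ins <- runif(n) < 0.5
      pieces <- s
      ins <- ind_at & is_ins
      del <- ind_at & !is_ins
      if (any(ins)) {
        pieces[ins] <- paste0(sample(DNA_LETTERS, sum(ins), TRUE), s[ins])
      }
      pieces[del] <- ""
      s <- pieces
    }
    paste(s, collapse = "")
  })
}

#' Simulate nanopore-style long reads from minicircles with ground truth
#'
#' Reads fall into four categories. *single*: a linear fragment starting at
#' a uniform offset on one circle, length drawn from a truncated normal
#' centred on the circle length and clamped above at the circle length (a
#' once-nicked circular molecule cannot be longer than the circle). *homo*: `k >= 2` tandem copies of one
#' circle (rolling-circle product), linearized at a uniform offset. *hetero*:
#' two distinct-gene circles sharing a constant group, joined in the
#' alternating cassette-constant-cassette-constant structure produced by
#' recombination across constant-region homology. *background*: random DNA.
#' Each read is drawn from either strand with probability 0.5, and errors
#' are injected with [mutate_sequence()].
#'
#' @param circles list of `minicircle_spec` from [generate_minicircles()].
#' @param params a `simulation_params` object.
#' @return list with `reads` (data.frame: read_id, sequence, quality) and
#'   `truth` (data.frame: read_id, category, genes, unit_count,
#'   origin_offset, strand, length).
#' @export
simulate_reads <- function(circles, params) {
  stopifnot(inherits(params, "simulation_params"))
  if (length(circles) == 0L) stop_validation("need at least one circle")
  n <- params$n_reads
  genes <- vapply(circles, `[[`, "", "gene")
  groups <- vapply(circles, `[[`, "", "constant_group")
  lens <- vapply(circles, function(x) nchar(x$sequence), 1L)

  # groups eligible for legitimate hetero joins need >= 2 distinct genes
  elig_groups <- names(which(tapply(genes, groups,
                                    function(g) length(unique(g)) >= 2)))
  withr::with_seed(child_seed(params$seed, 3L), {
    probs <- c(single = 1 - params$fraction_homo - params$fraction_hetero -
                 params$fraction_background,
               homo = params$fraction_homo, hetero = params$fraction_hetero,
               background = params$fraction_background)
    category <- sample(names(probs), n, replace = TRUE, prob = probs)
    if (length(elig_groups) == 0L && !params$allow_illegitimate &&
        any(category == "hetero")) {
      stop_validation("fraction_hetero > 0 but no constant group joins two ",
                      "distinct genes")
    }
    mut_seeds <- sample.int(2147483646L, n)
    recs <- vector("list", n)
    for (i in seq_len(n)) {
      cat_i <- category[i]
      if (cat_i == "background") {
        len <- max(200L, round(rnorm(1, 3000, 1000)))
        seq <- random_dna(len, params$background_gc)
        tr <- list(genes = "", unit_count = 0L, offset = NA_integer_)
      } else if (cat_i == "single") {
        ci <- sample.int(length(circles), 1L)
        L <- lens[ci]
        # a once-nicked circle linearizes to at most its own length, so the
        # truncated normal is clamped to [min_len, L]
        len <- min(L, max(params$min_len,
                          round(rnorm(1, L, params$length_sigma * L))))
        off <- sample.int(L, 1L) - 1L
        seq <- circ_substr(circles[[ci]]$sequence, off, len)
        tr <- list(genes = genes[ci], unit_count = 1L, offset = off)
      } else if (cat_i == "homo") {
        ci <- sample.int(length(circles), 1L)
        L <- lens[ci]
        k <- 2L + rpois(1, 0.5)
        off <- sample.int(L, 1L) - 1L
        seq <- circ_substr(circles[[ci]]$sequence, off, k * L)
        tr <- list(genes = genes[ci], unit_count = k, offset = off)
      } else {  # hetero
        if (params$allow_illegitimate) {
          pair <- sample(which(!duplicated(genes)), 2L)
        } else {
          grp <- if (length(elig_groups) == 1L) elig_groups else
            sample(elig_groups, 1L)
          cand <- which(groups == grp)
          repeat {
            pair <- sample(cand, 2L)
            if (genes[pair[1L]] != genes[pair[2L]]) break
          }
        }
        part <- function(ci) {
          x <- circles[[ci]]
          paste0(substr(x$sequence, x$cassette_interval[1] + 1L,
                        x$cassette_interval[2]),
                 substr(x$sequence, x$constant_interval[1] + 1L,
                        x$constant_interval[2]))
        }
        seq <- paste0(part(pair[1L]), part(pair[2L]))
        tr <- list(genes = paste(genes[pair], collapse = ","),
                   unit_count = 2L, offset = 0L)
      }
      strand <- if (runif(1) < 0.5) "+" else "-"
      if (strand == "-") seq <- revcomp(seq)
      if (params$sub_rate > 0 || params$indel_rate > 0) {
        seq <- mutate_sequence(seq, params$sub_rate, params$indel_rate,
                               seed = mut_seeds[i])
      }
      recs[[i]] <- list(seq = seq, category = cat_i, genes = tr$genes,
                        unit_count = tr$unit_count, offset = tr$offset,
                        strand = strand)
    }
  })
  seqs <- vapply(recs, `[[`, "", "seq")
  ids <- sprintf("read_%05d", seq_len(n))
  reads <- data.frame(read_id = ids, sequence = seqs,
                      quality = strrep("5", nchar(seqs)),  # Q20 placeholder
                      stringsAsFactors = FALSE)
  truth <- data.frame(
    read_id = ids,
    category = vapply(recs, `[[`, "", "category"),
    genes = vapply(recs, `[[`, "", "genes"),
    unit_count = vapply(recs, `[[`, 1L, "unit_count"),
    origin_offset = vapply(recs, `[[`, 1L, "offset"),
    strand = vapply(recs, `[[`, "", "strand"),
    length = nchar(seqs), stringsAsFactors = FALSE)
  list(reads = reads, truth = truth)
}
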