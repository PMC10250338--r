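#' Canonicalize the rotation of a circular sequence
#'
#' `lexicographic` returns the least rotation (Booth's algorithm on the
#' doubled string). `orf_anchored` (the package default, since minicircles
#' are drawn cassette first) rotates the circle so that its longest ORF
#' under genetic code 4 starts at position 0, falling back to lexicographic
#' when no ORF is found. Both modes are idempotent and rotation-invariant.
#'
#' @param seq circular DNA string.
#' @param mode `"orf_anchored"` or `"lexicographic"`.
#' @param min_len_aa minimum ORF length (aa) for anchoring.
#' @return the rotated sequence.
#' @export
canonicalize_rotation <- function(seq, mode = c("orf_anchored",
                                                "lexicographic"),
                                  min_len_aa = 30L) {
  mode <- match.arg(mode)
  check_dna(seq)
  L <- nchar(seq)
  if (L == 0L) stop_validation("empty sequence")
  if (mode == "lexicographic") {
    return(circ_substr(seq, booth_least_rotation(seq), L))
  }
  orfs <- find_orfs_table4(seq, min_len_aa = min_len_aa, circular = TRUE)
  if (nrow(orfs) == 0L) {
    return(circ_substr(seq, booth_least_rotation(seq), L))
  }
  best <- orfs[order(-orfs$length_aa, orfs$start), , drop = FALSE][1L, ]
  circ_substr(seq, best$start, L)
}

# Booth's O(n) least-rotation index (0-based) of a string.
booth_least_rotation <- function(s) {
  n <- nchar(s)
  if (n <= 1L) return(0L)
  S <- utf8ToInt(paste0(s, s))
  f <- rep(-1L, 2L * n)
  k <- 0L
  for (j in seq_len(2L * n - 1L)) {
    sj <- S[j + 1L]
    i <- f[j - k]
    while (i != -1L && sj != S[k + i + 2L]) {
      if (sj < S[k + i + 2L]) k <- j - i - 1L
      i <- f[i + 1L]
    }
    if (sj != S[k + i + 2L]) {
      if (sj < S[k + 1L]) k <- j
      f[j - k + 1L] <- -1L
    } else {
      f[j - k + 1L] <- i + 1L
    }
  }
  k %% n
}

#' Find ORFs under genetic code 4
#'
#' Six-frame search; on circular sequences the search runs across the
#' origin (on the doubled string). Under translation table 4 only TAA and
#' TAG are stop codons (TGA encodes tryptophan). ORFs require an ATG start
#' by default and a terminating stop codon.
#'
#' @param seq DNA string.
#' @param min_len_aa minimum protein length (aa, excluding the stop).
#' @param require_atg require an ATG start codon.
#' @param circular search across the origin and report wrap-aware
#'   intervals (`end` may exceed the sequence length; `start` is always in
#'   `[0, L)`).
#' @return data.frame: start, end (0-based half-open, `end > L` signals
#'   wrap), strand, frame, length_aa, protein.
#' @export
find_orfs_table4 <- function(seq, min_len_aa = 30L, require_atg = TRUE,
                             circular = TRUE) {
  if (!is_count(min_len_aa)) stop_validation("min_len_aa must be >= 1")
  check_dna(seq)
  L <- nchar(seq)
  if (L < 3L) stop_validation("sequence must be at least 3 bp")
  code4 <- Biostrings::getGeneticCode("4")
  out <- list()
  for (strand in c("+", "-")) {
    s <- if (strand == "+") seq else revcomp(seq)
    d <- if (circular) paste0(s, s) else s
    nd <- nchar(d)
    for (frame in 0:2) {
      starts_nt <- seq.int(frame + 1L, nd - 2L, by = 3L)
      codons <- substring(d, starts_nt, starts_nt + 2L)
      is_stop <- codons == "TAA" | codons == "TAG"
      is_start <- if (require_atg) codons == "ATG" else !is_stop
      stop_idx <- which(is_stop)
      prev <- 0L
      for (si in stop_idx) {
        if (si - prev >= 2L) {
          region <- (prev + 1L):(si - 1L)
          cand <- region[is_start[region]]
          if (length(cand)) {
            a <- cand[1L]
            aa_len <- si - a
            nt_len <- 3L * (aa_len + 1L)
            p0 <- starts_nt[a] - 1L
            if (aa_len >= min_len_aa && p0 < L && nt_len <= L) {
              prot <- as.character(Biostrings::translate(
                Biostrings::DNAString(substr(d, p0 + 1L, p0 + nt_len - 3L)),
                genetic.code = code4, no.init.codon = TRUE))
              start_f <- if (strand == "+") p0 else (L - (p0 + nt_len)) %% L
              out[[length(out) + 1L]] <- data.frame(
                start = start_f, end = start_f + nt_len, strand = strand,
                frame = frame, length_aa = aa_len, protein = prot,
                stringsAsFactors = FALSE)
            }
          }
        }
        prev <- si
      }
    }
  }
  if (!length(out)) {
    return(data.frame(start = integer(), end = integer(),
                      strand = character(), frame = integer(),
                      length_aa = integer(), protein = character(),
                      stringsAsFactors = FALSE))
  }
  res <- do.call(rbind, out)
  res <- unique(res)
  res[order(-res$length_aa, res$start), , drop = FALSE]
}

#' Detect maximal tandem repeat arrays
#'
#' Reports every maximal tandem array with a primitive unit of period at
#' most `max_unit` and at least `min_copies` copies (fractional terminal
#' copies allowed). Dispersed (non-tandem) extra occurrences of any
#' detected unit are reported as additional rows with `tandem = FALSE`.
#'
#' @param region DNA string.
#' @param max_unit maximal repeat unit length (bp).
#' @param min_copies minimum copy number of an array (>= 2).
#' @return data.frame: unit_seq, period, start, end (0-based half-open),
#'   copies, tandem.
#' @export
detect_tandem_repeats <- function(region, max_unit = 40L, min_copies = 2) {
  check_dna(region)
  if (min_copies < 2) stop_validation("min_copies must be >= 2")
  chars <- strsplit(region, "", fixed = TRUE)[[1L]]
  n <- length(chars)
  rows <- list()
  for (p in seq_len(min(max_unit, n %/% 2))) {
    eq <- chars[seq_len(n - p)] == chars[(p + 1L):n]
    r <- rle(eq)
    pos <- cumsum(c(1L, r$lengths))
    for (ri in which(r$values)) {
      q <- r$lengths[ri]
      alen <- q + p
      copies <- alen / p
      if (copies < min_copies) next
      i <- pos[ri]  # 1-based array start
      unit <- substr(region, i, i + p - 1L)
      if (!is_primitive_unit(unit)) next
      rows[[length(rows) + 1L]] <- data.frame(
        unit_seq = unit, period = p, start = i - 1L, end = i - 1L + alen,
        copies = copies, tandem = TRUE, stringsAsFactors = FALSE)
    }
  }
  tand <- if (length(rows)) do.call(rbind, rows) else
    data.frame(unit_seq = character(), period = integer(), start = integer(),
               end = integer(), copies = numeric(), tandem = logical(),
               stringsAsFactors = FALSE)
  # dispersed copies of detected units outside their arrays
  disp <- list()
  for (unit in unique(tand$unit_seq)) {
    m <- gregexpr(unit, region, fixed = TRUE)[[1L]]
    if (m[1L] == -1L) next
    arr <- tand[tand$unit_seq == unit, , drop = FALSE]
    p <- nchar(unit)
    for (pos0 in as.integer(m) - 1L) {
      inside <- any(pos0 >= arr$start & pos0 + p <= arr$end)
      if (!inside) {
        disp[[length(disp) + 1L]] <- data.frame(
          unit_seq = unit, period = p, start = pos0, end = pos0 + p,
          copies = 1, tandem = FALSE, stringsAsFactors = FALSE)
      }
    }
  }
  out <- rbind(tand, if (length(disp)) do.call(rbind, disp))
  out[order(out$start, out$period), , drop = FALSE]
}

is_primitive_unit <- function(unit) {
  p <- nchar(unit)
  if (p <= 1L) return(TRUE)
  divs <- which(p %% seq_len(p - 1L) == 0L)
  for (d in divs) {
    if (unit == strrep(substr(unit, 1L, d), p %/% d)) return(FALSE)
  }
  TRUE
}

#' Count occurrences of a repeat unit in a region
#'
#' Used to tabulate per-circle unit counts for a repeat catalogue, covering
#' units that occur singly (below the tandem detector's `min_copies`) or
#' dispersed rather than in tandem.
#'
#' @param region DNA string.
#' @param unit repeat unit sequence.
#' @param max_mismatch mismatches tolerated per occurrence.
#' @return integer count.
#' @export
count_repeat_units <- function(region, unit, max_mismatch = 0L) {
  length(Biostrings::matchPattern(unit, Biostrings::DNAString(region),
                                  max.mismatch = max_mismatch))
}

seqs_from_circles <- function(circles) {
  if (is.list(circles) && length(circles) &&
      inherits(circles[[1L]], "minicircle_spec")) {
    circles_as_fasta(circles)
  } else {
    as_named_seqs(circles, "circle")
  }
}

#' Segment minicircles into constant region and cassette
#'
#' The constant region of each circle is the maximal circular arc shared
#' with at least `min_share - 1` other circles at identity >=
#' `min_identity` (found by seeded local alignment of each circle, doubled
#' to cope with the origin, against every other circle); the cassette is
#' the complementary arc, which should contain the best ORF. Circles
#' sharing no arc are flagged low-confidence (their segmentation is
#' undefined from sharing alone), and pairs of effectively identical
#' circles are flagged because no cassette is callable.
#'
#' @param circles named character vector of circle sequences (canonical
#'   rotation), or a list of `minicircle_spec`.
#' @param min_share minimum number of circles sharing an arc.
#' @param min_identity minimum alignment identity for sharing.
#' @param config a [classifier_config()].
#' @param gap_tol bp gaps bridged when merging shared positions (absorbs
#'   repeat unit-count differences and alignment wobble).
#' @param min_hit minimum alignment length (columns) counted as sharing.
#' @return a list of class `segmentation`: per-circle entries with
#'   `constant_interval`, `cassette_interval` (0-based, end may exceed the
#'   length to signal wrap), `constant_seq`, flags, plus the hit table.
#' @export
segment_constant_cassette <- function(circles, min_share = 2L,
                                      min_identity = 0.90,
                                      config = classifier_config(),
                                      gap_tol = 30L, min_hit = 50L) {
  seqs <- seqs_from_circles(circles)
  k <- length(seqs)
  if (k < 2L) stop_validation("segmentation needs at least 2 circles")
  ids <- names(seqs)
  doubled <- stats::setNames(strrep(seqs, 2L), ids)
  hits <- align_reads(doubled, seqs, config)
  hits <- hits[hits$read_id != hits$ref_id &
                 hits$identity >= min_identity &
                 hits$columns >= min_hit, , drop = FALSE]
  out <- list()
  for (ci in ids) {
    L <- nchar(seqs[[ci]])
    h <- hits[hits$read_id == ci, , drop = FALSE]
    partners <- unique(h$ref_id)
    cov <- integer(L)
    for (pj in partners) {
      hp <- h[h$ref_id == pj, , drop = FALSE]
      covered <- logical(L)
      for (r in seq_len(nrow(hp))) {
        idx <- (hp$read_start[r]:(hp$read_end[r] - 1L)) %% L
        covered[idx + 1L] <- TRUE
      }
      cov <- cov + covered
    }
    # require a majority of hit partners (not just min_share - 1): a single
    # partner's chance alignment overhang would otherwise smear the boundary
    thr <- max(min_share - 1L, ceiling(length(partners) / 2))
    cand <- cov >= thr
    cand <- close_circular_gaps(cand, gap_tol)
    entry <- list(circle_id = ci, length = L, n_partners = length(partners))
    if (!any(cand)) {
      entry$constant_interval <- NULL
      entry$cassette_interval <- c(0L, L)
      entry$constant_seq <- NA_character_
      entry$low_confidence <- TRUE
      entry$whole_circle_constant <- FALSE
    } else if (all(cand)) {
      entry$constant_interval <- c(0L, L)
      entry$cassette_interval <- NULL
      entry$constant_seq <- seqs[[ci]]
      entry$low_confidence <- TRUE
      entry$whole_circle_constant <- TRUE
    } else {
      arc <- longest_circular_run(cand)
      s <- arc[1L]
      e <- arc[2L]
      entry$constant_interval <- c(s, e)
      entry$cassette_interval <- c(e %% L, e %% L + (L - (e - s)))
      entry$constant_seq <- circ_substr(seqs[[ci]], s, e - s)
      entry$low_confidence <- FALSE
      entry$whole_circle_constant <- FALSE
    }
    out[[ci]] <- entry
  }
  structure(list(circles = out, hits = hits, params = list(
    min_share = min_share, min_identity = min_identity,
    gap_tol = gap_tol, min_hit = min_hit)), class = "segmentation")
}

# close runs of FALSE of length <= gap_tol, treating the vector circularly
close_circular_gaps <- function(x, gap_tol) {
  if (gap_tol <= 0L || all(x) || !any(x)) return(x)
  n <- length(x)
  d <- c(x, x)
  r <- rle(d)
  pos <- cumsum(c(1L, r$lengths))
  for (i in which(!r$values & r$lengths <= gap_tol)) {
    lo <- pos[i]
    hi <- pos[i] + r$lengths[i] - 1L
    prev_ok <- lo > 1L && d[lo - 1L]
    next_ok <- hi < 2L * n && d[hi + 1L]
    if (prev_ok && next_ok) d[lo:hi] <- TRUE
  }
  # fold the doubled vector back
  d[seq_len(n)] | d[n + seq_len(n)]
}

# longest circular run of TRUE; returns c(start0, end0) 0-based, end may
# exceed length(x) to signal wrap
longest_circular_run <- function(x) {
  n <- length(x)
  d <- c(x, x)
  r <- rle(d)
  pos <- cumsum(c(1L, r$lengths))
  best_len <- 0L
  best_start <- 0L
  for (i in which(r$values)) {
    len <- min(r$lengths[i], n)
    if (pos[i] > n) next
    if (len > best_len) {
      best_len <- len
      best_start <- pos[i] - 1L
    }
  }
  c(best_start, best_start + best_len)
}

#' Group constant regions by single-linkage clustering
#'
#' Pairwise identity between constant arcs is the total matched bp of their
#' local alignments divided by the longer arc length; arcs at identity >=
#' `link_identity` are linked and connected components form the groups.
#' Group ids are the alphabetically smallest member circle id, so the
#' partition is independent of input order. Circles without a constant arc
#' become singleton groups.
#'
#' @param constant_seqs named character vector of constant arcs (`NA` for
#'   circles without one).
#' @param link_identity linkage threshold.
#' @param config a [classifier_config()].
#' @return named character vector mapping circle id to group id.
#' @export
group_constant_regions <- function(constant_seqs, link_identity = 0.80,
                                   config = classifier_config()) {
  ids <- names(constant_seqs)
  ok <- !is.na(constant_seqs)
  parent <- stats::setNames(ids, ids)
  find <- function(x) {
    while (parent[[x]] != x) x <- parent[[x]]
    x
  }
  if (sum(ok) >= 2L) {
    seqs <- constant_seqs[ok]
    hits <- align_reads(seqs, seqs, config)
    hits <- hits[hits$read_id != hits$ref_id, , drop = FALSE]
    if (nrow(hits)) {
      agg <- stats::aggregate(matches ~ read_id + ref_id + strand, hits, sum)
      for (r in seq_len(nrow(agg))) {
        a <- agg$read_id[r]
        b <- agg$ref_id[r]
        ident <- agg$matches[r] / max(nchar(seqs[[a]]), nchar(seqs[[b]]))
        if (ident >= link_identity) {
          ra <- find(a)
          rb <- find(b)
          if (ra != rb) parent[[max(ra, rb)]] <- min(ra, rb)
        }
      }
    }
  }
  roots <- vapply(ids, find, "")
  stats::setNames(unname(roots), ids)
}

#' Assign genes to circles by CDS alignment
#'
#' @param circles named character vector of circle sequences or list of
#'   `minicircle_spec`.
#' @param cds_refs named character vector of CDS references.
#' @param config a [classifier_config()].
#' @return data.frame: circle_id, gene, identity, cds_coverage (best hit
#'   per circle; `NA` gene when nothing aligns).
#' @export
assign_genes <- function(circles, cds_refs, config = classifier_config()) {
  seqs <- seqs_from_circles(circles)
  cds_refs <- as_named_seqs(cds_refs, "ref")
  doubled <- stats::setNames(strrep(seqs, 2L), names(seqs))
  hits <- align_reads(doubled, cds_refs, config)
  hits <- hits[hits$identity >= config$min_identity_collect, , drop = FALSE]
  rows <- lapply(names(seqs), function(ci) {
    h <- hits[hits$read_id == ci, , drop = FALSE]
    if (nrow(h) == 0L) {
      return(data.frame(circle_id = ci, gene = NA_character_,
                        identity = NA_real_, cds_coverage = NA_real_,
                        stringsAsFactors = FALSE))
    }
    agg <- stats::aggregate(matches ~ ref_id, h, sum)
    best <- agg$ref_id[which.max(agg$matches)]
    hb <- h[h$ref_id == best, , drop = FALSE]
    cds_len <- nchar(cds_refs[[best]])
    cov <- sum(IRanges::width(IRanges::reduce(
      IRanges::IRanges(hb$ref_start + 1L, hb$ref_end)))) / cds_len
    data.frame(circle_id = ci, gene = best,
               identity = max(hb$identity),
               cds_coverage = min(cov, 1), stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Annotate a set of assembled minicircles
#'
#' Full annotation workflow: canonical rotation (ORF-anchored), constant
#' region / cassette segmentation across the set, constant-region grouping,
#' tandem-repeat catalogue with per-circle unit counts, and (when CDS
#' references are supplied) gene assignment.
#'
#' @param circles named character vector of circle sequences or list of
#'   `minicircle_spec`.
#' @param cds_refs optional named character vector of CDS references.
#' @param min_share,min_identity segmentation thresholds (see
#'   [segment_constant_cassette()]).
#' @param link_identity grouping threshold (see
#'   [group_constant_regions()]).
#' @param config a [classifier_config()].
#' @param canonicalize rotate circles to canonical form first.
#' @return an `annotation_result`: list with `sequences` (canonical),
#'   `segmentation`, `constant_groups`, `repeat_catalog` (unit x circle
#'   counts), `gene_assignment`.
#' @export
annotate_minicircles <- function(circles, cds_refs = NULL, min_share = 2L,
                                 min_identity = 0.90, link_identity = 0.80,
                                 config = classifier_config(),
                                 canonicalize = TRUE) {
  seqs <- seqs_from_circles(circles)
  if (canonicalize) {
    seqs <- stats::setNames(
      vapply(seqs, canonicalize_rotation, "", mode = "orf_anchored"),
      names(seqs))
  }
  seg <- segment_constant_cassette(seqs, min_share = min_share,
                                   min_identity = min_identity,
                                   config = config)
  const_seqs <- vapply(seg$circles, function(e) e$constant_seq, "")
  names(const_seqs) <- names(seg$circles)
  groups <- group_constant_regions(const_seqs, link_identity, config)

  # repeat catalogue: units detected in any constant arc, counted everywhere
  units <- character(0)
  for (ci in names(const_seqs)) {
    if (is.na(const_seqs[[ci]])) next
    det <- detect_tandem_repeats(const_seqs[[ci]])
    units <- union(units, det$unit_seq[det$period >= 8L])
  }
  repeat_catalog <- NULL
  if (length(units)) {
    counts <- sapply(units, function(u) {
      vapply(const_seqs, function(s) {
        if (is.na(s)) NA_integer_ else count_repeat_units(s, u)
      }, 1L)
    })
    repeat_catalog <- matrix(counts, nrow = length(const_seqs),
                             dimnames = list(names(const_seqs), units))
  }
  gene_assignment <- if (!is.null(cds_refs)) {
    assign_genes(seqs, cds_refs, config)
  }
  structure(list(sequences = seqs, segmentation = seg,
                 constant_groups = groups, repeat_catalog = repeat_catalog,
                 gene_assignment = gene_assignment),
            class = "annotation_result")
}

#' @export
print.annotation_result <- function(x, ...) {
  cat("<annotation_result> ", length(x$sequences), " circles, ",
      length(unique(x$constant_groups)), " constant group(s)\n", sep = "")
  for (ci in names(x$sequences)) {
    e <- x$segmentation$circles[[ci]]
    gene <- if (!is.null(x$gene_assignment)) {
      x$gene_assignment$gene[x$gene_assignment$circle_id == ci]
    } else NA
    cat(sprintf("  %s: %d bp, gene %s, group %s%s\n", ci, e$length,
                gene %||% NA, x$constant_groups[[ci]],
                if (isTRUE(e$low_confidence)) " [low confidence]" else ""))
  }
  invisible(x)
}

#' Write a GFF3-like annotation of segmented minicircles
#'
#' Emits `cassette`, `constant_region` and `repeat_region` features (with
#' `unit_seq` and `copies` attributes) in 1-based inclusive coordinates;
#' features running across the origin are split at the wrap point.
#'
#' @param annotation an `annotation_result`.
#' @param path output file.
#' @return the path, invisibly.
#' @export
write_annotation_gff <- function(annotation, path) {
  lines <- "##gff-version 3"
  feat <- function(id, type, s, e, L, attrs) {
    # split wrap-around features at the origin
    if (e <= L) {
      sprintf("%s\tminicircler\t%s\t%d\t%d\t.\t+\t.\t%s", id, type, s + 1L,
              e, attrs)
    } else {
      c(sprintf("%s\tminicircler\t%s\t%d\t%d\t.\t+\t.\t%s", id, type, s + 1L,
                L, attrs),
        sprintf("%s\tminicircler\t%s\t%d\t%d\t.\t+\t.\t%s", id, type, 1L,
                e - L, attrs))
    }
  }
  for (ci in names(annotation$sequences)) {
    e <- annotation$segmentation$circles[[ci]]
    L <- e$length
    lines <- c(lines, sprintf("##sequence-region %s 1 %d", ci, L))
    if (!is.null(e$cassette_interval)) {
      lines <- c(lines, feat(ci, "cassette", e$cassette_interval[1L],
                             e$cassette_interval[2L], L,
                             sprintf("ID=%s_cassette", ci)))
    }
    if (!is.null(e$constant_interval)) {
      lines <- c(lines, feat(ci, "constant_region", e$constant_interval[1L],
                             e$constant_interval[2L], L,
                             sprintf("ID=%s_constant;group=%s", ci,
                                     annotation$constant_groups[[ci]])))
      if (!is.na(e$constant_seq)) {
        det <- detect_tandem_repeats(e$constant_seq)
        det <- det[det$tandem & det$period >= 8L, , drop = FALSE]
        off <- e$constant_interval[1L]
        for (r in seq_len(nrow(det))) {
          lines <- c(lines, feat(
            ci, "repeat_region", (off + det$start[r]) %% L,
            (off + det$start[r]) %% L + (det$end[r] - det$start[r]), L,
            sprintf("ID=%s_rep%d;unit_seq=%s;copies=%.1f", ci, r,
                    det$unit_seq[r], det$copies[r])))
        }
      }
    }
  }
  writeLines(lines, path)
  invisible(path)
}
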