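# Shared fixtures and independent oracles for the test suite.

`%||%` <- function(x, y) if (is.null(x)) y else x

# A small 5-circle, 2-group species model (fast to simulate and annotate).
small_model_config <- function(seed = 1L) {
  list(
    species_id = "toy", seed = seed, gc_constant = 0.6,
    constant_templates = list(
      list(id = "grpA", length = 600, repeat_regions = list(
        list(region_id = "D", unit_len = 21, min_units = 1, max_units = 3,
             tandem = TRUE),
        list(region_id = "E", unit_len = 12, min_units = 2, max_units = 4,
             tandem = TRUE))),
      list(id = "grpB", length = 500, repeat_regions = list(
        list(region_id = "A", unit_len = 30, min_units = 1, max_units = 2,
             tandem = TRUE)))),
    genes = list(
      list(name = "cox1", cds_len = 900, ncr_len = 200, gc = 0.52),
      list(name = "cox2", cds_len = 600, ncr_len = 200, gc = 0.50),
      list(name = "nad1", cds_len = 450, ncr_len = 200, gc = 0.49),
      list(name = "atp6", cds_len = 600, ncr_len = 200, gc = 0.51)),
    circle_plan = list(
      list(gene = "cox1", template = "grpA", units = list(D = 3, E = 2)),
      list(gene = "cox2", template = "grpA", units = list(D = 1, E = 2)),
      list(gene = "nad1", template = "grpA"),
      list(gene = "atp6", template = "grpB")))
}

small_world <- function(seed = 1L) {
  model <- build_species_model(small_model_config(seed))
  list(model = model, circles = generate_minicircles(model),
       cds = model_cds_refs(model), constant = model_constant_refs(model))
}

# Independent full Smith-Waterman oracle (forward strand) via Biostrings.
sw_oracle <- function(a, b, match = 2, mismatch = -3, gap_open = 5,
                      gap_extend = 2) {
  mat <- Biostrings::nucleotideSubstitutionMatrix(match = match,
                                                  mismatch = mismatch,
                                                  baseOnly = TRUE)
  pa <- Biostrings::pairwiseAlignment(a, b, type = "local",
                                      substitutionMatrix = mat,
                                      gapOpening = gap_open,
                                      gapExtension = gap_extend)
  cols <- nchar(as.character(Biostrings::alignedPattern(pa)))
  list(score = Biostrings::score(pa),
       identity = Biostrings::nmatch(pa) / cols)
}

# forward-strand top hit of the package aligner
top_fwd_hit <- function(a, b, score_floor = 1) {
  h <- align_reads(c(read = a), c(ref = b),
                   classifier_config(score_floor = score_floor))
  h <- h[h$strand == "+", , drop = FALSE]
  if (nrow(h) == 0L) return(NULL)
  h[which.max(h$score), ]
}

# Brute-force tandem-repeat oracle: enumerate every (start, period), extend
# maximally, apply the same reporting rules (primitive unit, >= min_copies,
# maximal array) by a different route than the rle-based detector.
tandem_oracle <- function(region, max_unit = 40L, min_copies = 2) {
  chars <- strsplit(region, "", fixed = TRUE)[[1L]]
  n <- length(chars)
  seen <- character(0)
  rows <- list()
  for (p in seq_len(min(max_unit, n %/% 2))) {
    for (i in seq_len(n - 2L * p + 1L)) {
      # maximal-left: position i-1 must not continue the array
      if (i > 1L && chars[i - 1L] == chars[i - 1L + p]) next
      j <- i
      while (j + p <= n && chars[j] == chars[j + p]) j <- j + 1L
      alen <- (j - i) + p
      if (alen < p + 1L) next  # no repetition at all
      copies <- alen / p
      if (copies < min_copies) next
      unit <- paste(chars[i:(i + p - 1L)], collapse = "")
      primitive <- TRUE
      for (d in seq_len(p - 1L)) {
        if (p %% d == 0L &&
            unit == strrep(substr(unit, 1L, d), p %/% d)) {
          primitive <- FALSE
          break
        }
      }
      if (!primitive) next
      key <- paste(i - 1L, p)
      if (key %in% seen) next
      seen <- c(seen, key)
      rows[[length(rows) + 1L]] <- data.frame(
        unit_seq = unit, period = p, start = i - 1L, end = i - 1L + alen,
        copies = copies, stringsAsFactors = FALSE)
    }
  }
  if (!length(rows)) {
    return(data.frame(unit_seq = character(), period = integer(),
                      start = integer(), end = integer(), copies = numeric(),
                      stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, rows)
  out[order(out$start, out$period), , drop = FALSE]
}

# Brute-force rank-sum permutation oracle over all C(n, na) assignments.
ranksum_oracle <- function(a, b) {
  na <- length(a)
  r <- rank(c(a, b))
  u_obs <- sum(r[seq_len(na)]) - na * (na + 1) / 2
  idx <- utils::combn(length(r), na)
  u_all <- colSums(matrix(r[idx], nrow = na)) - na * (na + 1) / 2
  min(1, 2 * min(mean(u_all <= u_obs), mean(u_all >= u_obs)))
}

# brute-force least rotation by sorting all rotations
least_rotation_oracle <- function(s) {
  n <- nchar(s)
  rots <- vapply(0:(n - 1L), function(k) {
    paste0(substr(s, k + 1L, n), substr(s, 1L, k))
  }, "")
  sort(rots, method = "radix")[1L]
}
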