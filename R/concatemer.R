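#' Decompose a read into ordered minicircle units
#'
#' Gene (cassette) hits and constant-region hits on one read are first
#' resolved greedily by score (allowing `max_read_overlap` bp of overlap),
#' then walked in read order. A gene hit merges into the most recent unit of
#' the same gene when only constant units intervene and its reference
#' interval does not re-cover CDS positions already covered by that unit:
#' such complementary fragments are one circularly wrapped copy (e.g. a
#' full-length read linearized inside the cassette), whereas re-covering the
#' CDS is evidence of an additional tandem copy and opens a new unit.
#' Adjacent constant hits merge; constant stretches act as separators.
#'
#' @param read_id read identifier.
#' @param gene_hits collect-filtered hits of reads against CDS references.
#'   CDS lengths are taken from attribute `"ref_len"` when present (set by
#'   [classify_reads()]), else from the maximal `ref_end` observed.
#' @param constant_hits hits against constant-region references (labelled
#'   `"constant"` in the output regardless of template id).
#' @param config a [classifier_config()].
#' @return data.frame of units in read order: label, read_start, read_end,
#'   strand, ref_cov (bp of reference covered), ref_len, copies
#'   (`ref_cov / ref_len`), n_hits.
#' @export
decompose_read <- function(read_id, gene_hits, constant_hits = NULL,
                           config = classifier_config()) {
  gh <- gene_hits[gene_hits$read_id == read_id, , drop = FALSE]
  ch <- if (is.null(constant_hits)) NULL else
    constant_hits[constant_hits$read_id == read_id, , drop = FALSE]
  ref_len_tab <- attr(gene_hits, "ref_len")
  if (is.null(ref_len_tab) && nrow(gene_hits)) {
    ref_len_tab <- tapply(gene_hits$ref_end, gene_hits$ref_id, max)
  }
  const_len_tab <- if (!is.null(constant_hits) && nrow(constant_hits)) {
    cl <- attr(constant_hits, "ref_len")
    if (is.null(cl)) tapply(constant_hits$ref_end, constant_hits$ref_id, max)
    else cl
  } else NULL
  decompose_units(gh, ch, ref_len_tab, const_len_tab, config)
}

empty_units <- function() {
  data.frame(label = character(), read_start = integer(),
             read_end = integer(), strand = character(), ref_cov = integer(),
             ref_len = integer(), copies = numeric(), n_hits = integer(),
             stringsAsFactors = FALSE)
}

decompose_units <- function(gh, ch, ref_len_tab, const_len_tab, config) {
  if (nrow(gh) == 0L && (is.null(ch) || nrow(ch) == 0L)) return(empty_units())
  gh$unit_label <- if (nrow(gh)) gh$ref_id else character(0)
  gh$unit_ref_len <- if (nrow(gh)) {
    unname(ref_len_tab[gh$ref_id])
  } else integer(0)
  if (!is.null(ch) && nrow(ch)) {
    ch$unit_label <- "constant"
    ch$unit_ref_len <- unname(const_len_tab[ch$ref_id])
    hits <- rbind(gh, ch)
  } else {
    hits <- gh
  }
  all_hits <- hits
  hits <- resolve_read_hits(hits, config$max_read_overlap)
  # chimeric-alignment signal: a discarded gene hit overlapping a retained
  # hit of a *different* gene by more than the tolerated wobble
  chimeric <- FALSE
  kept_gene <- hits[hits$unit_label != "constant", , drop = FALSE]
  drop_key <- setdiff(
    paste(all_hits$ref_id, all_hits$read_start, all_hits$read_end,
          all_hits$strand),
    paste(hits$ref_id, hits$read_start, hits$read_end, hits$strand))
  dropped <- all_hits[paste(all_hits$ref_id, all_hits$read_start,
                            all_hits$read_end, all_hits$strand) %in%
                        drop_key &
                        all_hits$unit_label != "constant", , drop = FALSE]
  for (i in seq_len(nrow(dropped))) {
    other <- kept_gene[kept_gene$unit_label != dropped$unit_label[i], ,
                       drop = FALSE]
    if (nrow(other) == 0L) next
    ov <- pmin(dropped$read_end[i], other$read_end) -
      pmax(dropped$read_start[i], other$read_start)
    if (any(ov > config$max_read_overlap)) chimeric <- TRUE
  }

  units <- list()  # each: label, read_start, read_end, strand, ranges, ...
  for (i in seq_len(nrow(hits))) {
    h <- hits[i, ]
    rng <- IRanges::IRanges(start = h$ref_start + 1L, end = h$ref_end)
    target <- 0L
    nu <- length(units)
    if (h$unit_label == "constant") {
      if (nu > 0L && units[[nu]]$label == "constant") target <- nu
    } else if (nu > 0L) {
      # most recent unit of the same gene, with only constant units after it
      k <- nu
      while (k >= 1L && units[[k]]$label == "constant") k <- k - 1L
      if (k >= 1L && units[[k]]$label == h$unit_label) {
        tol <- max(config$max_read_overlap, 0.1 * h$unit_ref_len)
        ov <- sum(IRanges::width(IRanges::intersect(units[[k]]$ranges, rng)))
        if (ov <= tol) target <- k
      }
    }
    if (target == 0L) {
      units[[nu + 1L]] <- list(label = h$unit_label,
                               read_start = h$read_start,
                               read_end = h$read_end, strand = h$strand,
                               ranges = rng, ref_len = h$unit_ref_len,
                               n_hits = 1L)
    } else {
      u <- units[[target]]
      u$read_end <- max(u$read_end, h$read_end)
      u$ranges <- c(u$ranges, rng)
      u$n_hits <- u$n_hits + 1L
      if (h$strand != u$strand) u$strand <- "*"
      units[[target]] <- u
    }
  }
  rows <- lapply(units, function(u) {
    cov <- sum(IRanges::width(IRanges::reduce(u$ranges)))
    data.frame(label = u$label, read_start = u$read_start,
               read_end = u$read_end, strand = u$strand, ref_cov = cov,
               ref_len = u$ref_len,
               copies = if (is.na(u$ref_len) || u$ref_len == 0) NA_real_ else
                 cov / u$ref_len,
               n_hits = u$n_hits, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  attr(out, "chimeric") <- chimeric
  out
}

#' Classify one decomposed read
#'
#' Zero gene units is `non_mito`; a single gene with an estimated copy
#' number of 1 is `single` and with >= 2 is `homo` (rolling-circle
#' candidate) provided the copies are co-oriented, else `ambiguous`; two or
#' more distinct genes is `hetero` unless gene units overlap on the read by
#' more than the configured tolerance (chimeric alignment), in which case
#' `ambiguous`. Copy number is estimated as total covered CDS bp divided by
#' CDS length, summed over units and rounded, which distinguishes a
#' circularly wrapped single copy from a genuine tandem duplication.
#' Confidence is `high` only when every gene unit covers at least
#' `min_cds_fraction` of its CDS and every junction between consecutive
#' gene units contains a constant unit covering at least `min_cds_fraction`
#' of the constant region.
#'
#' @param units data.frame from [decompose_read()].
#' @param config a [classifier_config()].
#' @param read_id read identifier carried into the result.
#' @return one-row data.frame: read_id, category, confidence, unit_count
#'   (estimated minicircle copies), genes (comma separated), structure.
#' @export
classify_read <- function(units, config = classifier_config(),
                          read_id = NA_character_) {
  gu <- units[units$label != "constant", , drop = FALSE]
  n_gene_units <- nrow(gu)
  genes <- unique(gu$label)
  structure_str <- paste(units$label, collapse = "-")
  copies <- sum(gu$copies, na.rm = TRUE)
  unit_count <- if (n_gene_units == 0L) 0L else max(1L, as.integer(round(copies)))

  category <- if (n_gene_units == 0L) "non_mito"
    else if (length(genes) >= 2L) "hetero"
    else if (unit_count >= 2L) "homo"
    else "single"
  if (category %in% c("hetero", "homo") && n_gene_units >= 2L) {
    ord <- order(gu$read_start)
    gs <- gu$read_start[ord]
    ge <- gu$read_end[ord]
    if (any(gs[-1L] < ge[-n_gene_units] - config$max_read_overlap)) {
      category <- "ambiguous"
    }
  }
  if (category == "homo" &&
      (any(gu$strand == "*") || length(unique(gu$strand)) > 1L)) {
    category <- "ambiguous"  # inverted repeat, not a rolling-circle product
  }
  if (category %in% c("single", "homo", "hetero") &&
      isTRUE(attr(units, "chimeric"))) {
    category <- "ambiguous"  # overlapping distinct-gene alignments
  }

  confidence <- "low"
  if (category %in% c("single", "homo", "hetero")) {
    cov_ok <- all(!is.na(gu$ref_len) &
                    gu$ref_cov >= config$min_cds_fraction * gu$ref_len)
    junc_ok <- TRUE
    gi <- which(units$label != "constant")
    if (length(gi) >= 2L) {
      for (k in seq_len(length(gi) - 1L)) {
        if (gi[k + 1L] - gi[k] == 1L) {
          junc_ok <- FALSE
          next
        }
        between <- units[(gi[k] + 1L):(gi[k + 1L] - 1L), , drop = FALSE]
        between <- between[between$label == "constant", , drop = FALSE]
        ok <- nrow(between) > 0L && !any(is.na(between$ref_len)) &&
          any(between$ref_cov >= config$min_cds_fraction * between$ref_len)
        if (!ok) junc_ok <- FALSE
      }
    }
    if (cov_ok && junc_ok) confidence <- "high"
  }
  data.frame(read_id = read_id, category = category, confidence = confidence,
             unit_count = unit_count, genes = paste(genes, collapse = ","),
             structure = structure_str, stringsAsFactors = FALSE)
}

#' Classify a full read set
#'
#' Decomposes and classifies every read from precomputed collect-mode gene
#' hits and constant-region hits; reads without hits are `non_mito`, so the
#' categories partition the input read set.
#'
#' @param read_ids character vector of all read ids.
#' @param gene_hits collect-filtered hits against CDS references.
#' @param constant_hits hits against constant-region references (optional).
#' @param cds_refs named character vector of CDS references (for CDS
#'   lengths); recommended.
#' @param constant_refs named character vector of constant-region
#'   references.
#' @param config a [classifier_config()].
#' @return a `read_classification_set`: data.frame of per-read
#'   classifications with the unit tables in attribute `"units"`.
#' @export
classify_reads <- function(read_ids, gene_hits, constant_hits = NULL,
                           cds_refs = NULL, constant_refs = NULL,
                           config = classifier_config()) {
  ref_len_tab <- if (!is.null(cds_refs)) {
    stats::setNames(nchar(cds_refs), names(cds_refs))
  } else if (nrow(gene_hits)) {
    tapply(gene_hits$ref_end, gene_hits$ref_id, max)
  } else NULL
  const_len_tab <- if (!is.null(constant_refs)) {
    stats::setNames(nchar(constant_refs), names(constant_refs))
  } else if (!is.null(constant_hits) && nrow(constant_hits)) {
    tapply(constant_hits$ref_end, constant_hits$ref_id, max)
  } else NULL
  gh_split <- if (nrow(gene_hits)) {
    split(gene_hits, factor(gene_hits$read_id, levels = read_ids))
  } else NULL
  ch_split <- if (!is.null(constant_hits) && nrow(constant_hits)) {
    split(constant_hits, factor(constant_hits$read_id, levels = read_ids))
  } else NULL
  units_by_read <- vector("list", length(read_ids))
  names(units_by_read) <- read_ids
  rows <- vector("list", length(read_ids))
  empty_g <- gene_hits[0, , drop = FALSE]
  for (i in seq_along(read_ids)) {
    rid <- read_ids[i]
    gh <- if (is.null(gh_split)) empty_g else gh_split[[rid]]
    ch <- if (is.null(ch_split)) NULL else ch_split[[rid]]
    units <- decompose_units(gh, ch, ref_len_tab, const_len_tab, config)
    units_by_read[[i]] <- units
    rows[[i]] <- classify_read(units, config, read_id = rid)
  }
  out <- do.call(rbind, rows)
  attr(out, "units") <- units_by_read
  class(out) <- c("read_classification_set", class(out))
  out
}

#' Summarize concatemer structure across a classified read set
#'
#' Builds undirected gene-pair edges from consecutive distinct-gene unit
#' pairs within each read (multiplicity = number of supporting pairs), plus
#' category counts and the structure strings of concatemer reads.
#'
#' @param classifications a `read_classification_set` from
#'   [classify_reads()].
#' @return a `concatemer_report`: list with `counts`, `edges` (gene_a,
#'   gene_b, count), `structures`, `n_reads`.
#' @export
summarize_concatemers <- function(classifications) {
  units <- attr(classifications, "units")
  pairs <- list()
  for (rid in classifications$read_id) {
    u <- units[[rid]]
    if (is.null(u) || nrow(u) == 0L) next
    g <- u$label[u$label != "constant"]
    if (length(g) < 2L) next
    for (k in seq_len(length(g) - 1L)) {
      if (g[k] != g[k + 1L]) {
        pairs[[length(pairs) + 1L]] <- sort(c(g[k], g[k + 1L]))
      }
    }
  }
  edges <- if (length(pairs)) {
    key <- vapply(pairs, paste, "", collapse = "\t")
    tab <- table(key)
    parts <- strsplit(names(tab), "\t", fixed = TRUE)
    data.frame(gene_a = vapply(parts, `[`, "", 1L),
               gene_b = vapply(parts, `[`, "", 2L),
               count = as.integer(tab), stringsAsFactors = FALSE)
  } else {
    data.frame(gene_a = character(), gene_b = character(), count = integer(),
               stringsAsFactors = FALSE)
  }
  counts <- table(factor(classifications$category,
                         levels = c("single", "homo", "hetero", "non_mito",
                                    "ambiguous")))
  structure(list(counts = counts, edges = edges,
                 structures = table(classifications$structure[
                   classifications$category %in% c("homo", "hetero")]),
                 n_reads = nrow(classifications)),
            class = "concatemer_report")
}

#' @export
print.concatemer_report <- function(x, ...) {
  cat("<concatemer_report> ", x$n_reads, " reads\n", sep = "")
  print(x$counts)
  if (nrow(x$edges)) {
    cat("gene-pair edges:\n")
    print(x$edges, row.names = FALSE)
  } else cat("no gene-pair edges\n")
  invisible(x)
}

#' Flag gene-pair joins incompatible with constant-region sharing
#'
#' Recombination between minicircles requires constant-region homology, so
#' an edge joining genes whose circles belong to different constant groups
#' is a candidate artifact and gets `suspect = TRUE`.
#'
#' @param report a `concatemer_report`.
#' @param constant_groups named character vector mapping gene to constant
#'   group.
#' @return the report with a `suspect` column added to `edges`.
#' @export
flag_incompatible_joins <- function(report, constant_groups) {
  stopifnot(inherits(report, "concatemer_report"))
  e <- report$edges
  if (nrow(e)) {
    miss <- setdiff(unique(c(e$gene_a, e$gene_b)), names(constant_groups))
    if (length(miss)) {
      stop_validation("genes without a constant group assignment: ",
                      paste(miss, collapse = ", "))
    }
    e$suspect <- unname(constant_groups[e$gene_a] != constant_groups[e$gene_b])
  } else {
    e$suspect <- logical(0)
  }
  report$edges <- e
  report
}
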