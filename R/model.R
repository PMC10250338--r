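#' Build a species-level minicircle genome model
#'
#' A species model fixes everything the simulator needs: one or more constant
#' region templates (a random backbone at elevated GC plus labelled repeat
#' region slots), a gene table (CDS length, cassette NCR length, target GC),
#' and a circle plan assigning each minicircle a gene and a constant
#' template. All template and gene sequences are materialized here, so two
#' circles sharing a template share an identical constant backbone by
#' construction.
#'
#' @param config a list, or path to a JSON file, with elements
#'   `species_id`, `gc_constant`, `constant_templates`, `genes`,
#'   `circle_plan` and optionally `seed`. See the bundled
#'   `system.file("extdata", "rmarinus_model.json", package = "minicircler")`
#'   for the full schema.
#' @param seed integer master seed; defaults to `config$seed`, else 1.
#' @return an object of class `species_model`.
#' @examples
#' cfg <- system.file("extdata", "rmarinus_model.json", package = "minicircler")
#' model <- build_species_model(cfg)
#' model
#' @export
build_species_model <- function(config, seed = NULL) {
  if (is.character(config) && length(config) == 1L) {
    config <- jsonlite::read_json(config, simplifyVector = FALSE)
  }
  if (!is.list(config)) stop_validation("config must be a list or JSON path")
  seed <- as.integer(seed %||% config$seed %||% 1L)

  genes <- config$genes
  if (is.null(genes) || length(genes) == 0L) {
    stop_validation("model must contain at least one gene")
  }
  gene_names <- vapply(genes, function(g) as.character(g$name), "")
  if (anyDuplicated(gene_names)) {
    stop_validation("duplicate gene names: ",
                    paste(unique(gene_names[duplicated(gene_names)]),
                          collapse = ", "))
  }
  for (g in genes) {
    if (!is_count(g$cds_len) || g$cds_len %% 3 != 0) {
      stop_validation("CDS length of ", g$name, " must be a positive multiple of 3")
    }
    if (!is_count(g$ncr_len)) stop_validation("ncr_len of ", g$name, " invalid")
    if (!is_fraction(g$gc) || g$gc <= 0 || g$gc >= 1) {
      stop_validation("gene GC of ", g$name, " must be in (0, 1)")
    }
  }
  gc_const <- config$gc_constant %||% 0.6
  if (!is_fraction(gc_const) || gc_const <= 0 || gc_const >= 1) {
    stop_validation("gc_constant must be in (0, 1)")
  }

  templates <- config$constant_templates
  if (is.null(templates) || length(templates) == 0L) {
    stop_validation("model must contain at least one constant template")
  }
  template_ids <- vapply(templates, function(t) as.character(t$id), "")
  if (anyDuplicated(template_ids)) stop_validation("duplicate template ids")
  for (tm in templates) {
    if (!is_count(tm$length)) stop_validation("template length invalid: ", tm$id)
    for (rr in tm$repeat_regions %||% list()) {
      if (!is_count(rr$unit_len) || rr$unit_len < 2) {
        stop_validation("repeat unit length must be >= 2 bp (region ",
                        rr$region_id, ")")
      }
      if (!is_count(rr$min_units) || !is_count(rr$max_units) ||
          rr$min_units > rr$max_units) {
        stop_validation("need 1 <= min_units <= max_units (region ",
                        rr$region_id, ")")
      }
    }
  }

  plan <- config$circle_plan
  if (is.null(plan) || length(plan) == 0L) {
    stop_validation("circle_plan must contain at least one circle")
  }
  for (p in plan) {
    if (!(p$gene %in% gene_names)) {
      stop_validation("circle_plan references unknown gene: ", p$gene)
    }
    if (!(p$template %in% template_ids)) {
      stop_validation("circle_plan references unknown template: ", p$template)
    }
  }

  withr::with_seed(child_seed(seed, 1L), {
    tmpl <- lapply(templates, function(tm) {
      reps <- lapply(tm$repeat_regions %||% list(), function(rr) {
        list(region_id = as.character(rr$region_id),
             unit_seq = random_dna(rr$unit_len, gc_const),
             min_units = as.integer(rr$min_units),
             max_units = as.integer(rr$max_units),
             tandem = isTRUE(rr$tandem %||% TRUE),
             # non-tandem units are separated by a short fixed spacer
             spacer = random_dna(8L, gc_const))
      })
      nseg <- length(reps) + 1L
      # backbone is cut into nseg chunks; repeat region i sits after chunk i
      cuts <- if (nseg > 1L) round(seq(0L, tm$length, length.out = nseg + 1L))
              else c(0L, tm$length)
      chunks <- vapply(seq_len(nseg), function(i) {
        random_dna(cuts[i + 1L] - cuts[i], gc_const)
      }, "")
      list(id = as.character(tm$id), chunks = chunks, repeats = reps)
    })
    names(tmpl) <- template_ids

    gene_seqs <- lapply(genes, function(g) {
      list(name = as.character(g$name),
           cds = make_cds(g$cds_len, g$gc),
           ncr = random_dna(g$ncr_len, g$gc),
           gc = g$gc)
    })
    names(gene_seqs) <- gene_names
  })

  plan_df <- data.frame(
    gene = vapply(plan, function(p) as.character(p$gene), ""),
    template = vapply(plan, function(p) as.character(p$template), ""),
    stringsAsFactors = FALSE)
  plan_df$units <- lapply(plan, function(p) {
    u <- p$units %||% list()
    stats::setNames(as.integer(unlist(u, use.names = FALSE)), names(u))
  })

  structure(list(species_id = as.character(config$species_id %||% "species"),
                 templates = tmpl, genes = gene_seqs, circle_plan = plan_df,
                 gc_constant = gc_const, seed = seed),
            class = "species_model")
}

#' @export
print.species_model <- function(x, ...) {
  cat("<species_model> ", x$species_id, "\n",
      "  circles: ", nrow(x$circle_plan),
      " | genes: ", length(x$genes),
      " | constant templates: ", length(x$templates),
      " | constant GC target: ", x$gc_constant, "\n", sep = "")
  invisible(x)
}

# Random CDS under genetic code 4 (TGA = Trp; only TAA/TAG are stops):
# ATG start, terminal TAA, no internal stop codons. GC drift from stop
# scrubbing is negligible for the lengths used here.
make_cds <- function(len, gc) {
  stopifnot(len %% 3 == 0, len >= 9)
  s <- strsplit(random_dna(len, gc), "", fixed = TRUE)[[1L]]
  s[1:3] <- c("A", "T", "G")
  s[(len - 2):len] <- c("T", "A", "A")
  starts <- seq(4L, len - 5L, by = 3L)
  codon1 <- s[starts]
  codon2 <- s[starts + 1L]
  codon3 <- s[starts + 2L]
  bad <- codon1 == "T" & codon2 == "A" & (codon3 == "A" | codon3 == "G")
  s[starts[bad] + 2L] <- "T"  # TAA/TAG -> TAT (Tyr)
  paste(s, collapse = "")
}

# Realize one constant region given a template and per-region unit counts.
constant_sequence <- function(template, unit_counts) {
  reps <- template$repeats
  parts <- character(0)
  regions <- list()
  pos <- 0L
  add <- function(parts, s) c(parts, s)
  for (i in seq_along(template$chunks)) {
    parts <- add(parts, template$chunks[i])
    pos <- pos + nchar(template$chunks[i])
    if (i <= length(reps)) {
      rr <- reps[[i]]
      k <- unit_counts[[rr$region_id]]
      block <- if (rr$tandem) strrep(rr$unit_seq, k) else
        paste(rep(rr$unit_seq, k), collapse = rr$spacer)
      regions[[rr$region_id]] <- list(region_id = rr$region_id, start = pos,
                                      end = pos + nchar(block), units = k,
                                      unit_seq = rr$unit_seq,
                                      tandem = rr$tandem)
      parts <- add(parts, block)
      pos <- pos + nchar(block)
    }
  }
  list(seq = paste(parts, collapse = ""), regions = regions)
}

#' Generate minicircle sequences from a species model
#'
#' Each planned circle is laid out cassette first: `[CDS][NCR][constant]`,
#' the canonical rotation used throughout the package. Repeat-region unit
#' counts fixed in the plan are honoured; unspecified ones are drawn
#' uniformly from `[min_units, max_units]`. Circles sharing a template are
#' identical across the constant region outside the repeat regions.
#'
#' @param model a `species_model`.
#' @param seed integer seed (defaults to the model's master seed).
#' @return a list of `minicircle_spec` objects: `circle_id`, `sequence`,
#'   `gene`, 0-based half-open `cassette_interval`, `cds_interval` and
#'   `constant_interval`, `repeat_regions`, and `constant_group`.
#' @export
generate_minicircles <- function(model, seed = NULL) {
  stopifnot(inherits(model, "species_model"))
  seed <- as.integer(seed %||% model$seed)
  withr::with_seed(child_seed(seed, 2L), {
    lapply(seq_len(nrow(model$circle_plan)), function(i) {
      gene <- model$circle_plan$gene[i]
      tid <- model$circle_plan$template[i]
      tmpl <- model$templates[[tid]]
      fixed <- model$circle_plan$units[[i]]
      counts <- lapply(tmpl$repeats, function(rr) {
        if (rr$region_id %in% names(fixed)) fixed[[rr$region_id]]
        else if (rr$min_units == rr$max_units) rr$min_units
        else sample(rr$min_units:rr$max_units, 1L)
      })
      names(counts) <- vapply(tmpl$repeats, `[[`, "", "region_id")
      const <- constant_sequence(tmpl, counts)
      g <- model$genes[[gene]]
      cass <- paste0(g$cds, g$ncr)
      off <- nchar(cass)
      regions <- lapply(const$regions, function(r) {
        r$start <- r$start + off
        r$end <- r$end + off
        r
      })
      structure(list(
        circle_id = paste0(model$species_id, "_", gene),
        sequence = paste0(cass, const$seq),
        gene = gene,
        cds_interval = c(0L, nchar(g$cds)),
        cassette_interval = c(0L, off),
        constant_interval = c(off, off + nchar(const$seq)),
        repeat_regions = regions,
        constant_group = tid), class = "minicircle_spec")
    })
  })
}

#' @export
print.minicircle_spec <- function(x, ...) {
  cat("<minicircle_spec> ", x$circle_id, ": ", nchar(x$sequence), " bp, gene ",
      x$gene, ", cassette [", x$cassette_interval[1], ",",
      x$cassette_interval[2], "), constant group ", x$constant_group, "\n",
      sep = "")
  invisible(x)
}

#' Collect minicircle sequences as a named vector (FASTA-ready)
#' @param circles list of `minicircle_spec`.
#' @return named character vector keyed by circle id.
#' @export
circles_as_fasta <- function(circles) {
  stats::setNames(vapply(circles, `[[`, "", "sequence"),
                  vapply(circles, `[[`, "", "circle_id"))
}

#' Extract CDS reference sequences from a species model
#' @param model a `species_model`.
#' @return named character vector, one CDS per gene.
#' @export
model_cds_refs <- function(model) {
  stats::setNames(vapply(model$genes, `[[`, "", "cds"), names(model$genes))
}

#' Extract one realized constant-region reference per template
#'
#' Uses the minimum unit count for every repeat region, giving the shortest
#' realization; alignment against it tolerates per-circle unit-count
#' variation.
#' @param model a `species_model`.
#' @return named character vector, one sequence per constant template.
#' @export
model_constant_refs <- function(model) {
  out <- vapply(model$templates, function(tm) {
    counts <- lapply(tm$repeats, `[[`, "min_units")
    names(counts) <- vapply(tm$repeats, `[[`, "", "region_id")
    constant_sequence(tm, counts)$seq
  }, "")
  stats::setNames(out, names(model$templates))
}
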