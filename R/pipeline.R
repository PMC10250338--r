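#' Load and validate a pipeline configuration
#'
#' A single JSON document with per-module sections: `model` (path to a
#' species-model config or an inline model section), `simulate`
#' (simulation parameters or `enabled: false`), `classify` (classifier
#' thresholds), `annotate`, `paths` (reads/references when simulation is
#' disabled), `outdir` and `seed`. Validation happens before any compute.
#'
#' @param config path to a JSON file or a list.
#' @return a validated `pipeline_config` list.
#' @export
pipeline_config <- function(config) {
  if (is.character(config) && length(config) == 1L) {
    base_dir <- dirname(normalizePath(config))
    config <- jsonlite::read_json(config, simplifyVector = FALSE)
    config$.base_dir <- base_dir
  }
  if (!is.list(config)) stop_validation("config must be a list or JSON path")
  config$seed <- as.integer(config$seed %||% 1L)
  sim_enabled <- !isFALSE(config$simulate$enabled %||% TRUE)
  if (!sim_enabled) {
    reads_path <- config$paths$reads
    if (is.null(reads_path)) {
      stop_validation("simulation disabled but no paths$reads given")
    }
    if (!is.null(config$.base_dir) && !file.exists(reads_path)) {
      reads_path <- file.path(config$.base_dir, reads_path)
    }
    if (!file.exists(reads_path)) {
      stop_validation("reads file not found: ", config$paths$reads)
    }
    config$paths$reads <- reads_path
  }
  config$.sim_enabled <- sim_enabled
  class(config) <- "pipeline_config"
  config
}

resolve_classifier_config <- function(config) {
  cc <- config$classify %||% list()
  do.call(classifier_config,
          cc[intersect(names(cc), names(formals(classifier_config)))])
}

#' Run the full minicircle analysis pipeline
#'
#' Executes (as requested by the config) simulate -> align/classify ->
#' concatemer summary -> annotate -> length statistics, writes TSV/JSON
#' outputs plus a run manifest (package version, seed, config hash) into
#' the output directory, and returns the in-memory results.
#'
#' @param config a [pipeline_config()] (or path/list coercible to one).
#' @param outdir output directory (created if needed); defaults to the
#'   config's `outdir` or a temporary directory.
#' @return invisibly, a list with the stage results and output paths.
#' @export
run_pipeline <- function(config, outdir = NULL) {
  if (!inherits(config, "pipeline_config")) config <- pipeline_config(config)
  outdir <- outdir %||% config$outdir %||% tempfile("minicircler_run_")
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  seed <- config$seed
  cc <- resolve_classifier_config(config)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop(errorCondition(paste0("stage ", name, " failed: ",
                                 conditionMessage(e)),
                          class = c("minicircler_stage_error", "error",
                                    "condition")))
    })
  }

  # --- model + simulate (or load reads) ---
  model <- circles <- truth <- NULL
  if (isTRUE(config$.sim_enabled)) {
    model_cfg <- config$model %||% system.file("extdata",
                                               "rmarinus_model.json",
                                               package = "minicircler")
    if (is.character(model_cfg) && !file.exists(model_cfg) &&
        !is.null(config$.base_dir)) {
      model_cfg <- file.path(config$.base_dir, model_cfg)
    }
    model <- stage("model", build_species_model(model_cfg, seed = seed))
    circles <- stage("model", generate_minicircles(model, seed = seed))
    sim <- config$simulate %||% list()
    sim$enabled <- NULL
    sim$seed <- seed
    params <- do.call(simulation_params,
                      sim[intersect(names(sim),
                                    names(formals(simulation_params)))])
    simres <- stage("simulate", simulate_reads(circles, params))
    reads <- simres$reads
    truth <- simres$truth
    write_fastq(reads, file.path(outdir, "reads.fastq"))
    write_fasta(circles_as_fasta(circles), file.path(outdir, "circles.fasta"))
    write_tsv(truth, file.path(outdir, "truth.tsv"))
    cds_refs <- model_cds_refs(model)
    constant_refs <- model_constant_refs(model)
  } else {
    reads <- stage("load", {
      p <- config$paths$reads
      if (grepl("\\.(fq|fastq)(\\.gz)?$", p)) read_fastq(p) else {
        fa <- read_fasta(p)
        data.frame(read_id = names(fa), sequence = unname(fa),
                   quality = strrep("5", nchar(fa)), stringsAsFactors = FALSE)
      }
    })
    cds_refs <- stage("load", read_fasta(config$paths$cds_refs))
    constant_refs <- if (!is.null(config$paths$constant_refs)) {
      stage("load", read_fasta(config$paths$constant_refs))
    }
    if (!is.null(config$paths$circles)) {
      fa <- stage("load", read_fasta(config$paths$circles))
      circles <- NULL
      config$.circle_seqs <- fa
    }
  }

  # --- align + classify ---
  gene_hits <- stage("classify", align_reads(reads, cds_refs, cc))
  gene_hits <- filter_hits(gene_hits, cds_refs, cc, mode = "collect")
  constant_hits <- if (!is.null(constant_refs)) {
    h <- stage("classify", align_reads(reads, constant_refs, cc))
    filter_hits(h, constant_refs, cc, mode = "collect")
  }
  write_tsv(gene_hits, file.path(outdir, "hits.tsv"))
  cls <- stage("concatemers",
               classify_reads(reads$read_id, gene_hits, constant_hits,
                              cds_refs = cds_refs,
                              constant_refs = constant_refs, config = cc))
  write_tsv(as.data.frame(cls), file.path(outdir, "classification.tsv"))
  report <- stage("concatemers", summarize_concatemers(cls))

  # --- annotate assembled circles (simulated or supplied) ---
  annotation <- NULL
  circle_seqs <- if (!is.null(circles)) circles_as_fasta(circles) else
    config$.circle_seqs
  if (!is.null(circle_seqs) && length(circle_seqs) >= 2L) {
    ann_cfg <- config$annotate %||% list()
    annotation <- stage("annotate", annotate_minicircles(
      circle_seqs, cds_refs = cds_refs,
      min_share = ann_cfg$min_share %||% 2L,
      min_identity = ann_cfg$min_identity %||% 0.90,
      link_identity = ann_cfg$link_identity %||% 0.80, config = cc))
    write_annotation_gff(annotation, file.path(outdir, "annotation.gff3"))
    if (!is.null(annotation$gene_assignment)) {
      ga <- annotation$gene_assignment
      grp <- annotation$constant_groups[ga$circle_id]
      ok <- !is.na(ga$gene)
      gene_groups <- stats::setNames(unname(grp[ok]), ga$gene[ok])
      report <- stage("concatemers",
                      flag_incompatible_joins(report, gene_groups))
    }
    write_tsv(data.frame(circle_id = names(annotation$constant_groups),
                         group = unname(annotation$constant_groups)),
              file.path(outdir, "constant_groups.tsv"))
  }
  write_tsv(report$edges, file.path(outdir, "concatemer_edges.tsv"))

  # --- per-gene read-length distributions ---
  strict_hits <- filter_hits(gene_hits, cds_refs, cc, mode = "strict")
  lengths <- stage("lengths",
                   length_distribution(reads, strict_hits, circles))
  write_tsv(lengths, file.path(outdir, "length_modes.tsv"))

  summary <- list(n_reads = nrow(reads),
                  counts = as.list(stats::setNames(as.integer(report$counts),
                                                   names(report$counts))),
                  n_edges = nrow(report$edges))
  jsonlite::write_json(summary, file.path(outdir, "summary.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  manifest <- list(package = "minicircler",
                   version = as.character(utils::packageVersion("minicircler")),
                   seed = seed, config_hash = config_hash(config),
                   timestamp = format(Sys.time(), tz = "UTC"))
  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(list(outdir = outdir, reads = reads, truth = truth,
                 hits = gene_hits, classification = cls, report = report,
                 annotation = annotation, lengths = lengths,
                 manifest = manifest))
}

# md5 of the canonicalized (sorted, private fields dropped) config
config_hash <- function(config) {
  cfg <- config[!startsWith(names(config), ".")]
  cfg <- cfg[order(names(cfg))]
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  jsonlite::write_json(cfg, tmp, auto_unbox = TRUE, digits = NA)
  unname(tools::md5sum(tmp))
}
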