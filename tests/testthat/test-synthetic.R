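test_that("build_species_model validates its config", {
  cfg <- small_model_config()
  expect_s3_class(build_species_model(cfg), "species_model")

  bad <- cfg
  bad$genes <- list()
  expect_error(build_species_model(bad), "at least one gene",
               class = "minicircler_validation_error")

  bad <- cfg
  bad$genes[[2]]$name <- "cox1"
  expect_error(build_species_model(bad), "duplicate gene",
               class = "minicircler_validation_error")

  bad <- cfg
  bad$genes[[1]]$cds_len <- 901
  expect_error(build_species_model(bad), "multiple of 3",
               class = "minicircler_validation_error")

  bad <- cfg
  bad$circle_plan[[1]]$gene <- "nope"
  expect_error(build_species_model(bad), "unknown gene",
               class = "minicircler_validation_error")
})

test_that("the bundled model gives 13 circles in 3 constant groups", {
  model <- build_species_model(system.file("extdata", "rmarinus_model.json",
                                           package = "minicircler"))
  circles <- generate_minicircles(model)
  expect_length(circles, 13L)
  expect_length(unique(vapply(circles, `[[`, "", "constant_group")), 3L)
  lens <- vapply(circles, function(x) nchar(x$sequence), 1L)
  expect_true(all(lens >= 1800 & lens <= 6000))
})

test_that("circle generation is deterministic and structurally consistent", {
  w <- small_world()
  again <- generate_minicircles(w$model)
  expect_identical(circles_as_fasta(w$circles), circles_as_fasta(again))

  for (x in w$circles) {
    L <- nchar(x$sequence)
    expect_identical(x$cassette_interval[1], 0L)
    expect_identical(x$cassette_interval[2], x$constant_interval[1])
    expect_identical(x$constant_interval[2], L)
    # cassette carries the gene's CDS verbatim at error rate 0
    expect_identical(substr(x$sequence, 1, nchar(w$cds[[x$gene]])),
                     unname(w$cds[[x$gene]]))
  }

  # same template => identical constant region outside repeat regions:
  # strip every repeat-region interval and compare
  strip <- function(x) {
    s <- substr(x$sequence, x$constant_interval[1] + 1, x$constant_interval[2])
    off <- x$constant_interval[1]
    keep <- rep(TRUE, nchar(s))
    for (r in x$repeat_regions) keep[(r$start - off + 1):(r$end - off)] <- FALSE
    paste(strsplit(s, "")[[1]][keep], collapse = "")
  }
  grpA <- Filter(function(x) x$constant_group == "grpA", w$circles)
  expect_length(unique(vapply(grpA, strip, "")), 1L)

  # unit-count difference translates into exact length difference
  c31 <- Filter(function(x) x$gene %in% c("cox1", "cox2"), w$circles)
  d_units <- 3L - 1L
  exp_diff <- d_units * 21L +
    (nchar(w$model$genes$cox1$cds) - nchar(w$model$genes$cox2$cds))
  expect_identical(nchar(c31[[1]]$sequence) - nchar(c31[[2]]$sequence),
                   exp_diff)
})

test_that("generated cassette GC concentrates on its target", {
  # binomial concentration: a 9 kb CDS at target 0.55 lands within +/- 0.02
  cfg <- small_model_config()
  cfg$genes[[1]] <- list(name = "cox1", cds_len = 9000, ncr_len = 200,
                         gc = 0.55)
  model <- build_species_model(cfg)
  expect_lt(abs(gc_content(model$genes$cox1$cds) - 0.55), 0.02)

  # 3-sigma convergence of constant-region GC
  w <- small_world()
  for (x in w$circles[1:2]) {
    s <- substr(x$sequence, x$constant_interval[1] + 1, x$constant_interval[2])
    n <- nchar(s)
    expect_lt(abs(gc_content(s) - 0.6), 3 * sqrt(0.6 * 0.4 / n))
  }
})

test_that("mutate_sequence matches the binomial error model", {
  s <- random_dna(1000)
  expect_identical(mutate_sequence(s, 0, 0, seed = 1), s)
  expect_identical(mutate_sequence(s, 0.1, 0.05, seed = 7),
                   mutate_sequence(s, 0.1, 0.05, seed = 7))
  expect_false(mutate_sequence(s, 0.1, 0.05, seed = 7) ==
                 mutate_sequence(s, 0.1, 0.05, seed = 8))
  expect_error(mutate_sequence(s, -0.1, 0), class =
                 "minicircler_validation_error")

  # substitution-only: mean mismatch count over 100 seeds within 3 binomial
  # sigma of rate * length (Levenshtein equals Hamming here)
  long <- withr::with_seed(1, random_dna(10000))
  base <- strsplit(long, "")[[1]]
  d <- vapply(1:100, function(sd) {
    sum(strsplit(mutate_sequence(long, 0.05, 0, seed = sd), "")[[1]] != base)
  }, 1)
  sigma <- sqrt(10000 * 0.05 * 0.95)
  expect_lt(abs(mean(d) - 500), 3 * sigma)

  # small case against a true edit-distance oracle
  sm <- withr::with_seed(2, random_dna(300))
  mut <- mutate_sequence(sm, 0.05, 0.02, seed = 3)
  expect_lt(utils::adist(sm, mut), 0.25 * 300)
  expect_gt(utils::adist(sm, mut), 0)
})

test_that("simulate_reads respects the category mixture and ground truth", {
  w <- small_world()
  p <- simulation_params(n_reads = 200, fraction_homo = 0, fraction_hetero = 0,
                         fraction_background = 0, seed = 4)
  sim <- simulate_reads(w$circles, p)
  expect_identical(nrow(sim$reads), 200L)
  expect_identical(nrow(sim$truth), 200L)
  expect_true(all(sim$truth$category == "single"))

  p2 <- simulation_params(n_reads = 400, fraction_homo = 0.1,
                          fraction_hetero = 0.1, fraction_background = 0.1,
                          seed = 5)
  sim2 <- simulate_reads(w$circles, p2)
  expect_identical(sum(table(sim2$truth$category)), 400L)
  expect_true(all(sim2$truth$unit_count[sim2$truth$category == "homo"] >= 2))

  # hetero reads join >= 2 distinct genes from one constant group
  het <- sim2$truth[sim2$truth$category == "hetero", ]
  expect_gt(nrow(het), 0)
  grp <- stats::setNames(vapply(w$circles, `[[`, "", "constant_group"),
                         vapply(w$circles, `[[`, "", "gene"))
  for (g in strsplit(het$genes, ",")) {
    expect_length(unique(g), 2L)
    expect_length(unique(grp[g]), 1L)
  }

  # invalid mixtures rejected
  expect_error(simulation_params(fraction_homo = 0.7, fraction_hetero = 0.7),
               class = "minicircler_validation_error")
})

test_that("simulation is byte-identical for identical config and seed", {
  w <- small_world()
  p <- simulation_params(n_reads = 50, sub_rate = 0.05, indel_rate = 0.02,
                         fraction_homo = 0.05, fraction_hetero = 0.05,
                         seed = 9)
  f1 <- tempfile(fileext = ".fastq")
  f2 <- tempfile(fileext = ".fastq")
  write_fastq(simulate_reads(w$circles, p)$reads, f1)
  write_fastq(simulate_reads(w$circles, p)$reads, f2)
  expect_identical(readLines(f1), readLines(f2))
  expect_identical(unname(tools::md5sum(f1)), unname(tools::md5sum(f2)))
})

test_that("error-free hetero reads have the cassette-constant-cassette anatomy", {
  w <- small_world()
  p <- simulation_params(n_reads = 60, fraction_hetero = 0.5, seed = 12)
  sim <- simulate_reads(w$circles, p)
  het <- sim$truth[sim$truth$category == "hetero", ]
  by_gene <- stats::setNames(w$circles, vapply(w$circles, `[[`, "", "gene"))
  cassette <- function(x) substr(x$sequence, x$cassette_interval[1] + 1,
                                 x$cassette_interval[2])
  constant <- function(x) substr(x$sequence, x$constant_interval[1] + 1,
                                 x$constant_interval[2])
  for (i in seq_len(nrow(het))) {
    seq <- sim$reads$sequence[sim$reads$read_id == het$read_id[i]]
    if (het$strand[i] == "-") seq <- revcomp(seq)
    gs <- strsplit(het$genes[i], ",")[[1]]
    a <- by_gene[[gs[1]]]
    b <- by_gene[[gs[2]]]
    # exact substring matches to both cassettes, separated by one full
    # constant region, at error rate 0
    pa <- regexpr(cassette(a), seq, fixed = TRUE)
    pb <- regexpr(cassette(b), seq, fixed = TRUE)
    expect_identical(as.integer(pa), 1L)
    expect_identical(as.integer(pb),
                     nchar(cassette(a)) + nchar(constant(a)) + 1L)
  }
})
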