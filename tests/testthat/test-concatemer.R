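# Hand-built hit tables for unit-level classification checks.
mk_hits <- function(..., ref = "cox3", read_id = "r1") {
  segs <- list(...)
  do.call(rbind, lapply(segs, function(s) {
    data.frame(read_id = read_id, ref_id = s$ref %||% ref,
               read_start = s$rs, read_end = s$re, ref_start = s$qs,
               ref_end = s$qe, strand = s$strand %||% "+",
               identity = s$identity %||% 0.95,
               score = 2 * (s$qe - s$qs), matches = s$qe - s$qs,
               columns = s$qe - s$qs, stringsAsFactors = FALSE)
  }))
}
with_len <- function(hits, lens) {
  attr(hits, "ref_len") <- lens
  hits
}
CDS_LEN <- c(cox3 = 800L, cox2 = 700L, nad1 = 600L)
CONST_LEN <- c(constA = 1000L)

test_that("single, homo and hetero reads classify per the unit rules", {
  cc <- classifier_config()
  # one cassette + one constant region -> one unit, single
  gh <- with_len(mk_hits(list(rs = 0, re = 800, qs = 0, qe = 800)), CDS_LEN)
  ch <- with_len(mk_hits(list(rs = 810, re = 1800, qs = 0, qe = 1000,
                              ref = "constA")), CONST_LEN)
  u <- decompose_read("r1", gh, ch, cc)
  expect_identical(nrow(u), 2L)
  cls <- classify_read(u, cc, "r1")
  expect_identical(cls$category, "single")
  expect_identical(cls$confidence, "high")
  expect_identical(cls$structure, "cox3-constant")

  # cox3 - constant - cox3 with full CDS copies -> homo
  gh <- with_len(mk_hits(list(rs = 0, re = 800, qs = 0, qe = 800),
                         list(rs = 1810, re = 2610, qs = 0, qe = 800)),
                 CDS_LEN)
  ch <- with_len(mk_hits(list(rs = 810, re = 1800, qs = 0, qe = 1000,
                              ref = "constA")), CONST_LEN)
  cls <- classify_read(decompose_read("r1", gh, ch, cc), cc, "r1")
  expect_identical(cls$category, "homo")
  expect_identical(cls$unit_count, 2L)
  expect_identical(cls$confidence, "high")

  # cox2 - constant - nad1 with full coverage -> hetero, high confidence
  gh <- with_len(mk_hits(list(rs = 0, re = 700, qs = 0, qe = 700,
                              ref = "cox2"),
                         list(rs = 1710, re = 2310, qs = 0, qe = 600,
                              ref = "nad1")), CDS_LEN)
  ch <- with_len(mk_hits(list(rs = 710, re = 1700, qs = 0, qe = 1000,
                              ref = "constA")), CONST_LEN)
  cls <- classify_read(decompose_read("r1", gh, ch, cc), cc, "r1")
  expect_identical(cls$category, "hetero")
  expect_identical(cls$confidence, "high")
  expect_identical(cls$genes, "cox2,nad1")

  # no hits -> non_mito
  cls <- classify_read(decompose_read("rX", gh[0, ], NULL, cc), cc, "rX")
  expect_identical(cls$category, "non_mito")
})

test_that("a wrapped single copy merges; re-covered CDS opens a new unit", {
  cc <- classifier_config()
  # read linearized inside the cassette: fragments cover [300,800) then
  # [0,300) -> complementary, one unit, single
  gh <- with_len(mk_hits(list(rs = 0, re = 500, qs = 300, qe = 800),
                         list(rs = 1510, re = 1810, qs = 0, qe = 300)),
                 CDS_LEN)
  ch <- with_len(mk_hits(list(rs = 510, re = 1500, qs = 0, qe = 1000,
                              ref = "constA")), CONST_LEN)
  cls <- classify_read(decompose_read("r1", gh, ch, cc), cc, "r1")
  expect_identical(cls$category, "single")
  expect_identical(cls$unit_count, 1L)

  # same layout but the second fragment re-covers the full CDS -> homo
  gh <- with_len(mk_hits(list(rs = 0, re = 500, qs = 300, qe = 800),
                         list(rs = 1510, re = 2310, qs = 0, qe = 800)),
                 CDS_LEN)
  cls <- classify_read(decompose_read("r1", gh, ch, cc), cc, "r1")
  expect_identical(cls$category, "homo")
})

test_that("chimeric overlaps and inverted repeats are ambiguous", {
  cc <- classifier_config()
  # two distinct genes overlapping on the read -> ambiguous, never hetero
  gh <- with_len(mk_hits(list(rs = 0, re = 700, qs = 0, qe = 700,
                              ref = "cox2"),
                         list(rs = 500, re = 1100, qs = 0, qe = 600,
                              ref = "nad1")), CDS_LEN)
  cls <- classify_read(decompose_read("r1", gh, NULL, cc), cc, "r1")
  expect_identical(cls$category, "ambiguous")

  # inverted same-gene copies -> ambiguous, not homo
  gh <- with_len(mk_hits(list(rs = 0, re = 800, qs = 0, qe = 800),
                         list(rs = 1810, re = 2610, qs = 0, qe = 800,
                              strand = "-")), CDS_LEN)
  ch <- with_len(mk_hits(list(rs = 810, re = 1800, qs = 0, qe = 1000,
                              ref = "constA")), CONST_LEN)
  cls <- classify_read(decompose_read("r1", gh, ch, cc), cc, "r1")
  expect_identical(cls$category, "ambiguous")
})

test_that("summaries conserve counts and recover generator truth pairs", {
  w <- small_world()
  p <- simulation_params(n_reads = 250, fraction_homo = 0.06,
                         fraction_hetero = 0.06, fraction_background = 0.04,
                         seed = 13)
  sim <- simulate_reads(w$circles, p)
  cc <- classifier_config()
  gh <- filter_hits(align_reads(sim$reads, w$cds, cc), w$cds, cc, "collect")
  ch <- filter_hits(align_reads(sim$reads, w$constant, cc), w$constant, cc,
                    "collect")
  cls <- classify_reads(sim$reads$read_id, gh, ch, cds_refs = w$cds,
                        constant_refs = w$constant, config = cc)
  # categories partition the read set
  expect_identical(nrow(cls), 250L)
  rep <- summarize_concatemers(cls)
  expect_identical(sum(rep$counts), 250L)

  # error-free classification recovers generator truth exactly
  map <- c(background = "non_mito", single = "single", homo = "homo",
           hetero = "hetero")
  expect_identical(unname(map[sim$truth$category]), cls$category)

  # edge list equals the generator's hetero pair composition
  truth_pairs <- sort(vapply(
    strsplit(sim$truth$genes[sim$truth$category == "hetero"], ","),
    function(g) paste(sort(g), collapse = "|"), ""))
  called_pairs <- sort(rep(paste(rep$edges$gene_a, rep$edges$gene_b,
                                 sep = "|"), rep$edges$count))
  expect_identical(called_pairs, truth_pairs)

  # order invariance: shuffling reads leaves the report identical
  perm <- withr::with_seed(5, sample(nrow(sim$reads)))
  cls2 <- classify_reads(sim$reads$read_id[perm], gh, ch, cds_refs = w$cds,
                         constant_refs = w$constant, config = cc)
  rep2 <- summarize_concatemers(cls2)
  expect_identical(rep$edges, rep2$edges)
  expect_identical(as.integer(rep$counts), as.integer(rep2$counts))
})

test_that("strand invariance: reverse-complementing reads keeps categories", {
  w <- small_world()
  sim <- simulate_reads(w$circles, simulation_params(
    n_reads = 120, sub_rate = 0.02, indel_rate = 0.01, fraction_homo = 0.05,
    fraction_hetero = 0.05, seed = 17))
  cc <- classifier_config()
  run <- function(reads) {
    gh <- filter_hits(align_reads(reads, w$cds, cc), w$cds, cc, "collect")
    ch <- filter_hits(align_reads(reads, w$constant, cc), w$constant, cc,
                      "collect")
    cls <- classify_reads(names(reads), gh, ch, cds_refs = w$cds,
                          constant_refs = w$constant, config = cc)
    table(cls$category)
  }
  fwd <- stats::setNames(sim$reads$sequence, sim$reads$read_id)
  expect_identical(run(fwd), run(stats::setNames(revcomp(fwd), names(fwd))))
})

test_that("incompatible constant-group joins are flagged", {
  groups <- c(atp6 = "grpAtp6", cox1 = "grpMain", cox2 = "grpMain")
  edges <- data.frame(gene_a = c("atp6", "cox1"), gene_b = c("cox1", "cox2"),
                      count = c(1L, 3L), stringsAsFactors = FALSE)
  rep <- structure(list(counts = table(character(0)), edges = edges,
                        structures = table(character(0)), n_reads = 4L),
                   class = "concatemer_report")
  out <- flag_incompatible_joins(rep, groups)
  expect_identical(out$edges$suspect, c(TRUE, FALSE))

  # empty edge list -> no flags
  rep$edges <- edges[0, ]
  expect_identical(nrow(flag_incompatible_joins(rep, groups)$edges), 0L)

  # unassigned gene -> validation error
  rep$edges <- edges
  expect_error(flag_incompatible_joins(rep, groups[-1]),
               class = "minicircler_validation_error")
})
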