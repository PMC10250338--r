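AVOGADRO <- 6.02214076e23
BP_MASS_G_PER_MOL <- 660  # average mass of one base pair, g/mol
BDNA_RISE_NM <- 0.34      # canonical B-DNA rise per bp

#' Copies of a DNA template from its mass
#'
#' `copies = x * N_A / (l * 660 * 1e9)` where `x` is DNA amount in ng,
#' `N_A` the Avogadro constant and `l` the template length in bp (660 g/mol
#' per bp; the 1e9 converts ng to g).
#'
#' @param x DNA amount in ng (vectorized).
#' @param l template length in bp.
#' @return copy number (double).
#' @examples
#' copies_from_mass(1, 150)  # ~6.08e9 copies of a 150 bp amplicon
#' @export
copies_from_mass <- function(x, l) {
  if (any(l < 1)) stop_validation("template length must be >= 1 bp")
  if (any(x < 0)) stop_validation("DNA amount must be >= 0 ng")
  x * AVOGADRO / (l * BP_MASS_G_PER_MOL * 1e9)
}

#' Fit a qPCR standard curve
#'
#' Ordinary least squares of Cq on log10 copies over a dilution series.
#' Amplification efficiency is `10^(-1/k) - 1` with `k` the slope; a
#' perfectly doubling reaction has slope `-1/log10(2) ~ -3.32` and
#' efficiency 1 (100%).
#'
#' @param dilution_series data.frame with columns `log10_copies` and `Cq`
#'   (replicate rows allowed).
#' @return a `standard_curve`: slope, intercept, r_squared, efficiency,
#'   n_points, cq_range.
#' @export
fit_standard_curve <- function(dilution_series) {
  d <- dilution_series
  if (!all(c("log10_copies", "Cq") %in% names(d))) {
    stop_validation("dilution_series needs columns log10_copies and Cq")
  }
  d <- d[complete.cases(d[, c("log10_copies", "Cq")]), , drop = FALSE]
  if (nrow(d) < 3L) stop_validation("standard curve needs >= 3 points")
  if (length(unique(d$log10_copies)) < 2L) {
    stop_validation("zero variance in log10_copies")
  }
  fit <- lm(Cq ~ log10_copies, data = d)
  k <- unname(coef(fit)[2L])
  ssr <- sum(fit$residuals^2)
  sst <- sum((d$Cq - mean(d$Cq))^2)
  structure(list(slope = k, intercept = unname(coef(fit)[1L]),
                 r_squared = if (sst == 0) 1 else 1 - ssr / sst,
                 efficiency = pcr_efficiency(k), n_points = nrow(d),
                 cq_range = range(d$Cq)),
            class = "standard_curve")
}

#' @rdname fit_standard_curve
#' @param k standard-curve slope (cycles per log10 copies, negative for a
#'   valid curve).
#' @export
pcr_efficiency <- function(k) 10^(-1 / k) - 1

#' @export
print.standard_curve <- function(x, ...) {
  cat(sprintf(
    "<standard_curve> slope %.4f, intercept %.3f, R^2 %.4f, efficiency %.1f%%\n",
    x$slope, x$intercept, x$r_squared, 100 * x$efficiency))
  invisible(x)
}

#' Mitochondrial-to-nuclear copy-number ratios from qPCR
#'
#' Replicate Cq values are averaged per gene, copies are interpolated from
#' each gene's own standard curve (`copies = 10^((Cq - intercept)/slope)`),
#' and each mitochondrial gene's copies are divided by the nuclear
#' reference gene's. The summary is the mean +/- sample (n-1) sd across
#' mitochondrial genes. Cq values outside a curve's calibrated range are
#' flagged as extrapolated.
#'
#' @param targets data.frame with columns `gene`, `Cq` (and optionally
#'   `replicate`).
#' @param curves named list of `standard_curve` objects, one per gene.
#' @param nuclear_reference name of the nuclear single-copy reference gene.
#' @return a `copy_ratio_result`: per-gene table (gene, mean_cq, copies,
#'   fold_ratio, extrapolated) plus `mean_ratio`, `sd_ratio`, `summary`.
#' @export
copy_ratio <- function(targets, curves, nuclear_reference) {
  if (!all(c("gene", "Cq") %in% names(targets))) {
    stop_validation("targets needs columns gene and Cq")
  }
  genes <- unique(targets$gene)
  if (!nuclear_reference %in% genes) {
    stop_validation("nuclear reference ", nuclear_reference,
                    " absent from targets")
  }
  miss <- setdiff(genes, names(curves))
  if (length(miss)) stop_validation("no standard curve for: ",
                                    paste(miss, collapse = ", "))
  per_gene <- do.call(rbind, lapply(genes, function(g) {
    cv <- curves[[g]]
    mcq <- mean(targets$Cq[targets$gene == g])
    data.frame(gene = g, mean_cq = mcq,
               copies = 10^((mcq - cv$intercept) / cv$slope),
               extrapolated = mcq < cv$cq_range[1L] | mcq > cv$cq_range[2L],
               stringsAsFactors = FALSE)
  }))
  ref_copies <- per_gene$copies[per_gene$gene == nuclear_reference]
  per_gene$fold_ratio <- per_gene$copies / ref_copies
  mito <- per_gene[per_gene$gene != nuclear_reference, , drop = FALSE]
  if (any(per_gene$extrapolated)) {
    warning("Cq outside calibrated range for: ",
            paste(per_gene$gene[per_gene$extrapolated], collapse = ", "),
            " (extrapolated)")
  }
  m <- mean(mito$fold_ratio)
  s <- if (nrow(mito) > 1L) sd(mito$fold_ratio) else NA_real_
  structure(list(per_gene = per_gene, nuclear_reference = nuclear_reference,
                 mean_ratio = m, sd_ratio = s,
                 summary = sprintf("%.1f ± %.1f", m, s)),
            class = "copy_ratio_result")
}

#' @export
print.copy_ratio_result <- function(x, ...) {
  cat("<copy_ratio_result> reference: ", x$nuclear_reference, "\n", sep = "")
  print(x$per_gene, row.names = FALSE)
  cat("mitochondrial : nuclear fold ratio = ", x$summary, "\n", sep = "")
  invisible(x)
}

#' GC content of DNA sequences
#'
#' `(G + C) / (A + C + G + T)`; N and other ambiguity codes are excluded
#' from the denominator. All-ambiguous sequences give `NA` with a warning.
#'
#' @param seqs character vector of sequences.
#' @return numeric vector of GC fractions.
#' @export
gc_content <- function(seqs) {
  out <- vapply(toupper(seqs), function(s) {
    check_dna(s)
    gc_fraction_chr(s)
  }, 1, USE.NAMES = FALSE)
  if (anyNA(out)) warning("GC undefined for all-N sequence(s)")
  if (!is.null(names(seqs))) names(out) <- names(seqs)
  out
}

#' Wilcoxon rank-sum (Mann-Whitney) comparison of two groups
#'
#' Implemented internally: for `min(n) <= 8` and combined `n <= 16` the
#' exact two-sided p-value is obtained by enumerating the permutation null
#' of the U statistic over all group assignments of the observed
#' (mid-)ranks, which remains valid under ties; otherwise the normal
#' approximation with tie correction and continuity correction is used.
#' The two-sided p is `min(1, 2 * min(P(U <= u), P(U >= u)))`.
#'
#' @param group_a,group_b numeric vectors (e.g. GC fractions).
#' @param exact force (`TRUE`) or suppress (`FALSE`) the exact enumeration;
#'   `NULL` applies the size rule above.
#' @return list: statistic (U of `group_a`), p_value, method.
#' @export
gc_compare <- function(group_a, group_b, exact = NULL) {
  if (length(group_a) < 1L || length(group_b) < 1L) {
    stop_validation("both groups must be non-empty")
  }
  na <- length(group_a)
  nb <- length(group_b)
  r <- rank(c(group_a, group_b))
  u_obs <- sum(r[seq_len(na)]) - na * (na + 1) / 2
  exact <- exact %||% (min(na, nb) <= 8L && (na + nb) <= 16L)
  if (exact) {
    sums <- rank_sum_null(r, na)
    u_all <- sums - na * (na + 1) / 2
    p <- min(1, 2 * min(mean(u_all <= u_obs), mean(u_all >= u_obs)))
    method <- "exact permutation enumeration"
  } else {
    n <- na + nb
    ties <- table(r)
    mu <- na * nb / 2
    sigma2 <- (na * nb / 12) * (n + 1 - sum(ties^3 - ties) / (n * (n - 1)))
    z_num <- u_obs - mu
    z <- (z_num - sign(z_num) * 0.5) / sqrt(sigma2)
    p <- min(1, 2 * pnorm(-abs(z)))
    method <- "normal approximation with tie and continuity correction"
  }
  list(statistic = u_obs, p_value = p, method = method)
}

# distribution of the group-a rank sum over all C(n, na) assignments
rank_sum_null <- function(r, na) {
  idx <- combn(length(r), na)
  colSums(matrix(r[idx], nrow = na))
}

#' Convert between DNA contour length and base pairs
#'
#' Microscopy measures contour length in nm; the canonical B-DNA rise is
#' 0.34 nm/bp but surface-deposited molecules are under-extended, so a
#' case-specific conversion factor is calibrated from a molecule of known
#' size. Supply `length_nm` and `bp` to calibrate `nm_per_bp` (and the
#' fractional extension `nm_per_bp / 0.34`); supply `length_nm` and
#' `nm_per_bp` to estimate `bp`.
#'
#' @param length_nm measured contour length (nm).
#' @param bp molecule size in bp (for calibration).
#' @param nm_per_bp effective conversion factor (for size estimation).
#' @return list: nm_per_bp, fractional_extension, bp_estimate (NA when not
#'   derivable).
#' @export
contour_conversions <- function(length_nm = NULL, bp = NULL,
                                nm_per_bp = NULL) {
  if (!is.null(bp) && any(bp <= 0)) stop_validation("bp must be positive")
  if (!is.null(length_nm) && any(length_nm <= 0)) {
    stop_validation("length_nm must be positive")
  }
  if (is.null(nm_per_bp)) {
    if (is.null(length_nm) || is.null(bp)) {
      stop_validation("supply length_nm and bp, or nm_per_bp")
    }
    nm_per_bp <- length_nm / bp
    bp_estimate <- bp
  } else {
    if (nm_per_bp <= 0) stop_validation("nm_per_bp must be positive")
    bp_estimate <- if (!is.null(length_nm)) length_nm / nm_per_bp else
      NA_real_
  }
  list(nm_per_bp = nm_per_bp,
       fractional_extension = nm_per_bp / BDNA_RISE_NM,
       bp_estimate = bp_estimate)
}
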