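#' Quality-control thresholds
#'
#' Defaults follow standard biobank-scale GWAS practice: variants need
#' minor allele frequency >= 0.01, genotyped variants a call rate >= 0.95,
#' imputed variants an INFO score >= 0.3, and an exact Hardy-Weinberg
#' equilibrium p-value >= 1e-20; samples need a genotype call rate >= 0.98.
#'
#' @param maf_min Minimum minor allele frequency (inclusive).
#' @param genotyped_call_rate_min Minimum call rate for genotyped variants.
#' @param info_min Minimum INFO score for imputed variants.
#' @param hwe_p_floor Variants with exact HWE p strictly below this are
#'   excluded.
#' @param sample_call_rate_min Minimum per-sample genotype call rate.
#' @return Object of class `qc_thresholds`.
#' @export
qc_thresholds <- function(maf_min = 0.01,
                          genotyped_call_rate_min = 0.95,
                          info_min = 0.3,
                          hwe_p_floor = 1e-20,
                          sample_call_rate_min = 0.98) {
  thr <- list(maf_min = maf_min,
              genotyped_call_rate_min = genotyped_call_rate_min,
              info_min = info_min,
              hwe_p_floor = hwe_p_floor,
              sample_call_rate_min = sample_call_rate_min)
  for (nm in names(thr)) {
    if (nm == "hwe_p_floor") next
    if (thr[[nm]] < 0 || thr[[nm]] > 1) stop(nm, " must lie in [0, 1]")
  }
  if (thr$hwe_p_floor < 0 || thr$hwe_p_floor > 1) stop("hwe_p_floor must lie in [0, 1]")
  structure(thr, class = "qc_thresholds")
}

#' Exact Hardy-Weinberg equilibrium test
#'
#' Exact (conditional) test of HWE given observed genotype counts: the
#' p-value is the total probability, under the exact distribution of the
#' heterozygote count conditional on the allele counts, of all heterozygote
#' configurations no more probable than the observed one. No mid-p
#' correction. All probabilities are accumulated in log space via the
#' upward recurrence over heterozygote counts, so p-values far below
#' double-precision underflow of intermediate terms (e.g. near 1e-20 and
#' beyond) are exact.
#'
#' @param n_hom_ref,n_het,n_hom_alt Genotype counts (non-negative, total > 0).
#' @return p-value in `(0, 1]`; symmetric in the allele labelling.
#' @examples
#' hwe_exact_test(25, 50, 25)  # perfect HWE proportions: p = 1
#' @export
hwe_exact_test <- function(n_hom_ref, n_het, n_hom_alt) {
  if (any(c(n_hom_ref, n_het, n_hom_alt) < 0)) stop("genotype counts must be >= 0")
  n <- n_hom_ref + n_het + n_hom_alt
  if (n == 0) stop("all genotype counts are zero")
  nA <- 2 * n_hom_ref + n_het
  nB <- 2 * n_hom_alt + n_het
  rare <- min(nA, nB)
  if (rare == 0) return(1)

  h_min <- rare %% 2
  hs <- seq.int(h_min, rare, by = 2)
  # log P(h+2) - log P(h) = log(4 * homR(h) * homC(h)) - log((h+2)(h+1))
  lp <- numeric(length(hs))
  if (length(hs) > 1) {
    h <- hs[-length(hs)]
    hom_r <- (rare - h) / 2
    hom_c <- (2 * n - rare - h) / 2
    steps <- log(4) + log(hom_r) + log(hom_c) - log(h + 2) - log(h + 1)
    lp <- c(0, cumsum(steps))
  }
  lp <- lp - logsumexp(lp)
  lp_obs <- lp[match(n_het, hs)]
  if (is.na(lp_obs)) stop("heterozygote count inconsistent with allele counts")
  keep <- lp <= lp_obs + 1e-10
  min(exp(logsumexp(lp[keep])), 1)
}

# Hard-call dosages to genotypes {0,1,2} (nearest integer); used only for HWE.
hard_calls <- function(dosages) {
  hc <- round_half_away(dosages)
  hc[hc < 0] <- 0
  hc[hc > 2] <- 2
  hc
}

# Per-variant statistics computed in column chunks so no temporary the size
# of the dosage matrix is ever allocated (panels can be hundreds of MB).
col_dosage_stats <- function(dosages, chunk_size = 2000, genotype_counts = FALSE) {
  m <- ncol(dosages)
  af <- call_rate <- numeric(m)
  n0 <- n1 <- n2 <- if (genotype_counts) numeric(m) else NULL
  for (start in seq(1, m, by = chunk_size)) {
    cols <- start:min(start + chunk_size - 1, m)
    d <- dosages[, cols, drop = FALSE]
    storage.mode(d) <- "double"
    af[cols] <- colMeans(d, na.rm = TRUE) / 2
    call_rate[cols] <- colMeans(!is.na(d))
    if (genotype_counts) {
      hc <- hard_calls(d)
      n0[cols] <- colSums(hc == 0, na.rm = TRUE)
      n1[cols] <- colSums(hc == 1, na.rm = TRUE)
      n2[cols] <- colSums(hc == 2, na.rm = TRUE)
    }
  }
  list(maf = fold_maf(af), call_rate = call_rate, n0 = n0, n1 = n1, n2 = n2)
}

# Per-variant minor allele frequency from non-missing dosages.
variant_maf <- function(dosages) {
  col_dosage_stats(dosages)$maf
}

new_qc_report <- function(stage, n_in, n_out, removed) {
  structure(list(stage = stage, n_in = n_in, n_out = n_out, removed = removed),
            class = "qc_report")
}

#' @export
print.qc_report <- function(x, ...) {
  cat(sprintf("QC (%s): %d in -> %d out\n", x$stage, x$n_in, x$n_out))
  for (nm in names(x$removed)) {
    cat(sprintf("  removed by %s: %d\n", nm, x$removed[[nm]]))
  }
  invisible(x)
}

#' Variant-level quality control
#'
#' Applies, in order: (1) minor allele frequency >= `maf_min`; (2) call
#' rate >= `genotyped_call_rate_min` for genotyped variants, INFO score >=
#' `info_min` for imputed variants; (3) exact HWE p >= `hwe_p_floor`,
#' computed on hard-called genotypes. Each variant is tallied against the
#' first rule it fails, so the per-rule removal counts plus the survivors
#' reconcile exactly with the input count.
#'
#' @param geno A [genotype_dataset()].
#' @param thr A [qc_thresholds()].
#' @return List with `genotypes` (filtered dataset) and `report`
#'   (a `qc_report`).
#' @export
variant_qc <- function(geno, thr = qc_thresholds()) {
  m <- nrow(geno$variants)
  if (m == 0) stop("empty genotype dataset")

  st <- col_dosage_stats(geno$dosages, genotype_counts = TRUE)
  fail_maf <- !is.finite(st$maf) | st$maf < thr$maf_min

  fail_cr_info <- ifelse(geno$variants$is_imputed,
                         geno$variants$info_score < thr$info_min,
                         st$call_rate < thr$genotyped_call_rate_min)
  fail_cr_info <- fail_cr_info & !fail_maf

  candidates <- which(!fail_maf & !fail_cr_info)
  fail_hwe <- logical(m)
  if (length(candidates) > 0) {
    hwe_p <- vapply(candidates, function(j) {
      if (st$n0[j] + st$n1[j] + st$n2[j] == 0) return(NA_real_)
      hwe_exact_test(st$n0[j], st$n1[j], st$n2[j])
    }, numeric(1))
    fail_hwe[candidates] <- is.na(hwe_p) | hwe_p < thr$hwe_p_floor
  }

  keep <- !fail_maf & !fail_cr_info & !fail_hwe
  if (!any(keep)) warning("no variants pass QC")
  report <- new_qc_report(
    "variants", m, sum(keep),
    c(maf = sum(fail_maf), call_rate_or_info = sum(fail_cr_info),
      hwe = sum(fail_hwe))
  )
  list(genotypes = subset_genotypes(geno, variants = which(keep)),
       report = report)
}

#' Sample-level quality control
#'
#' Removes samples whose fraction of non-missing genotype calls falls below
#' `sample_call_rate_min`.
#'
#' @inheritParams variant_qc
#' @return List with `genotypes` and `report`.
#' @export
sample_qc <- function(geno, thr = qc_thresholds()) {
  n <- length(geno$sample_ids)
  if (n == 0) stop("empty genotype dataset")
  m <- ncol(geno$dosages)
  n_obs <- numeric(n)
  for (start in seq(1, m, by = 2000)) {   # chunked: avoid m x n temporaries
    cols <- start:min(start + 1999, m)
    n_obs <- n_obs + rowSums(!is.na(geno$dosages[, cols, drop = FALSE]))
  }
  call_rate <- n_obs / m
  keep <- call_rate >= thr$sample_call_rate_min
  report <- new_qc_report("samples", n, sum(keep),
                          c(call_rate = sum(!keep)))
  list(genotypes = subset_genotypes(geno, samples = which(keep)),
       report = report)
}
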