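#' SNP-overlap accuracy between two significant-SNP sets
#'
#' Treats variants significant in both scans as true positives (TP),
#' variants significant only in the degraded scan as false positives (FP)
#' and variants significant only in the baseline scan as false negatives
#' (FN), and returns `TP / (TP + FP + FN)` — the Jaccard index of the two
#' sets. When both sets are empty there is no signal to lose and the
#' accuracy is defined as 1.
#'
#' @param base_set,degraded_set Character vectors of significant
#'   `variant_id`s (canonical `"chrom:pos:ref:alt"` strings).
#' @return List with `accuracy` in `[0, 1]` and counts `tp`, `fp`, `fn`.
#' @examples
#' snp_accuracy(c("a", "b", "c", "d"), c("a", "b", "e"))$accuracy  # 0.4
#' @export
snp_accuracy <- function(base_set, degraded_set) {
  base_set <- unique(as.character(base_set))
  degraded_set <- unique(as.character(degraded_set))
  tp <- length(intersect(base_set, degraded_set))
  fp <- length(setdiff(degraded_set, base_set))
  fn <- length(setdiff(base_set, degraded_set))
  denom <- tp + fp + fn
  list(accuracy = if (denom == 0) 1 else tp / denom,
       tp = tp, fp = fp, fn = fn)
}

#' Loci sensitivity from a locus match
#'
#' The fraction of baseline genome-wide-significant loci that persist in
#' the degraded scan: `peaks_correct / peaks_base`. With no baseline loci
#' there is no signal to lose, and sensitivity is defined as 1.
#'
#' @param match A `locus_match` from [match_loci()], or any list with
#'   `peaks_base` and `peaks_correct`.
#' @return Sensitivity in `[0, 1]`.
#' @export
loci_sensitivity <- function(match) {
  if (match$peaks_base < 0 || match$peaks_correct < 0 ||
      match$peaks_correct > match$peaks_base) {
    stop("invalid peak counts")
  }
  if (match$peaks_base == 0) return(1)
  match$peaks_correct / match$peaks_base
}

#' Agreement metrics between paired measurements
#'
#' Mean absolute error, squared Pearson correlation, and the intraclass
#' correlation coefficient in its two-way random-effects,
#' absolute-agreement, single-measure form (ICC(A,1)), computed from the
#' two-way ANOVA mean squares for n subjects x 2 raters.
#'
#' @param original,modified Paired numeric vectors of equal length >= 2.
#' @return An `agreement_metrics` list with `mae`, `r2` (`NA` if either
#'   vector has zero variance) and `icc`.
#' @export
agreement <- function(original, modified) {
  if (length(original) != length(modified)) {
    stop("original and modified must have equal length")
  }
  ok <- !is.na(original) & !is.na(modified)
  x <- original[ok]; y <- modified[ok]
  n <- length(x)
  if (n < 2) stop("need at least 2 complete pairs")

  mae <- mean(abs(y - x))
  r2 <- if (stats::var(x) == 0 || stats::var(y) == 0) NA_real_ else
    stats::cor(x, y)^2

  # two-way ANOVA mean squares, k = 2 raters
  mat <- cbind(x, y)
  k <- 2
  grand <- mean(mat)
  ssr <- k * sum((rowMeans(mat) - grand)^2)
  ssc <- n * sum((colMeans(mat) - grand)^2)
  sst <- sum((mat - grand)^2)
  sse <- max(sst - ssr - ssc, 0)
  msr <- ssr / (n - 1)
  msc <- ssc / (k - 1)
  mse <- sse / ((n - 1) * (k - 1))
  icc <- (msr - mse) / (msr + (k - 1) * mse + (k / n) * (msc - mse))

  structure(list(mae = mae, r2 = r2, icc = icc, n = n),
            class = "agreement_metrics")
}

#' @export
print.agreement_metrics <- function(x, ...) {
  cat(sprintf("agreement over %d pairs: MAE = %.3f, R2 = %s, ICC = %.3f\n",
              x$n, x$mae,
              if (is.na(x$r2)) "NA" else sprintf("%.3f", x$r2), x$icc))
  invisible(x)
}

#' Power metrics of a degraded scan against a baseline scan
#'
#' Convenience wrapper: computes significant-SNP sets, clusters loci in
#' both scans, matches them, and returns SNP accuracy plus loci
#' sensitivity for one degradation condition.
#'
#' @param base_res,degraded_res `assoc_result` objects on the same variant
#'   universe.
#' @param alpha Genome-wide significance threshold.
#' @param merge_distance Locus clustering cutoff in base pairs.
#' @return List with `snp_accuracy`, `loci_sensitivity`, `peaks_base`,
#'   `peaks_correct`, and the overlap counts.
#' @export
power_metrics <- function(base_res, degraded_res, alpha = 5e-8,
                          merge_distance = 1e6) {
  base_set <- significant_snps(base_res, alpha)
  deg_set <- significant_snps(degraded_res, alpha)
  acc <- snp_accuracy(base_set, deg_set)
  base_loci <- cluster_loci(base_res, alpha, merge_distance)
  deg_loci <- cluster_loci(degraded_res, alpha, merge_distance)
  mt <- match_loci(base_loci, deg_loci)
  list(snp_accuracy = acc$accuracy,
       loci_sensitivity = loci_sensitivity(mt),
       peaks_base = mt$peaks_base,
       peaks_correct = mt$peaks_correct,
       tp = acc$tp, fp = acc$fp, fn = acc$fn)
}
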