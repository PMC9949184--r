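#' Noise sweep: GWAS power versus phenotype measurement error
#'
#' Applies sample and variant QC once, runs the baseline covariate-adjusted
#' scan on the undegraded phenotype, then for each noise SD draws an
#' independent Gaussian degradation (fresh seed per level), rescans, and
#' compares significant SNPs and clustered loci against the single baseline
#' scan. The per-condition empirical mean absolute error between degraded
#' and original phenotype is recorded as the regression predictor. A
#' baseline row (sigma 0, both metrics 1) is included.
#'
#' @param geno A [genotype_dataset()] (pre-QC).
#' @param pheno Phenotype data frame (`sample_id`, `value`, `age`, `sex`).
#' @param sigmas Noise SDs to sweep (default 1..10, phenotype units).
#' @param alpha Genome-wide significance threshold.
#' @param merge_distance Locus clustering cutoff (bp).
#' @param thresholds A [qc_thresholds()].
#' @param covariates Covariate column names for the scan.
#' @param seed Base seed; per-condition and per-replicate seeds are derived
#'   from it deterministically.
#' @param n_seeds Replicate degradations per condition; metrics are
#'   averaged across replicates (default 1, matching a single-realisation
#'   design).
#' @return A `sweep_table`: data frame with one row per condition
#'   (`condition_type`, `condition`, `mae`, `n_samples`, `peaks_base`,
#'   `peaks_correct`, `snp_accuracy`, `loci_sensitivity`).
#' @export
noise_sweep <- function(geno, pheno, sigmas = 1:10, alpha = 5e-8,
                        merge_distance = 1e6,
                        thresholds = qc_thresholds(),
                        covariates = c("age", "sex"),
                        seed = 1, n_seeds = 1) {
  sq <- sample_qc(geno, thresholds)
  vq <- variant_qc(sq$genotypes, thresholds)
  g <- vq$genotypes
  sq <- vq <- NULL   # release intermediate dosage copies
  pheno <- pheno[pheno$sample_id %in% g$sample_ids, , drop = FALSE]

  base <- run_gwas(g, pheno, "value", covariates)
  base_loci <- cluster_loci(base, alpha, merge_distance)

  rows <- list(sweep_row("noise", 0, mae = 0, n = attr(base, "n_total"),
                         pb = nrow(base_loci), pc = nrow(base_loci),
                         acc = 1, sens = 1))
  for (i in seq_along(sigmas)) {
    sg <- sigmas[i]
    res <- tryCatch({
      accs <- senss <- maes <- pcs <- numeric(n_seeds)
      for (r in seq_len(n_seeds)) {
        ph <- add_gaussian_noise(pheno, sigma = sg,
                                 seed = derive_seed(seed, i, r))
        maes[r] <- mean(abs(ph$noisy - ph$value))
        scan <- run_gwas(g, ph, "noisy", covariates)
        pm <- power_metrics(base, scan, alpha, merge_distance)
        accs[r] <- pm$snp_accuracy; senss[r] <- pm$loci_sensitivity
        pcs[r] <- pm$peaks_correct
      }
      sweep_row("noise", sg, mae = mean(maes), n = attr(base, "n_total"),
                pb = nrow(base_loci), pc = mean(pcs),
                acc = mean(accs), sens = mean(senss))
    }, error = function(e) {
      warning("noise condition sigma = ", sg, " failed: ", conditionMessage(e))
      sweep_row("noise", sg, mae = NA, n = NA, pb = NA, pc = NA,
                acc = NA, sens = NA)
    })
    rows[[length(rows) + 1]] <- res
  }
  finish_sweep(rows, alpha, merge_distance)
}

#' Cohort sweep: GWAS power versus cohort size
#'
#' For each retention fraction, the cohort is randomly downsampled before
#' QC (as in a cohort-reduction design), QC is re-applied to the subsample,
#' the scan is re-run on the undegraded phenotype, and metrics are computed
#' against the full-cohort baseline scan. The condition column holds the
#' percent of samples retained.
#'
#' @inheritParams noise_sweep
#' @param fractions Retention fractions in `(0, 1]`
#'   (default 1.0, 0.9, ..., 0.4).
#' @return A `sweep_table` (rows keyed by percent retained; `mae` is `NA`:
#'   the phenotype itself is unchanged).
#' @export
cohort_sweep <- function(geno, pheno, fractions = seq(1, 0.4, by = -0.1),
                         alpha = 5e-8, merge_distance = 1e6,
                         thresholds = qc_thresholds(),
                         covariates = c("age", "sex"),
                         seed = 1, n_seeds = 1) {
  if (any(fractions <= 0 | fractions > 1)) stop("fractions must lie in (0, 1]")
  sq <- sample_qc(geno, thresholds)
  vq <- variant_qc(sq$genotypes, thresholds)
  sq <- NULL
  base <- run_gwas(vq$genotypes,
                   pheno[pheno$sample_id %in% vq$genotypes$sample_ids, ,
                         drop = FALSE],
                   "value", covariates)
  vq <- NULL   # release QC'd dosage copy; comparisons only need `base`
  base_loci <- cluster_loci(base, alpha, merge_distance)

  rows <- list()
  for (i in seq_along(fractions)) {
    f <- fractions[i]
    if (f == 1) {
      rows[[length(rows) + 1]] <-
        sweep_row("cohort", 100, mae = NA_real_, n = attr(base, "n_total"),
                  pb = nrow(base_loci), pc = nrow(base_loci),
                  acc = 1, sens = 1)
      next
    }
    res <- tryCatch({
      accs <- senss <- pcs <- ns <- numeric(n_seeds)
      for (r in seq_len(n_seeds)) {
        sub <- subsample_cohort(geno, pheno, f, seed = derive_seed(seed, i, r))
        sq_s <- sample_qc(sub$genotypes, thresholds)
        sub$genotypes <- NULL
        vq_s <- variant_qc(sq_s$genotypes, thresholds)
        sq_s <- NULL
        ph_s <- sub$phenotypes[sub$phenotypes$sample_id %in%
                                 vq_s$genotypes$sample_ids, , drop = FALSE]
        scan <- run_gwas(vq_s$genotypes, ph_s, "value", covariates)
        vq_s <- NULL
        pm <- power_metrics(base, scan, alpha, merge_distance)
        accs[r] <- pm$snp_accuracy; senss[r] <- pm$loci_sensitivity
        pcs[r] <- pm$peaks_correct; ns[r] <- attr(scan, "n_total")
      }
      sweep_row("cohort", 100 * f, mae = NA_real_, n = mean(ns),
                pb = nrow(base_loci), pc = mean(pcs),
                acc = mean(accs), sens = mean(senss))
    }, error = function(e) {
      warning("cohort condition fraction = ", f, " failed: ",
              conditionMessage(e))
      sweep_row("cohort", 100 * f, mae = NA, n = NA, pb = NA, pc = NA,
                acc = NA, sens = NA)
    })
    rows[[length(rows) + 1]] <- res
  }
  finish_sweep(rows, alpha, merge_distance)
}

sweep_row <- function(type, condition, mae, n, pb, pc, acc, sens) {
  data.frame(condition_type = type, condition = condition, mae = mae,
             n_samples = n, peaks_base = pb, peaks_correct = pc,
             snp_accuracy = acc, loci_sensitivity = sens,
             stringsAsFactors = FALSE)
}

finish_sweep <- function(rows, alpha, merge_distance) {
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "params") <- list(alpha = alpha, merge_distance = merge_distance)
  class(out) <- c("sweep_table", "data.frame")
  out
}

#' Fit the MAE versus cohort-size power-equivalence model
#'
#' Ordinary least squares of each power metric on the empirical phenotype
#' MAE (noise sweep) and on the percent of samples retained (cohort
#' sweep). The equivalence ratio per metric is the MAE slope magnitude
#' divided by the cohort slope: the cohort-size reduction (in percent of
#' samples) whose effect on the metric equals a 1-unit (1 percentage
#' point) increase in phenotype MAE.
#'
#' @param noise_table A `sweep_table` from [noise_sweep()].
#' @param cohort_table A `sweep_table` from [cohort_sweep()].
#' @param metrics Metric columns to model.
#' @param include_baseline Include the undegraded/full-cohort rows in the
#'   fits (default `TRUE`).
#' @return An `equivalence_model` with coefficient table `coefficients`
#'   (per metric and predictor: slope, SE, p), `ratios` (per metric), and
#'   the underlying [stats::lm] fits in `fits`.
#' @export
fit_equivalence <- function(noise_table, cohort_table,
                            metrics = c("loci_sensitivity", "snp_accuracy"),
                            include_baseline = TRUE) {
  nt <- noise_table[stats::complete.cases(noise_table[, c("mae", metrics)]), ,
                    drop = FALSE]
  ct <- cohort_table[stats::complete.cases(cohort_table[, c("condition", metrics)]), ,
                     drop = FALSE]
  if (!include_baseline) {
    nt <- nt[nt$condition != 0, , drop = FALSE]
    ct <- ct[ct$condition != 100, , drop = FALSE]
  }
  if (nrow(nt) < 3 || nrow(ct) < 3) stop("need >= 3 usable rows per sweep table")
  if (stats::var(nt$mae) == 0) stop("degenerate predictor: MAE is constant")
  if (stats::var(ct$condition) == 0) stop("degenerate predictor: cohort percent is constant")

  fits <- list()
  coefs <- list()
  ratios <- numeric(0)
  for (mt in metrics) {
    fn <- stats::lm(stats::reformulate("mae", mt), data = nt)
    fc <- stats::lm(stats::reformulate("condition", mt), data = ct)
    sn <- summary(fn)$coefficients
    sc <- summary(fc)$coefficients
    fits[[mt]] <- list(noise = fn, cohort = fc)
    coefs[[mt]] <- data.frame(
      metric = mt,
      predictor = c("mae", "cohort_pct"),
      slope = c(sn["mae", 1], sc["condition", 1]),
      se = c(sn["mae", 2], sc["condition", 2]),
      p = c(sn["mae", 4], sc["condition", 4]),
      stringsAsFactors = FALSE
    )
    ratios[mt] <- if (abs(sc["condition", 1]) < 1e-12) NA_real_ else
      -sn["mae", 1] / sc["condition", 1]
  }
  structure(list(coefficients = do.call(rbind, coefs),
                 ratios = ratios, fits = fits,
                 data = list(noise = nt, cohort = ct)),
            class = "equivalence_model")
}

#' @export
print.equivalence_model <- function(x, digits = 3, ...) {
  cat("Phenotype-precision / cohort-size equivalence model\n")
  cf <- x$coefficients
  for (mt in unique(cf$metric)) {
    a <- cf[cf$metric == mt & cf$predictor == "mae", ]
    b <- cf[cf$metric == mt & cf$predictor == "cohort_pct", ]
    cat(sprintf("  %s: %+.4g per 1%% MAE (p = %.2g); %+.4g per 1%% cohort retained (p = %.2g)\n",
                mt, a$slope, a$p, b$slope, b$p))
    r <- x$ratios[[mt]]
    if (is.finite(r)) {
      cat(sprintf("    -> a 1%% MAE increase is equivalent to a %.3g%% cohort decrease\n", r))
    }
  }
  invisible(x)
}

#' @export
summary.equivalence_model <- function(object, ...) {
  out <- list(coefficients = object$coefficients, ratios = object$ratios,
              n_noise = nrow(object$data$noise),
              n_cohort = nrow(object$data$cohort),
              r_squared = vapply(object$fits, function(f)
                c(noise = summary(f$noise)$r.squared,
                  cohort = summary(f$cohort)$r.squared), numeric(2)))
  class(out) <- "summary.equivalence_model"
  out
}

#' @export
print.summary.equivalence_model <- function(x, ...) {
  cat(sprintf("sweep sizes: %d noise rows, %d cohort rows\n",
              x$n_noise, x$n_cohort))
  print(x$coefficients, row.names = FALSE)
  cat("equivalence ratios (% cohort per 1% MAE):\n")
  print(x$ratios)
  cat("fit R-squared:\n")
  print(x$r_squared)
  invisible(x)
}

#' @export
coef.equivalence_model <- function(object, ...) {
  cf <- object$coefficients
  out <- matrix(cf$slope, ncol = 2, byrow = TRUE,
                dimnames = list(unique(cf$metric), c("mae", "cohort_pct")))
  out
}

#' Predict a power metric from the equivalence model
#'
#' @param object An `equivalence_model`.
#' @param metric Which metric to predict.
#' @param mae Phenotype MAE values (noise model), or `NULL`.
#' @param cohort_pct Percent-retained values (cohort model), or `NULL`.
#' @param ... Unused.
#' @return Numeric vector of predicted metric values (from whichever
#'   predictor was supplied).
#' @export
predict.equivalence_model <- function(object,
                                      metric = "loci_sensitivity",
                                      mae = NULL, cohort_pct = NULL, ...) {
  if (!metric %in% names(object$fits)) stop("unknown metric: ", metric)
  if (!is.null(mae)) {
    return(unname(stats::predict(object$fits[[metric]]$noise,
                                 newdata = data.frame(mae = mae))))
  }
  if (!is.null(cohort_pct)) {
    return(unname(stats::predict(object$fits[[metric]]$cohort,
                                 newdata = data.frame(condition = cohort_pct))))
  }
  stop("supply either mae or cohort_pct")
}
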