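# Small planted-architecture cohort shared across the sweep tests; sized so
# the baseline scan finds every planted locus in seconds.
sweep_cohort <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      g <- simulate_genotypes(1200, 1500, maf_range = c(0.1, 0.5),
                              ld_block_size = 10, ld_rho = 0.8,
                              missing_rate = 0.002, seed = 301)
      sp <- simulate_phenotype(g, causal_spec(n_causal_loci = 3,
                                              heritability_target = 0.25),
                               seed = 302)
      cache <<- list(geno = g, pheno = sp$phenotypes, causal = sp$causal)
    }
    cache
  }
})

test_that("noise sweep has a perfect baseline row and records empirical MAE", {
  co <- sweep_cohort()
  nt <- noise_sweep(co$geno, co$pheno, sigmas = c(2, 30), seed = 5)
  expect_s3_class(nt, "sweep_table")
  expect_equal(nrow(nt), 3)
  base_row <- nt[nt$condition == 0, ]
  expect_equal(base_row$snp_accuracy, 1)
  expect_equal(base_row$loci_sensitivity, 1)
  expect_equal(base_row$mae, 0)
  expect_gt(base_row$peaks_base, 0)
  # empirical MAE tracks sigma * sqrt(2/pi)
  expect_equal(nt$mae[nt$condition == 2], 2 * sqrt(2 / pi), tolerance = 0.1)
  # overwhelming noise destroys the signal
  big <- nt[nt$condition == 30, ]
  expect_lt(big$loci_sensitivity, base_row$loci_sensitivity + 1e-9)
  expect_lt(big$snp_accuracy, 0.2)
})

test_that("noise sweep is deterministic given its seeds", {
  co <- sweep_cohort()
  a <- noise_sweep(co$geno, co$pheno, sigmas = 3, seed = 9)
  b <- noise_sweep(co$geno, co$pheno, sigmas = 3, seed = 9)
  expect_identical(a, b)
})

test_that("cohort sweep compares subsamples against the full-cohort baseline", {
  co <- sweep_cohort()
  ct <- cohort_sweep(co$geno, co$pheno, fractions = c(1, 0.5), seed = 6)
  expect_equal(nrow(ct), 2)
  expect_equal(ct$snp_accuracy[ct$condition == 100], 1)
  expect_equal(ct$loci_sensitivity[ct$condition == 100], 1)
  expect_equal(ct$n_samples[ct$condition == 50], 600)
  expect_lte(ct$snp_accuracy[ct$condition == 50], 1)
  expect_error(cohort_sweep(co$geno, co$pheno, fractions = c(1.5)), "fraction")
})

test_that("fit_equivalence recovers planted slopes exactly on noiseless tables", {
  mae <- c(0, 1, 2, 3, 4)
  nt <- data.frame(condition_type = "noise", condition = c(0, 1:4), mae = mae,
                   n_samples = 1000, peaks_base = 5,
                   peaks_correct = 5 * (1 - 0.13 * mae),
                   snp_accuracy = 1 - 0.14 * mae,
                   loci_sensitivity = 1 - 0.13 * mae)
  pct <- c(100, 90, 80, 70, 60)
  ct <- data.frame(condition_type = "cohort", condition = pct, mae = NA,
                   n_samples = 10 * pct, peaks_base = 5,
                   peaks_correct = 5 * (1 - 0.013 * (100 - pct)),
                   snp_accuracy = 1 - 0.019 * (100 - pct),
                   loci_sensitivity = 1 - 0.013 * (100 - pct))
  em <- suppressWarnings(fit_equivalence(nt, ct))
  cf <- em$coefficients
  expect_equal(cf$slope[cf$metric == "loci_sensitivity" & cf$predictor == "mae"],
               -0.13, tolerance = 1e-12)
  expect_equal(cf$slope[cf$metric == "loci_sensitivity" & cf$predictor == "cohort_pct"],
               0.013, tolerance = 1e-12)
  expect_equal(cf$slope[cf$metric == "snp_accuracy" & cf$predictor == "mae"],
               -0.14, tolerance = 1e-12)
  # 1% MAE is equivalent to a 10% cohort decrease on sensitivity
  expect_equal(unname(em$ratios["loci_sensitivity"]), 10, tolerance = 1e-9)
  expect_equal(unname(em$ratios["snp_accuracy"]), 0.14 / 0.019, tolerance = 1e-9)
})

test_that("degenerate sweep tables are rejected", {
  nt <- data.frame(condition_type = "noise", condition = 0:3, mae = rep(1, 4),
                   n_samples = 100, peaks_base = 2, peaks_correct = 2,
                   snp_accuracy = 1, loci_sensitivity = 1)
  ct <- data.frame(condition_type = "cohort", condition = c(100, 90, 80),
                   mae = NA, n_samples = 100, peaks_base = 2,
                   peaks_correct = 2, snp_accuracy = 1, loci_sensitivity = 1)
  expect_error(fit_equivalence(nt, ct), "MAE is constant")
})

test_that("equivalence model methods expose slopes and predictions", {
  mae <- 0:4
  nt <- data.frame(condition_type = "noise", condition = mae, mae = mae,
                   n_samples = 1000, peaks_base = 5,
                   peaks_correct = 5 * (1 - 0.1 * mae),
                   snp_accuracy = 1 - 0.1 * mae,
                   loci_sensitivity = 1 - 0.1 * mae)
  pct <- seq(100, 60, by = -10)
  ct <- data.frame(condition_type = "cohort", condition = pct, mae = NA,
                   n_samples = 10 * pct, peaks_base = 5,
                   peaks_correct = 5 * (1 - 0.01 * (100 - pct)),
                   snp_accuracy = 1 - 0.01 * (100 - pct),
                   loci_sensitivity = 1 - 0.01 * (100 - pct))
  em <- suppressWarnings(fit_equivalence(nt, ct))
  cm <- coef(em)
  expect_equal(dim(cm), c(2, 2))
  expect_equal(cm["loci_sensitivity", "mae"], -0.1, tolerance = 1e-12)
  expect_equal(predict(em, metric = "loci_sensitivity", mae = 2), 0.8,
               tolerance = 1e-9)
  expect_equal(predict(em, metric = "snp_accuracy", cohort_pct = 80), 0.8,
               tolerance = 1e-9)
  expect_output(print(em), "equivalent to")
})
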