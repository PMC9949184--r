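test_that("simulated dosages match the requested MAF and are symmetric at 0.5", {
  g <- simulate_genotypes(100, 10, maf_range = c(0.5, 0.5), seed = 7)
  # at MAF 0.5 the mean dosage is 1 within binomial sampling error
  mean_dos <- colMeans(g$dosages)
  se <- sqrt(2 * 0.5 * 0.5 / 100)
  expect_true(all(abs(mean_dos - 1) < 4 * se))
  expect_true(all(g$dosages %in% 0:2))
})

test_that("LD blocks reach the target adjacent-dosage correlation", {
  g <- simulate_genotypes(4000, 200, maf_range = c(0.2, 0.5),
                          ld_block_size = 10, ld_rho = 0.9, seed = 21)
  block <- ceiling(seq_len(200) / 10)
  within_cor <- across_cor <- c()
  for (j in 2:200) {
    r <- cor(g$dosages[, j - 1], g$dosages[, j])
    if (block[j] == block[j - 1]) within_cor <- c(within_cor, r)
    else across_cor <- c(across_cor, r)
  }
  expect_equal(mean(within_cor), 0.9, tolerance = 0.03)
  expect_lt(abs(mean(across_cor)), 0.1)
})

test_that("missingness is injected at the requested rate", {
  g <- simulate_genotypes(500, 200, missing_rate = 0.05, seed = 3)
  n_total <- 500 * 200
  n_miss <- sum(is.na(g$dosages))
  sd_binom <- sqrt(n_total * 0.05 * 0.95)
  expect_lt(abs(n_miss - n_total * 0.05), 3 * sd_binom)
})

test_that("genotype simulation is bit-stable under a fixed seed", {
  g1 <- simulate_genotypes(50, 30, ld_block_size = 5, ld_rho = 0.5,
                           missing_rate = 0.02, seed = 99)
  g2 <- simulate_genotypes(50, 30, ld_block_size = 5, ld_rho = 0.5,
                           missing_rate = 0.02, seed = 99)
  expect_identical(g1, g2)
})

test_that("invalid simulation parameters are rejected by name", {
  expect_error(simulate_genotypes(0, 10), "n_samples")
  expect_error(simulate_genotypes(10, 0), "n_variants")
  expect_error(simulate_genotypes(10, 10, maf_range = c(0, 0.5)), "maf_range")
  expect_error(simulate_genotypes(10, 10, maf_range = c(0.1, 0.6)), "maf_range")
  expect_error(simulate_genotypes(10, 10, ld_rho = 1), "ld_rho")
})

test_that("genotype_dataset enforces its invariants", {
  d <- matrix(c(0, 1, 2, 3), 2, 2)
  expect_error(make_geno(d), "\\[0, 2\\]")
  d2 <- matrix(0, 2, 2)
  expect_error(genotype_dataset(d2, data.frame(chrom = "1", pos = 1),
                                c("a", "b")),
               "missing column")
})

test_that("phenotype with zero heritability is independent of genotype", {
  g <- simulate_genotypes(3000, 50, maf_range = c(0.2, 0.5), seed = 5)
  sp <- simulate_phenotype(g, causal_spec(n_causal_loci = 5,
                                          heritability_target = 0),
                           seed = 6)
  res <- run_gwas(g, sp$phenotypes)
  expect_gt(ks.test(res$p, "punif")$p.value, 0.01)
  comp <- attr(sp, "components")
  expect_equal(comp$genetic, rep(0, 3000))
})

test_that("realised variance decomposition matches the heritability target", {
  g <- simulate_genotypes(5000, 100, maf_range = c(0.1, 0.5), seed = 8)
  sp <- simulate_phenotype(g, causal_spec(n_causal_loci = 5,
                                          heritability_target = 0.3),
                           seed = 9)
  comp <- attr(sp, "components")
  share <- var(comp$genetic) / var(sp$phenotypes$value)
  expect_equal(share, 0.3, tolerance = 0.03)
  expect_equal(sd(sp$phenotypes$value), 6.78, tolerance = 0.15)
  expect_equal(mean(sp$phenotypes$value), 55.4, tolerance = 0.3)
})

test_that("a single causal variant with no residual gives a collinear phenotype", {
  g <- simulate_genotypes(200, 10, maf_range = c(0.3, 0.5), seed = 10)
  sp <- simulate_phenotype(g, causal_spec(n_causal_loci = 1,
                                          heritability_target = 1,
                                          covariate_effects = c(age = 0, sex = 0)),
                           seed = 11)
  dos <- g$dosages[, sp$causal$variant_id]
  fit <- summary(lm(sp$phenotypes$value ~ dos))
  expect_equal(fit$r.squared, 1, tolerance = 1e-10)
})

test_that("infeasible heritability is rejected", {
  g <- simulate_genotypes(100, 10, seed = 12)
  expect_error(causal_spec(heritability_target = 1.2), "heritability")
  # covariate variance plus full heritability exceeds the total
  expect_error(
    simulate_phenotype(g, causal_spec(n_causal_loci = 1,
                                      heritability_target = 1,
                                      covariate_effects = c(age = 5, sex = 5)),
                       seed = 1),
    "infeasible"
  )
})

test_that("phenotype simulation is reproducible under a fixed seed", {
  g <- simulate_genotypes(100, 20, seed = 1)
  s1 <- simulate_phenotype(g, causal_spec(), seed = 2)
  s2 <- simulate_phenotype(g, causal_spec(), seed = 2)
  expect_identical(s1$phenotypes, s2$phenotypes)
  expect_identical(s1$causal, s2$causal)
})

test_that("cohort subsampling retains round-half-away counts and stays aligned", {
  g <- simulate_genotypes(10, 5, seed = 2)
  ph <- make_pheno(rnorm(10, 55, 7))
  # 0.25 * 10 = 2.5 -> 3 under round half away from zero
  sub <- subsample_cohort(g, ph, fraction = 0.25, seed = 4)
  expect_equal(sub$n_retained, 3)
  expect_identical(sub$genotypes$sample_ids, sub$phenotypes$sample_id)

  expect_identical(subsample_cohort(g, ph, 1.0, seed = 1)$genotypes, g)
  expect_error(subsample_cohort(g, ph, 0), "fraction")
  expect_error(subsample_cohort(g, ph, 1.5), "fraction")
})

test_that("subsampling is deterministic and monotone in fraction", {
  g <- simulate_genotypes(200, 5, seed = 3)
  s1 <- subsample_cohort(g, NULL, 0.5, seed = 11)
  s2 <- subsample_cohort(g, NULL, 0.5, seed = 11)
  expect_identical(s1$genotypes$sample_ids, s2$genotypes$sample_ids)
  counts <- vapply(seq(0.1, 1, by = 0.1), function(f)
    subsample_cohort(g, NULL, f, seed = 1)$n_retained, numeric(1))
  expect_true(all(diff(counts) >= 0))
})
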