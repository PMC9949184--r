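test_that("scan matches a direct normal-equations solve on a worked fixture", {
  # 8-sample fixture with printed dosages, phenotype and covariates
  dos <- c(0, 1, 2, 1, 0, 2, 1, 0)
  age <- c(45, 52, 61, 48, 57, 63, 50, 55)
  sex <- c("male", "female", "male", "male", "female", "female", "male", "female")
  y <- c(54.2, 57.1, 49.8, 56.0, 58.3, 47.9, 55.5, 59.0)
  g <- make_geno(matrix(dos, 8, 1))
  ph <- make_pheno(y, sex = sex, age = age)

  res <- run_gwas(g, ph)
  X <- cbind(1, age, ifelse(sex == "male", 1, 0), dos)
  oracle <- ols_oracle(X, y)
  expect_equal(res$beta, oracle$beta, tolerance = 1e-10)
  expect_equal(res$se, oracle$se, tolerance = 1e-10)
  expect_equal(res$t, oracle$t, tolerance = 1e-10)
  expect_equal(res$p, oracle$p, tolerance = 1e-10)
  expect_equal(res$n_used, 8L)
})

test_that("vectorised residualisation equals per-variant OLS across a panel", {
  set.seed(77)
  cohort <- make_cohort(n = 300, m = 40, n_causal = 2, h2 = 0.2)
  res <- run_gwas(cohort$geno, cohort$pheno)
  age <- cohort$pheno$age
  sexn <- ifelse(cohort$pheno$sex == "male", 1, 0)
  for (j in sample(40, 10)) {
    X <- cbind(1, age, sexn, cohort$geno$dosages[, j])
    oracle <- ols_oracle(X, cohort$pheno$value)
    expect_equal(res$beta[j], oracle$beta, tolerance = 1e-10)
    expect_equal(res$se[j], oracle$se, tolerance = 1e-10)
    expect_equal(res$p[j], oracle$p, tolerance = 1e-10)
  }
})

test_that("missing dosages use per-variant complete-case analysis", {
  set.seed(78)
  n <- 200
  dos <- rbinom(n, 2, 0.4)
  dos[sample(n, 15)] <- NA
  y <- 55 + 0.8 * ifelse(is.na(dos), 0, dos) + rnorm(n, 0, 3)
  g <- make_geno(matrix(as.numeric(dos), n, 1))
  ph <- make_pheno(y)
  res <- run_gwas(g, ph)
  expect_equal(res$n_used, n - 15L)
  obs <- !is.na(dos)
  X <- cbind(1, ph$age[obs], ifelse(ph$sex[obs] == "male", 1, 0), dos[obs])
  oracle <- ols_oracle(X, y[obs])
  expect_equal(res$beta, oracle$beta, tolerance = 1e-10)
  expect_equal(res$p, oracle$p, tolerance = 1e-10)
})

test_that("monomorphic variants are flagged, not silently dropped", {
  d <- cbind(rep(1, 50), rbinom(50, 2, 0.5))
  g <- make_geno(d)
  ph <- make_pheno(rnorm(50, 55, 5))
  res <- run_gwas(g, ph)
  expect_equal(nrow(res), 2)
  expect_true(res$degenerate[1])
  expect_true(is.na(res$beta[1]))
  expect_false(res$variant_id[1] %in% significant_snps(res, alpha = 0.99))
})

test_that("p-values are invariant to affine rescaling of phenotype and covariates", {
  cohort <- make_cohort(n = 150, m = 20, n_causal = 1, h2 = 0.2, seed = 55)
  res1 <- run_gwas(cohort$geno, cohort$pheno)
  ph2 <- cohort$pheno
  ph2$value <- 3.7 * ph2$value - 12
  ph2$age <- ph2$age / 10 + 5
  res2 <- run_gwas(cohort$geno, ph2)
  expect_equal(res1$p, res2$p, tolerance = 1e-9)
  expect_equal(res2$beta, 3.7 * res1$beta, tolerance = 1e-9)
})

test_that("rank-deficient covariates are rejected with the collinear column named", {
  g <- make_geno(matrix(rbinom(40, 2, 0.5), 20, 2))
  ph <- make_pheno(rnorm(20, 55, 5))
  ph$age2 <- ph$age * 2
  expect_error(run_gwas(g, ph, covariates = c("age", "age2")), "age2")
  expect_error(run_gwas(g, ph, phenotype_column = "nope"), "nope")
})

test_that("binary traits run through the linear engine and optionally logistic", {
  set.seed(91)
  cohort <- make_cohort(n = 400, m = 10, n_causal = 1, h2 = 0.4)
  ph <- binarize_normal_abnormal(cohort$pheno)
  lin <- run_gwas(cohort$geno, ph, phenotype_column = "abnormal")
  expect_true(all(lin$p > 0 & lin$p <= 1, na.rm = TRUE))
  logi <- run_gwas(cohort$geno, ph, phenotype_column = "abnormal",
                   engine = "logistic")
  # effect directions agree between engines for the strongest signal
  top <- which.min(lin$log10_p)
  expect_equal(sign(lin$beta[top]), sign(logi$beta[top]))
})

test_that("significant_snps uses a strict threshold", {
  res <- make_result("1", c(1e6, 2e6, 3e6), c(0.5, 5e-8, 4.9e-8))
  expect_equal(significant_snps(res), res$variant_id[3])
  res2 <- make_result("1", c(1e6, 2e6), c(0.5, 0.5))
  expect_length(significant_snps(res2), 0)
})

test_that("qq_data returns calibrated diagnostics", {
  # a perfectly uniform p grid sits on the diagonal with lambda 1
  p <- (1:1000 - 0.5) / 1000
  res <- make_result("1", seq_len(1000) * 1000, p)
  qq <- qq_data(res)
  expect_equal(qq$lambda, 1, tolerance = 0.01)
  expect_equal(qq$table$observed, qq$table$expected, tolerance = 0.01)
  # halving the p-values shifts the observed curve above the diagonal
  res2 <- make_result("1", seq_len(1000) * 1000, p / 2)
  qq2 <- qq_data(res2)
  expect_true(all(qq2$table$observed >= qq$table$observed))
  expect_gt(qq2$lambda, 1)
})
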