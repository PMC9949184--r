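# Independent oracles and small fixture builders used across the suite.

# Exact HWE probability of every heterozygote configuration via the
# closed-form multinomial expression (lfactorial), independent of the
# package's recurrence-based implementation.
hwe_oracle <- function(n_hom_ref, n_het, n_hom_alt) {
  n <- n_hom_ref + n_het + n_hom_alt
  nA <- 2 * n_hom_ref + n_het
  nB <- 2 * n_hom_alt + n_het
  rare <- min(nA, nB)
  if (rare == 0) return(1)
  hs <- seq(rare %% 2, rare, by = 2)
  logp <- vapply(hs, function(h) {
    hr <- (rare - h) / 2
    hc <- (max(nA, nB) - h) / 2
    lfactorial(n) - lfactorial(hr) - lfactorial(h) - lfactorial(hc) +
      h * log(2) + lfactorial(nA) + lfactorial(nB) - lfactorial(2 * n)
  }, numeric(1))
  p_obs <- logp[hs == n_het]
  min(sum(exp(logp[logp <= p_obs + 1e-10])), 1)
}

# Full OLS solve via the normal equations; returns stats for the last column.
ols_oracle <- function(X, y) {
  XtX <- crossprod(X)
  b <- solve(XtX, crossprod(X, y))
  r <- y - X %*% b
  df <- nrow(X) - ncol(X)
  s2 <- sum(r^2) / df
  se <- sqrt(s2 * diag(solve(XtX)))
  tv <- b / se
  p <- 2 * pt(abs(tv), df, lower.tail = FALSE)
  j <- ncol(X)
  list(beta = unname(b[j]), se = unname(se[j]),
       t = unname(tv[j]), p = unname(p[j]))
}

# Connected components of 1-D positions with edges at distance <= cutoff.
cc_oracle <- function(pos, cutoff) {
  n <- length(pos)
  if (n == 0) return(integer(0))
  adj <- abs(outer(pos, pos, "-")) <= cutoff
  comp <- rep(NA_integer_, n)
  next_id <- 0L
  for (i in seq_len(n)) {
    if (!is.na(comp[i])) next
    next_id <- next_id + 1L
    frontier <- i
    comp[i] <- next_id
    while (length(frontier) > 0) {
      nb <- which(adj[frontier[1], ] & is.na(comp))
      comp[nb] <- next_id
      frontier <- c(frontier[-1], nb)
    }
  }
  comp
}

# Wrap a bare dosage matrix (samples x variants) as a genotype_dataset.
make_geno <- function(dosages, chrom = NULL, pos = NULL,
                      info_score = NULL, is_imputed = NULL) {
  m <- ncol(dosages)
  if (is.null(chrom)) chrom <- rep("1", m)
  if (is.null(pos)) pos <- seq_len(m) * 1000L
  if (is.null(info_score)) info_score <- rep(1, m)
  if (is.null(is_imputed)) is_imputed <- rep(FALSE, m)
  variants <- data.frame(
    chrom = chrom, pos = pos, ref = "A", alt = "G",
    variant_id = paste(chrom, pos, "A", "G", sep = ":"),
    info_score = info_score, is_imputed = is_imputed,
    stringsAsFactors = FALSE
  )
  genotype_dataset(dosages, variants, paste0("S", seq_len(nrow(dosages))))
}

# Minimal phenotype table with deterministic covariates.
make_pheno <- function(values, sex = NULL, age = NULL) {
  n <- length(values)
  if (is.null(sex)) sex <- rep(c("male", "female"), length.out = n)
  if (is.null(age)) age <- seq(40, 70, length.out = n)
  data.frame(sample_id = paste0("S", seq_len(n)), value = values,
             age = age, sex = sex, stringsAsFactors = FALSE)
}

# Build an assoc_result-shaped frame directly from p-values (for locus and
# metric tests that do not need a real scan).
make_result <- function(chrom, pos, p) {
  pos <- as.integer(pos)
  res <- data.frame(
    variant_id = paste(chrom, pos, "A", "G", sep = ":"),
    chrom = as.character(chrom), pos = pos, ref = "A", alt = "G",
    beta = 1, se = 1, t = 1, p = p, log10_p = log10(p),
    n_used = 100L, maf = 0.2, degenerate = FALSE,
    stringsAsFactors = FALSE
  )
  class(res) <- c("assoc_result", "data.frame")
  res
}

# A small cohort with planted causal loci, shared by association and
# experiment tests.
make_cohort <- function(n = 800, m = 400, n_causal = 3, h2 = 0.3,
                        seed = 42, ...) {
  g <- simulate_genotypes(n, m, maf_range = c(0.1, 0.5),
                          ld_block_size = 5, ld_rho = 0.8, seed = seed, ...)
  sp <- simulate_phenotype(g, causal_spec(n_causal_loci = n_causal,
                                          heritability_target = h2),
                           seed = seed + 1)
  list(geno = g, pheno = sp$phenotypes, causal = sp$causal,
       components = attr(sp, "components"))
}
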