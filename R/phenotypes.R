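#' Specify the causal architecture of a simulated quantitative trait
#'
#' Defaults emulate a left-ventricular-ejection-fraction-like phenotype:
#' mean 55.4%, SD 6.78%, measured in a middle-aged cohort (age ~ N(54.9,
#' 7.47^2) years, 47.8% male) with small negative age and male effects.
#'
#' @param n_causal_loci Number of causal variants, placed in well-separated
#'   strata of the variant panel so each seeds its own locus.
#' @param heritability_target Fraction of phenotype variance explained by
#'   the causal variants jointly, in `[0, 1]`.
#' @param effect_weights Optional numeric vector of relative per-variant
#'   effect weights (length `n_causal_loci`); rescaled jointly so the
#'   genetic variance hits `heritability_target`. Default: equal weights
#'   with random signs.
#' @param covariate_effects Named numeric vector `c(age = ..., sex = ...)`
#'   of additive effects, in phenotype units per year and per male sex.
#' @param phenotype_mean,phenotype_sd Target trait mean and SD (percent).
#' @param age_mean,age_sd Age distribution (years).
#' @param male_fraction Probability a simulated sample is male.
#' @return An object of class `causal_spec`.
#' @export
causal_spec <- function(n_causal_loci = 5,
                        heritability_target = 0.05,
                        effect_weights = NULL,
                        covariate_effects = c(age = -0.05, sex = -2),
                        phenotype_mean = 55.4, phenotype_sd = 6.78,
                        age_mean = 54.9, age_sd = 7.47,
                        male_fraction = 0.478) {
  if (heritability_target < 0 || heritability_target > 1) {
    stop("heritability_target must lie in [0, 1]")
  }
  if (!is.null(effect_weights)) {
    if (length(effect_weights) != n_causal_loci) {
      stop("effect_weights must have length n_causal_loci")
    }
    if (any(!is.finite(effect_weights))) stop("effect_weights must be finite")
  }
  if (!all(c("age", "sex") %in% names(covariate_effects))) {
    stop("covariate_effects must name both 'age' and 'sex'")
  }
  structure(
    list(n_causal_loci = as.integer(n_causal_loci),
         heritability_target = heritability_target,
         effect_weights = effect_weights,
         covariate_effects = covariate_effects,
         phenotype_mean = phenotype_mean, phenotype_sd = phenotype_sd,
         age_mean = age_mean, age_sd = age_sd,
         male_fraction = male_fraction),
    class = "causal_spec"
  )
}

#' Simulate a quantitative phenotype with known causal variants
#'
#' Builds the phenotype as mean + genetic component + age/sex component +
#' Gaussian residual. Each component is empirically rescaled (and the
#' residual orthogonalised against the others) so that the realised variance
#' decomposition matches the targets: genetic share =
#' `heritability_target`, total SD = `phenotype_sd`.
#'
#' Causal variants are sampled one per equal-width stratum of the variant
#' panel, so with a blocked LD layout each causal variant founds a distinct,
#' well-separated locus. Missing dosages are mean-imputed when forming the
#' genetic component (ground truth only; association scans see the missing
#' values).
#'
#' @param geno A [genotype_dataset()].
#' @param spec A [causal_spec()].
#' @param seed Integer seed; bit-reproducible given it.
#' @return List with `phenotypes` (data frame: `sample_id`, `value`, `age`,
#'   `sex`) and `causal` (data frame: `variant_id`, `beta` in phenotype
#'   units per alt allele). The realised components are attached as
#'   attribute `"components"` for variance-decomposition checks.
#' @export
simulate_phenotype <- function(geno, spec = causal_spec(), seed = NULL) {
  n <- length(geno$sample_ids)
  m <- nrow(geno$variants)
  k <- spec$n_causal_loci
  if (k > m) stop("requested ", k, " causal variants but panel has only ", m)
  var_total <- spec$phenotype_sd^2

  with_seed(seed, {
    # one causal variant per stratum, drawn from the middle half of the
    # stratum so consecutive causal variants are at least half a stratum
    # apart and found distinct loci
    causal_idx <- integer(0)
    if (k > 0) {
      bounds <- floor(seq(0, m, length.out = k + 1))
      causal_idx <- vapply(seq_len(k), function(j) {
        lo <- bounds[j] + 1L; hi <- bounds[j + 1]
        pad <- (hi - lo + 1L) %/% 4L
        lo <- lo + pad; hi <- hi - pad
        if (hi > lo) sample(lo:hi, 1L) else lo
      }, integer(1))
    }

    weights <- spec$effect_weights
    if (is.null(weights) && k > 0) {
      weights <- sample(c(-1, 1), k, replace = TRUE)
    }

    g <- numeric(n)
    beta <- numeric(0)
    if (k > 0 && spec$heritability_target > 0) {
      D <- geno$dosages[, causal_idx, drop = FALSE]
      for (j in seq_len(ncol(D))) {   # mean-impute missing for ground truth
        miss <- is.na(D[, j])
        if (any(miss)) D[miss, j] <- mean(D[, j], na.rm = TRUE)
      }
      g0 <- drop(D %*% weights)
      v0 <- stats::var(g0)
      if (v0 <= 0) stop("causal variants are monomorphic; cannot reach heritability target")
      scale_g <- sqrt(spec$heritability_target * var_total / v0)
      g <- (g0 - mean(g0)) * scale_g
      beta <- weights * scale_g
    }

    age <- stats::rnorm(n, spec$age_mean, spec$age_sd)
    sex_male <- stats::rbinom(n, 1L, spec$male_fraction)
    cov_comp <- spec$covariate_effects[["age"]] * (age - mean(age)) +
      spec$covariate_effects[["sex"]] * (sex_male - mean(sex_male))

    var_resid <- var_total - stats::var(g) - stats::var(cov_comp)
    if (var_resid < -1e-8) {
      stop("infeasible heritability: genetic + covariate variance (",
           signif(stats::var(g) + stats::var(cov_comp), 4),
           ") exceeds total phenotype variance (", signif(var_total, 4), ")")
    }
    var_resid <- max(var_resid, 0)
    e <- numeric(n)
    if (var_resid > 0) {
      e0 <- stats::rnorm(n)
      # orthogonalise against realised components so shares are exact
      X <- cbind(1, g, cov_comp)
      X <- X[, c(TRUE, stats::var(g) > 0, stats::var(cov_comp) > 0), drop = FALSE]
      e1 <- stats::lm.fit(X, e0)$residuals
      e <- e1 * sqrt(var_resid / stats::var(e1))
    }
    value <- spec$phenotype_mean + g + cov_comp + e

    pheno <- data.frame(
      sample_id = geno$sample_ids,
      value = value,
      age = age,
      sex = ifelse(sex_male == 1L, "male", "female"),
      stringsAsFactors = FALSE
    )
    causal <- data.frame(
      variant_id = geno$variants$variant_id[causal_idx],
      beta = if (length(beta)) beta else numeric(length(causal_idx)),
      stringsAsFactors = FALSE
    )
    out <- list(phenotypes = pheno, causal = causal)
    attr(out, "components") <- list(genetic = g, covariate = cov_comp,
                                    residual = e)
    out
  })
}

# Validate a phenotype table's required columns and ID uniqueness.
validate_phenotypes <- function(pheno,
                                required = c("sample_id", "value", "age", "sex")) {
  missing_cols <- setdiff(required, names(pheno))
  if (length(missing_cols) > 0) {
    stop("phenotype table is missing column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  dup <- unique(pheno$sample_id[duplicated(pheno$sample_id)])
  if (length(dup) > 0) {
    stop("duplicated sample_id in phenotype table: ",
         paste(utils::head(dup, 5), collapse = ", "))
  }
  invisible(pheno)
}
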