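#' Covariate-adjusted per-variant association scan
#'
#' For each variant, fits phenotype ~ intercept + covariates + dosage by
#' ordinary least squares and reports the dosage effect, its standard
#' error, t statistic and two-sided p-value (t distribution, `n_used - k`
#' degrees of freedom). Binary traits coded 0/1 go through the same linear
#' engine by default, mirroring biobank-scale practice; `engine =
#' "logistic"` fits per-variant logistic regressions instead.
#'
#' The linear engine residualises the phenotype and the dosages against the
#' covariate design once and then runs per-variant simple regressions on
#' the residuals, which is algebraically identical to the full OLS fit but
#' O(n * m). Variants with missing dosages fall back to a per-variant
#' complete-case fit; variants with zero dosage variance are emitted with
#' `NA` effect estimates and flagged `degenerate` rather than dropped.
#' p-values are computed in log space, so scans with association signals
#' far beyond double-precision underflow still order correctly via the
#' `log10_p` column.
#'
#' @param geno A [genotype_dataset()] (after QC).
#' @param pheno Phenotype data frame with `sample_id`, the phenotype column
#'   and the covariate columns. `sex` is recoded male = 1, female = 0.
#' @param phenotype_column Name of the (numeric or 0/1) phenotype column.
#' @param covariates Character vector of covariate column names.
#' @param engine `"linear"` (default) or `"logistic"`.
#' @param chunk_size Number of variants per residualisation block.
#' @return An `assoc_result`: a data frame with one row per variant
#'   (`variant_id`, `chrom`, `pos`, `ref`, `alt`, `beta`, `se`, `t`, `p`,
#'   `log10_p`, `n_used`, `maf`, `degenerate`) and metadata attributes
#'   `phenotype_column`, `covariates`, `n_total`.
#' @export
run_gwas <- function(geno, pheno, phenotype_column = "value",
                     covariates = c("age", "sex"),
                     engine = c("linear", "logistic"),
                     chunk_size = 2000) {
  engine <- match.arg(engine)
  if (!phenotype_column %in% names(pheno)) {
    stop("phenotype column '", phenotype_column, "' not found")
  }
  missing_cov <- setdiff(covariates, names(pheno))
  if (length(missing_cov) > 0) {
    stop("covariate column(s) not found: ", paste(missing_cov, collapse = ", "))
  }
  validate_phenotypes(pheno, required = c("sample_id", phenotype_column, covariates))

  idx <- match(geno$sample_ids, pheno$sample_id)
  in_both <- !is.na(idx)
  ph <- pheno[idx[in_both], , drop = FALSE]
  dos <- if (all(in_both)) geno$dosages else
    geno$dosages[in_both, , drop = FALSE]

  y <- as.numeric(ph[[phenotype_column]])
  X <- matrix(1, nrow(ph), 1, dimnames = list(NULL, "(Intercept)"))
  for (cv in covariates) {
    col <- ph[[cv]]
    if (cv == "sex" || is.character(col) || is.factor(col)) {
      col <- as.character(col)
      col <- ifelse(col == "male", 1, ifelse(col == "female", 0, NA_real_))
    }
    X <- cbind(X, as.numeric(col))
    colnames(X)[ncol(X)] <- cv
  }

  complete <- !is.na(y) & rowSums(is.na(X)) == 0
  y <- y[complete]; X <- X[complete, , drop = FALSE]
  if (!all(complete)) dos <- dos[complete, , drop = FALSE]
  n <- length(y)
  k <- ncol(X) + 1L  # parameters incl. dosage
  if (n <= k) stop("too few complete samples (", n, ") for ", k, " parameters")

  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    bad <- colnames(X)[qrX$pivot[(qrX$rank + 1):ncol(X)]]
    stop("covariate design is rank deficient; collinear column(s): ",
         paste(bad, collapse = ", "))
  }

  m <- ncol(dos)
  beta <- se <- tval <- log10p <- rep(NA_real_, m)
  n_used <- rep(n, m)

  ry <- qr.resid(qrX, y)
  ryy <- sum(ry^2)
  has_na <- logical(m)
  for (start in seq(1, m, by = chunk_size)) {   # chunked NA scan
    cols <- start:min(start + chunk_size - 1, m)
    has_na[cols] <- colSums(is.na(dos[, cols, drop = FALSE])) > 0
  }

  # vectorised path: complete dosage columns, chunked residualisation
  full_cols <- which(!has_na)
  for (start in if (length(full_cols)) seq(1, length(full_cols), by = chunk_size)
       else integer(0)) {
    cols <- full_cols[start:min(start + chunk_size - 1, length(full_cols))]
    G <- dos[, cols, drop = FALSE]
    storage.mode(G) <- "double"
    RG <- qr.resid(qrX, G)
    ss <- colSums(RG^2)
    ok <- ss > n * 1e-12
    b <- ifelse(ok, colSums(RG * ry) / ss, NA_real_)
    rss <- pmax(ryy - b^2 * ss, 0)
    df <- n - k
    s2 <- rss / df
    s <- sqrt(s2 / ss)
    tv <- b / s
    beta[cols] <- ifelse(ok, b, NA_real_)
    se[cols] <- ifelse(ok, s, NA_real_)
    tval[cols] <- ifelse(ok, tv, NA_real_)
    lp <- (stats::pt(abs(tv), df, lower.tail = FALSE, log.p = TRUE) + log(2)) / log(10)
    log10p[cols] <- ifelse(ok, lp, NA_real_)
  }

  if (engine == "linear") {
    for (j in which(has_na)) {
      obs <- !is.na(dos[, j])
      nj <- sum(obs)
      n_used[j] <- nj
      if (nj <= k) next
      fit <- ols_last_column(cbind(X[obs, , drop = FALSE], dos[obs, j]), y[obs])
      if (is.null(fit)) next
      beta[j] <- fit$beta; se[j] <- fit$se; tval[j] <- fit$t
      log10p[j] <- fit$log10p
    }
  } else {
    for (j in seq_len(m)) {
      obs <- !is.na(dos[, j])
      nj <- sum(obs)
      n_used[j] <- nj
      g <- dos[obs, j]
      if (nj <= k || stats::var(g) < 1e-12) {
        beta[j] <- se[j] <- tval[j] <- log10p[j] <- NA_real_
        next
      }
      fit <- stats::glm.fit(cbind(X[obs, , drop = FALSE], g), y[obs],
                            family = stats::binomial())
      cf <- summary_glm_last(fit)
      beta[j] <- cf$beta; se[j] <- cf$se; tval[j] <- cf$t; log10p[j] <- cf$log10p
    }
  }

  p <- 10^log10p
  p[!is.na(p) & p == 0] <- .Machine$double.xmin
  maf <- variant_maf(dos)

  res <- data.frame(
    variant_id = geno$variants$variant_id,
    chrom = geno$variants$chrom,
    pos = geno$variants$pos,
    ref = geno$variants$ref,
    alt = geno$variants$alt,
    beta = beta, se = se, t = tval, p = p, log10_p = log10p,
    n_used = n_used, maf = maf,
    degenerate = is.na(beta),
    stringsAsFactors = FALSE
  )
  rownames(res) <- NULL
  attr(res, "phenotype_column") <- phenotype_column
  attr(res, "covariates") <- covariates
  attr(res, "n_total") <- n
  attr(res, "engine") <- engine
  class(res) <- c("assoc_result", "data.frame")
  res
}

# OLS via QR on a design whose last column is the variant dosage.
ols_last_column <- function(Xg, y) {
  qx <- qr(Xg)
  if (qx$rank < ncol(Xg)) return(NULL)
  cf <- qr.coef(qx, y)
  r <- y - Xg %*% cf
  df <- nrow(Xg) - ncol(Xg)
  s2 <- sum(r^2) / df
  covm <- chol2inv(qr.R(qx))
  unpiv <- integer(ncol(Xg)); unpiv[qx$pivot] <- seq_len(ncol(Xg))
  XtXinv_last <- covm[unpiv[ncol(Xg)], unpiv[ncol(Xg)]]
  se <- sqrt(s2 * XtXinv_last)
  tv <- cf[length(cf)] / se
  lp <- (stats::pt(abs(tv), df, lower.tail = FALSE, log.p = TRUE) + log(2)) / log(10)
  list(beta = unname(cf[length(cf)]), se = se, t = unname(tv), log10p = unname(lp))
}

summary_glm_last <- function(fit) {
  p <- fit$rank
  covm <- chol2inv(fit$qr$qr[1:p, 1:p, drop = FALSE])
  j <- length(fit$coefficients)
  pj <- which(fit$qr$pivot[1:p] == j)
  if (length(pj) != 1) return(list(beta = NA_real_, se = NA_real_,
                                   t = NA_real_, log10p = NA_real_))
  b <- fit$coefficients[j]
  se <- sqrt(covm[pj, pj])
  z <- b / se
  lp <- (stats::pnorm(abs(z), lower.tail = FALSE, log.p = TRUE) + log(2)) / log(10)
  list(beta = unname(b), se = se, t = unname(z), log10p = unname(lp))
}

#' @export
print.assoc_result <- function(x, ...) {
  cat("assoc_result:", nrow(x), "variants, phenotype '",
      attr(x, "phenotype_column"), "' adjusted for ",
      paste(attr(x, "covariates"), collapse = " + "),
      " (n = ", attr(x, "n_total"), ")\n", sep = "")
  top <- x[order(x$log10_p), , drop = FALSE]
  print.data.frame(utils::head(top[, c("variant_id", "beta", "se", "p", "n_used", "maf")], 5))
  invisible(x)
}

#' @export
summary.assoc_result <- function(object, alpha = 5e-8, ...) {
  sig <- significant_snps(object, alpha)
  qq <- qq_data(object)
  out <- list(n_variants = nrow(object),
              n_degenerate = sum(object$degenerate),
              n_significant = length(sig),
              alpha = alpha,
              lambda = qq$lambda)
  class(out) <- "summary.assoc_result"
  out
}

#' @export
print.summary.assoc_result <- function(x, ...) {
  cat(sprintf("variants: %d (%d degenerate)\n", x$n_variants, x$n_degenerate))
  cat(sprintf("genome-wide significant (p < %g): %d\n", x$alpha, x$n_significant))
  cat(sprintf("genomic inflation lambda: %.3f\n", x$lambda))
  invisible(x)
}

#' Genome-wide-significant variant set
#'
#' @param res An `assoc_result` from [run_gwas()].
#' @param alpha Significance threshold; variants with `p < alpha`
#'   (strictly) are returned. Default 5e-8.
#' @return Character vector of significant `variant_id`s (degenerate
#'   variants never qualify).
#' @export
significant_snps <- function(res, alpha = 5e-8) {
  if (alpha <= 0 || alpha >= 1) stop("alpha must lie in (0, 1)")
  ok <- !is.na(res$log10_p) & res$log10_p < log10(alpha)
  res$variant_id[ok]
}

#' Quantile-quantile data and genomic inflation factor
#'
#' @param res An `assoc_result`.
#' @return List with `table` (columns `expected`, `observed`, both
#'   -log10 p, sorted ascending) and `lambda`, the median chi-square(1)
#'   quantile of the observed p-values divided by its null expectation
#'   (0.4549...).
#' @export
qq_data <- function(res) {
  lp <- res$log10_p[!is.na(res$log10_p)]
  m <- length(lp)
  if (m < 2) stop("need at least 2 valid p-values")
  obs <- sort(-lp)                       # -log10 p, ascending
  exp <- sort(-log10(stats::ppoints(m)))
  chisq <- stats::qchisq(lp * log(10), df = 1,
                         lower.tail = FALSE, log.p = TRUE)
  lambda <- stats::median(chisq) / stats::qchisq(0.5, df = 1)
  list(table = data.frame(expected = exp, observed = obs), lambda = lambda)
}
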