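#' Construct a genotype dataset
#'
#' The package's central genotype container: an `n_samples x n_variants`
#' matrix of alt-allele dosages in `[0, 2]` (`NA` = missing call) plus
#' per-variant metadata.
#'
#' @param dosages Numeric matrix, one row per sample, one column per variant.
#'   Non-missing entries must lie in `[0, 2]`.
#' @param variants Data frame with columns `chrom`, `pos`, `ref`, `alt`,
#'   `variant_id`, `info_score`, `is_imputed`, one row per variant.
#'   `variant_id` follows the canonical `"chrom:pos:ref:alt"` form.
#' @param sample_ids Character vector of unique sample identifiers, one per
#'   dosage row.
#' @return An object of class `genotype_dataset`.
#' @export
genotype_dataset <- function(dosages, variants, sample_ids) {
  dosages <- as.matrix(dosages)
  sample_ids <- as.character(sample_ids)
  required <- c("chrom", "pos", "ref", "alt", "variant_id", "info_score", "is_imputed")
  missing_cols <- setdiff(required, names(variants))
  if (length(missing_cols) > 0) {
    stop("variants is missing column(s): ", paste(missing_cols, collapse = ", "))
  }
  if (nrow(dosages) != length(sample_ids)) {
    stop("dosages has ", nrow(dosages), " rows but sample_ids has ",
         length(sample_ids), " entries")
  }
  if (ncol(dosages) != nrow(variants)) {
    stop("dosages has ", ncol(dosages), " columns but variants has ",
         nrow(variants), " rows")
  }
  if (anyDuplicated(sample_ids)) {
    stop("duplicated sample_ids: ",
         paste(unique(sample_ids[duplicated(sample_ids)]), collapse = ", "))
  }
  if (anyDuplicated(variants$variant_id)) {
    stop("duplicated variant_id values")
  }
  rng <- range(dosages, na.rm = TRUE)
  if (!all(is.na(dosages)) && (rng[1] < 0 || rng[2] > 2)) {
    stop("non-missing dosages must lie in [0, 2]; observed range [",
         rng[1], ", ", rng[2], "]")
  }
  if (any(variants$pos < 1)) stop("variant positions must be >= 1")
  if (any(variants$info_score < 0 | variants$info_score > 1, na.rm = TRUE)) {
    stop("info_score must lie in [0, 1]")
  }
  for (ch in unique(variants$chrom)) {
    p <- variants$pos[variants$chrom == ch]
    if (is.unsorted(p)) {
      stop("positions within chromosome ", ch, " are not non-decreasing")
    }
  }
  rownames(dosages) <- sample_ids
  colnames(dosages) <- variants$variant_id
  structure(
    list(dosages = dosages,
         variants = as.data.frame(variants, stringsAsFactors = FALSE),
         sample_ids = sample_ids),
    class = "genotype_dataset"
  )
}

#' @export
print.genotype_dataset <- function(x, ...) {
  cat("genotype_dataset:", length(x$sample_ids), "samples x",
      nrow(x$variants), "variants\n")
  cat("  chromosomes:", paste(unique(x$variants$chrom), collapse = ", "), "\n")
  miss <- mean(is.na(x$dosages))
  cat(sprintf("  missing dosage fraction: %.4f\n", miss))
  cat(sprintf("  imputed variants: %d\n", sum(x$variants$is_imputed)))
  invisible(x)
}

#' @export
dim.genotype_dataset <- function(x) {
  c(length(x$sample_ids), nrow(x$variants))
}

# Subset a genotype dataset by sample index or by variant index.
subset_genotypes <- function(geno, samples = NULL, variants = NULL) {
  d <- geno$dosages
  v <- geno$variants
  ids <- geno$sample_ids
  if (!is.null(samples) && length(samples) == length(ids) &&
      all(samples == seq_along(ids))) samples <- NULL
  if (!is.null(variants) && length(variants) == nrow(v) &&
      all(variants == seq_len(nrow(v)))) variants <- NULL
  if (is.null(samples) && is.null(variants)) return(geno)
  if (!is.null(samples)) {
    d <- d[samples, , drop = FALSE]
    ids <- ids[samples]
  }
  if (!is.null(variants)) {
    d <- d[, variants, drop = FALSE]
    v <- v[variants, , drop = FALSE]
    rownames(v) <- NULL
  }
  genotype_dataset(d, v, ids)
}

#' Simulate a genotype panel with a realistic MAF spectrum and block LD
#'
#' Diploid dosages are built from two haplotypes per sample. Within an LD
#' block, haplotypes follow a first-order copying process: the allele at a
#' variant copies the allele at the previous variant with probability
#' `ld_rho`, and is otherwise a fresh Bernoulli draw at the block's allele
#' frequency. All variants in one block share a single allele frequency
#' (drawn uniformly from `maf_range`), which makes the adjacent-variant
#' dosage correlation equal `ld_rho` exactly in expectation while keeping
#' per-variant frequencies on target. Blocks are independent, so correlation
#' across block boundaries is ~0.
#'
#' Variants are laid out on `n_chrom` chromosomes in contiguous runs of
#' blocks, `spacing_bp` base pairs apart.
#'
#' @param n_samples,n_variants Panel dimensions (both >= 1).
#' @param maf_range Length-2 interval within `(0, 0.5]` from which block
#'   minor-allele frequencies are drawn.
#' @param ld_block_size Number of consecutive variants per LD block
#'   (1 = no LD).
#' @param ld_rho Target adjacent-variant dosage correlation within a block,
#'   in `[0, 1)`.
#' @param missing_rate Fraction of dosage entries set missing at random.
#' @param imputed_fraction Fraction of variants flagged imputed; imputed
#'   variants get an INFO score drawn from Beta(10, 0.5), genotyped variants
#'   get 1.
#' @param n_chrom Number of chromosomes to spread blocks across.
#' @param spacing_bp Base-pair spacing between adjacent variants.
#' @param seed Integer seed; the simulation is bit-reproducible given it.
#' @return A [genotype_dataset()].
#' @examples
#' g <- simulate_genotypes(100, 50, maf_range = c(0.1, 0.5), seed = 1)
#' dim(g)
#' @export
simulate_genotypes <- function(n_samples, n_variants,
                               maf_range = c(0.05, 0.5),
                               ld_block_size = 1, ld_rho = 0,
                               missing_rate = 0,
                               imputed_fraction = 0.9,
                               n_chrom = 22, spacing_bp = 5000,
                               seed = NULL) {
  if (length(n_samples) != 1 || n_samples < 1) stop("n_samples must be a positive count")
  if (length(n_variants) != 1 || n_variants < 1) stop("n_variants must be a positive count")
  if (length(maf_range) != 2 || maf_range[1] > maf_range[2] ||
      maf_range[1] <= 0 || maf_range[2] > 0.5) {
    stop("maf_range must be an interval within (0, 0.5]")
  }
  if (ld_block_size < 1) stop("ld_block_size must be >= 1")
  if (ld_rho < 0 || ld_rho >= 1) stop("ld_rho must lie in [0, 1)")
  if (missing_rate < 0 || missing_rate >= 1) stop("missing_rate must lie in [0, 1)")
  n <- as.integer(n_samples); m <- as.integer(n_variants)

  with_seed(seed, {
    block <- ceiling(seq_len(m) / ld_block_size)
    n_blocks <- max(block)
    block_maf <- stats::runif(n_blocks, maf_range[1], maf_range[2])
    maf <- block_maf[block]

    # only the previous column of each haplotype is needed (first-order
    # copying), so dosages are filled column-by-column without ever
    # materialising the haplotype matrices
    dos <- matrix(NA_integer_, n, m)
    h1 <- h2 <- integer(n)
    for (j in seq_len(m)) {
      f1 <- stats::rbinom(n, 1L, maf[j])
      f2 <- stats::rbinom(n, 1L, maf[j])
      if (j > 1 && block[j] == block[j - 1] && ld_rho > 0) {
        keep1 <- stats::runif(n) < ld_rho
        keep2 <- stats::runif(n) < ld_rho
        f1[keep1] <- h1[keep1]
        f2[keep2] <- h2[keep2]
      }
      h1 <- f1; h2 <- f2
      dos[, j] <- f1 + f2
    }

    if (missing_rate > 0) {
      dos[stats::runif(n * m) < missing_rate] <- NA_integer_
    }

    n_chrom_eff <- min(n_chrom, n_blocks)
    chrom_of_block <- as.integer(cut(seq_len(n_blocks), breaks = n_chrom_eff,
                                     labels = FALSE))
    chrom <- as.character(chrom_of_block[block])
    pos <- integer(m)
    for (ch in unique(chrom)) {
      idx <- which(chrom == ch)
      pos[idx] <- spacing_bp * seq_along(idx)
    }

    is_imputed <- stats::runif(m) < imputed_fraction
    info <- ifelse(is_imputed, stats::rbeta(m, 10, 0.5), 1)

    variants <- data.frame(
      chrom = chrom, pos = pos, ref = "A", alt = "G",
      variant_id = paste(chrom, pos, "A", "G", sep = ":"),
      info_score = info, is_imputed = is_imputed,
      stringsAsFactors = FALSE
    )
    genotype_dataset(dos, variants, paste0("S", seq_len(n)))
  })
}

#' Randomly downsample a cohort
#'
#' Retains `round-half-away(fraction * n)` samples drawn uniformly without
#' replacement, keeping the genotype and phenotype tables aligned. Intended
#' to be applied before quality control, mirroring a cohort-reduction study
#' design.
#'
#' @param geno A [genotype_dataset()].
#' @param pheno Phenotype data frame with a `sample_id` column (may be
#'   `NULL` to subsample genotypes alone).
#' @param fraction Fraction of samples to retain, in `(0, 1]`.
#' @param seed Integer seed; selection is deterministic given it.
#' @return List with elements `genotypes`, `phenotypes` (subset in genotype
#'   order), and `n_retained`.
#' @examples
#' g <- simulate_genotypes(10, 5, seed = 1)
#' subsample_cohort(g, NULL, fraction = 0.25, seed = 1)$n_retained  # 3
#' @export
subsample_cohort <- function(geno, pheno = NULL, fraction, seed = NULL) {
  if (length(fraction) != 1 || fraction <= 0 || fraction > 1) {
    stop("fraction must lie in (0, 1]")
  }
  n <- length(geno$sample_ids)
  keep_n <- as.integer(round_half_away(fraction * n))
  if (keep_n == n) {
    return(list(genotypes = geno, phenotypes = pheno, n_retained = n))
  }
  idx <- with_seed(seed, sort(sample.int(n, keep_n)))
  geno_sub <- subset_genotypes(geno, samples = idx)
  pheno_sub <- NULL
  if (!is.null(pheno)) {
    pheno_sub <- pheno[match(geno_sub$sample_ids, pheno$sample_id), , drop = FALSE]
    pheno_sub <- pheno_sub[!is.na(pheno_sub$sample_id), , drop = FALSE]
    rownames(pheno_sub) <- NULL
  }
  list(genotypes = geno_sub, phenotypes = pheno_sub, n_retained = keep_n)
}
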