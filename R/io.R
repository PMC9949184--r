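#' Read genotypes from a VCF file
#'
#' Parses dosages from the `DS` FORMAT field when present, otherwise from
#' hard-call `GT` (unphased or phased); `./.` and `.` become missing.
#' Imputation quality is read from an INFO key (default `"INFO"`); when the
#' key is absent for a variant, the variant is treated as genotyped
#' (`info_score` 1, `is_imputed` `FALSE`).
#'
#' @param path Path to an (uncompressed or bgzipped) VCF.
#' @param info_key INFO key holding the imputation quality score.
#' @return A [genotype_dataset()].
#' @export
read_vcf <- function(path, info_key = "INFO") {
  if (!file.exists(path)) stop("VCF not found: ", path)
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  if (nrow(v@fix) == 0) stop("VCF contains no variant records: ", path)
  fix <- as.data.frame(v@fix, stringsAsFactors = FALSE)

  fmt <- strsplit(v@gt[, 1], ":", fixed = TRUE)[[1]]
  if ("DS" %in% fmt) {
    dsm <- vcfR::extract.gt(v, element = "DS", as.numeric = TRUE)
  } else if ("GT" %in% fmt) {
    gt <- vcfR::extract.gt(v, element = "GT")
    cnt <- function(s) {
      a <- strsplit(s, "[/|]")
      vapply(a, function(x) {
        if (any(x == "." | is.na(x))) NA_real_ else sum(as.numeric(x) > 0)
      }, numeric(1))
    }
    dsm <- apply(gt, 2, cnt)
    dim(dsm) <- dim(gt); dimnames(dsm) <- dimnames(gt)
  } else {
    stop("VCF has neither DS nor GT in FORMAT")
  }

  info_raw <- suppressWarnings(
    vcfR::extract.info(v, element = info_key, as.numeric = TRUE))
  is_imputed <- !is.na(info_raw)
  info <- ifelse(is_imputed, info_raw, 1)

  variants <- data.frame(
    chrom = fix$CHROM,
    pos = as.integer(fix$POS),
    ref = fix$REF, alt = fix$ALT,
    variant_id = paste(fix$CHROM, fix$POS, fix$REF, fix$ALT, sep = ":"),
    info_score = info, is_imputed = is_imputed,
    stringsAsFactors = FALSE
  )
  genotype_dataset(t(dsm), variants, colnames(v@gt)[-1])
}

#' Write genotypes as VCF
#'
#' Emits VCF v4.2 with a `DS` FORMAT field (dosages, 6 significant
#' digits, `.` for missing). Imputed variants carry the INFO key; genotyped
#' variants carry `.` in INFO, so the dataset round-trips through
#' [read_vcf()].
#'
#' @param geno A [genotype_dataset()].
#' @param path Output path.
#' @param info_key INFO key under which to write imputation quality.
#' @export
write_vcf <- function(geno, path, info_key = "INFO") {
  v <- geno$variants
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    "##fileformat=VCFv4.2",
    sprintf("##INFO=<ID=%s,Number=1,Type=Float,Description=\"Imputation quality score\">",
            info_key),
    "##FORMAT=<ID=DS,Number=1,Type=Float,Description=\"Alt allele dosage\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", geno$sample_ids), collapse = "\t")
  ), con)
  ds <- t(geno$dosages)
  ds_chr <- matrix(sprintf("%.6g", ds), nrow = nrow(ds))
  ds_chr[is.na(ds)] <- "."
  info <- ifelse(v$is_imputed,
                 sprintf("%s=%.6g", info_key, v$info_score), ".")
  lines <- paste(v$chrom, v$pos, v$variant_id, v$ref, v$alt, ".", "PASS",
                 info, "DS",
                 apply(ds_chr, 1, paste, collapse = "\t"),
                 sep = "\t")
  writeLines(lines, con)
  invisible(path)
}

#' Read a phenotype/covariate table
#'
#' Tab-delimited with header; requires `sample_id`, `value`, `age`, `sex`
#' (degraded columns are carried along). Duplicate sample IDs are an error.
#'
#' @param path Input path.
#' @return Data frame.
#' @export
read_phenotypes <- function(path) {
  ph <- utils::read.delim(path, stringsAsFactors = FALSE)
  validate_phenotypes(ph)
  ph
}

#' Write a phenotype/covariate table
#'
#' @param pheno Data frame.
#' @param path Output path.
#' @export
write_phenotypes <- function(pheno, path) {
  utils::write.table(pheno, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

ss_columns <- c("CHR", "POS", "ID", "REF", "ALT", "BETA", "SE", "T", "P",
                "LOG10P", "N", "MAF")

#' Write GWAS summary statistics
#'
#' Tab-delimited, one row per variant, columns `CHR POS ID REF ALT BETA SE
#' T P LOG10P N MAF`. `LOG10P` preserves p-value ordering below
#' double-precision underflow.
#'
#' @param res An `assoc_result`.
#' @param path Output path.
#' @export
write_summary_stats <- function(res, path) {
  out <- data.frame(CHR = res$chrom, POS = res$pos, ID = res$variant_id,
                    REF = res$ref, ALT = res$alt, BETA = res$beta,
                    SE = res$se, T = res$t, P = res$p, LOG10P = res$log10_p,
                    N = res$n_used, MAF = res$maf)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read GWAS summary statistics written by [write_summary_stats()]
#'
#' Validates the column set and the p-value range.
#'
#' @param path Input path.
#' @return An `assoc_result` data frame (metadata attributes absent).
#' @export
read_summary_stats <- function(path) {
  x <- utils::read.delim(path, stringsAsFactors = FALSE)
  missing_cols <- setdiff(ss_columns, names(x))
  if (length(missing_cols) > 0) {
    stop("summary statistics file is missing column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  bad <- !is.na(x$P) & (x$P <= 0 | x$P > 1)
  if (any(bad)) stop(sum(bad), " p-value(s) outside (0, 1]")
  res <- data.frame(variant_id = x$ID, chrom = as.character(x$CHR),
                    pos = x$POS, ref = x$REF, alt = x$ALT, beta = x$BETA,
                    se = x$SE, t = x$T, p = x$P, log10_p = x$LOG10P,
                    n_used = x$N, maf = x$MAF,
                    degenerate = is.na(x$BETA),
                    stringsAsFactors = FALSE)
  class(res) <- c("assoc_result", "data.frame")
  res
}

#' Write a locus set as BED
#'
#' BED uses 0-based half-open intervals, so a 1-based inclusive locus
#' `[start, end]` becomes `start-1, end`. Name = lead variant, score =
#' -log10 lead p.
#'
#' @param loci A `locus_set`.
#' @param path Output path.
#' @export
write_locus_bed <- function(loci, path) {
  out <- data.frame(chrom = loci$chrom,
                    start = loci$start - 1L,
                    end = loci$end,
                    name = loci$lead_variant_id,
                    score = -loci$lead_log10_p)
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Write a sweep table
#'
#' @param tab A `sweep_table`.
#' @param path Output path.
#' @export
write_sweep_table <- function(tab, path) {
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a sweep table written by [write_sweep_table()]
#'
#' @param path Input path.
#' @return A `sweep_table` data frame.
#' @export
read_sweep_table <- function(path) {
  x <- utils::read.delim(path, stringsAsFactors = FALSE)
  class(x) <- c("sweep_table", "data.frame")
  x
}

#' Write a structured key-value metrics report
#'
#' Flat `key<TAB>value` lines; nested lists are flattened with
#' dot-separated keys.
#'
#' @param metrics Named list (possibly nested) of scalar values.
#' @param path Output path.
#' @export
write_metrics_report <- function(metrics, path) {
  flat <- unlist(metrics)
  writeLines(paste(names(flat), format(flat, digits = 10, trim = TRUE),
                   sep = "\t"), path)
  invisible(path)
}

#' Read a key-value metrics report
#'
#' @param path Input path.
#' @return Named list; values converted to numeric where possible.
#' @export
read_metrics_report <- function(path) {
  x <- utils::read.delim(path, header = FALSE, stringsAsFactors = FALSE,
                         col.names = c("key", "value"))
  vals <- as.list(x$value)
  num <- suppressWarnings(as.numeric(x$value))
  vals[!is.na(num)] <- num[!is.na(num)]
  stats::setNames(vals, x$key)
}
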