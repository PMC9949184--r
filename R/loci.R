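#' Cluster genome-wide-significant SNPs into loci
#'
#' Per chromosome, significant SNP positions are agglomerated by single
#' linkage and the dendrogram is cut at `merge_distance`: two SNPs fall in
#' the same locus iff they are connected by a chain of significant SNPs
#' with adjacent gaps <= `merge_distance`. On 1-D positions this is
#' equivalent to splitting the sorted positions at gaps exceeding the
#' cutoff (standard distance-based clumping), which is how it is computed.
#' Each cluster becomes one locus spanning its min and max position, led by
#' its smallest-p variant (ties: smallest position).
#'
#' @param res An `assoc_result` from [run_gwas()].
#' @param alpha Genome-wide significance threshold (strict `<`).
#' @param merge_distance Single-linkage cutoff in base pairs (> 0).
#' @return A `locus_set`: data frame with columns `chrom`, `start`, `end`
#'   (1-based, inclusive), `lead_variant_id`, `lead_p`, `lead_log10_p`,
#'   `n_snps`, sorted by chromosome then start, with the clustering
#'   parameters attached as attribute `params`.
#' @export
cluster_loci <- function(res, alpha = 5e-8, merge_distance = 1e6) {
  if (merge_distance <= 0) stop("merge_distance must be > 0")
  ids <- significant_snps(res, alpha)
  sig <- res[res$variant_id %in% ids, , drop = FALSE]

  loci <- list()
  for (ch in unique(sig$chrom)) {
    s <- sig[sig$chrom == ch, , drop = FALSE]
    s <- s[order(s$pos, s$variant_id), , drop = FALSE]
    gaps <- diff(s$pos)
    cluster <- cumsum(c(1, as.integer(gaps > merge_distance)))
    for (cl in unique(cluster)) {
      rows <- s[cluster == cl, , drop = FALSE]
      lead <- rows[order(rows$log10_p, rows$pos), , drop = FALSE][1, ]
      loci[[length(loci) + 1]] <- data.frame(
        chrom = ch, start = min(rows$pos), end = max(rows$pos),
        lead_variant_id = lead$variant_id, lead_p = lead$p,
        lead_log10_p = lead$log10_p, n_snps = nrow(rows),
        stringsAsFactors = FALSE
      )
    }
  }
  out <- if (length(loci)) do.call(rbind, loci) else
    data.frame(chrom = character(), start = integer(), end = integer(),
               lead_variant_id = character(), lead_p = numeric(),
               lead_log10_p = numeric(), n_snps = integer(),
               stringsAsFactors = FALSE)
  out <- out[order(chrom_order(out$chrom), out$start), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "params") <- list(alpha = alpha, merge_distance = merge_distance)
  class(out) <- c("locus_set", "data.frame")
  out
}

#' @export
print.locus_set <- function(x, ...) {
  p <- attr(x, "params")
  cat(sprintf("locus_set: %d loci (alpha = %g, merge distance = %g bp)\n",
              nrow(x), p$alpha, p$merge_distance))
  if (nrow(x) > 0) print.data.frame(x)
  invisible(x)
}

#' Match loci between a baseline and a degraded scan
#'
#' A baseline locus persists iff some degraded locus on the same chromosome
#' overlaps it after both intervals are extended by `merge_distance / 2` on
#' each side. Persistence is interval-based, not lead-SNP identity, so a
#' locus whose lead shifts to an LD partner still counts. Each baseline
#' locus counts at most once; one degraded locus may satisfy several
#' baseline loci.
#'
#' @param base,degraded `locus_set` objects built with identical `alpha`
#'   and `merge_distance`.
#' @return A `locus_match`: list with `peaks_base`, `peaks_correct`, and
#'   the per-baseline-locus logical vector `persisted`.
#' @export
match_loci <- function(base, degraded) {
  pb <- attr(base, "params"); pd <- attr(degraded, "params")
  if (!isTRUE(all.equal(pb, pd))) {
    stop("locus sets were built with different clustering parameters")
  }
  slack <- pb$merge_distance / 2
  persisted <- logical(nrow(base))
  for (i in seq_len(nrow(base))) {
    d <- degraded[degraded$chrom == base$chrom[i], , drop = FALSE]
    if (nrow(d) == 0) next
    persisted[i] <- any(d$start - slack <= base$end[i] + slack &
                        d$end + slack >= base$start[i] - slack)
  }
  structure(list(peaks_base = nrow(base),
                 peaks_correct = sum(persisted),
                 persisted = persisted),
            class = "locus_match")
}

#' @export
print.locus_match <- function(x, ...) {
  cat(sprintf("locus match: %d of %d baseline loci persisted\n",
              x$peaks_correct, x$peaks_base))
  invisible(x)
}
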