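#' Round half away from zero
#'
#' Fixed tie-breaking convention used everywhere the package rounds:
#' `x.5` rounds away from zero (2.5 -> 3, -2.5 -> -3), unlike base
#' [round()], which rounds half to even.
#'
#' @param x Numeric vector.
#' @return Numeric vector of rounded values.
#' @keywords internal
round_half_away <- function(x) {
  sign(x) * floor(abs(x) + 0.5)
}

#' Evaluate an expression under a temporary RNG seed
#'
#' Sets the seed for the duration of `code` and restores the caller's RNG
#' state afterwards, so seeded package functions never disturb the global
#' random stream.
#'
#' @param seed Integer seed, or `NULL` to use the current stream.
#' @param code Expression to evaluate.
#' @keywords internal
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    had_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    old <- if (had_seed) get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (had_seed) {
        assign(".Random.seed", old, envir = globalenv())
      } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    }, add = TRUE)
    set.seed(as.integer(seed))
  }
  force(code)
}

# Deterministic per-condition seed derivation; stays below 2^31 - 1.
derive_seed <- function(seed, i, j = 0L) {
  if (is.null(seed)) return(NULL)
  as.integer((as.numeric(seed) * 7919 + i * 104729 + j * 131) %% 2147483629)
}

# log(sum(exp(x))) without overflow/underflow
logsumexp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

# Fold an alt-allele frequency onto the minor allele.
fold_maf <- function(af) {
  pmin(af, 1 - af)
}

# Order chromosome labels numerically where possible, then lexically.
chrom_order <- function(chrom) {
  u <- unique(chrom)
  num <- suppressWarnings(as.numeric(sub("^chr", "", u)))
  ord <- order(is.na(num), num, u)
  match(chrom, u[ord])
}
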