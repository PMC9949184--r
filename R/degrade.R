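#' Specify a phenotype degradation
#'
#' @param kind One of `"gaussian"` (additive measurement noise),
#'   `"round5"` (round to the nearest multiple of 5, as in visual reads),
#'   or `"binarize"` (sex-specific normal/abnormal label).
#' @param sigma Noise SD in phenotype units; required iff `kind = "gaussian"`.
#' @param seed Integer seed for the noise draw.
#' @return Object of class `noise_spec`.
#' @export
noise_spec <- function(kind = c("gaussian", "round5", "binarize"),
                       sigma = NULL, seed = NULL) {
  kind <- match.arg(kind)
  if (kind == "gaussian") {
    if (is.null(sigma)) stop("sigma is required for gaussian noise")
    if (sigma < 0) stop("sigma must be >= 0")
  } else if (!is.null(sigma)) {
    stop("sigma applies only to gaussian noise")
  }
  structure(list(kind = kind, sigma = sigma, seed = seed), class = "noise_spec")
}

#' Apply a degradation specified by a [noise_spec()]
#'
#' @param pheno Phenotype data frame.
#' @param spec A [noise_spec()].
#' @param ... Passed to the underlying operator.
#' @return The phenotype table with a degraded column appended.
#' @export
degrade_phenotype <- function(pheno, spec, ...) {
  switch(spec$kind,
    gaussian = add_gaussian_noise(pheno, sigma = spec$sigma, seed = spec$seed, ...),
    round5 = round_to_5(pheno, ...),
    binarize = binarize_normal_abnormal(pheno, ...)
  )
}

#' Add Gaussian measurement noise to a phenotype
#'
#' Each sample's value gets an independent draw from `Normal(0, sigma^2)`;
#' the original column is preserved. Values are not clamped to the
#' physiologic range by default: measurement noise can push an ejection
#' fraction outside (0, 100), and downstream linear scans are unaffected.
#'
#' @param pheno Phenotype data frame.
#' @param sigma Noise standard deviation (phenotype units, >= 0).
#' @param seed Integer seed; the draw is reproducible given it.
#' @param column Source column name (default `"value"`).
#' @param new_column Name of the degraded column (default `"noisy"`).
#' @param clamp If `TRUE`, clamp the degraded values into `[0, 100]`.
#' @return `pheno` with `new_column` appended.
#' @examples
#' p <- data.frame(sample_id = "a", value = 55, age = 50, sex = "female")
#' add_gaussian_noise(p, sigma = 0)$noisy  # identical to value
#' @export
add_gaussian_noise <- function(pheno, sigma, seed = NULL,
                               column = "value", new_column = "noisy",
                               clamp = FALSE) {
  if (!column %in% names(pheno)) stop("column '", column, "' not found")
  if (length(sigma) != 1 || is.na(sigma) || sigma < 0) {
    stop("sigma must be a single value >= 0")
  }
  x <- pheno[[column]]
  y <- with_seed(seed, x + stats::rnorm(length(x), 0, sigma))
  if (clamp) y <- pmin(pmax(y, 0), 100)
  pheno[[new_column]] <- y
  pheno
}

#' Round a phenotype to the nearest multiple of 5
#'
#' Emulates visual assessment, where readers report values in 5% steps.
#' Ties (x.5 relative to the step) round away from zero, so 57.5 -> 60.
#'
#' @inheritParams add_gaussian_noise
#' @param new_column Name of the degraded column (default `"rounded"`).
#' @return `pheno` with `new_column` appended; every entry is a multiple of
#'   5 and within 2.5 of the original.
#' @export
round_to_5 <- function(pheno, column = "value", new_column = "rounded") {
  if (!column %in% names(pheno)) stop("column '", column, "' not found")
  pheno[[new_column]] <- 5 * round_half_away(pheno[[column]] / 5)
  pheno
}

#' Binarize a phenotype into normal/abnormal by sex-specific reference range
#'
#' Normal is 52-72% for males and 54-74% for females, bounds inclusive;
#' everything else is abnormal. The label is encoded 0 = normal,
#' 1 = abnormal, so the binary trait can enter the same linear association
#' scan as the continuous one. Records with an unknown sex level get `NA`
#' and are counted in a warning.
#'
#' @inheritParams add_gaussian_noise
#' @param new_column Name of the binary column (default `"abnormal"`).
#' @param male_range,female_range Inclusive normal ranges.
#' @return `pheno` with `new_column` appended (0/1, `NA` for unknown sex).
#' @export
binarize_normal_abnormal <- function(pheno, column = "value",
                                     new_column = "abnormal",
                                     male_range = c(52, 72),
                                     female_range = c(54, 74)) {
  if (!column %in% names(pheno)) stop("column '", column, "' not found")
  if (!"sex" %in% names(pheno)) stop("sex column required for binarization")
  x <- pheno[[column]]
  sex <- as.character(pheno$sex)
  lo <- ifelse(sex == "male", male_range[1],
               ifelse(sex == "female", female_range[1], NA_real_))
  hi <- ifelse(sex == "male", male_range[2],
               ifelse(sex == "female", female_range[2], NA_real_))
  out <- ifelse(x >= lo & x <= hi, 0, 1)
  n_bad <- sum(is.na(lo))
  if (n_bad > 0) {
    warning(n_bad, " record(s) with unknown sex level set to NA")
  }
  pheno[[new_column]] <- out
  pheno
}
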