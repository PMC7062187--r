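#' Scaled median absolute deviation
#'
#' MAD = 1.4826 * median(|x - median(x)|). The constant 1.4826 (the
#' reciprocal of the standard-normal upper quartile) makes the MAD a
#' consistent estimate of the standard deviation under normality, so MAD and
#' S.D. can be used interchangeably in SSMD denominators. Missing values are
#' dropped.
#'
#' Thin, argument-checked wrapper around [stats::mad()].
#'
#' @param values numeric vector with at least one finite value.
#' @return the scaled MAD (same units as `values`).
#' @examples
#' scaled_mad(c(1, 2, 3, 4, 5)) # 1.4826
#' @export
scaled_mad <- function(values) {
  values <- values[is.finite(values)]
  if (length(values) == 0L) stop("empty-input error: no finite values for MAD")
  stats::mad(values, constant = 1.4826)
}

#' Plate-wise quality-control SSMD
#'
#' The robust plate QC score
#' \deqn{SSMD_{QC} = \frac{median(C^{+}) - median(C^{-})}
#'                        {\sqrt{MAD(C^{+})^2 + MAD(C^{-})^2}}}
#' contrasts the positive-control wells (siPINK1, which abolishes parkin
#' recruitment, so lower readouts) against the negative-control wells (NTC).
#' On a good plate the score is strongly negative; plates with
#' `SSMD_QC > -2` are considered poor quality (the cut-off suggested for
#' very strong positive controls).
#'
#' @param positive,negative numeric vectors of control readouts (>= 2 finite
#'   values each).
#' @return an `SSMDValue`: list with `value`, `kind = "qc"`, and operand
#'   provenance (`n_pos`, `n_neg`).
#' @examples
#' ssmd_qc(rnorm(8, 0), rnorm(8, 6))$value # strongly negative
#' @export
ssmd_qc <- function(positive, negative) {
  positive <- positive[is.finite(positive)]
  negative <- negative[is.finite(negative)]
  if (length(positive) < 2L || length(negative) < 2L) {
    stop("ssmd_qc needs >= 2 finite values per control group")
  }
  num <- stats::median(positive) - stats::median(negative)
  den <- sqrt(scaled_mad(positive)^2 + scaled_mad(negative)^2)
  value <- ssmd_ratio(num, den)
  structure(
    list(value = value, kind = "qc",
         operands = list(n_pos = length(positive), n_neg = length(negative))),
    class = "SSMDValue"
  )
}

# shared 0/0 convention: identical constant groups give 0 (with a warning for
# the contradictory 'zero spread, different medians' case)
ssmd_ratio <- function(num, den) {
  if (den == 0) {
    if (num == 0) {
      warning("SSMD 0/0: zero spread and equal medians; defined as 0")
      return(0)
    }
    warning("SSMD with zero spread and different medians: signed infinity")
    return(sign(num) * Inf)
  }
  num / den
}

#' Per-gene (per-well) SSMD effect score
#'
#' Estimates the effect of silencing gene *i* relative to the negative
#' controls of the same plates:
#' \deqn{SSMD_i = \frac{median(well_i) - median(C^{-})}
#'                     {\sqrt{\tfrac12 s^2_{well_i} + \tfrac12 s_0^2}}}
#' where \eqn{s^2_{well_i}} is the squared S.D. of the well's readout across
#' plate replicates and \eqn{s_0^2} is the median of the squared S.D. values
#' over all plate replicates (see [pooled_s0_squared()]), which regularises
#' the per-well spread estimated from few replicates.
#'
#' @param well_values the gene's readout across plate replicates (>= 2
#'   finite values).
#' @param negative_values negative-control readouts from the same plates.
#' @param s0_squared pooled squared S.D. (median over all wells), >= 0.
#' @return an `SSMDValue` with `kind = "gene"`.
#' @examples
#' # median(well)=14, s^2=4, neg median 10, s0^2=4 -> 4/sqrt(4) = 2
#' ssmd_gene(c(12, 14, 16), rep(10, 8), s0_squared = 4)$value
#' @export
ssmd_gene <- function(well_values, negative_values, s0_squared) {
  well_values <- well_values[is.finite(well_values)]
  negative_values <- negative_values[is.finite(negative_values)]
  if (length(well_values) < 2L) {
    stop("insufficient-replication error: ssmd_gene needs >= 2 replicate values")
  }
  if (length(negative_values) < 1L) stop("no finite negative-control values")
  stopifnot(s0_squared >= 0)
  num <- stats::median(well_values) - stats::median(negative_values)
  den <- sqrt(0.5 * stats::var(well_values) + 0.5 * s0_squared)
  value <- ssmd_ratio(num, den)
  structure(
    list(value = value, kind = "gene",
         operands = list(n_well = length(well_values),
                         n_neg = length(negative_values),
                         s0_squared = s0_squared)),
    class = "SSMDValue"
  )
}

#' @export
print.SSMDValue <- function(x, ...) {
  cat("SSMD (", x$kind, "): ", format(x$value), "\n", sep = "")
  invisible(x)
}

#' Pooled squared S.D. over all plate replicates
#'
#' The regulariser \eqn{s_0^2} of the per-gene SSMD: the median, over all
#' wells of the dataset, of the squared across-replicate S.D. of the given
#' parameter. S.D. uses the n-1 denominator. Wells with fewer than two
#' finite replicate values are skipped.
#'
#' @param dataset a `ScreenDataset` with >= 2 replicates per plate.
#' @param parameter readout name.
#' @return a single non-negative number.
#' @export
pooled_s0_squared <- function(dataset, parameter) {
  stopifnot(inherits(dataset, "ScreenDataset"))
  if (!parameter %in% dataset$parameter_names) {
    stop("lookup error: unknown parameter '", parameter, "'")
  }
  w <- dataset$wells
  v <- w[[parameter]]
  key <- paste(w$plate_id, w$well)
  n_rep <- tapply(!is.na(v), key, sum)
  if (all(n_rep < 2L, na.rm = TRUE)) {
    stop("insufficient-replication error: no well has >= 2 replicates")
  }
  s2 <- tapply(v, key, function(x) {
    x <- x[is.finite(x)]
    if (length(x) < 2L) return(NA_real_)
    stats::var(x)
  })
  stats::median(s2, na.rm = TRUE)
}
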