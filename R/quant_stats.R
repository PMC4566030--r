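# Small quantitative formulas: PSI from band intensities with product-size
# normalisation, mutually-exclusive-exon inclusion ratios, percent change,
# two-group t-tests from summary statistics, and Pearson concordance.

#' PSI from RT-PCR band intensities
#'
#' Converts inclusion/skipping band intensities to percent spliced in,
#' normalising each intensity by its RT-PCR product length so the ratio is
#' molar: `PSI = (I_inc/L_inc) / (I_inc/L_inc + I_skip/L_skip)`.
#'
#' @param inclusion_intensity,skipping_intensity Band intensities
#'   (non-negative, arbitrary units; not both zero).
#' @param inclusion_length,skipping_length RT-PCR product lengths in nt
#'   (> 0).
#' @return PSI in \[0, 1\].
#' @export
psi_from_bands <- function(inclusion_intensity, inclusion_length,
                           skipping_intensity, skipping_length) {
  stopifnot(inclusion_intensity >= 0, skipping_intensity >= 0,
            inclusion_length > 0, skipping_length > 0)
  if (all(inclusion_intensity == 0 & skipping_intensity == 0))
    .stopf("PSI is undefined when both band intensities are zero")
  inc <- inclusion_intensity / inclusion_length
  skp <- skipping_intensity / skipping_length
  inc / (inc + skp)
}

#' Inclusion ratio for mutually exclusive exons
#'
#' The IIIb-type inclusion ratio for a mutually exclusive exon pair,
#' `IIIb / (IIIb + IIIc)`, from molar isoform amounts (length-normalised
#' intensities).
#'
#' @param iiib,iiic Molar amounts of the two isoforms (non-negative, not
#'   both zero).
#' @return Ratio in \[0, 1\].
#' @export
psi_iiib <- function(iiib, iiic) {
  stopifnot(iiib >= 0, iiic >= 0)
  if (all(iiib == 0 & iiic == 0))
    .stopf("inclusion ratio is undefined when both amounts are zero")
  iiib / (iiib + iiic)
}

#' Percent change of a group mean relative to a reference
#'
#' `100 * (reference - test) / reference`; positive values are reductions.
#'
#' @param reference_mean Reference group mean (> 0).
#' @param test_mean Test group mean.
#' @return Percent change.
#' @export
percent_change <- function(reference_mean, test_mean) {
  if (any(reference_mean <= 0))
    .stopf("percent change is undefined for a non-positive reference mean")
  100 * (reference_mean - test_mean) / reference_mean
}

#' Two-tailed two-sample t-test from summary statistics
#'
#' Unpaired Student's t-test computed from group means, sample standard
#' deviations and sizes.  The default pools the variances (df =
#' `n1 + n2 - 2`); `variance = "welch"` uses the Welch-Satterthwaite
#' approximation.  When both groups have zero standard deviation and equal
#' means the p-value is 1 by convention.
#'
#' @param mean1,sd1,n1 Summary statistics of group 1 (`n1 >= 2`, `sd1` a
#'   sample SD).
#' @param mean2,sd2,n2 Summary statistics of group 2.
#' @param variance `"pooled"` (default) or `"welch"`.
#' @return A list with `statistic` (t), `df` and `p_value`.
#' @export
t_test_two_tailed <- function(mean1, sd1, n1, mean2, sd2, n2,
                              variance = c("pooled", "welch")) {
  variance <- match.arg(variance)
  stopifnot(n1 >= 2, n2 >= 2, sd1 >= 0, sd2 >= 0)
  if (sd1 == 0 && sd2 == 0) {
    if (mean1 == mean2)
      return(list(statistic = 0, df = n1 + n2 - 2, p_value = 1))
    return(list(statistic = sign(mean1 - mean2) * Inf,
                df = n1 + n2 - 2, p_value = 0))
  }
  if (variance == "pooled") {
    df <- n1 + n2 - 2
    sp2 <- ((n1 - 1) * sd1^2 + (n2 - 1) * sd2^2) / df
    se <- sqrt(sp2 * (1 / n1 + 1 / n2))
  } else {
    v1 <- sd1^2 / n1
    v2 <- sd2^2 / n2
    se <- sqrt(v1 + v2)
    df <- (v1 + v2)^2 / (v1^2 / (n1 - 1) + v2^2 / (n2 - 1))
  }
  t <- (mean1 - mean2) / se
  list(statistic = t, df = df, p_value = 2 * stats::pt(-abs(t), df))
}

#' Pearson concordance of predicted versus measured delta PSI
#'
#' Sample Pearson correlation with a two-tailed p-value from the t
#' transform on `n - 2` degrees of freedom.  Used to compare
#' sequencing-predicted and RT-PCR-validated delta-PSI values.
#'
#' @param predicted,measured Paired numeric vectors (equal length >= 3,
#'   finite, non-degenerate).
#' @return A list with `r`, `p_value` and `n`.
#' @export
concordance <- function(predicted, measured) {
  if (length(predicted) != length(measured) || length(predicted) < 3L)
    .stopf("`predicted` and `measured` must have equal length >= 3")
  if (anyNA(predicted) || anyNA(measured) ||
      any(!is.finite(predicted)) || any(!is.finite(measured)))
    .stopf("concordance requires finite values")
  if (stats::sd(predicted) == 0 || stats::sd(measured) == 0)
    .stopf("correlation is undefined for a zero-variance vector")
  n <- length(predicted)
  r <- stats::cor(predicted, measured)
  if (abs(r) >= 1) return(list(r = r, p_value = 0, n = n))
  t <- r * sqrt((n - 2) / (1 - r^2))
  list(r = r, p_value = 2 * stats::pt(-abs(t), n - 2), n = n)
}
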