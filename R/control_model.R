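# Control-anchored Gaussian model.
#
# Because patients and controls are clinically distinct, a Gaussian is fitted
# to the control values of each region and the 95% confidence intervals of its
# parameters become box constraints for the healthy component of the mixture
# model. The mean interval is the exact t-interval; the SD interval is the
# exact chi-square interval.

#' Fit a Gaussian with 95% parameter intervals to one control sample
#'
#' @param x Numeric vector of control values for one region (n >= 3, non-zero
#'   spread).
#' @param conf Confidence level for the parameter intervals (default 0.95).
#' @return A one-row tibble: `mu`, `sigma`, `mu_lo`, `mu_hi`, `sigma_lo`,
#'   `sigma_hi`, `n`.
#' @export
fit_control_gaussian <- function(x, conf = 0.95) {
  x <- x[!is.na(x)]
  n <- length(x)
  if (n < 3) {
    abort_sample_size(paste0("At least 3 control values are required (got ", n, ")."))
  }
  s <- sd(x)
  if (s == 0) {
    abort_degenerate("Control sample has zero variance.")
  }
  m <- mean(x)
  alpha <- 1 - conf
  tq <- qt(1 - alpha / 2, df = n - 1)
  half <- tq * s / sqrt(n)
  # chi-square interval for sigma: (n-1)s^2 / chisq quantiles
  sig_lo <- sqrt((n - 1) * s^2 / qchisq(1 - alpha / 2, df = n - 1))
  sig_hi <- sqrt((n - 1) * s^2 / qchisq(alpha / 2, df = n - 1))
  tibble::tibble(
    mu = m, sigma = s,
    mu_lo = m - half, mu_hi = m + half,
    sigma_lo = sig_lo, sigma_hi = sig_hi,
    n = n
  )
}

#' Fit control Gaussians for every region of a biomarker table
#'
#' @param data A validated biomarker table with at least 3 controls.
#' @param conf Confidence level for the parameter intervals.
#' @return A tibble of class `ebm_control_model`, one row per region.
#' @export
fit_control_model <- function(data, conf = 0.95) {
  ctrl <- control_rows(data)
  labels <- region_cols(data)
  if (nrow(ctrl) < 3) {
    abort_sample_size("At least 3 controls are required to fit the control model.")
  }
  out <- purrr::map_dfr(labels, function(lab) {
    dplyr::bind_cols(tibble::tibble(region = lab),
                     fit_control_gaussian(ctrl[[lab]], conf = conf))
  })
  structure(out, class = c("ebm_control_model", class(out)))
}
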