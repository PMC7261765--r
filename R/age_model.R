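# Region-level age correction.
#
# Normal ageing lowers FA; left uncorrected, an age imbalance between the
# groups would masquerade as disease signal. A per-region ordinary
# least-squares fit of value on age is estimated on controls only, then the
# fitted age effect is subtracted from patients and controls alike, anchoring
# every value at the control mean age so the corrected values stay on the FA
# scale.

#' Fit a control-only linear age model per region
#'
#' @param data A validated biomarker table containing at least three controls
#'   with non-missing age.
#' @return An object of class `ebm_age_model`: a tibble with columns `region`,
#'   `intercept`, `slope` (FA units per year), with the control mean age in
#'   attribute `"reference_age"`.
#' @export
fit_age_model <- function(data) {
  ctrl <- control_rows(data)
  if (!"age" %in% names(ctrl)) {
    abort_validation("Age column required to fit an age model.")
  }
  ctrl <- ctrl[!is.na(ctrl$age), ]
  if (nrow(ctrl) < 3) {
    abort_sample_size(paste0("At least 3 controls with age are required to fit ",
                             "the age model (got ", nrow(ctrl), ")."))
  }
  if (sd(ctrl$age) == 0) {
    abort_degenerate("Control ages are constant; the age model design is degenerate.")
  }
  labels <- region_cols(data)
  y <- biomarker_matrix(ctrl, labels)
  fit <- stats::lm(y ~ age, data = ctrl)
  coefs <- stats::coef(fit)
  out <- tibble::tibble(
    region = labels,
    intercept = as.numeric(coefs["(Intercept)", ]),
    slope = as.numeric(coefs["age", ])
  )
  structure(out, reference_age = mean(ctrl$age),
            class = c("ebm_age_model", class(out)))
}

#' Remove the fitted age effect from all subjects
#'
#' Subtracts `slope * (age - reference_age)` from each region value, for
#' patients and controls alike, using the control-fitted model. The control
#' mean of every region is preserved.
#'
#' @param data A validated biomarker table; every row must have an age.
#' @param model An [fit_age_model()] object fitted on the same regions.
#' @return The table with age-residualized region values.
#' @export
residualize_age <- function(data, model) {
  if (!"age" %in% names(data) || anyNA(data$age)) {
    abort_validation("All subjects must have a non-missing age to residualize.")
  }
  labels <- region_cols(data)
  if (!setequal(labels, model$region)) {
    abort_schema("Age model regions do not match the table's region columns.")
  }
  ref <- attr(model, "reference_age")
  slopes <- setNames(model$slope, model$region)
  centred <- data$age - ref
  for (lab in labels) {
    data[[lab]] <- data[[lab]] - slopes[[lab]] * centred
  }
  data
}

#' @export
tidy.ebm_age_model <- function(x, ...) {
  tibble::as_tibble(unclass(x))
}

#' @export
glance.ebm_age_model <- function(x, ...) {
  tibble::tibble(
    n_regions = nrow(x),
    reference_age = attr(x, "reference_age"),
    mean_abs_slope = mean(abs(x$slope))
  )
}
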