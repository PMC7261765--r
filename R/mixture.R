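# Two-component Gaussian mixtures with control-anchored constraints.
#
# Each biomarker gets a two-component Gaussian mixture: a healthy component
# modelling P(x | event not yet occurred) and a diseased component modelling
# P(x | event occurred). The healthy component is constrained to the 95%
# confidence box of the control-only Gaussian fit (projected EM: parameters
# are clamped after every M-step); the diseased component and the mixing
# proportion are unconstrained by default. To blunt the influence of outliers
# the mixture is refitted on bootstrap resamples, replicates whose mixing
# proportion collapsed to 0 or 1 are discarded, and the element-wise median of
# the surviving replicates is taken as the final fit.

#' Weak constraints used during cross-validation
#'
#' During bootstrap cross-validation the mixtures are fitted directly (no
#' inner bootstrap), with the mixing proportion confined to `[0.01, 0.99]` and
#' the diseased-component SD floored at 0.001 so single resamples cannot
#' produce degenerate fits.
#'
#' @return A list with `theta_bounds` and `sigma_d_min`.
#' @export
weak_constraints <- function() {
  list(theta_bounds = c(0.01, 0.99), sigma_d_min = 0.001)
}

clamp <- function(x, lo, hi) min(max(x, lo), hi)

#' Fit one constrained two-component Gaussian mixture by projected EM
#'
#' @param x Numeric sample for one region (pooled patients + controls by
#'   default upstream; n >= 10).
#' @param control One row of an [fit_control_model()] (list or one-row data
#'   frame) giving the healthy-component starting point and 95% CI box.
#' @param theta_bounds Length-2 bounds for the healthy mixing proportion
#'   (default `c(0, 1)`, i.e. unconstrained).
#' @param sigma_d_min Lower bound for the diseased-component SD.
#' @param constrain If `FALSE`, the healthy component is not clamped to the
#'   control CI box (used for reference fits).
#' @param collapse_tol Mixing proportion within this distance of 0 or 1 marks
#'   the fit as collapsed.
#' @param tol EM stops when the log-likelihood gain drops below this.
#' @param max_iter Iteration cap; hitting it sets `converged = FALSE`.
#'
#' @return A one-row tibble: `mu_h`, `sigma_h`, `mu_d`, `sigma_d`, `theta`
#'   (healthy mixing proportion), `loglik`, `n_iter`, `converged`, `collapsed`.
#' @export
fit_constrained_mixture <- function(x, control,
                                    theta_bounds = c(0, 1),
                                    sigma_d_min = 1e-8,
                                    constrain = TRUE,
                                    collapse_tol = 1e-3,
                                    tol = 1e-6, max_iter = 500) {
  x <- x[!is.na(x)]
  n <- length(x)
  if (n < 10) {
    abort_sample_size(paste0("At least 10 values are required for a mixture fit (got ", n, ")."))
  }
  if (sd(x) == 0) {
    abort_degenerate("All values identical; mixture fit is degenerate.")
  }
  em <- em_fit_raw(x, as.list(control), theta_bounds, sigma_d_min, constrain,
                   tol, max_iter)
  tibble::tibble(
    mu_h = em[["mu_h"]], sigma_h = em[["sigma_h"]],
    mu_d = em[["mu_d"]], sigma_d = em[["sigma_d"]],
    theta = em[["theta"]], loglik = em[["loglik"]],
    n_iter = as.integer(em[["n_iter"]]),
    converged = em[["converged"]] > 0,
    collapsed = em[["theta"]] <= collapse_tol || em[["theta"]] >= 1 - collapse_tol
  )
}

# Lean fitting core shared by the public fit and the bootstrap loop: builds
# the deterministic, separation-seeking start (diseased component initialized
# from values outside the control 95% band, else a point 2 SDs below the
# control mean) and runs the projected EM. Returns a named numeric vector.
em_fit_raw <- function(x, control, theta_bounds, sigma_d_min, constrain,
                       tol, max_iter) {
  n <- length(x)
  out_band <- x[abs(x - control$mu) > 1.96 * control$sigma]
  if (length(out_band) >= 2 && sd(out_band) > 0) {
    mu_d <- mean(out_band)
    sigma_d <- sd(out_band)
  } else {
    mu_d <- control$mu - 2 * control$sigma
    sigma_d <- control$sigma
  }
  sigma_d <- max(sigma_d, sigma_d_min)
  theta <- clamp(1 - length(out_band) / n, 0.1, 0.9)
  theta <- clamp(theta, theta_bounds[1], theta_bounds[2])
  em <- ebm_em_cpp(
    x, control$mu, control$sigma, mu_d, sigma_d, theta,
    mu_lo = if (constrain) control$mu_lo else -Inf,
    mu_hi = if (constrain) control$mu_hi else Inf,
    sig_lo = if (constrain) control$sigma_lo else 1e-10,
    sig_hi = if (constrain) control$sigma_hi else Inf,
    theta_lo = theta_bounds[1], theta_hi = theta_bounds[2],
    sigma_d_min = sigma_d_min, tol = tol, max_iter = as.integer(max_iter)
  )
  c(mu_h = em$mu_h, sigma_h = em$sigma_h, mu_d = em$mu_d, sigma_d = em$sigma_d,
    theta = em$theta, loglik = em$loglik, n_iter = em$n_iter,
    converged = as.numeric(em$converged))
}

#' Median-aggregate bootstrap mixture replicates
#'
#' Drops replicates whose mixing proportion collapsed to 0 or 1, then takes
#' the element-wise median of the remaining parameters.
#'
#' @param replicates A tibble of per-replicate fits as returned by
#'   [fit_constrained_mixture()].
#' @param region Region label used in error messages.
#' @return A one-row tibble of median parameters plus `n_retained` and `B`.
#' @export
aggregate_bootstrap_fits <- function(replicates, region = "<region>") {
  kept <- dplyr::filter(replicates, !.data$collapsed)
  if (nrow(kept) == 0) {
    abort_estimation(paste0("All bootstrap mixture replicates collapsed for region '",
                            region, "'."))
  }
  tibble::tibble(
    mu_h = median(kept$mu_h), sigma_h = median(kept$sigma_h),
    mu_d = median(kept$mu_d), sigma_d = median(kept$sigma_d),
    theta = median(kept$theta),
    loglik = median(kept$loglik),
    converged = mean(kept$converged) >= 0.5,
    collapsed = FALSE,
    n_retained = nrow(kept), B = nrow(replicates)
  )
}

#' Bootstrap-median mixture fit for one region
#'
#' Fits the constrained mixture on `B` bootstrap resamples of the data,
#' excludes collapsed replicates, and returns element-wise median parameters.
#'
#' @inheritParams fit_constrained_mixture
#' @param B Number of bootstrap replicates (default 1000).
#' @param seed Optional integer seed for the resampling.
#' @param region Region label used in error messages.
#' @param keep_replicates If `TRUE`, the per-replicate fits are attached as
#'   attribute `"replicates"`.
#' @return A one-row tibble of median parameters with `n_retained` and `B`.
#' @export
bootstrap_median_fit <- function(x, control, B = 1000,
                                 theta_bounds = c(0, 1), sigma_d_min = 1e-8,
                                 collapse_tol = 1e-3, tol = 1e-6, max_iter = 500,
                                 seed = NULL, region = "<region>",
                                 keep_replicates = FALSE) {
  if (B < 1) abort_validation("B must be >= 1.")
  x <- x[!is.na(x)]
  if (length(x) < 10) {
    abort_sample_size(paste0("At least 10 values are required for a mixture fit (got ",
                             length(x), ")."))
  }
  control <- as.list(control)
  with_seed_if(seed, {
    rows <- matrix(NA_real_, B, 8,
                   dimnames = list(NULL, c("mu_h", "sigma_h", "mu_d", "sigma_d",
                                           "theta", "loglik", "n_iter", "converged")))
    for (b in seq_len(B)) {
      xb <- x[sample.int(length(x), replace = TRUE)]
      if (sd(xb) == 0) next   # degenerate resample counts as collapsed
      rows[b, ] <- em_fit_raw(xb, control, theta_bounds, sigma_d_min,
                              constrain = TRUE, tol = tol, max_iter = max_iter)
    }
    reps <- tibble::as_tibble(as.data.frame(rows))
    reps$converged <- !is.na(reps$converged) & reps$converged > 0
    reps$collapsed <- is.na(reps$theta) | reps$theta <= collapse_tol |
      reps$theta >= 1 - collapse_tol
    out <- aggregate_bootstrap_fits(reps, region = region)
    if (keep_replicates) attr(out, "replicates") <- reps
    out
  })
}

resolve_theta_bounds <- function(theta_bounds, label) {
  if (is.null(theta_bounds)) return(c(0, 1))
  if (is.numeric(theta_bounds)) return(theta_bounds)
  if (is.list(theta_bounds)) {
    if (!is.null(theta_bounds[[label]])) return(theta_bounds[[label]])
    return(theta_bounds$default %||% c(0, 1))
  }
  abort_validation("theta_bounds must be a length-2 numeric or a named list of them.")
}

#' Fit event mixtures for every region of a biomarker table
#'
#' The table-level wrapper: fits the control Gaussians (unless supplied) and a
#' bootstrap-median constrained mixture per region.
#'
#' @param data A validated biomarker table with both groups.
#' @param control_model Optional precomputed [fit_control_model()] result.
#' @param subjects Which values enter the mixture fit: `"pooled"` (patients +
#'   controls, default) or `"patients"`.
#' @param B Bootstrap replicates per region (default 1000); `B = 0` requests a
#'   single direct fit (as used in cross-validation).
#' @param theta_bounds Either a length-2 numeric applied to every region or a
#'   named list of per-region bounds with an optional `default` entry, e.g.
#'   `list(default = c(0, 1), ILF_R = c(0.5, 1))`.
#' @param sigma_d_min Lower bound for the diseased-component SD.
#' @param collapse_tol Collapse tolerance for the mixing proportion.
#' @param seed Optional integer seed for the bootstrap resampling.
#' @return A tibble of class `ebm_mixture_fits`, one row per region.
#' @export
fit_mixture_models <- function(data, control_model = NULL,
                               subjects = c("pooled", "patients"),
                               B = 1000, theta_bounds = NULL,
                               sigma_d_min = 1e-8, collapse_tol = 1e-3,
                               seed = NULL) {
  subjects <- match.arg(subjects)
  labels <- region_cols(data)
  if (nrow(patient_rows(data)) < 1 || nrow(control_rows(data)) < 1) {
    abort_validation("Both patients and controls are required to fit mixtures.")
  }
  if (is.null(control_model)) control_model <- fit_control_model(data)
  fit_data <- if (subjects == "pooled") data else patient_rows(data)
  with_seed_if(seed, {
    out <- purrr::map_dfr(labels, function(lab) {
      ctrl_row <- control_model[control_model$region == lab, ]
      if (nrow(ctrl_row) != 1) {
        abort_schema(paste0("Control model lacks region '", lab, "'."))
      }
      bounds <- resolve_theta_bounds(theta_bounds, lab)
      x <- fit_data[[lab]]
      fit <- if (B >= 1) {
        bootstrap_median_fit(x, ctrl_row, B = B, theta_bounds = bounds,
                             sigma_d_min = sigma_d_min,
                             collapse_tol = collapse_tol, region = lab)
      } else {
        f <- fit_constrained_mixture(x, ctrl_row, theta_bounds = bounds,
                                     sigma_d_min = sigma_d_min,
                                     collapse_tol = collapse_tol)
        dplyr::mutate(dplyr::select(f, -"n_iter"),
                      n_retained = NA_integer_, B = 0L)
      }
      dplyr::bind_cols(tibble::tibble(region = lab), fit)
    })
    structure(out, subjects = subjects,
              class = c("ebm_mixture_fits", class(out)))
  })
}

#' Event and no-event densities of a biomarker value
#'
#' @param fit A one-row mixture fit (or a row of an `ebm_mixture_fits` tibble).
#' @param x Numeric values.
#' @param log If `TRUE`, return log densities.
#' @return A tibble with columns `p_event` (diseased-component density) and
#'   `p_no_event` (healthy-component density).
#' @export
event_densities <- function(fit, x, log = FALSE) {
  fit <- as.list(fit)
  tibble::tibble(
    p_event = dnorm(x, fit$mu_d, fit$sigma_d, log = log),
    p_no_event = dnorm(x, fit$mu_h, fit$sigma_h, log = log)
  )
}

# J x N log-density matrices for the likelihood core. Densities are floored at
# the smallest positive normal double so extreme outliers cannot yield -Inf;
# flooring triggers a warning.
event_log_density_matrices <- function(data, fits) {
  labels <- fits$region
  missing <- setdiff(labels, names(data))
  if (length(missing)) {
    abort_schema(paste0("Table lacks region column(s): ",
                        paste(missing, collapse = ", ")))
  }
  xm <- biomarker_matrix(data, labels)
  floor_log <- log(.Machine$double.xmin)
  log_e <- matrix(0, nrow(xm), ncol(xm), dimnames = dimnames(xm))
  log_h <- log_e
  for (i in seq_along(labels)) {
    log_e[, i] <- dnorm(xm[, i], fits$mu_d[i], fits$sigma_d[i], log = TRUE)
    log_h[, i] <- dnorm(xm[, i], fits$mu_h[i], fits$sigma_h[i], log = TRUE)
  }
  n_floored <- sum(log_e < floor_log) + sum(log_h < floor_log)
  if (n_floored > 0) {
    warn(paste0(n_floored, " density value(s) floored at the smallest positive",
                " normal double; extreme outliers present."))
    log_e <- pmax(log_e, floor_log)
    log_h <- pmax(log_h, floor_log)
  }
  list(log_e = log_e, log_h = log_h, labels = labels)
}

#' @export
tidy.ebm_mixture_fits <- function(x, ...) {
  tibble::as_tibble(as.data.frame(x))
}

#' @export
glance.ebm_mixture_fits <- function(x, ...) {
  tibble::tibble(
    n_regions = nrow(x),
    n_collapsed = sum(x$collapsed),
    mean_theta = mean(x$theta),
    mean_separation = mean((x$mu_h - x$mu_d) / x$sigma_h),
    subjects = attr(x, "subjects") %||% "pooled"
  )
}
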