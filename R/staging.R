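# Subject-level staging along the inferred event ordering.
#
# A subject at stage k has experienced the first k events of the ordering. The
# stage likelihood multiplies event densities for the first k ordered regions
# and no-event densities for the rest; the assigned stage is the argmax over
# k = 0..N, with ties going to the lowest (healthier) stage. Staging is
# applied to patients and controls alike.

#' Maximum-likelihood stage for every subject
#'
#' @param data A validated biomarker table (patients and controls).
#' @param fits An `ebm_mixture_fits` tibble covering all regions.
#' @param ordering The inferred event ordering (labels or indices), typically
#'   the MAP ordering from [mcmc_sample()].
#' @return A tibble of class `ebm_stages`: `subject_id`, `group`, `stage`
#'   (0..N), `max_posterior` (the normalized posterior mass of the assigned
#'   stage), and a list-column `posterior` holding the full length-N+1
#'   normalized stage posterior.
#' @export
stage_subjects <- function(data, fits, ordering) {
  if (nrow(data) == 0) abort_validation("No subjects to stage.")
  mats <- event_log_density_matrices(data, fits)
  idx <- ordering_to_indices(ordering, mats$labels)
  ll <- ebm_stage_loglik_cpp(mats$log_e, mats$log_h, idx)
  # normalized posterior per subject, log-sum-exp for stability
  m <- apply(ll, 1, max)
  w <- exp(ll - m)
  post <- w / rowSums(w)
  stage <- apply(ll, 1, which.max) - 1L   # which.max takes the lowest k on ties
  out <- tibble::tibble(
    subject_id = data$subject_id,
    group = data$group,
    stage = as.integer(stage),
    max_posterior = post[cbind(seq_len(nrow(post)), stage + 1L)],
    posterior = lapply(seq_len(nrow(post)), function(i) post[i, ])
  )
  structure(out, ordering = mats$labels[idx], n_events = length(idx),
            class = c("ebm_stages", class(out)))
}

#' Per-group proportion of subjects at each stage
#'
#' @param stages An [stage_subjects()] result.
#' @return A tibble of class `ebm_stage_proportions` with columns `group`,
#'   `stage` (0..N, all stages present), `n`, `proportion`; proportions sum to
#'   1 within each group.
#' @export
stage_proportions <- function(stages) {
  n_events <- attr(stages, "n_events") %||% max(stages$stage)
  out <- tibble::as_tibble(as.data.frame(stages)[c("group", "stage")]) |>
    dplyr::mutate(stage = factor(.data$stage, levels = 0:n_events)) |>
    dplyr::count(.data$group, .data$stage, .drop = FALSE) |>
    dplyr::group_by(.data$group) |>
    dplyr::mutate(proportion = .data$n / sum(.data$n)) |>
    dplyr::ungroup() |>
    dplyr::mutate(stage = as.integer(as.character(.data$stage)))
  structure(out, class = c("ebm_stage_proportions", class(out)))
}

#' Classify subjects by a stage cut-off
#'
#' Predicts "diseased" for every subject at or above `cutoff` (e.g. cutoff 1:
#' stage 0 = healthy, stage >= 1 = diseased) and reports sensitivity (fraction
#' of patients predicted diseased) and specificity (fraction of controls
#' predicted healthy).
#'
#' @param stages An [stage_subjects()] result containing both groups.
#' @param cutoff Stage cut-off(s) in `1..N`; vectorized.
#' @return A tibble with one row per cutoff: `cutoff`, `sensitivity`,
#'   `specificity`.
#' @export
classify_by_stage <- function(stages, cutoff = 1) {
  if (!all(c("patient", "control") %in% stages$group)) {
    abort_validation("Both groups are required to compute sensitivity and specificity.")
  }
  n_events <- attr(stages, "n_events") %||% max(stages$stage)
  if (any(cutoff < 1) || any(cutoff > n_events)) {
    abort_validation("cutoff must lie in 1..N.")
  }
  pat <- stages$stage[stages$group == "patient"]
  ctl <- stages$stage[stages$group == "control"]
  purrr::map_dfr(cutoff, function(k) {
    tibble::tibble(
      cutoff = k,
      sensitivity = mean(pat >= k),
      specificity = mean(ctl < k)
    )
  })
}

#' @export
tidy.ebm_stages <- function(x, ...) {
  tibble::as_tibble(as.data.frame(x)[c("subject_id", "group", "stage", "max_posterior")])
}

#' @export
glance.ebm_stages <- function(x, ...) {
  tibble::tibble(
    n_subjects = nrow(x),
    n_events = attr(x, "n_events"),
    mean_stage_patients = mean(x$stage[x$group == "patient"]),
    mean_stage_controls = mean(x$stage[x$group == "control"]),
    prop_patients_stage0 = mean(x$stage[x$group == "patient"] == 0)
  )
}
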