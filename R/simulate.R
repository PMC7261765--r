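# Synthetic cohort generator.
#
# Realizes the event-based generative model exactly: each control draws every
# region from its healthy Gaussian; each patient draws a latent stage k from a
# stage distribution, then draws regions at positions 1..k of the ground-truth
# event ordering from the diseased Gaussian and the remaining regions from the
# healthy one. Optional linear age effects and additive site offsets are added
# afterwards. The latent truth (per-patient stage, true ordering) is returned
# alongside the table, never inside it, so the inference path cannot see it.

#' Default per-region healthy/diseased FA parameters
#'
#' Documented stand-in parameters on a realistic FA scale. No published
#' per-tract effect sizes exist for these regions, so the defaults place
#' healthy means in the 0.42-0.70 band typical of mean tract FA, use a common
#' within-group SD, and set every diseased mean below its healthy mean
#' (white-matter damage lowers FA) by `separation` healthy SDs.
#'
#' @param region_set An `ebm_region_set` or character vector of labels.
#' @param separation Healthy-diseased mean separation in units of `sigma_h`
#'   (default 2.5).
#' @param sigma_h,sigma_d Healthy and diseased SDs in FA units.
#' @return A tibble with columns `region`, `mu_h`, `sigma_h`, `mu_d`, `sigma_d`.
#' @export
default_fa_params <- function(region_set, separation = 2.5,
                              sigma_h = 0.02, sigma_d = 0.025) {
  labels <- region_labels(region_set)
  base <- c(
    CST_inf = 0.58, CST_mid = 0.60, CST_sup = 0.56,
    CC_genu = 0.70, CC_body = 0.62, CC_splenium = 0.68,
    Cingulum = 0.52, SLF = 0.48, ILF = 0.50, IFOF = 0.50, UF = 0.42
  )
  mu_h <- purrr::map_dbl(labels, function(lab) {
    stem <- sub("_(L|R)$", "", lab)
    if (stem %in% names(base)) base[[stem]] else 0.50
  })
  tibble::tibble(
    region = labels,
    mu_h = mu_h,
    sigma_h = sigma_h,
    mu_d = mu_h - separation * sigma_h,
    sigma_d = sigma_d
  )
}

#' Generate a synthetic patient/control cohort with known ground truth
#'
#' @param region_set Region set defining the biomarkers (default: the 11
#'   combined-hemisphere regions).
#' @param params Per-region mixture parameters as from [default_fa_params()].
#' @param true_ordering Ground-truth event ordering as a character vector of
#'   region labels (a permutation of `params$region`). Default: the region-set
#'   order.
#' @param n_patients,n_controls Cohort sizes.
#' @param stage_distribution Probability vector of length N+1 over latent
#'   stages 0..N. Default: uniform, matching the model's uniform stage prior.
#' @param age_range Ages are drawn uniformly from this interval (years).
#' @param age_slope Linear age effect in FA units per year, recycled across
#'   regions; the effect is centred at the midpoint of `age_range`. Default 0.
#' @param site_labels,site_offsets Optional site labels (assigned uniformly at
#'   random) and additive per-site offsets in FA units. Default: none.
#' @param seed Integer seed; the whole cohort is reproducible from it.
#'
#' @return A list of class `ebm_cohort`:
#'   * `data` — the biomarker table (no truth columns),
#'   * `truth` — tibble `subject_id`, `group`, `stage` (controls at stage 0),
#'   * `ordering` — the ground-truth ordering (labels),
#'   * `params`, `seed`.
#' @export
simulate_cohort <- function(region_set = canonical_region_set("combined"),
                            params = default_fa_params(region_set),
                            true_ordering = NULL,
                            n_patients = 150, n_controls = 130,
                            stage_distribution = NULL,
                            age_range = c(40, 75),
                            age_slope = 0,
                            site_labels = NULL, site_offsets = NULL,
                            seed = NULL) {
  labels <- region_labels(region_set)
  if (!setequal(params$region, labels)) {
    abort_schema("params$region must match the region-set labels.")
  }
  params <- params[match(labels, params$region), ]
  n <- length(labels)
  if (is.null(true_ordering)) true_ordering <- labels
  if (!setequal(true_ordering, labels) || length(true_ordering) != n) {
    abort_validation("true_ordering must be a permutation of the region labels.")
  }
  if (is.null(stage_distribution)) stage_distribution <- rep(1 / (n + 1), n + 1)
  if (length(stage_distribution) != n + 1 || any(stage_distribution < 0) ||
      abs(sum(stage_distribution) - 1) > 1e-8) {
    abort_validation("stage_distribution must be a length N+1 probability vector summing to 1.")
  }
  if (any(params$sigma_h <= 0) || any(params$sigma_d <= 0)) {
    abort_validation("All sigma parameters must be positive.")
  }
  if (!is.null(site_labels) &&
      (is.null(site_offsets) || length(site_offsets) != length(site_labels))) {
    abort_validation("site_offsets must be given, one per site label.")
  }
  age_slope <- rep_len(age_slope, n)
  ord_idx <- match(true_ordering, labels)

  with_seed_if(seed, {
    draw_subject <- function(id, group) {
      age <- runif(1, age_range[1], age_range[2])
      if (group == "patient") {
        k <- sample.int(n + 1, 1, prob = stage_distribution) - 1L
      } else {
        k <- 0L
      }
      diseased <- logical(n)
      if (k > 0) diseased[ord_idx[seq_len(k)]] <- TRUE
      # one draw per region, region order fixed, so the stream is stable
      vals <- rnorm(n,
                    mean = ifelse(diseased, params$mu_d, params$mu_h),
                    sd = ifelse(diseased, params$sigma_d, params$sigma_h))
      site <- if (!is.null(site_labels)) {
        site_labels[sample.int(length(site_labels), 1)]
      } else NA_character_
      list(id = id, group = group, age = age, site = site, stage = k, vals = vals)
    }
    subjects <- c(
      purrr::map(seq_len(n_controls),
                 ~ draw_subject(sprintf("ctrl_%03d", .x), "control")),
      purrr::map(seq_len(n_patients),
                 ~ draw_subject(sprintf("pat_%03d", .x), "patient"))
    )
    values <- do.call(rbind, purrr::map(subjects, "vals"))
    colnames(values) <- labels
    data <- tibble::tibble(
      subject_id = purrr::map_chr(subjects, "id"),
      group = purrr::map_chr(subjects, "group"),
      age = purrr::map_dbl(subjects, "age"),
      site = purrr::map_chr(subjects, "site")
    )
    age_mid <- mean(age_range)
    for (i in seq_len(n)) {
      col <- values[, i] + age_slope[i] * (data$age - age_mid)
      if (!is.null(site_labels)) {
        offs <- setNames(site_offsets, site_labels)
        col <- col + ifelse(is.na(data$site), 0, offs[data$site])
      }
      data[[labels[i]]] <- col
    }
    if (is.null(site_labels)) data$site <- NULL
    truth <- tibble::tibble(
      subject_id = data$subject_id,
      group = data$group,
      stage = purrr::map_int(subjects, ~ as.integer(.x$stage))
    )
    structure(
      list(data = data, truth = truth, ordering = true_ordering,
           params = params, seed = seed),
      class = "ebm_cohort"
    )
  })
}

#' Write a simulated cohort to disk
#'
#' The biomarker table goes to `<stem>.csv`; the latent truth (stages and the
#' ground-truth ordering) goes to a separate sidecar `<stem>_truth.json` so
#' the inference path never touches it.
#'
#' @param cohort An [simulate_cohort()] result.
#' @param stem Output path stem (no extension).
#' @return Named character vector of the two paths written, invisibly.
#' @export
write_cohort <- function(cohort, stem) {
  stopifnot(inherits(cohort, "ebm_cohort"))
  data_path <- paste0(stem, ".csv")
  truth_path <- paste0(stem, "_truth.json")
  write_biomarker_table(cohort$data, data_path)
  jsonlite::write_json(
    list(ordering = cohort$ordering,
         stages = cohort$truth,
         seed = cohort$seed),
    truth_path, auto_unbox = TRUE, digits = NA
  )
  invisible(c(data = data_path, truth = truth_path))
}

#' @export
print.ebm_cohort <- function(x, ...) {
  cat("Synthetic biomarker cohort:",
      sum(x$data$group == "patient"), "patients,",
      sum(x$data$group == "control"), "controls,",
      length(x$ordering), "regions\n")
  cat("Ground-truth ordering:", paste(x$ordering, collapse = " > "), "\n")
  invisible(x)
}
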