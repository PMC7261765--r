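# End-to-end orchestration: validate -> (optional) age residualization ->
# control fits -> bootstrap-median mixtures -> greedy + MCMC ordering on
# patients -> positional variance -> (optional) bootstrap cross-validation ->
# staging -> stage-threshold classification, with a manifest that makes every
# run reproducible from its seed.

write_pvd_csv <- function(pvd, path) {
  df <- tibble::as_tibble(unclass(pvd), .name_repair = "minimal")
  df <- dplyr::bind_cols(tibble::tibble(region = rownames(pvd)), df)
  readr::write_csv(df, path)
}

read_pvd_csv <- function(path) {
  df <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  m <- as.matrix(df[-1])
  rownames(m) <- df$region
  structure(m, reference = df$region, class = c("ebm_pvd", "matrix", "array"))
}

#' Run the full event-based modelling pipeline
#'
#' @param data A validated biomarker table (tibble) or a path to a CSV file
#'   (requires `region_set`).
#' @param out_dir Output directory; created if absent. All artifacts (manifest,
#'   fitted parameters, orderings, positional variance matrices, stage tables,
#'   classification metrics) are written here as CSV/JSON.
#' @param region_set Optional region set used to validate `data`.
#' @param values Validation mode for region values (`"fa"` or `"free"`).
#' @param age_correct Residualize age effects (control-fitted, applied to all
#'   subjects) before modelling. Requires an `age` column.
#' @param subjects Values entering the mixture fits (`"pooled"` or `"patients"`).
#' @param mixture_B Bootstrap replicates per region for the mixture fits
#'   (default 1000).
#' @param theta_bounds Per-region mixing-proportion bounds (see
#'   [fit_mixture_models()]).
#' @param n_iter,burn_in,restarts MCMC chain length, burn-in, and greedy
#'   initialization restarts.
#' @param cv_B Cross-validation bootstrap replicates (default 10000; 0 skips
#'   cross-validation).
#' @param cv_restarts Greedy restarts per cross-validation replicate.
#' @param cutoff Stage cut-off for the classification metrics.
#' @param seed Integer seed; two runs with the same config and seed produce
#'   identical numerical outputs.
#'
#' @return An object of class `ebm_run`: a list with the fitted
#'   `control_model`, `fits`, `posterior`, `pvd_mcmc`, `cv` (or `NULL`),
#'   `stages`, `proportions`, `metrics`, and `out_dir`.
#' @export
run_ebm_pipeline <- function(data, out_dir,
                             region_set = NULL, values = c("fa", "free"),
                             age_correct = FALSE,
                             subjects = c("pooled", "patients"),
                             mixture_B = 1000, theta_bounds = NULL,
                             n_iter = 100000, burn_in = 10000, restarts = 10,
                             cv_B = 10000, cv_restarts = 5,
                             cutoff = 1, seed = NULL) {
  values <- match.arg(values)
  subjects <- match.arg(subjects)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  config <- list(values = values, age_correct = age_correct,
                 subjects = subjects, mixture_B = mixture_B,
                 theta_bounds = theta_bounds, n_iter = n_iter,
                 burn_in = burn_in, restarts = restarts, cv_B = cv_B,
                 cv_restarts = cv_restarts, cutoff = cutoff, seed = seed)
  timings <- list()
  run_stage <- function(name, expr) {
    t0 <- Sys.time()
    res <- tryCatch(expr, error = function(e) {
      writeLines(paste0("stage: ", name, "\n", conditionMessage(e)),
                 file.path(out_dir, "FAILED"))
      abort(paste0("Pipeline stage '", name, "' failed: ", conditionMessage(e)),
            class = "ebmseq_pipeline_error", parent = e)
    })
    timings[[name]] <<- as.numeric(difftime(Sys.time(), t0, units = "secs"))
    res
  }

  data <- run_stage("validate", {
    if (is.character(data)) {
      if (is.null(region_set)) {
        abort_schema("region_set is required when reading the table from a file.")
      }
      read_biomarker_table(data, region_set, values = values)
    } else if (!is.null(region_set)) {
      validate_biomarker_table(data, region_set, values = values)
    } else {
      tibble::as_tibble(data)
    }
  })

  with_seed_if(seed, {
    if (age_correct) {
      data <- run_stage("age_residualization", {
        residualize_age(data, fit_age_model(data))
      })
    }
    control_model <- run_stage("control_model", fit_control_model(data))
    fits <- run_stage("mixture_models", {
      fit_mixture_models(data, control_model = control_model,
                         subjects = subjects, B = mixture_B,
                         theta_bounds = theta_bounds)
    })
    posterior <- run_stage("mcmc_ordering", {
      mcmc_sample(patient_rows(data), fits, n_iter = n_iter,
                  burn_in = burn_in, restarts = restarts)
    })
    pvd_mcmc <- positional_variance(posterior)
    cv <- NULL
    if (cv_B > 0) {
      cv <- run_stage("cross_validation", {
        cross_validate_ordering(data, B = cv_B, subjects = subjects,
                                restarts = cv_restarts,
                                reference = posterior$map)
      })
    }
    stages <- run_stage("staging", stage_subjects(data, fits, posterior$map))
    proportions <- stage_proportions(stages)
    metrics <- run_stage("classification", classify_by_stage(stages, cutoff))
  })

  run_stage("serialize", {
    readr::write_csv(tibble::as_tibble(as.data.frame(control_model)),
                     file.path(out_dir, "control_model.csv"))
    readr::write_csv(tidy(fits), file.path(out_dir, "mixture_fits.csv"))
    jsonlite::write_json(
      list(map_ordering = posterior$map, map_loglik = posterior$map_loglik,
           acceptance_rate = posterior$acceptance_rate,
           n_iter = n_iter, burn_in = burn_in),
      file.path(out_dir, "ordering.json"), auto_unbox = TRUE, digits = NA)
    write_pvd_csv(pvd_mcmc, file.path(out_dir, "pvd_mcmc.csv"))
    if (!is.null(cv)) {
      write_pvd_csv(cv$pvd, file.path(out_dir, "pvd_cv.csv"))
    }
    readr::write_csv(tidy(stages), file.path(out_dir, "stages.csv"))
    readr::write_csv(tibble::as_tibble(as.data.frame(proportions)),
                     file.path(out_dir, "stage_proportions.csv"))
    jsonlite::write_json(metrics, file.path(out_dir, "metrics.json"),
                         auto_unbox = FALSE, digits = NA)
    jsonlite::write_json(
      list(package = "ebmseq",
           version = as.character(utils::packageVersion("ebmseq")),
           config = config, seed = seed, timings = timings),
      file.path(out_dir, "manifest.json"), auto_unbox = TRUE, digits = NA,
      null = "null")
  })

  structure(
    list(control_model = control_model, fits = fits, posterior = posterior,
         pvd_mcmc = pvd_mcmc, cv = cv, stages = stages,
         proportions = proportions, metrics = metrics, out_dir = out_dir,
         config = config),
    class = "ebm_run"
  )
}

#' @export
print.ebm_run <- function(x, ...) {
  cat("Event-based model run (", x$out_dir, ")\n", sep = "")
  cat("MAP ordering:", paste(x$posterior$map, collapse = " > "), "\n")
  cat(sprintf("Sensitivity %.3f / specificity %.3f at stage cut-off %s\n",
              x$metrics$sensitivity[1], x$metrics$specificity[1],
              format(x$metrics$cutoff[1])))
  invisible(x)
}

#' Render figures for a pipeline run directory
#'
#' Writes a grayscale positional variance heatmap (MCMC and cross-validation
#' side by side when both exist) and a per-group stage-proportion bar chart.
#'
#' @param run_dir Directory produced by [run_ebm_pipeline()], or an `ebm_run`.
#' @param format Figure file format (`"png"` or `"svg"`).
#' @return Named character vector of figure paths, invisibly.
#' @export
render_ebm_reports <- function(run_dir, format = c("png", "svg")) {
  format <- match.arg(format)
  if (inherits(run_dir, "ebm_run")) run_dir <- run_dir$out_dir
  need <- function(name) {
    path <- file.path(run_dir, name)
    if (!file.exists(path)) {
      abort(paste0("Expected run artifact not found: ", path),
            class = "ebmseq_missing_artifact_error")
    }
    path
  }
  pvd_mcmc <- read_pvd_csv(need("pvd_mcmc.csv"))
  cv_path <- file.path(run_dir, "pvd_cv.csv")
  panels <- dplyr::bind_rows(
    dplyr::mutate(tidy(pvd_mcmc), panel = "MCMC posterior"),
    if (file.exists(cv_path)) {
      dplyr::mutate(tidy(read_pvd_csv(cv_path)), panel = "Cross-validation")
    }
  )
  panels$panel <- factor(panels$panel,
                         levels = c("MCMC posterior", "Cross-validation"))
  panels$region <- factor(panels$region, levels = rev(rownames(pvd_mcmc)))
  p_pvd <- ggplot2::ggplot(panels,
                           ggplot2::aes(x = .data$position, y = .data$region,
                                        fill = .data$probability)) +
    ggplot2::geom_tile(colour = "grey80", linewidth = 0.2) +
    ggplot2::scale_fill_gradient(low = "white", high = "black",
                                 limits = c(0, 1), name = "Posterior\nconfidence") +
    ggplot2::facet_wrap(~panel) +
    ggplot2::labs(x = "Sequence position", y = NULL) +
    ggplot2::theme_minimal() +
    ggplot2::theme(panel.grid = ggplot2::element_blank())
  props <- readr::read_csv(need("stage_proportions.csv"),
                           show_col_types = FALSE, progress = FALSE)
  class(props) <- c("ebm_stage_proportions", class(props))
  p_stage <- autoplot(props)

  pvd_file <- file.path(run_dir, paste0("pvd.", format))
  stage_file <- file.path(run_dir, paste0("stage_proportions.", format))
  ggplot2::ggsave(pvd_file, p_pvd, width = 9, height = 4.5, dpi = 150)
  ggplot2::ggsave(stage_file, p_stage, width = 7, height = 4, dpi = 150)
  invisible(c(pvd = pvd_file, stage_proportions = stage_file))
}
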