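# Event-ordering inference: likelihood, greedy ascent, MCMC over
# permutations, positional variance diagrams, and bootstrap cross-validation.

# Normalize an ordering to integer indices into `labels` and check that it is
# a permutation.
ordering_to_indices <- function(ordering, labels) {
  if (is.character(ordering)) {
    idx <- match(ordering, labels)
    if (anyNA(idx)) {
      abort_schema(paste0("Ordering contains unknown region(s): ",
                          paste(ordering[is.na(idx)], collapse = ", ")))
    }
  } else {
    idx <- as.integer(ordering)
  }
  n <- length(labels)
  if (length(idx) != n || !setequal(idx, seq_len(n))) {
    abort_validation("Ordering must be a permutation of the region set.")
  }
  idx
}

ensure_patients_only <- function(data, allow_controls = FALSE) {
  if (!allow_controls && any(data$group != "patient")) {
    abort_validation(paste0("Ordering inference runs on patient rows only; ",
                            "filter with patient rows or set allow_controls = TRUE."))
  }
  if (nrow(data) == 0) {
    abort_validation("No subjects available for the ordering likelihood.")
  }
  data
}

#' Log-likelihood of an event ordering
#'
#' For each patient the likelihood marginalizes a uniform prior over stages
#' k = 0..N of the product of event densities for the first k ordered regions
#' and no-event densities for the rest, computed in the log domain.
#'
#' @param ordering Character vector of region labels or integer indices into
#'   `fits$region`; must be a permutation.
#' @param data Biomarker table restricted to patients (set
#'   `allow_controls = TRUE` to override).
#' @param fits An `ebm_mixture_fits` tibble covering all regions.
#' @param allow_controls Permit non-patient rows (e.g. for staging research).
#' @return The log-likelihood (a single number).
#' @export
ordering_log_likelihood <- function(ordering, data, fits, allow_controls = FALSE) {
  data <- ensure_patients_only(data, allow_controls)
  mats <- event_log_density_matrices(data, fits)
  idx <- ordering_to_indices(ordering, mats$labels)
  ebm_loglik_cpp(mats$log_e, mats$log_h, idx)
}

#' Greedy pairwise-swap ascent over orderings
#'
#' From each random start permutation, repeatedly applies the best improving
#' pairwise swap until no swap improves the likelihood; the best ordering
#' across restarts is returned. Used to initialize the MCMC and, per
#' replicate, inside cross-validation.
#'
#' @inheritParams ordering_log_likelihood
#' @param restarts Number of random starts (>= 1).
#' @param seed Optional integer seed.
#' @return A list with `ordering` (region labels), `loglik`.
#' @export
greedy_ascent <- function(data, fits, restarts = 10, seed = NULL,
                          allow_controls = FALSE) {
  if (restarts < 1) abort_validation("restarts must be >= 1.")
  data <- ensure_patients_only(data, allow_controls)
  mats <- event_log_density_matrices(data, fits)
  n <- length(mats$labels)
  with_seed_if(seed, {
    best <- NULL
    for (r in seq_len(restarts)) {
      start <- if (r == 1) seq_len(n) else sample.int(n)
      res <- ebm_greedy_cpp(mats$log_e, mats$log_h, start)
      if (is.null(best) || res$loglik > best$loglik) best <- res
    }
    list(ordering = mats$labels[best$ordering], loglik = best$loglik)
  })
}

#' Sample the posterior over event orderings by MCMC
#'
#' Metropolis chain over permutations with a symmetric two-position swap
#' proposal and a uniform prior over orderings, run on patient data only. The
#' maximum-likelihood (MAP) ordering is the best state visited anywhere in the
#' chain, including the initial state.
#'
#' @inheritParams ordering_log_likelihood
#' @param init Initial ordering (labels or indices). Default: greedy ascent
#'   with `restarts` random starts.
#' @param n_iter Total Metropolis iterations (default 100000).
#' @param burn_in Iterations discarded before retaining samples (default 10000).
#' @param restarts Greedy restarts used when `init` is `NULL`.
#' @param seed Optional integer seed covering both initialization and chain.
#' @return An object of class `ebm_posterior`: retained samples (matrix of
#'   region indices, one row per retained iteration), their log-likelihoods,
#'   the MAP ordering and log-likelihood, acceptance rate, region labels,
#'   `burn_in` and `seed`.
#' @export
mcmc_sample <- function(data, fits, init = NULL, n_iter = 100000,
                        burn_in = 10000, restarts = 10, seed = NULL,
                        allow_controls = FALSE) {
  if (!(n_iter > burn_in && burn_in >= 0)) {
    abort_validation("Need n_iter > burn_in >= 0.")
  }
  data <- ensure_patients_only(data, allow_controls)
  mats <- event_log_density_matrices(data, fits)
  n <- length(mats$labels)
  with_seed_if(seed, {
    if (is.null(init)) {
      init_idx <- seq_len(n)
      best <- ebm_greedy_cpp(mats$log_e, mats$log_h, init_idx)
      if (restarts > 1) {
        for (r in seq_len(restarts - 1)) {
          res <- ebm_greedy_cpp(mats$log_e, mats$log_h, sample.int(n))
          if (res$loglik > best$loglik) best <- res
        }
      }
      init_idx <- as.integer(best$ordering)
    } else {
      init_idx <- ordering_to_indices(init, mats$labels)
    }
    chain <- ebm_mcmc_cpp(mats$log_e, mats$log_h, init_idx,
                          as.integer(n_iter), as.integer(burn_in))
    structure(
      list(
        samples = chain$samples,
        sample_loglik = chain$sample_loglik,
        map = mats$labels[chain$map],
        map_loglik = chain$map_loglik,
        acceptance_rate = chain$acceptance_rate,
        regions = mats$labels,
        n_iter = n_iter, burn_in = burn_in, seed = seed
      ),
      class = "ebm_posterior"
    )
  })
}

#' @export
print.ebm_posterior <- function(x, ...) {
  cat("Event-ordering posterior:", nrow(x$samples), "retained samples over",
      length(x$regions), "regions\n")
  cat("MAP ordering:", paste(x$map, collapse = " > "), "\n")
  cat(sprintf("MAP log-likelihood: %.3f  acceptance rate: %.3f\n",
              x$map_loglik, x$acceptance_rate))
  invisible(x)
}

#' Positional variance diagram
#'
#' Builds the N x N matrix whose entry (i, p) is the fraction of posterior (or
#' cross-validation) samples placing event i at sequence position p. Rows are
#' indexed in the order of `reference` (by default the MAP ordering), matching
#' the convention of plotting the inferred order down the y-axis.
#'
#' @param samples An `ebm_posterior`, an `ebm_cv` result, or a matrix of
#'   orderings (one row per sample, entries = region indices).
#' @param reference Reference ordering for the row order (labels or indices).
#'   Defaults to the MAP ordering for posteriors, the modal replicate ordering
#'   for cross-validation results, and the first row for plain matrices.
#' @param regions Region labels, required for plain matrices.
#' @return A matrix of class `ebm_pvd` with region labels as row names; every
#'   row and every column sums to 1.
#' @export
positional_variance <- function(samples, reference = NULL, regions = NULL) {
  if (inherits(samples, "ebm_posterior")) {
    regions <- samples$regions
    if (is.null(reference)) reference <- samples$map
    samples <- samples$samples
  } else if (inherits(samples, "ebm_cv")) {
    regions <- samples$regions
    if (is.null(reference)) reference <- samples$reference
    samples <- samples$orderings
  } else {
    samples <- as.matrix(samples)
    if (is.null(regions)) {
      abort_schema("Region labels are required when passing a plain sample matrix.")
    }
    if (is.null(reference)) reference <- samples[1, ]
  }
  n <- length(regions)
  if (nrow(samples) < 1) abort_validation("At least one sample is required.")
  if (ncol(samples) != n ||
      !all(apply(samples, 1, function(s) setequal(s, seq_len(n))))) {
    abort_schema("Every sample must be a permutation of the region set.")
  }
  ref_idx <- ordering_to_indices(reference, regions)
  counts <- matrix(0, n, n)
  for (p in seq_len(n)) {
    tab <- tabulate(samples[, p], nbins = n)
    counts[, p] <- tab
  }
  v <- counts[ref_idx, , drop = FALSE] / nrow(samples)
  dimnames(v) <- list(regions[ref_idx], paste0("pos_", seq_len(n)))
  structure(v, reference = regions[ref_idx], class = c("ebm_pvd", "matrix", "array"))
}

#' Mean row entropy of a positional variance diagram
#'
#' Natural-log entropy of each event's positional distribution, averaged over
#' events; 0 for a point-mass (permutation-matrix) PVD, larger for more
#' positional uncertainty.
#'
#' @param pvd An [positional_variance()] matrix.
#' @return Mean row entropy in nats.
#' @export
pvd_entropy <- function(pvd) {
  rows <- apply(unclass(pvd), 1, function(p) {
    p <- p[p > 0]
    -sum(p * log(p))
  })
  mean(rows)
}

#' Normalized Kendall tau distance between two orderings
#'
#' The fraction of region pairs whose relative order differs between the two
#' orderings; 0 for identical orderings, 1 for exact reversal.
#'
#' @param a,b Orderings as character label vectors (same label set).
#' @return A number in `[0, 1]`.
#' @export
kendall_distance <- function(a, b) {
  if (!setequal(a, b) || length(a) != length(b)) {
    abort_validation("Orderings must be permutations of the same label set.")
  }
  n <- length(a)
  if (n < 2) return(0)
  pos_b <- match(a, b)
  disc <- 0L
  for (i in seq_len(n - 1)) {
    disc <- disc + sum(pos_b[(i + 1):n] < pos_b[i])
  }
  disc / choose(n, 2)
}

#' Bootstrap cross-validation of the event ordering
#'
#' Resamples patients and controls with replacement (within group, preserving
#' group sizes), refits the control model and a single direct mixture fit per
#' region under weak constraints, re-estimates the most likely ordering, and
#' accumulates the replicate orderings into a positional variance diagram.
#' This deliberately overstates ordering uncertainty relative to the MCMC
#' posterior, giving a conservative picture.
#'
#' @param data A validated biomarker table with both groups.
#' @param B Number of bootstrap replicates (default 10000).
#' @param theta_bounds,sigma_d_min Weak constraints applied to every region
#'   (defaults from [weak_constraints()]).
#' @param subjects Which values enter the per-replicate mixture fit
#'   (`"pooled"` or `"patients"`).
#' @param restarts Greedy restarts per replicate (default 5).
#' @param mcmc Optionally run a full MCMC per replicate instead of greedy
#'   ascent; a list of arguments for [mcmc_sample()] (e.g.
#'   `list(n_iter = 20000, burn_in = 2000)`), or `NULL` (default) for greedy.
#' @param reference Reference ordering for the PVD rows (e.g. the MCMC MAP);
#'   default: the modal replicate ordering.
#' @param seed Optional integer seed.
#' @return An object of class `ebm_cv`: `pvd`, `orderings` (matrix of region
#'   indices, one row per successful replicate), `loglik` per replicate,
#'   `n_failed`, `regions`, `reference`, `B`, `seed`.
#' @export
cross_validate_ordering <- function(data, B = 10000,
                                    theta_bounds = weak_constraints()$theta_bounds,
                                    sigma_d_min = weak_constraints()$sigma_d_min,
                                    subjects = c("pooled", "patients"),
                                    restarts = 5, mcmc = NULL,
                                    reference = NULL, seed = NULL) {
  if (B < 1) abort_validation("B must be >= 1.")
  subjects <- match.arg(subjects)
  pats <- patient_rows(data)
  ctrls <- control_rows(data)
  if (nrow(pats) < 1 || nrow(ctrls) < 1) {
    abort_validation("Cross-validation requires both patients and controls.")
  }
  labels <- region_cols(data)
  n <- length(labels)
  with_seed_if(seed, {
    orderings <- matrix(NA_integer_, B, n)
    logliks <- rep(NA_real_, B)
    n_failed <- 0L
    for (b in seq_len(B)) {
      res <- tryCatch({
        pb <- pats[sample.int(nrow(pats), replace = TRUE), ]
        cb <- ctrls[sample.int(nrow(ctrls), replace = TRUE), ]
        boot <- dplyr::bind_rows(cb, pb)
        fits <- fit_mixture_models(boot, subjects = subjects, B = 0,
                                   theta_bounds = theta_bounds,
                                   sigma_d_min = sigma_d_min)
        if (is.null(mcmc)) {
          g <- greedy_ascent(pb, fits, restarts = restarts)
          list(ordering = g$ordering, loglik = g$loglik)
        } else {
          args <- c(list(data = pb, fits = fits, restarts = restarts), mcmc)
          post <- do.call(mcmc_sample, args)
          list(ordering = post$map, loglik = post$map_loglik)
        }
      }, error = function(e) e)
      if (inherits(res, "error")) {
        n_failed <- n_failed + 1L
      } else {
        orderings[b, ] <- match(res$ordering, labels)
        logliks[b] <- res$loglik
      }
    }
    if (n_failed > B / 2) {
      abort_estimation(paste0("Cross-validation failed on ", n_failed, " of ", B,
                              " replicates."))
    }
    ok <- !is.na(logliks)
    orderings <- orderings[ok, , drop = FALSE]
    logliks <- logliks[ok]
    if (is.null(reference)) {
      keys <- apply(orderings, 1, paste, collapse = ",")
      modal <- names(which.max(table(keys)))
      reference <- labels[as.integer(strsplit(modal, ",")[[1]])]
    } else if (!is.character(reference)) {
      reference <- labels[ordering_to_indices(reference, labels)]
    }
    out <- structure(
      list(orderings = orderings, loglik = logliks, n_failed = n_failed,
           regions = labels, reference = reference, B = B, seed = seed),
      class = "ebm_cv"
    )
    out$pvd <- positional_variance(out)
    out
  })
}

#' @export
print.ebm_cv <- function(x, ...) {
  cat("Bootstrap cross-validation:", nrow(x$orderings), "of", x$B,
      "replicates succeeded (", x$n_failed, "failed )\n")
  cat("Reference ordering:", paste(x$reference, collapse = " > "), "\n")
  invisible(x)
}

#' @export
tidy.ebm_posterior <- function(x, ...) {
  tidy(positional_variance(x))
}

#' @export
glance.ebm_posterior <- function(x, ...) {
  tibble::tibble(
    n_samples = nrow(x$samples),
    n_iter = x$n_iter,
    burn_in = x$burn_in,
    acceptance_rate = x$acceptance_rate,
    map_loglik = x$map_loglik
  )
}

#' @export
tidy.ebm_pvd <- function(x, ...) {
  m <- unclass(x)
  tibble::tibble(
    region = rep(rownames(m), times = ncol(m)),
    position = rep(seq_len(ncol(m)), each = nrow(m)),
    probability = as.vector(m)
  )
}

#' @export
glance.ebm_cv <- function(x, ...) {
  tibble::tibble(
    B = x$B,
    n_success = nrow(x$orderings),
    n_failed = x$n_failed,
    mean_row_entropy = pvd_entropy(x$pvd)
  )
}
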