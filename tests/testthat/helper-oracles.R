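# Shared fixtures and independent oracles for the test suite. Every oracle
# here is deliberately written in plain R (exhaustive enumeration, direct
# probability products at small N) and never calls the package's C++ path.

# All permutations of a vector (fine for n <= 6).
perms <- function(v) {
  if (length(v) <= 1) return(list(v))
  out <- list()
  for (i in seq_along(v)) {
    for (p in perms(v[-i])) out[[length(out) + 1]] <- c(v[i], p)
  }
  out
}

# Brute-force ordering log-likelihood: explicit double loop over patients and
# stages, probability products in the raw (non-log) domain.
brute_ordering_loglik <- function(ordering, patients, fits) {
  labels <- fits$region
  n <- length(labels)
  total <- 0
  for (j in seq_len(nrow(patients))) {
    x <- setNames(as.numeric(patients[j, labels]), labels)
    pe <- setNames(dnorm(x, fits$mu_d, fits$sigma_d), labels)
    ph <- setNames(dnorm(x, fits$mu_h, fits$sigma_h), labels)
    s <- 0
    for (k in 0:n) {
      before <- ordering[seq_len(k)]
      after <- setdiff(ordering, before)
      s <- s + prod(pe[before]) * prod(ph[after]) / (n + 1)
    }
    total <- total + log(s)
  }
  total
}

# Exhaustive maximum-likelihood ordering (the oracle the search must match).
exhaustive_best_ordering <- function(patients, fits) {
  cand <- perms(fits$region)
  ll <- vapply(cand, brute_ordering_loglik, numeric(1),
               patients = patients, fits = fits)
  cand[[which.max(ll)]]
}

# A mixture-fit table built directly from generating parameters (oracle fits
# that bypass estimation entirely).
oracle_fits <- function(params, theta = 0.5) {
  out <- tibble::tibble(
    region = params$region,
    mu_h = params$mu_h, sigma_h = params$sigma_h,
    mu_d = params$mu_d, sigma_d = params$sigma_d,
    theta = theta, loglik = NA_real_, converged = TRUE, collapsed = FALSE
  )
  structure(out, class = c("ebm_mixture_fits", class(out)))
}

# Fits in which event and no-event densities coincide: the ordering
# likelihood is then flat over all permutations.
flat_fits <- function(fits) {
  fits$mu_d <- fits$mu_h
  fits$sigma_d <- fits$sigma_h
  fits
}

# Small synthetic cohort with custom labels; strong separation by default.
sim_small <- function(n_regions = 4, n_patients = 80, n_controls = 60,
                      separation = 3, seed = 1, ...) {
  labels <- paste0("R", seq_len(n_regions))
  simulate_cohort(
    region_set = labels,
    params = default_fa_params(labels, separation = separation),
    n_patients = n_patients, n_controls = n_controls, seed = seed, ...
  )
}

patients_of <- function(cohort) dplyr::filter(cohort$data, group == "patient")
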