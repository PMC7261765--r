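# Ordering likelihood, greedy ascent, MCMC, positional variance, Kendall
# distance, and cross-validation.

test_that("ordering likelihood matches the brute-force oracle", {
  co <- sim_small(n_regions = 3, n_patients = 40, n_controls = 50, seed = 41)
  fits <- fit_mixture_models(co$data, B = 0)
  pats <- patients_of(co)
  for (ord in perms(fits$region)) {
    expect_equal(ordering_log_likelihood(ord, pats, fits),
                 brute_ordering_loglik(ord, pats, fits), tolerance = 1e-9)
  }
})

test_that("single-event likelihood reduces to the marginal density", {
  # with p_E = p_notE = g everywhere the stage sum collapses: LL = log g
  fit <- oracle_fits(default_fa_params("R1"))
  fit <- flat_fits(fit)
  pat <- tibble::tibble(subject_id = "p1", group = "patient", R1 = 0.57)
  g <- dnorm(0.57, fit$mu_h, fit$sigma_h)
  expect_equal(ordering_log_likelihood("R1", pat, fit), log(g))
})

test_that("flat densities make every ordering equally likely", {
  co <- sim_small(n_regions = 4, n_patients = 30, n_controls = 30, seed = 42)
  fits <- flat_fits(fit_mixture_models(co$data, B = 0))
  pats <- patients_of(co)
  lls <- vapply(perms(fits$region), ordering_log_likelihood, numeric(1),
                data = pats, fits = fits)
  expect_lt(max(lls) - min(lls), 1e-9)
})

test_that("likelihood is invariant to patient row order and region relabeling", {
  co <- sim_small(n_regions = 4, n_patients = 50, n_controls = 40, seed = 43)
  fits <- fit_mixture_models(co$data, B = 0)
  pats <- patients_of(co)
  ord <- c("R3", "R1", "R4", "R2")
  ll <- ordering_log_likelihood(ord, pats, fits)

  shuffled <- pats[rev(seq_len(nrow(pats))), ]
  expect_equal(ordering_log_likelihood(ord, shuffled, fits), ll,
               tolerance = 1e-13)

  # relabel regions (R1<->R2) in both data and fits, and in the ordering
  relab <- function(x) dplyr::recode(x, R1 = "R2", R2 = "R1")
  pats2 <- dplyr::rename(pats, R2 = "R1", R1 = "R2")
  fits2 <- dplyr::mutate(fits, region = relab(region))
  expect_equal(ordering_log_likelihood(relab(ord), pats2, fits2), ll,
               tolerance = 1e-12)
})

test_that("control rows are rejected unless explicitly allowed", {
  co <- sim_small(n_regions = 3, n_patients = 20, n_controls = 20, seed = 44)
  fits <- fit_mixture_models(co$data, B = 0)
  expect_error(ordering_log_likelihood(fits$region, co$data, fits),
               class = "ebmseq_validation_error")
  ll_all <- suppressWarnings(
    ordering_log_likelihood(fits$region, co$data, fits, allow_controls = TRUE)
  )
  expect_true(is.finite(ll_all))
  expect_error(ordering_log_likelihood(fits$region, patients_of(co)[0, ], fits),
               class = "ebmseq_validation_error")
  expect_error(ordering_log_likelihood(c("R1", "R2"), patients_of(co), fits),
               class = "ebmseq_validation_error")
})

test_that("greedy ascent finds the exhaustive optimum under strong separation", {
  co <- sim_small(n_regions = 4, n_patients = 120, n_controls = 80, seed = 45)
  fits <- fit_mixture_models(co$data, B = 0)
  pats <- patients_of(co)
  best <- exhaustive_best_ordering(pats, fits)
  g <- greedy_ascent(pats, fits, restarts = 5, seed = 1)
  expect_equal(g$ordering, best)
  expect_equal(g$loglik, brute_ordering_loglik(best, pats, fits),
               tolerance = 1e-9)
})

test_that("greedy ascent terminates on flat likelihoods with a valid permutation", {
  co <- sim_small(n_regions = 5, n_patients = 20, n_controls = 20, seed = 46)
  fits <- flat_fits(fit_mixture_models(co$data, B = 0))
  g <- greedy_ascent(patients_of(co), fits, restarts = 2, seed = 2)
  expect_setequal(g$ordering, fits$region)
})

test_that("a single-event chain is degenerate and exact", {
  fit <- oracle_fits(default_fa_params("R1"))
  pats <- tibble::tibble(subject_id = c("p1", "p2"), group = "patient",
                         R1 = c(0.5, 0.56))
  post <- mcmc_sample(pats, fit, n_iter = 50, burn_in = 10, seed = 3)
  expect_true(all(post$samples == 1))
  expect_equal(post$acceptance_rate, 1)
  expect_equal(post$map, "R1")
  g <- greedy_ascent(pats, fit, restarts = 1, seed = 1)
  expect_equal(g$ordering, "R1")
})

test_that("MCMC is reproducible from its seed", {
  co <- sim_small(n_regions = 4, n_patients = 60, n_controls = 40, seed = 47)
  fits <- fit_mixture_models(co$data, B = 0)
  a <- mcmc_sample(patients_of(co), fits, n_iter = 2000, burn_in = 200, seed = 11)
  b <- mcmc_sample(patients_of(co), fits, n_iter = 2000, burn_in = 200, seed = 11)
  expect_identical(a$samples, b$samples)
  expect_identical(a$map, b$map)
})

test_that("MCMC MAP matches the exhaustive optimum (N = 5)", {
  co <- sim_small(n_regions = 5, n_patients = 150, n_controls = 100, seed = 48)
  fits <- fit_mixture_models(co$data, B = 0)
  pats <- patients_of(co)
  best <- exhaustive_best_ordering(pats, fits)
  post <- mcmc_sample(pats, fits, n_iter = 5000, burn_in = 500, seed = 4)
  expect_equal(post$map, best)
})

test_that("with flat densities the chain explores positions uniformly", {
  co <- sim_small(n_regions = 5, n_patients = 30, n_controls = 20, seed = 49)
  fits <- flat_fits(fit_mixture_models(co$data, B = 0))
  post <- mcmc_sample(patients_of(co), fits, n_iter = 50000, burn_in = 0,
                      seed = 5, init = fits$region)
  pvd <- positional_variance(post, reference = fits$region)
  # every proposal is accepted on a flat target
  expect_equal(post$acceptance_rate, 1)
  # naive MC SE inflated ~4x for swap-chain autocorrelation at N=5
  tol <- 3 * sqrt(0.2 * 0.8 * 4 / nrow(post$samples))
  expect_lt(max(abs(unclass(pvd) - 0.2)), tol)
})

test_that("positional variance diagrams count positions correctly", {
  regions <- paste0("R", 1:4)
  ref <- 1:4
  # point mass: identity matrix
  pv <- positional_variance(matrix(rep(1:4, 10), 10, byrow = TRUE),
                            reference = ref, regions = regions)
  expect_equal(unclass(pv), diag(4), ignore_attr = TRUE)
  # two orderings differing by one swap, equal counts
  m <- rbind(c(1, 2, 3, 4), c(2, 1, 3, 4))
  pv2 <- positional_variance(m, reference = ref, regions = regions)
  expect_equal(pv2["R1", "pos_1"], 0.5)
  expect_equal(pv2["R2", "pos_1"], 0.5)
  expect_equal(pv2["R3", "pos_3"], 1)
  # row order follows the reference ordering
  pv3 <- positional_variance(m, reference = c(4, 3, 2, 1), regions = regions)
  expect_equal(rownames(pv3), paste0("R", 4:1))
})

test_that("PVDs are doubly stochastic for arbitrary sample sets", {
  set.seed(51)
  m <- t(replicate(200, sample.int(6)))
  pv <- positional_variance(m, regions = paste0("R", 1:6))
  expect_true(all(abs(rowSums(pv) - 1) < 1e-12))
  expect_true(all(abs(colSums(pv) - 1) < 1e-12))
  expect_error(positional_variance(cbind(m[, 1:5], m[, 5]),
                                   regions = paste0("R", 1:6)),
               class = "ebmseq_schema_error")
})

test_that("pvd entropy separates point mass from uniform", {
  ident <- positional_variance(matrix(1:3, 1), regions = paste0("R", 1:3))
  expect_equal(pvd_entropy(ident), 0)
  unif <- structure(matrix(1 / 3, 3, 3, dimnames = list(paste0("R", 1:3), NULL)),
                    class = c("ebm_pvd", "matrix", "array"))
  expect_equal(pvd_entropy(unif), log(3))
})

test_that("kendall distance counts discordant pairs", {
  a <- paste0("R", 1:5)
  expect_equal(kendall_distance(a, a), 0)
  expect_equal(kendall_distance(a, rev(a)), 1)
  expect_equal(kendall_distance(a, c("R2", "R1", "R3", "R4", "R5")), 1 / 10)
  expect_error(kendall_distance(a, paste0("R", 1:4)),
               class = "ebmseq_validation_error")
})

test_that("cross-validation accumulates replicate orderings into a PVD", {
  co <- sim_small(n_regions = 4, n_patients = 100, n_controls = 80,
                  separation = 4, seed = 52)
  cv <- cross_validate_ordering(co$data, B = 12, seed = 6)
  expect_equal(nrow(cv$orderings) + cv$n_failed, 12)
  expect_true(all(abs(rowSums(cv$pvd) - 1) < 1e-12))
  # strong separation: every replicate recovers the same ordering -> permutation matrix
  expect_true(all(unclass(cv$pvd) %in% c(0, 1)))
  # reproducible from seed
  cv2 <- cross_validate_ordering(co$data, B = 12, seed = 6)
  expect_identical(cv$orderings, cv2$orderings)
  expect_error(cross_validate_ordering(patients_of(co), B = 2),
               class = "ebmseq_validation_error")
})
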