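# Constrained mixture fitting: projected EM, bootstrap-median
# robustification, and the event/no-event densities they supply.

sample_mixture <- function(n, theta, mu_h, sigma_h, mu_d, sigma_d) {
  z <- runif(n) < theta
  ifelse(z, rnorm(n, mu_h, sigma_h), rnorm(n, mu_d, sigma_d))
}

test_that("EM recovers all five parameters of a well-separated mixture", {
  set.seed(31)
  x <- sample_mixture(400, 0.5, 0.55, 0.02, 0.45, 0.03)
  cm <- fit_control_gaussian(rnorm(200, 0.55, 0.02))
  fit <- fit_constrained_mixture(x, cm)
  truth <- c(0.55, 0.02, 0.45, 0.03, 0.5)
  est <- c(fit$mu_h, fit$sigma_h, fit$mu_d, fit$sigma_d, fit$theta)
  expect_true(all(abs(est - truth) / truth < 0.10))
  expect_true(fit$converged)
  expect_false(fit$collapsed)
})

test_that("one-component data drives theta toward a bound", {
  cm <- withr::with_seed(32, fit_control_gaussian(rnorm(200, 0.55, 0.02)))
  # pure-control data: theta driven high, remaining "diseased" mass is a
  # sliver of the control tail, inside the control band
  fit_h <- withr::with_seed(32,
                            fit_constrained_mixture(rnorm(300, 0.55, 0.02), cm))
  expect_gte(fit_h$theta, 0.8)
  expect_gt(fit_h$mu_d, cm$mu - 3 * cm$sigma)
  # data wholly from a remote diseased distribution: the anchored healthy
  # component loses all mass and the collapse flag fires
  fit_d <- withr::with_seed(1,
                            fit_constrained_mixture(rnorm(300, 0.40, 0.025), cm))
  expect_lte(fit_d$theta, 1e-3)
  expect_true(fit_d$collapsed)
})

test_that("per-region mixing-proportion bounds are honoured", {
  set.seed(33)
  # data favouring a small healthy proportion
  x <- sample_mixture(300, 0.2, 0.55, 0.02, 0.45, 0.03)
  cm <- fit_control_gaussian(rnorm(200, 0.55, 0.02))
  fit <- fit_constrained_mixture(x, cm, theta_bounds = c(0.5, 1))
  expect_gte(fit$theta, 0.5)
})

test_that("constraint satisfaction is assertable on every returned fit", {
  set.seed(34)
  for (rep in 1:5) {
    x <- sample_mixture(200, runif(1, 0.3, 0.7), 0.55, 0.02, 0.46, 0.03)
    cm <- fit_control_gaussian(rnorm(150, 0.55, 0.02))
    fit <- fit_constrained_mixture(x, cm)
    expect_true(cm$mu_lo <= fit$mu_h && fit$mu_h <= cm$mu_hi)
    expect_true(cm$sigma_lo <= fit$sigma_h && fit$sigma_h <= cm$sigma_hi)
    expect_true(fit$theta >= 0 && fit$theta <= 1)
  }
})

test_that("unconstrained EM matches an independent reference fit", {
  library(mclust)
  set.seed(35)
  x <- sample_mixture(400, 0.5, 0.55, 0.02, 0.42, 0.03)
  cm <- fit_control_gaussian(rnorm(200, 0.55, 0.02))
  mine <- fit_constrained_mixture(x, cm, constrain = FALSE, tol = 1e-10)
  ref <- mclust::Mclust(x, G = 2, modelNames = "V", verbose = FALSE,
                        control = mclust::emControl(tol = c(1e-10, 1e-10)))
  expect_equal(mine$loglik, ref$loglik, tolerance = 1e-6)
})

test_that("median aggregation drops collapsed replicates", {
  reps <- tibble::tibble(
    mu_h = c(0.5, 0.55, 0.6, 0.7), sigma_h = c(0.02, 0.02, 0.02, 0.5),
    mu_d = c(0.4, 0.45, 0.5, 0.1), sigma_d = c(0.03, 0.03, 0.03, 9),
    theta = c(0.3, 0.5, 0.7, 0.0), loglik = c(1, 2, 3, 4),
    converged = TRUE, collapsed = c(FALSE, FALSE, FALSE, TRUE)
  )
  agg <- aggregate_bootstrap_fits(reps, region = "R1")
  expect_equal(agg$theta, 0.5)
  expect_equal(agg$mu_h, 0.55)
  expect_equal(agg$n_retained, 3)
  expect_equal(agg$B, 4)

  all_collapsed <- dplyr::mutate(reps, collapsed = TRUE)
  expect_error(aggregate_bootstrap_fits(all_collapsed, region = "R1"),
               regexp = "R1", class = "ebmseq_estimation_error")
})

test_that("bootstrap medians track the generating parameters", {
  # n sized so the 10% band on the scale parameters spans > 2.4 sampling SDs
  set.seed(36)
  x <- sample_mixture(600, 0.5, 0.55, 0.02, 0.43, 0.03)
  cm <- fit_control_gaussian(rnorm(300, 0.55, 0.02))
  fit <- bootstrap_median_fit(x, cm, B = 200, seed = 1)
  truth <- c(0.55, 0.02, 0.43, 0.03, 0.5)
  est <- c(fit$mu_h, fit$sigma_h, fit$mu_d, fit$sigma_d, fit$theta)
  expect_true(all(abs(est - truth) / truth < 0.10))
  expect_gt(fit$n_retained, 150)
})

test_that("a single uncollapsed bootstrap replicate equals the direct fit", {
  set.seed(37)
  x <- sample_mixture(300, 0.5, 0.55, 0.02, 0.45, 0.03)
  cm <- fit_control_gaussian(rnorm(200, 0.55, 0.02))
  boot <- bootstrap_median_fit(x, cm, B = 1, seed = 99)
  xb <- withr::with_seed(99L, x[sample.int(length(x), replace = TRUE)])
  direct <- fit_constrained_mixture(xb, cm)
  expect_equal(boot$mu_h, direct$mu_h)
  expect_equal(boot$theta, direct$theta)
  expect_equal(boot$loglik, direct$loglik)
})

test_that("retained fraction is non-increasing in the collapse tolerance", {
  set.seed(38)
  # weakly separated data so some replicates collapse
  x <- sample_mixture(80, 0.85, 0.55, 0.02, 0.51, 0.02)
  cm <- fit_control_gaussian(rnorm(100, 0.55, 0.02))
  fit <- bootstrap_median_fit(x, cm, B = 100, seed = 2, keep_replicates = TRUE)
  reps <- attr(fit, "replicates")
  retained <- vapply(c(1e-4, 1e-3, 1e-2, 0.1), function(eps) {
    sum(!is.na(reps$theta) & reps$theta > eps & reps$theta < 1 - eps)
  }, numeric(1))
  expect_true(all(diff(retained) <= 0))
})

test_that("production-scale bootstrap defaults are wired in", {
  expect_equal(eval(formals(bootstrap_median_fit)$B), 1000)
  expect_equal(eval(formals(fit_mixture_models)$B), 1000)
  expect_equal(eval(formals(cross_validate_ordering)$B), 10000)
  expect_equal(weak_constraints(),
               list(theta_bounds = c(0.01, 0.99), sigma_d_min = 0.001))
})

test_that("event densities are the component Gaussians", {
  fit <- tibble::tibble(mu_h = 0.55, sigma_h = 0.02, mu_d = 0.45, sigma_d = 0.03)
  d <- event_densities(fit, c(0.45, 0.55))
  expect_equal(d$p_event[1], 1 / (0.03 * sqrt(2 * pi)))
  expect_equal(d$p_no_event[2], 1 / (0.02 * sqrt(2 * pi)))
  # each component integrates to 1
  int_e <- stats::integrate(function(x) event_densities(fit, x)$p_event,
                            0.45 - 0.5, 0.45 + 0.5, rel.tol = 1e-10)
  int_h <- stats::integrate(function(x) event_densities(fit, x)$p_no_event,
                            0.55 - 0.5, 0.55 + 0.5, rel.tol = 1e-10)
  expect_lt(abs(int_e$value - 1), 1e-6)
  expect_lt(abs(int_h$value - 1), 1e-6)
})

test_that("table-level fitting honours per-region bounds and reports retention", {
  co <- sim_small(n_regions = 3, n_patients = 80, n_controls = 60, seed = 39)
  fits <- fit_mixture_models(co$data, B = 25, seed = 3,
                             theta_bounds = list(default = c(0, 1), R2 = c(0.6, 1)))
  expect_s3_class(fits, "ebm_mixture_fits")
  expect_equal(fits$region, paste0("R", 1:3))
  expect_gte(fits$theta[fits$region == "R2"], 0.6)
  expect_true(all(fits$n_retained >= 1 & fits$n_retained <= 25))
  expect_error(fit_mixture_models(dplyr::filter(co$data, group == "patient")),
               class = "ebmseq_validation_error")
})
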