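test_that("the logistic log posterior matches hand-computed values", {
  empty <- make_two_arm_cohort(1, 0, 1, 0)[0, ]
  m <- model_spec(site_term = "none")
  # no likelihood contribution: the joint log prior of the coefficients
  lp <- log_posterior_logistic(list(alpha = 0.3, beta = -0.2), empty, m)
  expect_equal(lp, dnorm(0.3, 0, 2.5, log = TRUE) +
                 dnorm(-0.2, 0, 0.355, log = TRUE), tolerance = 1e-12)
  # one record, arm = 1, death = 1, alpha = beta = 0: Bernoulli(expit(0))
  one <- make_two_arm_cohort(1, 1, 0, 0)
  lp1 <- log_posterior_logistic(list(alpha = 0, beta = 0), one, m)
  expect_equal(lp1, log(0.5) + dnorm(0, 0, 2.5, log = TRUE) +
                 dnorm(0, 0, 0.355, log = TRUE), tolerance = 1e-12)
  expect_error(log_posterior_logistic(list(alpha = Inf, beta = 0), one, m),
               "non-finite")
})

test_that("site deviations shift the hierarchical log posterior as densities dictate", {
  ds <- generate_cohort(make_small_config(n_per_arm = c(30, 30), n_sites = 3,
                                          largest_site_size = 22, seed = 1))
  m <- model_spec()  # random intercept
  base <- list(alpha = -0.7, beta = 0.1, log_tau = log(0.5), z = c(0, 0, 0))
  shifted <- base; shifted$z <- c(0.5, 0.5, 0.5)
  lp0 <- log_posterior_logistic(base, ds, m)
  lp1 <- log_posterior_logistic(shifted, ds, m)
  # a common shift of all site deviations changes the posterior (the
  # non-identifiability is absorbed by the priors), and both stay finite
  expect_true(is.finite(lp0) && is.finite(lp1))
  expect_false(isTRUE(all.equal(lp0, lp1)))
})

test_that("the Efron Cox partial likelihood matches hand computation and is scale-free", {
  d <- data.frame(time = c(1, 2), event = c(1, 1), x = c(1, 0))
  expect_equal(log_partial_likelihood_cox(0, d), -log(2), tolerance = 1e-12)
  # at beta = 0 the value ignores the covariate entirely
  dties <- data.frame(time = c(3, 3, 5, 5, 5, 8, 9, 9),
                      event = c(1, 1, 0, 1, 1, 1, 0, 1),
                      x = c(0.3, -1, 2, 0, 1, 1, 0, 0.5))
  dties2 <- dties; dties2$x <- rnorm(8)
  expect_equal(log_partial_likelihood_cox(0, dties),
               log_partial_likelihood_cox(0, dties2), tolerance = 1e-12)
  # scaling every time by a positive constant leaves the value unchanged
  dscaled <- dties; dscaled$time <- dties$time * 2.7
  for (b in c(-0.5, 0, 1.2))
    expect_equal(log_partial_likelihood_cox(b, dties),
                 log_partial_likelihood_cox(b, dscaled), tolerance = 1e-12)
  # all-censored data are rejected
  dcens <- dties; dcens$event <- 0
  expect_error(log_partial_likelihood_cox(0, dcens), "no events")
  expect_error(log_partial_likelihood_cox(0, transform(dties, time = time - 3)),
               "positive")
})

test_that("the flat-prior Cox maximiser matches an independent Cox fit", {
  skip_if_not_installed("survival")
  ds <- generate_cohort(make_small_config(n_per_arm = c(100, 100), n_sites = 4,
                                          largest_site_size = 80,
                                          beta_true = 0.3, seed = 21))
  sub <- prepare_subdistribution(ds)
  sub$x2 <- as.numeric(ds$sofa >= 9)
  ours <- cox_map(sub, covariates = c("arm", "x2"), flat = TRUE)
  ref <- survival::coxph(survival::Surv(time, event) ~ arm + x2, data = sub,
                         ties = "efron")
  expect_equal(unname(ours$coef), unname(coef(ref)), tolerance = 1e-4)
  expect_equal(ours$loglik, ref$loglik[2], tolerance = 1e-8)
})

test_that("sampled 2-parameter logistic posteriors match deterministic quadrature", {
  # deaths 10/20 under treatment vs 5/20 under control, sceptical prior
  ds <- make_two_arm_cohort(20, 10, 20, 5)
  oracle <- quadrature_logistic_2d(ds$death60, ds$arm)
  m <- model_spec(site_term = "none")
  draws <- sample_posterior(m, ds, n_chains = 4, n_iter = 8000,
                            n_warmup = 1500, seed = 31)
  b <- param_draws(draws, "beta")
  expect_equal(mean(b > 0), oracle$p_beta_pos, tolerance = 0.02)
  expect_lt(abs(quantile(b, 0.5) - oracle$q50), 0.02)
  expect_lt(abs(quantile(b, 0.025) - oracle$q025), 0.02)
  expect_lt(abs(quantile(b, 0.975) - oracle$q975), 0.02)
})

test_that("sampling is deterministic for a fixed seed", {
  ds <- make_two_arm_cohort(30, 9, 30, 7)
  m <- model_spec(site_term = "none")
  d1 <- sample_posterior(m, ds, n_chains = 2, n_iter = 200, n_warmup = 200,
                         seed = 5)
  d2 <- sample_posterior(m, ds, n_chains = 2, n_iter = 200, n_warmup = 200,
                         seed = 5)
  expect_identical(d1$draws, d2$draws)
  d3 <- sample_posterior(m, ds, n_chains = 2, n_iter = 200, n_warmup = 200,
                         seed = 6)
  expect_false(identical(d1$draws, d3$draws))
})

test_that("with no data the sampled treatment effect reproduces its prior", {
  empty <- make_two_arm_cohort(1, 0, 1, 0)[0, ]
  m <- model_spec(site_term = "none")
  draws <- sample_posterior(m, empty, n_chains = 4, n_iter = 3000,
                            n_warmup = 1000, seed = 13)
  b <- param_draws(draws, "beta")
  expect_equal(mean(b), 0, tolerance = 0.03)
  expect_equal(sd(b), 0.355, tolerance = 0.03)
  expect_equal(unname(quantile(b, c(0.025, 0.975))),
               c(-1, 1) * qnorm(0.975) * 0.355, tolerance = 0.06)
})

test_that("doubling the data contracts the posterior SD by about 1/sqrt(2)", {
  ds1 <- make_two_arm_cohort(200, 60, 200, 50)
  ds2 <- make_two_arm_cohort(400, 120, 400, 100)  # every record duplicated
  m <- model_spec(site_term = "none",
                  treatment_prior = weakly_informative_prior())
  s1 <- sd(param_draws(sample_posterior(m, ds1, n_chains = 4, n_iter = 2500,
                                        n_warmup = 1000, seed = 17), "beta"))
  s2 <- sd(param_draws(sample_posterior(m, ds2, n_chains = 4, n_iter = 2500,
                                        n_warmup = 1000, seed = 17), "beta"))
  expect_gt(s2 / s1, 0.65)
  expect_lt(s2 / s1, 0.75)
})

test_that("diagnostics recognise converged and divergent chains", {
  fake_draws <- function(mat) {
    structure(list(draws = array(mat, c(nrow(mat), ncol(mat), 1),
                                 dimnames = list(NULL, NULL, "beta")),
                   n_chains = ncol(mat), n_iterations = nrow(mat),
                   acceptance = cbind(global = rep(0.3, ncol(mat))),
                   meta = list(outcome = "mortality")),
              class = "posterior_draws")
  }
  set.seed(1)
  iid <- fake_draws(matrix(rnorm(4000), 1000, 4))
  di <- diagnose(iid)
  expect_gte(di$rhat[["beta"]], 1)
  expect_lt(di$rhat[["beta"]], 1.01)
  # ESS of independent draws is close to the number of draws
  expect_equal(di$ess_bulk[["beta"]], 4000, tolerance = 0.2)
  expect_true(di$acceptable)
  div <- fake_draws(cbind(matrix(rnorm(2000, -5), 1000, 2),
                          matrix(rnorm(2000, 5), 1000, 2)))
  dd <- diagnose(div)
  expect_gt(dd$rhat[["beta"]], 1.1)
  expect_false(dd$acceptable)
  one_chain <- fake_draws(matrix(rnorm(1000), 1000, 1))
  expect_error(diagnose(one_chain), "2 chains")
})

test_that("draws persist to long CSV and diagnostics to JSON", {
  ds <- make_two_arm_cohort(20, 6, 20, 5)
  m <- model_spec(site_term = "none")
  draws <- sample_posterior(m, ds, n_chains = 2, n_iter = 50, n_warmup = 100,
                            seed = 3)
  f <- withr::local_tempfile(fileext = ".csv")
  write_draws_csv(draws, f)
  long <- read.csv(f)
  expect_equal(nrow(long), 2 * 50 * 2)
  expect_setequal(unique(long$parameter), c("alpha", "beta"))
  expect_equal(long$value[long$parameter == "beta" & long$chain == 1],
               unname(param_draws(draws, "beta", merge = FALSE)[, 1]))
  fj <- withr::local_tempfile(fileext = ".json")
  write_diagnostics_json(diagnose(draws), fj)
  parsed <- jsonlite::read_json(fj)
  expect_true(all(c("rhat", "ess_bulk", "ess_tail", "acceptable") %in%
                    names(parsed)))
})
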