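# Shared fixtures and independent oracles for the test suite.

# Small synthetic cohort with configurable truth; single dominant site plus a
# few small ones so hierarchical fits stay cheap.
make_small_config <- function(n_per_arm = c(200, 200), n_sites = 5,
                              largest_site_size = NULL, beta_true = 0,
                              site_sd = 0.2, seed = 1, ...) {
  n_total <- sum(n_per_arm)
  if (is.null(largest_site_size))
    largest_site_size <- ceiling(n_total / 2)
  generator_config(n_per_arm = n_per_arm, n_sites = n_sites,
                   largest_site_size = largest_site_size,
                   beta_true = beta_true, site_sd = site_sd,
                   gamma_creatinine = 0, gamma_sofa = 0, gamma_bmi = 0,
                   n_missing_outcome = 0, n_missing_creatinine = 0,
                   seed = seed, ...)
}

# Hand-rolled two-arm dataset: one site, fixed death counts per arm.
make_two_arm_cohort <- function(n1, d1, n0, d0, site = "S01") {
  n <- n1 + n0
  trial_dataset(data.frame(
    patient_id = sprintf("P%04d", seq_len(n)),
    site_id = site,
    arm = rep(c(1L, 0L), c(n1, n0)),
    death60 = c(rep(c(1L, 0L), c(d1, n1 - d1)), rep(c(1L, 0L), c(d0, n0 - d0))),
    t_discharge = rep(30, n), discharge_event = 0L, died_in_hospital = 0L,
    sofa = 9L, creatinine = 90, bmi = 28, aki = 0L))
}

# Deterministic grid-quadrature oracle for the 2-parameter (alpha, beta)
# logistic posterior with independent normal priors. Independent of the
# package's log-posterior code: the Bernoulli likelihood is written out here.
quadrature_logistic_2d <- function(y, arm, prior_alpha = c(0, 2.5),
                                   prior_beta = c(0, 0.355),
                                   lim = 4, n_grid = 601) {
  # wide grids spanning both the prior mass and the likelihood mode, so the
  # posterior (which lies between them) is fully covered
  fit <- suppressWarnings(stats::glm(y ~ arm, family = stats::binomial()))
  a_hat <- stats::coef(fit)[1]; b_hat <- stats::coef(fit)[2]
  if (!is.finite(a_hat)) a_hat <- prior_alpha[1]
  if (!is.finite(b_hat)) b_hat <- prior_beta[1]
  a_grid <- seq(min(a_hat, prior_alpha[1]) - lim,
                max(a_hat, prior_alpha[1]) + lim, length.out = n_grid)
  b_grid <- seq(min(b_hat, prior_beta[1]) - lim * max(prior_beta[2], 0.3) - 1,
                max(b_hat, prior_beta[1]) + lim * max(prior_beta[2], 0.3) + 1,
                length.out = n_grid)
  ll <- matrix(0, n_grid, n_grid)
  for (i in seq_len(n_grid)) {
    eta1 <- a_grid[i] + b_grid          # arm = 1
    eta0 <- a_grid[i]                   # arm = 0
    n1 <- sum(arm == 1); d1 <- sum(y[arm == 1])
    n0 <- sum(arm == 0); d0 <- sum(y[arm == 0])
    ll[i, ] <- d1 * eta1 - n1 * log1p(exp(eta1)) +
      d0 * eta0 - n0 * log1p(exp(eta0))
  }
  lp <- ll + outer(stats::dnorm(a_grid, prior_alpha[1], prior_alpha[2],
                                log = TRUE),
                   stats::dnorm(b_grid, prior_beta[1], prior_beta[2],
                                log = TRUE), "+")
  w <- exp(lp - max(lp))
  w <- w / sum(w)
  marg_b <- colSums(w)
  cdf <- cumsum(marg_b)
  qtl <- function(p) stats::approx(cdf, b_grid, p, ties = "ordered")$y
  list(p_beta_pos = sum(marg_b[b_grid > 0]),
       q025 = qtl(0.025), q50 = qtl(0.5), q975 = qtl(0.975),
       mean = sum(marg_b * b_grid))
}

# Assemble a posterior_draws object from given per-parameter draw vectors
# (single chain duplicated so diagnostics still work), for summariser tests.
make_fake_draws <- function(params, meta = list(outcome = "mortality",
                                                reference_site = "S01",
                                                n_analysed = NA_integer_)) {
  n <- length(params[[1]])
  half <- floor(n / 2)
  arr <- array(NA_real_, c(half, 2, length(params)),
               dimnames = list(NULL, NULL, names(params)))
  for (j in seq_along(params)) {
    v <- params[[j]][seq_len(2 * half)]
    arr[, , j] <- matrix(v, ncol = 2)
  }
  structure(list(draws = arr, n_chains = 2L, n_iterations = half,
                 acceptance = cbind(global = c(0.3, 0.3)),
                 meta = meta),
            class = "posterior_draws")
}
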