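# Self-contained adaptive MCMC engine: log posteriors for the hierarchical
# logistic and Cox partial-likelihood models, blocked random-walk Metropolis
# sampling with warm-up adaptation, and convergence diagnostics.

#' Specify a Bayesian outcome model
#'
#' Describes one model fit: the outcome family, the treatment-effect prior,
#' an optional covariate (with its treatment interaction) and how the
#' randomisation site enters. Mortality models use a site random intercept
#' with a non-centred parameterisation (`u_site = tau * z_site`,
#' `z ~ N(0,1)`, `tau ~ half-normal(0, site_sd_scale)`); discharge models use
#' site fixed effects. Nuisance priors default to wide normals so the
#' likelihood dominates.
#'
#' @param outcome `"mortality"` (binary, logistic) or `"discharge"`
#'   (time-to-event, Cox partial likelihood).
#' @param treatment_prior A [prior_spec()] for the treatment coefficient.
#' @param covariate Optional covariate name (one of `"creatinine"`, `"sofa"`,
#'   `"bmi"`, `"aki"`); adds a main effect and a treatment interaction.
#' @param transform Transform applied to the covariate before fitting; see
#'   [transform_covariate()].
#' @param threshold Threshold for indicator transforms.
#' @param site_term How site enters: `"random_intercept"`, `"fixed_effects"`,
#'   or `"none"`.
#' @param intercept_prior,covariate_prior,interaction_prior,site_coef_prior
#'   [prior_spec()] objects for the nuisance coefficients.
#' @param site_sd_scale Scale of the half-normal prior on the between-site SD.
#' @return An object of class `model_spec`.
#' @export
model_spec <- function(outcome = c("mortality", "discharge"),
                       treatment_prior = mortality_prior_family()$sceptical,
                       covariate = NULL,
                       transform = c("identity", "log2", "indicator_ge",
                                     "indicator_gt"),
                       threshold = NULL,
                       site_term = NULL,
                       intercept_prior = weakly_informative_prior(),
                       covariate_prior = weakly_informative_prior(),
                       interaction_prior = weakly_informative_prior(),
                       site_coef_prior = weakly_informative_prior(),
                       site_sd_scale = 1) {
  outcome <- match.arg(outcome)
  transform <- match.arg(transform)
  if (is.null(site_term))
    site_term <- if (outcome == "mortality") "random_intercept" else "fixed_effects"
  site_term <- match.arg(site_term, c("random_intercept", "fixed_effects",
                                      "none"))
  stopifnot(inherits(treatment_prior, "prior_spec"))
  structure(list(outcome = outcome, treatment_prior = treatment_prior,
                 covariate = covariate, transform = transform,
                 threshold = threshold, site_term = site_term,
                 intercept_prior = intercept_prior,
                 covariate_prior = covariate_prior,
                 interaction_prior = interaction_prior,
                 site_coef_prior = site_coef_prior,
                 site_sd_scale = site_sd_scale),
            class = "model_spec")
}

# ---------------------------------------------------------------------------
# Logistic model preparation and log posterior

#' Prepare complete-case data for the logistic model
#' @keywords internal
#' @noRd
.prep_logistic <- function(ds, model) {
  stopifnot(inherits(ds, "trial_dataset"), inherits(model, "model_spec"))
  keep <- !is.na(ds$death60)
  cov_centre <- NULL
  if (!is.null(model$covariate)) {
    raw <- ds[[model$covariate]]
    keep <- keep & !is.na(raw)
  }
  dsc <- ds[keep, , drop = FALSE]
  n_excluded <- nrow(ds) - nrow(dsc)
  y <- as.integer(dsc$death60)
  X <- cbind(alpha = rep(1, nrow(dsc)), beta = as.numeric(dsc$arm))
  prior_loc <- c(model$intercept_prior$location,
                 model$treatment_prior$location)
  prior_scale <- c(model$intercept_prior$scale, model$treatment_prior$scale)
  if (!is.null(model$covariate)) {
    v <- transform_covariate(dsc[[model$covariate]], model$transform,
                             model$threshold)
    if (length(unique(v)) < 2L)
      stop("covariate '", model$covariate,
           "' is constant in the analysed cohort; the interaction is ",
           "unidentifiable", call. = FALSE)
    if (model$transform %in% c("identity", "log2")) {
      cov_centre <- stats::median(v)
      v <- v - cov_centre
    } else cov_centre <- 0
    X <- cbind(X, gamma = v, delta = dsc$arm * v)
    prior_loc <- c(prior_loc, model$covariate_prior$location,
                   model$interaction_prior$location)
    prior_scale <- c(prior_scale, model$covariate_prior$scale,
                     model$interaction_prior$scale)
  }
  # site structure (reference = largest site, listed first); with no records
  # the model reduces to the joint prior on the coefficients
  site_term <- model$site_term
  if (nrow(dsc) == 0L) {
    site_term <- "none"
    site_levels <- character(0)
    site_index <- integer(0)
    ref <- NA_character_
  } else {
    tab <- table(dsc$site_id)
    sizes <- stats::setNames(as.integer(tab), names(tab))
    ref <- sort(names(sizes)[sizes == max(sizes)])[1L]
    site_levels <- c(ref, setdiff(names(sort(-sizes)), ref))
    site_index <- match(dsc$site_id, site_levels)
  }
  list(y = y, X = X, k = ncol(X), coef_names = colnames(X),
       prior_loc = prior_loc, prior_scale = prior_scale,
       site_index = site_index, site_levels = site_levels,
       n_sites = length(site_levels), site_term = site_term,
       site_sd_scale = model$site_sd_scale,
       n_analysed = nrow(dsc), n_excluded = n_excluded,
       reference_site = ref, cov_centre = cov_centre)
}

#' Stable Bernoulli-logit log likelihood contributions
#' @keywords internal
#' @noRd
.bern_logit_ll <- function(y, eta) {
  y * eta - (pmax(eta, 0) + log1p(exp(-abs(eta))))
}

#' Logistic log posterior from a prepared model (flat parameter vector)
#'
#' theta = c(coefs, log_tau, z) for random-intercept models, just coefs
#' otherwise.
#' @keywords internal
#' @noRd
.lp_logistic <- function(theta, prep) {
  k <- prep$k
  b <- theta[seq_len(k)]
  eta <- as.vector(prep$X %*% b)
  lp <- sum(stats::dnorm(b, prep$prior_loc, prep$prior_scale, log = TRUE))
  if (prep$site_term == "random_intercept") {
    log_tau <- theta[k + 1L]
    z <- theta[(k + 2L):length(theta)]
    tau <- exp(log_tau)
    eta <- eta + tau * z[prep$site_index]
    # half-normal(0, site_sd_scale) on tau, with the log-scale Jacobian
    lp <- lp + log(2) +
      stats::dnorm(tau, 0, prep$site_sd_scale, log = TRUE) + log_tau +
      sum(stats::dnorm(z, 0, 1, log = TRUE))
  }
  if (length(prep$y)) lp <- lp + sum(.bern_logit_ll(prep$y, eta))
  lp
}

#' Log posterior of the hierarchical logistic model
#'
#' Evaluates the sum of the Bernoulli log likelihood (logit link) over the
#' complete-case records, the log prior densities of all coefficients, and
#' the hierarchical terms of the site random intercepts
#' (`u_site = tau * z_site`, `z ~ N(0, 1)`, `tau ~ half-normal`). With an
#' empty dataset there is no site structure and the value is the joint log
#' prior density of the coefficients. Supplied mainly
#' for transparency and for checking the sampler against deterministic
#' quadrature.
#'
#' @param params Named list with elements `alpha`, `beta`, optionally `gamma`
#'   and `delta`, and for random-intercept models `log_tau` and `z` (one
#'   standard-normal deviate per site, ordered as the prepared site levels:
#'   reference site first, then by decreasing size).
#' @param ds A [trial_dataset()].
#' @param model A [model_spec()] with `outcome = "mortality"`.
#' @return The unnormalised log posterior density (a single finite number for
#'   finite parameters).
#' @export
log_posterior_logistic <- function(params, ds, model = model_spec()) {
  prep <- .prep_logistic(ds, model)
  b <- vapply(prep$coef_names, function(nm) {
    if (is.null(params[[nm]]))
      stop("params is missing coefficient '", nm, "'", call. = FALSE)
    as.numeric(params[[nm]])
  }, numeric(1))
  theta <- b
  if (prep$site_term == "random_intercept") {
    if (is.null(params$log_tau) || is.null(params$z))
      stop("random-intercept models need 'log_tau' and 'z' in params",
           call. = FALSE)
    z <- rep_len(as.numeric(params$z), prep$n_sites)
    theta <- c(b, as.numeric(params$log_tau), z)
  }
  if (any(!is.finite(theta)))
    stop("non-finite parameter values", call. = FALSE)
  .lp_logistic(theta, prep)
}

# ---------------------------------------------------------------------------
# Cox partial likelihood (Efron ties)

#' Precompute risk-set structure for the Efron partial likelihood
#' @keywords internal
#' @noRd
.cox_prep <- function(time, event, X) {
  stopifnot(length(time) == length(event), nrow(X) == length(time))
  if (sum(event) == 0)
    stop("no events in the data; the partial likelihood is undefined",
         call. = FALSE)
  ord <- order(time)
  time <- time[ord]; event <- as.integer(event[ord])
  X <- X[ord, , drop = FALSE]
  # risk set for an event at t = all subjects with time >= t
  first_at_risk <- match(time, time)  # first index of each tied time value
  ev <- which(event == 1L)
  grp_time <- time[ev]
  grp <- match(grp_time, unique(grp_time))
  list(time = time, event = event, X = X, ev = ev, grp = grp,
       n_groups = max(grp), risk_start = first_at_risk[ev], n = length(time))
}

#' Efron log partial likelihood and gradient
#' @keywords internal
#' @noRd
.cox_loglik <- function(beta, prep, gradient = FALSE) {
  eta <- as.vector(prep$X %*% beta)
  w <- exp(eta - max(eta))
  logw_shift <- max(eta)
  # cumulative risk sums from the largest time downwards
  W <- rev(cumsum(rev(w)))
  p <- ncol(prep$X)
  if (gradient) {
    S1 <- apply(prep$X * w, 2, function(col) rev(cumsum(rev(col))))
    S1 <- matrix(S1, ncol = p)
  }
  ll <- 0
  grad <- numeric(p)
  for (g in seq_len(prep$n_groups)) {
    idx <- prep$ev[prep$grp == g]
    d <- length(idx)
    R <- W[prep$risk_start[prep$grp == g][1L]]
    D <- sum(w[idx])
    l <- seq_len(d) - 1L
    denom <- R - (l / d) * D
    ll <- ll + sum(eta[idx]) - sum(log(denom) + logw_shift)
    if (gradient) {
      R1 <- S1[prep$risk_start[prep$grp == g][1L], ]
      D1 <- colSums(prep$X[idx, , drop = FALSE] * w[idx])
      grad <- grad + colSums(prep$X[idx, , drop = FALSE]) -
        colSums(outer(1 / denom, R1) - outer(l / d / denom, D1))
    }
  }
  if (gradient) list(ll = ll, grad = grad) else ll
}

#' Efron-corrected Cox log partial likelihood
#'
#' Log partial likelihood for right-censored time-to-event data with Efron's
#' correction for tied event times; the linear predictor is
#' `X beta` over the supplied covariate columns. Scaling all times by a
#' positive constant leaves the value unchanged (only the ordering matters).
#'
#' @param beta Coefficient vector, one entry per covariate column.
#' @param data A data frame with columns `time` (positive) and `event`
#'   (0/1), e.g. the output of [prepare_subdistribution()].
#' @param covariates Character vector of covariate column names; defaults to
#'   every column except `time`, `event`, `patient_id` and `site_id`.
#' @return The log partial likelihood (a single number).
#' @examples
#' d <- data.frame(time = c(1, 2), event = c(1, 1), x = c(1, 0))
#' log_partial_likelihood_cox(0, d)  # -log(2)
#' @export
log_partial_likelihood_cox <- function(beta, data,
                                       covariates = NULL) {
  if (is.null(covariates))
    covariates <- setdiff(names(data), c("time", "event", "patient_id",
                                         "site_id"))
  if (any(data$time <= 0)) stop("event/censoring times must be positive",
                                call. = FALSE)
  X <- as.matrix(data[covariates])
  storage.mode(X) <- "double"
  stopifnot(length(beta) == ncol(X))
  prep <- .cox_prep(data$time, data$event, X)
  .cox_loglik(beta, prep)
}

#' Maximum a posteriori fit of the Cox model
#'
#' Newton-type (BFGS with analytic gradient) maximiser of the Efron partial
#' likelihood plus optional normal log priors; with `flat = TRUE` it is the
#' partial-likelihood maximiser and matches a standard Cox fit.
#'
#' @param data Data frame with `time`, `event` and covariate columns.
#' @param covariates Covariate column names (default: all others).
#' @param prior_loc,prior_scale Normal prior location/scale per coefficient
#'   (recycled); ignored when `flat = TRUE`.
#' @param flat If `TRUE`, maximise the partial likelihood alone.
#' @return List with `coef`, `loglik`, `hessian` (of the negative log
#'   target), and `convergence` (0 = success).
#' @export
cox_map <- function(data, covariates = NULL, prior_loc = 0, prior_scale = 2.5,
                    flat = FALSE) {
  if (is.null(covariates))
    covariates <- setdiff(names(data), c("time", "event", "patient_id",
                                         "site_id"))
  X <- as.matrix(data[covariates])
  storage.mode(X) <- "double"
  prep <- .cox_prep(data$time, data$event, X)
  p <- ncol(X)
  loc <- rep_len(prior_loc, p); sc <- rep_len(prior_scale, p)
  neg <- function(b) {
    v <- -.cox_loglik(b, prep)
    if (!flat) v <- v - sum(stats::dnorm(b, loc, sc, log = TRUE))
    v
  }
  gneg <- function(b) {
    g <- -.cox_loglik(b, prep, gradient = TRUE)$grad
    if (!flat) g <- g + (b - loc) / sc^2
    g
  }
  fit <- stats::optim(numeric(p), neg, gneg, method = "BFGS",
                      control = list(maxit = 500, reltol = 1e-14))
  H <- stats::optimHess(fit$par, neg, gneg)
  list(coef = stats::setNames(fit$par, covariates), loglik = -fit$value,
       hessian = H, convergence = fit$convergence)
}

# ---------------------------------------------------------------------------
# Adaptive random-walk Metropolis

#' Robbins-Monro step size
#' @keywords internal
#' @noRd
.rm_gamma <- function(t) min(0.5, 3 / sqrt(t))

#' Run one logistic-model chain
#' @keywords internal
#' @noRd
.run_chain_logistic <- function(prep, n_warmup, n_iter, chain_seed) {
  set.seed(chain_seed)
  k <- prep$k
  hier <- prep$site_term == "random_intercept"
  S <- if (hier) prep$n_sites else 0L
  # in hierarchical models the intercept gets its own scalar update (its
  # conditional spread given the site effects is much narrower than its
  # marginal, which the translation sweep explores); the joint block then
  # covers the remaining coefficients and log_tau
  idx_G <- if (hier) seq(2L, k + 1L) else seq_len(k)
  dG <- length(idx_G)
  # jittered, overdispersed but in-support starts
  b <- stats::rnorm(k, 0, 0.5)
  log_tau <- if (hier) log(0.5) + stats::rnorm(1, 0, 0.3) else numeric(0)
  z <- if (hier) stats::rnorm(S) else numeric(0)
  theta <- c(b, log_tau, z)
  lp_cur <- .lp_logistic(theta, prep)
  if (!is.finite(lp_cur))
    stop("non-finite log posterior at initialisation", call. = FALSE)
  # adaptation state
  s_G <- 2.38 / sqrt(dG)
  mu_G <- theta[idx_G]; cov_G <- diag(dG) * 0.1; nG <- 0
  L_G <- chol(cov_G + 1e-6 * diag(dG))
  s_a <- 0.2
  s_z <- rep(2.38, S)
  s_sweep <- 0.5
  s_scale <- 0.5
  acc_G <- 0; acc_z <- 0; n_kept <- 0
  # per-record likelihood contributions for the site block
  eta_fix <- as.vector(prep$X %*% theta[seq_len(k)])
  out <- matrix(NA_real_, n_iter, k + if (hier) 1L + S else 0L)
  total <- n_warmup + n_iter
  for (t in seq_len(total)) {
    warm <- t <= n_warmup
    # --- intercept update (hierarchical models only)
    if (hier) {
      prop <- theta
      prop[1L] <- theta[1L] + s_a * stats::rnorm(1)
      lp_prop <- .lp_logistic(prop, prep)
      ok <- is.finite(lp_prop) && log(stats::runif(1)) < lp_prop - lp_cur
      if (ok) {
        eta_fix <- eta_fix + (prop[1L] - theta[1L])
        theta <- prop; lp_cur <- lp_prop
      }
      if (warm) s_a <- exp(log(s_a) + .rm_gamma(t) * (as.numeric(ok) - 0.44))
    }
    # --- global block: coefficients (+ log_tau), joint random walk
    prop <- theta
    prop[idx_G] <- theta[idx_G] + s_G * as.vector(crossprod(L_G, stats::rnorm(dG)))
    lp_prop <- .lp_logistic(prop, prep)
    a <- lp_prop - lp_cur
    if (is.finite(lp_prop) && log(stats::runif(1)) < a) {
      theta <- prop; lp_cur <- lp_prop
      eta_fix <- as.vector(prep$X %*% theta[seq_len(k)])
      acc_ind <- 1
    } else acc_ind <- 0
    if (warm) {
      g <- .rm_gamma(t)
      s_G <- exp(log(s_G) + g * (acc_ind - 0.35))
      # running covariance of the global block
      nG <- nG + 1
      dlt <- theta[idx_G] - mu_G
      mu_G <- mu_G + dlt / nG
      cov_G <- cov_G + (outer(dlt, theta[idx_G] - mu_G) - cov_G) / nG
      if (nG >= 100 && nG %% 25 == 0)
        L_G <- chol(cov_G + 1e-8 * diag(dG))
    } else acc_G <- acc_G + acc_ind
    # --- site block: all z updated componentwise with per-site acceptance
    if (hier) {
      tau <- exp(theta[k + 1L])
      z <- theta[(k + 2L):length(theta)]
      z_prop <- z + s_z * stats::rnorm(S)
      ll_cur <- .bern_logit_ll(prep$y, eta_fix + tau * z[prep$site_index])
      ll_prop <- .bern_logit_ll(prep$y, eta_fix + tau * z_prop[prep$site_index])
      d_site <- rowsum(ll_prop - ll_cur, prep$site_index,
                       reorder = TRUE)[, 1L]
      site_delta <- numeric(S)
      site_delta[sort(unique(prep$site_index))] <- d_site
      log_r <- site_delta +
        stats::dnorm(z_prop, log = TRUE) - stats::dnorm(z, log = TRUE)
      acc <- log(stats::runif(S)) < log_r
      z[acc] <- z_prop[acc]
      theta[(k + 2L):length(theta)] <- z
      if (any(acc)) lp_cur <- .lp_logistic(theta, prep)
      if (warm) {
        g <- .rm_gamma(t)
        s_z <- exp(log(s_z) + g * (as.numeric(acc) - 0.44))
      } else acc_z <- acc_z + mean(acc)
      # translation sweep: shift the intercept and compensate the site
      # deviations; the likelihood is invariant, so only the priors decide.
      # Breaks the intercept/site-effect confounding (worst with few sites).
      delta <- s_sweep * stats::rnorm(1)
      a_new <- theta[1L] + delta
      z_new <- z - delta / tau
      log_r_sweep <-
        stats::dnorm(a_new, prep$prior_loc[1L], prep$prior_scale[1L],
                     log = TRUE) -
        stats::dnorm(theta[1L], prep$prior_loc[1L], prep$prior_scale[1L],
                     log = TRUE) +
        sum(stats::dnorm(z_new, log = TRUE) - stats::dnorm(z, log = TRUE))
      sweep_ok <- log(stats::runif(1)) < log_r_sweep
      if (sweep_ok) {
        theta[1L] <- a_new
        theta[(k + 2L):length(theta)] <- z_new
        eta_fix <- eta_fix + delta
        lp_cur <- .lp_logistic(theta, prep)
      }
      if (warm)
        s_sweep <- exp(log(s_sweep) + .rm_gamma(t) * (as.numeric(sweep_ok) - 0.44))
      # scale sweep: rescale tau and compensate the deviates so u = tau * z
      # is unchanged; again likelihood-invariant, with the log-scale Jacobian
      # exp(-S * eps). Breaks the tau/z funnel ridge.
      eps <- s_scale * stats::rnorm(1)
      z <- theta[(k + 2L):length(theta)]
      z_new <- z * exp(-eps)
      lt_new <- theta[k + 1L] + eps
      tau_new <- exp(lt_new)
      log_r_scale <- (log(2) + stats::dnorm(tau_new, 0, prep$site_sd_scale,
                                            log = TRUE) + lt_new) -
        (log(2) + stats::dnorm(exp(theta[k + 1L]), 0, prep$site_sd_scale,
                               log = TRUE) + theta[k + 1L]) +
        sum(stats::dnorm(z_new, log = TRUE) - stats::dnorm(z, log = TRUE)) -
        S * eps
      scale_ok <- log(stats::runif(1)) < log_r_scale
      if (scale_ok) {
        theta[k + 1L] <- lt_new
        theta[(k + 2L):length(theta)] <- z_new
        lp_cur <- .lp_logistic(theta, prep)
      }
      if (warm)
        s_scale <- exp(log(s_scale) + .rm_gamma(t) * (as.numeric(scale_ok) - 0.44))
    }
    if (!warm) {
      n_kept <- n_kept + 1
      if (hier) {
        tau <- exp(theta[k + 1L])
        out[n_kept, ] <- c(theta[seq_len(k)], tau,
                           tau * theta[(k + 2L):length(theta)])
      } else out[n_kept, ] <- theta
    }
  }
  list(draws = out,
       acceptance = c(global = acc_G / n_iter,
                      site = if (hier) acc_z / n_iter else NA_real_))
}

#' Run one Cox-model chain (blocked random walk on the coefficients)
#' @keywords internal
#' @noRd
.run_chain_cox <- function(prep, prior_loc, prior_scale, init, step_sd,
                           n_warmup, n_iter, chain_seed) {
  set.seed(chain_seed)
  p <- ncol(prep$X)
  blocks <- split(seq_len(p), ceiling(seq_len(p) / 8))
  theta <- init + stats::rnorm(p, 0, 0.5 * step_sd)
  lp <- function(b) .cox_loglik(b, prep) +
    sum(stats::dnorm(b, prior_loc, prior_scale, log = TRUE))
  lp_cur <- lp(theta)
  if (!is.finite(lp_cur))
    stop("non-finite log posterior at initialisation", call. = FALSE)
  s_b <- vapply(blocks, function(ix) 2.38 / sqrt(length(ix)), numeric(1))
  acc <- numeric(length(blocks)); n_kept <- 0
  out <- matrix(NA_real_, n_iter, p)
  total <- n_warmup + n_iter
  for (t in seq_len(total)) {
    warm <- t <= n_warmup
    for (bi in seq_along(blocks)) {
      ix <- blocks[[bi]]
      prop <- theta
      prop[ix] <- theta[ix] + s_b[bi] * step_sd[ix] * stats::rnorm(length(ix))
      lp_prop <- lp(prop)
      ok <- is.finite(lp_prop) && log(stats::runif(1)) < lp_prop - lp_cur
      if (ok) { theta <- prop; lp_cur <- lp_prop }
      if (warm) s_b[bi] <- exp(log(s_b[bi]) + .rm_gamma(t) * (as.numeric(ok) - 0.3))
      else acc[bi] <- acc[bi] + as.numeric(ok)
    }
    if (!warm) { n_kept <- n_kept + 1; out[n_kept, ] <- theta }
  }
  list(draws = out, acceptance = c(global = mean(acc) / n_iter, site = NA_real_))
}

#' Draw from the posterior of a specified model
#'
#' Samples the posterior of a [model_spec()] applied to a [trial_dataset()]
#' with an adaptive blocked random-walk Metropolis sampler. Mortality models
#' update the coefficient block (intercept, treatment, optional covariate and
#' interaction, log between-site SD) jointly with a covariance-adapted
#' proposal, and all non-centred site deviates simultaneously with per-site
#' acceptance; discharge models update the treatment and site fixed-effect
#' coefficients in blocks scaled by the curvature at the posterior mode.
#' Proposal adaptation runs only during warm-up and is frozen afterwards.
#' Fixed seeds give identical draws.
#'
#' @param model A [model_spec()].
#' @param ds A [trial_dataset()].
#' @param n_chains Number of chains (>= 2; default 4).
#' @param n_iter Post-warm-up iterations per chain (default 2500).
#' @param n_warmup Warm-up iterations per chain (default 2500).
#' @param seed Integer seed.
#' @return An object of class `posterior_draws`: an iterations x chains x
#'   parameters array plus acceptance rates and metadata (model fingerprint,
#'   numbers analysed/excluded, reference site, seed).
#' @export
sample_posterior <- function(model, ds, n_chains = 4L, n_iter = 2500L,
                             n_warmup = 2500L, seed = 1L) {
  stopifnot(inherits(model, "model_spec"), inherits(ds, "trial_dataset"))
  if (n_chains < 2L) stop("at least 2 chains are required", call. = FALSE)
  chain_seeds <- .with_seed(seed,
    sample.int(2147483000L, n_chains))
  if (model$outcome == "mortality") {
    prep <- .prep_logistic(ds, model)
    chains <- lapply(seq_len(n_chains), function(ch)
      .run_chain_logistic(prep, n_warmup, n_iter, chain_seeds[ch]))
    hier <- prep$site_term == "random_intercept"
    pnames <- prep$coef_names
    if (hier) pnames <- c(pnames, "tau", paste0("u_", prep$site_levels))
    meta <- list(outcome = "mortality", stance = model$treatment_prior$stance,
                 n_analysed = prep$n_analysed, n_excluded = prep$n_excluded,
                 reference_site = prep$reference_site,
                 site_levels = prep$site_levels,
                 covariate = model$covariate, transform = model$transform,
                 cov_centre = prep$cov_centre, seed = seed)
  } else {
    sub <- prepare_subdistribution(ds)
    dm <- .cox_design(sub)
    prep <- .cox_prep(dm$data$time, dm$data$event, dm$X)
    p <- ncol(dm$X)
    prior_loc <- c(model$treatment_prior$location,
                   rep(model$site_coef_prior$location, p - 1L))
    prior_scale <- c(model$treatment_prior$scale,
                     rep(model$site_coef_prior$scale, p - 1L))
    map <- cox_map(cbind(dm$data[c("time", "event")], as.data.frame(dm$X)),
                   covariates = colnames(dm$X),
                   prior_loc = prior_loc, prior_scale = prior_scale)
    step_sd <- sqrt(diag(solve(map$hessian + 1e-8 * diag(p))))
    chains <- lapply(seq_len(n_chains), function(ch)
      .run_chain_cox(prep, prior_loc, prior_scale, map$coef, step_sd,
                     n_warmup, n_iter, chain_seeds[ch]))
    pnames <- colnames(dm$X)
    meta <- list(outcome = "discharge", stance = model$treatment_prior$stance,
                 n_analysed = nrow(dm$data), n_excluded = 0L,
                 n_events = sum(dm$data$event),
                 reference_site = dm$reference_site,
                 site_levels = dm$site_levels, seed = seed)
  }
  draws <- array(NA_real_, c(n_iter, n_chains, length(pnames)),
                 dimnames = list(NULL, NULL, pnames))
  for (ch in seq_len(n_chains)) draws[, ch, ] <- chains[[ch]]$draws
  acceptance <- do.call(rbind, lapply(chains, `[[`, "acceptance"))
  structure(list(draws = draws, n_chains = n_chains, n_iterations = n_iter,
                 acceptance = acceptance, meta = meta),
            class = "posterior_draws")
}

#' @export
print.posterior_draws <- function(x, ...) {
  cat(sprintf("<posterior_draws> %d chains x %d iterations, %d parameters (%s model)\n",
              x$n_chains, x$n_iterations, dim(x$draws)[3], x$meta$outcome))
  cat("  parameters:", paste(utils::head(dimnames(x$draws)[[3]], 6),
                             collapse = ", "),
      if (dim(x$draws)[3] > 6) "...", "\n")
  invisible(x)
}

#' Extract draws of one parameter
#'
#' @param draws A `posterior_draws` object.
#' @param parameter Parameter name.
#' @param merge If `TRUE` (default) return a single vector pooling chains;
#'   otherwise an iterations x chains matrix.
#' @return Numeric vector or matrix of posterior draws.
#' @export
param_draws <- function(draws, parameter, merge = TRUE) {
  stopifnot(inherits(draws, "posterior_draws"))
  if (!parameter %in% dimnames(draws$draws)[[3]])
    stop("no parameter '", parameter, "' in draws", call. = FALSE)
  m <- draws$draws[, , parameter, drop = TRUE]
  m <- matrix(m, nrow = draws$n_iterations)
  if (merge) as.vector(m) else m
}

#' Persist posterior draws as long-format CSV
#'
#' Columns: `chain`, `iteration`, `parameter`, `value`.
#'
#' @param draws A `posterior_draws` object.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_draws_csv <- function(draws, path) {
  stopifnot(inherits(draws, "posterior_draws"))
  pn <- dimnames(draws$draws)[[3]]
  long <- do.call(rbind, lapply(seq_along(pn), function(j) {
    data.frame(chain = rep(seq_len(draws$n_chains),
                           each = draws$n_iterations),
               iteration = rep(seq_len(draws$n_iterations), draws$n_chains),
               parameter = pn[j],
               value = as.vector(draws$draws[, , j]))
  }))
  utils::write.csv(long, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

# ---------------------------------------------------------------------------
# Convergence diagnostics

#' Rank-normalise pooled draws
#' @keywords internal
#' @noRd
.rank_normalise <- function(m) {
  S <- length(m)
  z <- stats::qnorm((rank(m) - 3 / 8) / (S + 1 / 4))
  matrix(z, nrow = nrow(m))
}

#' Split chains in half
#' @keywords internal
#' @noRd
.split_chains <- function(m) {
  n <- nrow(m)
  h <- floor(n / 2)
  cbind(m[seq_len(h), , drop = FALSE],
        m[(n - h + 1):n, , drop = FALSE])
}

#' Split R-hat of an iterations x chains matrix
#' @keywords internal
#' @noRd
.split_rhat <- function(m) {
  m <- .split_chains(m)
  n <- nrow(m); M <- ncol(m)
  if (stats::var(as.vector(m)) == 0) return(1)
  mns <- colMeans(m)
  vars <- apply(m, 2, stats::var)
  W <- mean(vars)
  B <- n * stats::var(mns)
  if (W == 0) return(Inf)
  sqrt(((n - 1) / n * W + B / n) / W)
}

#' Effective sample size of an iterations x chains matrix (Geyer truncation)
#' @keywords internal
#' @noRd
.ess <- function(m) {
  m <- .split_chains(m)
  n <- nrow(m); M <- ncol(m)
  if (n < 4L) return(NA_real_)
  vars <- apply(m, 2, stats::var)
  W <- mean(vars)
  if (W == 0) return(NA_real_)
  B <- n * stats::var(colMeans(m))
  var_plus <- (n - 1) / n * W + B / n
  # mean autocovariance across chains; correlations beyond a few hundred
  # lags are negligible for this sampler and Geyer truncation stops earlier
  lag_max <- min(n - 1L, 300L)
  acov <- sapply(seq_len(M), function(j)
    stats::acf(m[, j], lag.max = lag_max, type = "covariance",
               plot = FALSE, demean = TRUE)$acf[, 1, 1])
  rho <- 1 - (W - rowMeans(acov)) / var_plus
  # Geyer initial monotone positive sequence on paired sums
  max_pairs <- floor((length(rho) - 1) / 2)
  P <- numeric(0)
  prev <- Inf
  for (kk in 0:max_pairs) {
    pk <- rho[2 * kk + 1] + if (2 * kk + 2 <= length(rho)) rho[2 * kk + 2] else 0
    if (pk < 0) break
    pk <- min(pk, prev)
    P <- c(P, pk)
    prev <- pk
  }
  tau <- max(-1 + 2 * sum(P), 1 / (n * M))
  min(n * M / tau, n * M)
}

#' Convergence diagnostics for posterior draws
#'
#' Computes per-parameter split R-hat on rank-normalised draws, bulk
#' effective sample size (rank-normalised) and tail effective sample size
#' (minimum ESS of the 5% / 95% tail indicators), plus per-chain acceptance
#' rates, and issues an overall verdict under the configured thresholds.
#' Acceptance rates far outside the targeted band are surfaced as a sampling
#' warning in the returned object.
#'
#' @param draws A `posterior_draws` object from [sample_posterior()]
#'   (>= 2 chains).
#' @param rhat_threshold Largest acceptable R-hat (default 1.01).
#' @param ess_threshold Smallest acceptable bulk ESS (default 400).
#' @return An object of class `mcmc_diagnostics`: lists `rhat`, `ess_bulk`,
#'   `ess_tail` (named per parameter), `acceptance_rate`, `acceptable`
#'   (logical verdict) and `warnings`.
#' @export
diagnose <- function(draws, rhat_threshold = 1.01, ess_threshold = 400) {
  stopifnot(inherits(draws, "posterior_draws"))
  if (draws$n_chains < 2L)
    stop("diagnostics require at least 2 chains", call. = FALSE)
  pn <- dimnames(draws$draws)[[3]]
  rhat <- ess_bulk <- ess_tail <- stats::setNames(numeric(length(pn)), pn)
  for (j in seq_along(pn)) {
    m <- matrix(draws$draws[, , j], nrow = draws$n_iterations)
    if (stats::var(as.vector(m)) == 0) {
      rhat[j] <- 1; ess_bulk[j] <- ess_tail[j] <- NA_real_
      next
    }
    zn <- .rank_normalise(m)
    rhat[j] <- .split_rhat(zn)
    ess_bulk[j] <- .ess(zn)
    q <- stats::quantile(m, c(0.05, 0.95), names = FALSE)
    lo <- matrix(as.numeric(m <= q[1]), nrow = nrow(m))
    hi <- matrix(as.numeric(m >= q[2]), nrow = nrow(m))
    ess_tail[j] <- min(.ess(lo), .ess(hi), na.rm = TRUE)
  }
  warns <- character(0)
  acc <- draws$acceptance[, "global"]
  if (any(acc < 0.1 | acc > 0.7))
    warns <- c(warns, sprintf(
      "global-block acceptance rate outside [0.10, 0.70] in chain(s) %s",
      paste(which(acc < 0.1 | acc > 0.7), collapse = ", ")))
  acceptable <- all(rhat < rhat_threshold, na.rm = TRUE) &&
    all(ess_bulk[!is.na(ess_bulk)] > ess_threshold) && length(warns) == 0
  structure(list(rhat = rhat, ess_bulk = ess_bulk, ess_tail = ess_tail,
                 acceptance_rate = draws$acceptance,
                 rhat_threshold = rhat_threshold,
                 ess_threshold = ess_threshold,
                 acceptable = acceptable, warnings = warns),
            class = "mcmc_diagnostics")
}

#' @export
print.mcmc_diagnostics <- function(x, ...) {
  cat(sprintf("<mcmc_diagnostics> max R-hat %.4f, min bulk ESS %.0f, min tail ESS %.0f\n",
              max(x$rhat, na.rm = TRUE), min(x$ess_bulk, na.rm = TRUE),
              min(x$ess_tail, na.rm = TRUE)))
  cat(sprintf("  verdict: %s (thresholds R-hat < %g, bulk ESS > %g)\n",
              if (x$acceptable) "acceptable" else "NOT acceptable",
              x$rhat_threshold, x$ess_threshold))
  for (w in x$warnings) cat("  warning:", w, "\n")
  invisible(x)
}

#' Write a diagnostics report as JSON
#'
#' @param diagnostics An `mcmc_diagnostics` object.
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
write_diagnostics_json <- function(diagnostics, path) {
  stopifnot(inherits(diagnostics, "mcmc_diagnostics"))
  jsonlite::write_json(
    list(rhat = as.list(diagnostics$rhat),
         ess_bulk = as.list(diagnostics$ess_bulk),
         ess_tail = as.list(diagnostics$ess_tail),
         acceptance_rate = as.data.frame(diagnostics$acceptance_rate),
         acceptable = diagnostics$acceptable,
         warnings = diagnostics$warnings),
    path, auto_unbox = TRUE, digits = NA, na = "null")
  invisible(path)
}
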