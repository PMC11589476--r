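# Primary-outcome analysis: hierarchical Bayesian logistic regression for
# 60-day mortality with site random intercepts, summarised as conditional
# RR/RD/OR with threshold probabilities.

#' Fit the primary 60-day mortality model
#'
#' Hierarchical Bayesian logistic regression of death within 60 days on
#' treatment, adjusted for randomisation site as a random intercept, under a
#' given treatment-effect prior. Records with a missing outcome are excluded
#' (complete-case analysis) and counted in the metadata. Datasets in which
#' every analysed participant died, or none did, trigger a separation warning
#' but still return draws: the prior regularises the fit.
#'
#' @param ds A [trial_dataset()].
#' @param prior Treatment-effect [prior_spec()] on the log odds ratio
#'   (default: the sceptical member of [mortality_prior_family()]).
#' @param n_chains,n_iter,n_warmup,seed Sampler settings, see
#'   [sample_posterior()].
#' @return A `posterior_draws` object with parameters `alpha` (reference-site
#'   log-odds in the usual arm), `beta` (treatment log-OR), `tau`
#'   (between-site SD) and `u_<site>` (site deviations); metadata records
#'   `n_analysed` and `n_excluded`.
#' @export
fit_primary <- function(ds, prior = mortality_prior_family()$sceptical,
                        n_chains = 4L, n_iter = 2500L, n_warmup = 2500L,
                        seed = 1L) {
  stopifnot(inherits(ds, "trial_dataset"))
  y <- ds$death60[!is.na(ds$death60)]
  if (length(y) && (all(y == 1L) || all(y == 0L)))
    warning("outcome is separated (all analysed participants ",
            if (all(y == 1L)) "died" else "survived",
            "); the posterior is driven by the prior", call. = FALSE)
  model <- model_spec(outcome = "mortality", treatment_prior = prior)
  sample_posterior(model, ds, n_chains = n_chains, n_iter = n_iter,
                   n_warmup = n_warmup, seed = seed)
}

#' Per-draw arm risks at the reference site
#'
#' Converts posterior draws into per-draw death probabilities under each arm
#' for a patient at the reference (largest) site:
#' `p_usual = plogis(eta_ref)` and `p_high = plogis(eta_ref + beta)`, where
#' `eta_ref = alpha + u_ref` is the reference site's linear predictor in the
#' usual arm (plus the covariate term at its centred zero, for interaction
#' models).
#'
#' @param draws A `posterior_draws` from a mortality model.
#' @param ref Reference site label; defaults to the fit's own reference site.
#' @param covariate_value Value of the centred covariate at which to evaluate
#'   the risks (interaction models only; default 0, the centring point).
#' @return A data frame with one row per pooled draw and columns `p_usual`,
#'   `p_high`.
#' @export
arm_risks <- function(draws, ref = NULL, covariate_value = 0) {
  stopifnot(inherits(draws, "posterior_draws"))
  if (draws$meta$outcome != "mortality")
    stop("arm risks are defined for mortality models", call. = FALSE)
  if (is.null(ref)) ref <- draws$meta$reference_site
  pn <- dimnames(draws$draws)[[3]]
  alpha <- param_draws(draws, "alpha")
  beta <- param_draws(draws, "beta")
  u_name <- paste0("u_", ref)
  eta_ref <- alpha
  if (u_name %in% pn) {
    eta_ref <- eta_ref + param_draws(draws, u_name)
  } else if (!is.null(ref) && !is.na(ref) &&
             !identical(ref, draws$meta$reference_site) &&
             length(grep("^u_", pn))) {
    stop("unknown reference site '", ref, "'", call. = FALSE)
  }
  if (covariate_value != 0) {
    if (!"gamma" %in% pn)
      stop("no covariate term in this model", call. = FALSE)
    eta_ref <- eta_ref + param_draws(draws, "gamma") * covariate_value
    beta <- beta + param_draws(draws, "delta") * covariate_value
  }
  data.frame(p_usual = stats::plogis(eta_ref),
             p_high = stats::plogis(eta_ref + beta))
}

#' Summarise arm-risk draws as conditional effects and threshold probabilities
#'
#' From per-draw arm risks computes the conditional risk ratio
#' (`p_high / p_usual`), risk difference (in percentage points,
#' `100 * (p_high - p_usual)`) and odds ratio, summarised by posterior
#' medians and 95% percentile credible intervals, plus the probabilities of:
#' any harm (RD > 0), any benefit (RD < 0), clinically important harm
#' (RD >= mcid), clinically important benefit (RD <= -mcid) and no clinically
#' important difference (-mcid < RD < mcid). The minimally clinically
#' important difference (`mcid`) defaults to 2.0 percentage points. Draws
#' with `p_usual = 0` are excluded from the RR summary with a warning.
#'
#' @param risks Data frame of per-draw `p_usual`, `p_high` from
#'   [arm_risks()].
#' @param mcid Minimally clinically important absolute risk difference, in
#'   percentage points (> 0).
#' @param n_analysed Optional number of analysed participants, carried into
#'   the summary.
#' @return An object of class `effect_summary`.
#' @export
effect_summaries <- function(risks, mcid = 2, n_analysed = NA_integer_) {
  stopifnot(is.data.frame(risks), all(c("p_usual", "p_high") %in% names(risks)))
  if (!is.numeric(mcid) || length(mcid) != 1L || mcid <= 0)
    stop("'mcid' must be a single positive number of percentage points",
         call. = FALSE)
  p_u <- risks$p_usual; p_h <- risks$p_high
  rd <- 100 * (p_h - p_u)
  ok <- p_u > 0
  if (!all(ok)) {
    warning(sum(!ok), " draw(s) with p_usual = 0 excluded from the RR summary",
            call. = FALSE)
  }
  rr <- p_h[ok] / p_u[ok]
  or_ok <- ok & p_u < 1 & p_h < 1
  or_draws <- (p_h[or_ok] / (1 - p_h[or_ok])) / (p_u[or_ok] / (1 - p_u[or_ok]))
  qs <- function(x) {
    q <- stats::quantile(x, c(0.5, 0.025, 0.975), names = FALSE, type = 7)
    stats::setNames(q, c("median", "lower", "upper"))
  }
  n <- length(rd)
  out <- list(
    risk_usual = qs(p_u), risk_high = qs(p_h),
    rr = qs(rr), rd = qs(rd), or_ = qs(or_draws),
    p_any_harm = sum(rd > 0) / n,
    p_any_benefit = sum(rd < 0) / n,
    p_important_harm = sum(rd >= mcid) / n,
    p_important_benefit = sum(rd <= -mcid) / n,
    p_no_important_difference = sum(rd > -mcid & rd < mcid) / n,
    mcid = mcid, n_draws = n, n_analysed = n_analysed)
  class(out) <- "effect_summary"
  out
}

#' @export
print.effect_summary <- function(x, ...) {
  f <- function(q, d = 2) sprintf(paste0("%.", d, "f (%.", d, "f to %.", d, "f)"),
                                  q["median"], q["lower"], q["upper"])
  cat("<effect_summary>",
      if (!is.na(x$n_analysed)) sprintf("n analysed = %d,", x$n_analysed),
      sprintf("MCID = %g %%-points\n", x$mcid))
  cat(sprintf("  risk, high protein:  %s %%\n",
              f(100 * x$risk_high)))
  cat(sprintf("  risk, usual protein: %s %%\n", f(100 * x$risk_usual)))
  cat(sprintf("  RR %s | RD %s %%-points | OR %s\n",
              f(x$rr), f(x$rd, 1), f(x$or_)))
  cat(sprintf("  P(any harm) %.3f | P(any benefit) %.3f\n",
              x$p_any_harm, x$p_any_benefit))
  cat(sprintf("  P(important harm) %.3f | P(important benefit) %.3f | P(no important difference) %.3f\n",
              x$p_important_harm, x$p_important_benefit,
              x$p_no_important_difference))
  invisible(x)
}

#' Flatten an effect summary to a one-row data frame
#'
#' Mirrors the column layout of a published results table: per-arm risks,
#' RR, RD and the threshold probabilities (as percentages), with 95% CrIs.
#'
#' @param x An `effect_summary`.
#' @param row.names,optional,... Passed on per the generic's contract (unused).
#' @return A one-row `data.frame`.
#' @export
as.data.frame.effect_summary <- function(x, row.names = NULL,
                                         optional = FALSE, ...) {
  data.frame(
    n_analysed = x$n_analysed,
    risk_high = 100 * x$risk_high[["median"]],
    risk_high_lo = 100 * x$risk_high[["lower"]],
    risk_high_hi = 100 * x$risk_high[["upper"]],
    risk_usual = 100 * x$risk_usual[["median"]],
    risk_usual_lo = 100 * x$risk_usual[["lower"]],
    risk_usual_hi = 100 * x$risk_usual[["upper"]],
    rr = x$rr[["median"]], rr_lo = x$rr[["lower"]], rr_hi = x$rr[["upper"]],
    rd = x$rd[["median"]], rd_lo = x$rd[["lower"]], rd_hi = x$rd[["upper"]],
    or_ = x$or_[["median"]], or_lo = x$or_[["lower"]], or_hi = x$or_[["upper"]],
    p_any_harm = 100 * x$p_any_harm,
    p_any_benefit = 100 * x$p_any_benefit,
    p_important_harm = 100 * x$p_important_harm,
    p_important_benefit = 100 * x$p_important_benefit,
    p_no_important_difference = 100 * x$p_no_important_difference,
    row.names = row.names)
}

#' Serialise an effect summary as JSON
#'
#' @param x An `effect_summary`.
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
write_effect_summary_json <- function(x, path) {
  stopifnot(inherits(x, "effect_summary"))
  jsonlite::write_json(unclass(x), path, auto_unbox = TRUE, digits = NA,
                       na = "null")
  invisible(path)
}

#' Fit the mortality model under a whole prior family
#'
#' Runs [fit_primary()] once per prior stance on identical data with the same
#' sampler seed, so differences between stances reflect only the priors, and
#' summarises each fit with [effect_summaries()].
#'
#' @param ds A [trial_dataset()].
#' @param family A `prior_family` (default [mortality_prior_family()]).
#' @param mcid Minimally clinically important difference, percentage points.
#' @param n_chains,n_iter,n_warmup,seed Sampler settings.
#' @return Named list (one element per stance) of lists with components
#'   `draws`, `summary` and `diagnostics`; class `prior_family_fit`.
#' @export
run_prior_family <- function(ds, family = mortality_prior_family(), mcid = 2,
                             n_chains = 4L, n_iter = 2500L, n_warmup = 2500L,
                             seed = 1L) {
  stopifnot(inherits(ds, "trial_dataset"), length(family) >= 1L)
  out <- lapply(family, function(prior) {
    draws <- fit_primary(ds, prior, n_chains = n_chains, n_iter = n_iter,
                         n_warmup = n_warmup, seed = seed)
    summ <- effect_summaries(arm_risks(draws), mcid = mcid,
                             n_analysed = draws$meta$n_analysed)
    list(draws = draws, summary = summ, diagnostics = diagnose(draws))
  })
  class(out) <- c("prior_family_fit", "list")
  out
}

#' Tabulate a prior-family fit
#'
#' One row per prior stance, in the shape of a published mortality results
#' table.
#'
#' @param x A `prior_family_fit` from [run_prior_family()].
#' @param row.names,optional,... Per the generic's contract (unused).
#' @return A `data.frame` with a `stance` column and the
#'   [as.data.frame.effect_summary()] columns.
#' @export
as.data.frame.prior_family_fit <- function(x, row.names = NULL,
                                           optional = FALSE, ...) {
  rows <- lapply(names(x), function(st)
    cbind(stance = st, as.data.frame(x[[st]]$summary)))
  do.call(rbind, rows)
}
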