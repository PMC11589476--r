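# Heterogeneity of treatment effects: treatment-by-covariate interaction
# models for 60-day mortality, for binary subgroups (AKI, SOFA >= 9,
# BMI > 30) and continuous covariates (log2 creatinine, SOFA, BMI).

#' Transform a baseline covariate for interaction modelling
#'
#' Supported transforms: `"identity"` (SOFA, BMI on their natural scales),
#' `"log2"` (creatinine, so one unit is a doubling), `"indicator_ge"`
#' (1 when the value is >= `threshold`, e.g. SOFA >= 9) and `"indicator_gt"`
#' (1 when strictly above, e.g. BMI > 30, so a BMI of exactly 30 falls in the
#' lower stratum).
#'
#' @param values Numeric covariate values (may contain `NA`).
#' @param transform One of `"identity"`, `"log2"`, `"indicator_ge"`,
#'   `"indicator_gt"`.
#' @param threshold Cut point for the indicator transforms.
#' @return Numeric vector of transformed values.
#' @examples
#' transform_covariate(c(80, 160), "log2")        # differ by exactly 1
#' transform_covariate(c(8, 9), "indicator_ge", 9) # 0, 1
#' @export
transform_covariate <- function(values,
                                transform = c("identity", "log2",
                                              "indicator_ge", "indicator_gt"),
                                threshold = NULL) {
  transform <- match.arg(transform)
  switch(transform,
    identity = as.numeric(values),
    log2 = {
      if (any(values <= 0, na.rm = TRUE))
        stop("log2 transform requires strictly positive values",
             call. = FALSE)
      log2(values)
    },
    indicator_ge = {
      if (is.null(threshold)) stop("indicator transform needs a 'threshold'",
                                   call. = FALSE)
      as.numeric(values >= threshold)
    },
    indicator_gt = {
      if (is.null(threshold)) stop("indicator transform needs a 'threshold'",
                                   call. = FALSE)
      as.numeric(values > threshold)
    })
}

#' Default transform and threshold for each HTE covariate
#' @keywords internal
#' @noRd
.hte_defaults <- list(
  creatinine = list(transform = "log2", threshold = NULL),
  sofa = list(transform = "identity", threshold = 9),
  bmi = list(transform = "identity", threshold = 30),
  aki = list(transform = "indicator_ge", threshold = 1)
)

#' Fit a treatment-by-covariate interaction model for mortality
#'
#' Hierarchical Bayesian logistic regression of 60-day death on treatment,
#' a baseline covariate, their interaction, and site random intercepts:
#' `logit p = alpha + u_site + beta*arm + gamma*v + delta*arm*v` with `v` the
#' transformed covariate. Continuous covariates (`identity`, `log2`) are
#' centred at the analysed-cohort median before fitting, so `beta` is the
#' treatment effect for a typical patient; `delta` is unchanged by centring.
#' The treatment effect keeps the sceptical prior; the covariate and
#' interaction coefficients get weakly informative normal(0, 2.5) priors so
#' the likelihood dominates. Complete cases for both the outcome and the
#' covariate are analysed; the exclusions are counted in the metadata. A
#' covariate that is constant in the analysed cohort is rejected (the
#' interaction would be unidentifiable).
#'
#' @param ds A [trial_dataset()].
#' @param covariate `"creatinine"`, `"sofa"`, `"bmi"` or `"aki"`.
#' @param transform Covariate transform (see [transform_covariate()]);
#'   defaults to `log2` for creatinine, identity for SOFA and BMI, and the
#'   covariate's own 0/1 coding for AKI. Use `"indicator_ge"` /
#'   `"indicator_gt"` with the default thresholds (SOFA 9, BMI 30) for the
#'   subgroup analyses.
#' @param prior Treatment-effect [prior_spec()] (default sceptical).
#' @param threshold Cut point for indicator transforms; defaults to the
#'   covariate's conventional threshold.
#' @param n_chains,n_iter,n_warmup,seed Sampler settings.
#' @return A `posterior_draws` with parameters `alpha`, `beta`, `gamma`
#'   (covariate main effect), `delta` (interaction), `tau`, `u_<site>`.
#' @export
fit_interaction <- function(ds, covariate = c("creatinine", "sofa", "bmi",
                                              "aki"),
                            transform = NULL,
                            prior = mortality_prior_family()$sceptical,
                            threshold = NULL,
                            n_chains = 4L, n_iter = 2500L, n_warmup = 2500L,
                            seed = 1L) {
  stopifnot(inherits(ds, "trial_dataset"))
  covariate <- match.arg(covariate)
  if (is.null(transform)) transform <- .hte_defaults[[covariate]]$transform
  if (is.null(threshold) && startsWith(transform, "indicator"))
    threshold <- .hte_defaults[[covariate]]$threshold
  model <- model_spec(outcome = "mortality", treatment_prior = prior,
                      covariate = covariate, transform = transform,
                      threshold = threshold)
  sample_posterior(model, ds, n_chains = n_chains, n_iter = n_iter,
                   n_warmup = n_warmup, seed = seed)
}

#' Summarise an interaction posterior
#'
#' Reports the interaction odds ratio per unit of the (transformed)
#' covariate, `exp(delta)`, as a posterior median with 95% percentile CrI,
#' together with the probability of a positive interaction (`delta > 0`:
#' mortality under high protein increases with the covariate) and of a
#' negative interaction.
#'
#' @param draws A `posterior_draws` from [fit_interaction()].
#' @return An object of class `interaction_summary`.
#' @export
interaction_summary <- function(draws) {
  stopifnot(inherits(draws, "posterior_draws"))
  d <- param_draws(draws, "delta")
  q <- stats::quantile(exp(d), c(0.5, 0.025, 0.975), names = FALSE)
  out <- list(covariate = draws$meta$covariate,
              transform = draws$meta$transform,
              delta_or = stats::setNames(q, c("median", "lower", "upper")),
              p_positive_interaction = mean(d > 0),
              p_negative_interaction = mean(d < 0),
              n_analysed = draws$meta$n_analysed,
              n_excluded = draws$meta$n_excluded)
  class(out) <- "interaction_summary"
  out
}

#' @export
print.interaction_summary <- function(x, ...) {
  cat(sprintf("<interaction_summary> treatment x %s (%s)\n",
              x$covariate, x$transform))
  cat(sprintf("  interaction OR per unit: %.3f (95%% CrI %.3f to %.3f)\n",
              x$delta_or[["median"]], x$delta_or[["lower"]],
              x$delta_or[["upper"]]))
  cat(sprintf("  P(positive interaction) = %.3f; n analysed = %d (%d excluded)\n",
              x$p_positive_interaction, x$n_analysed, x$n_excluded))
  invisible(x)
}

#' Serialise an interaction summary as JSON
#'
#' @param x An `interaction_summary`.
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
write_interaction_summary_json <- function(x, path) {
  stopifnot(inherits(x, "interaction_summary"))
  jsonlite::write_json(unclass(x), path, auto_unbox = TRUE, digits = NA,
                       na = "null")
  invisible(path)
}

#' Per-stratum conditional effects from a binary-covariate interaction fit
#'
#' For an interaction model with a 0/1 covariate, evaluates the per-draw arm
#' risks at the reference site within each stratum (covariate fixed at 0 and
#' at 1) and applies [effect_summaries()] to each, giving the stratum-level
#' RR and RD with credible intervals.
#'
#' @param draws A `posterior_draws` from [fit_interaction()] with an
#'   indicator-transformed (or natively binary) covariate.
#' @param mcid Minimally clinically important difference, percentage points.
#' @return Named list of two `effect_summary` objects (`stratum_0`,
#'   `stratum_1`).
#' @export
subgroup_effects <- function(draws, mcid = 2) {
  stopifnot(inherits(draws, "posterior_draws"))
  if (is.null(draws$meta$covariate))
    stop("draws do not come from an interaction model", call. = FALSE)
  binary <- startsWith(draws$meta$transform, "indicator") ||
    draws$meta$covariate == "aki"
  if (!binary)
    stop("subgroup effects are defined for binary covariates; '",
         draws$meta$covariate, "' was fitted as ", draws$meta$transform,
         call. = FALSE)
  centre <- draws$meta$cov_centre
  out <- lapply(c(stratum_0 = 0, stratum_1 = 1), function(s)
    effect_summaries(arm_risks(draws, covariate_value = s - centre),
                     mcid = mcid, n_analysed = draws$meta$n_analysed))
  class(out) <- c("subgroup_effects", "list")
  out
}

#' Tabulate subgroup effects in a results-table shape
#'
#' @param x A `subgroup_effects` list.
#' @param row.names,optional,... Per the generic's contract (unused).
#' @return A `data.frame`, one row per stratum.
#' @export
as.data.frame.subgroup_effects <- function(x, row.names = NULL,
                                           optional = FALSE, ...) {
  do.call(rbind, lapply(names(x), function(s)
    cbind(stratum = s, as.data.frame(x[[s]]))))
}
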