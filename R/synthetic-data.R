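# Synthetic trial cohorts with known ground truth, and reconstruction of
# approximate cohorts from published arm-level summaries.

#' Evaluate an expression under a temporary RNG seed
#' @keywords internal
#' @noRd
.with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed)
  expr
}

# Covariate-generating constants: baseline SOFA discretised around mean 9
# (SD 3, clipped to 0-24); creatinine log-normal(ln 90, 0.5) umol/L; BMI
# log-normal(ln 32, 0.22) kg/m^2; AKI = creatinine above 120 umol/L, i.e. a
# KDIGO-stage-1 1.5-fold rise over an assumed 80 umol/L baseline. The
# generator's linear predictor centres log2 creatinine at log2(90), SOFA at 9
# and BMI at 30 so that `alpha_true` is the reference-site log-odds of death
# for a typical usual-protein patient.
.covariate_defaults <- list(
  sofa_mean = 9, sofa_sd = 3,
  creat_meanlog = log(90), creat_sdlog = 0.5,
  bmi_meanlog = log(32), bmi_sdlog = 0.22,
  aki_threshold = 120,
  centre_log2_creat = log2(90), centre_sofa = 9, centre_bmi = 30
)

#' Configuration for the synthetic cohort generator
#'
#' Defines the ground truth of a simulated two-arm, multi-site trial. The
#' defaults emulate the structure of a 1301-participant, 85-centre critical
#' care nutrition trial: 645 high-protein and 656 usual-protein participants,
#' a dominant reference site of 120 patients with geometrically decaying
#' sizes for the rest, a usual-protein 60-day mortality near 32%, a small
#' harmful treatment log-odds ratio, modest site heterogeneity, and
#' competing discharge/death processes over a 60-day horizon with 4 missing
#' primary outcomes and 90 missing creatinine values.
#'
#' @param n_per_arm Integer pair: participants in the (high, usual) protein
#'   arms.
#' @param n_sites Number of randomisation sites.
#' @param largest_site_size Size of the dominant reference site.
#' @param site_size_decay Geometric decay ratio for the remaining site sizes.
#' @param alpha_true Reference-site log-odds of 60-day death for a typical
#'   usual-protein patient.
#' @param beta_true Treatment effect (log odds ratio, high vs usual).
#' @param site_sd True between-site SD of the log-odds of death.
#' @param gamma_creatinine,gamma_sofa,gamma_bmi Covariate main effects on the
#'   log-odds of death, per log2 umol/L, per SOFA point, and per kg/m^2.
#' @param delta_creatinine,delta_sofa,delta_bmi Treatment-by-covariate
#'   interaction coefficients on the same per-unit scales.
#' @param discharge_hazard,death_hazard Named numeric pairs `c(high=, usual=)`
#'   of constant cause-specific hazards (events/day) for discharge alive and
#'   in-hospital death; a zero rate disables the corresponding process.
#' @param n_missing_outcome,n_missing_creatinine Numbers of records whose
#'   60-day outcome / baseline creatinine are set missing.
#' @param seed Integer seed; mandatory, every draw is reproducible.
#' @return An object of class `generator_config`.
#' @export
generator_config <- function(n_per_arm = c(645L, 656L),
                             n_sites = 85L,
                             largest_site_size = 120L,
                             site_size_decay = 0.97,
                             alpha_true = stats::qlogis(0.322),
                             beta_true = 0.103,
                             site_sd = 0.3,
                             gamma_creatinine = 0.5,
                             gamma_sofa = 0.07,
                             gamma_bmi = 0,
                             delta_creatinine = 0,
                             delta_sofa = 0,
                             delta_bmi = 0,
                             discharge_hazard = c(high = 0.0273, usual = 0.030),
                             death_hazard = c(high = 0.008, usual = 0.008),
                             n_missing_outcome = 4L,
                             n_missing_creatinine = 90L,
                             seed) {
  if (missing(seed)) stop("'seed' is mandatory", call. = FALSE)
  stopifnot(length(n_per_arm) == 2L, all(n_per_arm >= 0),
            n_sites >= 1L, largest_site_size >= 1L, site_size_decay > 0,
            length(discharge_hazard) == 2L, length(death_hazard) == 2L,
            all(discharge_hazard >= 0), all(death_hazard >= 0),
            n_missing_outcome >= 0L, n_missing_creatinine >= 0L)
  n_total <- sum(n_per_arm)
  if (n_missing_outcome > n_total || n_missing_creatinine > n_total)
    stop("missingness counts cannot exceed the cohort size", call. = FALSE)
  if (largest_site_size > n_total)
    stop("'largest_site_size' cannot exceed the cohort size", call. = FALSE)
  cfg <- list(n_per_arm = as.integer(n_per_arm), n_sites = as.integer(n_sites),
              largest_site_size = as.integer(largest_site_size),
              site_size_decay = site_size_decay, alpha_true = alpha_true,
              beta_true = beta_true, site_sd = site_sd,
              gamma_creatinine = gamma_creatinine, gamma_sofa = gamma_sofa,
              gamma_bmi = gamma_bmi, delta_creatinine = delta_creatinine,
              delta_sofa = delta_sofa, delta_bmi = delta_bmi,
              discharge_hazard = discharge_hazard,
              death_hazard = death_hazard,
              n_missing_outcome = as.integer(n_missing_outcome),
              n_missing_creatinine = as.integer(n_missing_creatinine),
              seed = as.integer(seed))
  class(cfg) <- "generator_config"
  cfg
}

#' Read a generator configuration from YAML
#'
#' The YAML mapping mirrors the arguments of [generator_config()]; `seed` is
#' mandatory.
#'
#' @param path Path to a YAML file.
#' @return A [generator_config()].
#' @export
read_generator_config_yaml <- function(path) {
  x <- yaml::read_yaml(path)
  if (is.null(x$seed)) stop("generator YAML must set 'seed'", call. = FALSE)
  for (h in c("discharge_hazard", "death_hazard"))
    if (!is.null(x[[h]])) x[[h]] <- unlist(x[[h]])
  do.call(generator_config, x)
}

#' Site-size plan with one dominant reference site
#'
#' Allocates a cohort across sites: the largest site is fixed, and the
#' remaining participants are spread over the other sites proportionally to a
#' geometric decay of ratio `decay`, with integer sizes set by the
#' largest-remainder method. Site 1 is the dominant site; every other site is
#' strictly smaller.
#'
#' @param n_total Total number of participants.
#' @param n_sites Number of sites.
#' @param largest_site_size Participants at the dominant site.
#' @param decay Geometric decay ratio for the remaining sites.
#' @return Named integer vector of site sizes (names `S01`, `S02`, ...).
#' @export
site_size_plan <- function(n_total, n_sites, largest_site_size = 120L,
                           decay = 0.97) {
  stopifnot(n_total >= n_sites, n_sites >= 1L, largest_site_size >= 1L,
            decay > 0)
  width <- max(2L, nchar(as.character(n_sites)))
  labels <- sprintf(paste0("S%0", width, "d"), seq_len(n_sites))
  if (n_sites == 1L) {
    if (largest_site_size != n_total)
      stop("with one site, 'largest_site_size' must equal 'n_total'",
           call. = FALSE)
    return(stats::setNames(as.integer(n_total), labels))
  }
  rest <- n_total - largest_site_size
  if (rest < n_sites - 1L)
    stop("not enough participants to give every site at least one",
         call. = FALSE)
  w <- decay^seq_len(n_sites - 1L)
  target <- rest * w / sum(w)
  sizes <- floor(target)
  rem <- rest - sum(sizes)
  if (rem > 0) {
    extra <- order(target - sizes, decreasing = TRUE)[seq_len(rem)]
    sizes[extra] <- sizes[extra] + 1L
  }
  sizes <- pmax(sizes, 1L)
  # largest-remainder can leave the total off by the pmax clamp; repair from
  # the biggest non-reference sites downwards
  excess <- sum(sizes) - rest
  i <- 1L
  while (excess > 0) {
    if (sizes[i] > 1L) { sizes[i] <- sizes[i] - 1L; excess <- excess - 1L }
    i <- if (i == length(sizes)) 1L else i + 1L
  }
  if (max(sizes) >= largest_site_size)
    stop("site-size plan does not leave the reference site strictly largest",
         call. = FALSE)
  stats::setNames(as.integer(c(largest_site_size, sizes)), labels)
}

#' Stratified 1:1 arm allocation within sites
#'
#' Splits every site as evenly as possible between arms (|high - usual| <= 1
#' within each site) while hitting the exact overall arm totals; which
#' odd-sized sites contribute their extra participant to the high-protein arm
#' is chosen uniformly at random from the allocations consistent with the
#' totals.
#'
#' @keywords internal
#' @noRd
.allocate_arms <- function(sizes, n_high, n_usual) {
  if (sum(sizes) != n_high + n_usual)
    stop("arm totals do not match the site-size plan", call. = FALSE)
  base_high <- floor(sizes / 2)
  odd <- which(sizes %% 2L == 1L)
  k <- n_high - sum(base_high)
  if (k < 0 || k > length(odd))
    stop("impossible configuration: arm totals incompatible with ",
         "within-site 1:1 allocation", call. = FALSE)
  extra_high <- if (k > 0) odd[sample.int(length(odd), k)] else integer(0)
  n_high_site <- base_high
  n_high_site[extra_high] <- n_high_site[extra_high] + 1L
  unlist(lapply(seq_along(sizes), function(s) {
    a <- c(rep(1L, n_high_site[s]), rep(0L, sizes[s] - n_high_site[s]))
    a[sample.int(length(a))]
  }), use.names = FALSE)
}

#' Draw baseline covariates
#' @keywords internal
#' @noRd
.draw_covariates <- function(n) {
  cd <- .covariate_defaults
  sofa <- pmin(24L, pmax(0L, as.integer(round(stats::rnorm(n, cd$sofa_mean,
                                                           cd$sofa_sd)))))
  creatinine <- stats::rlnorm(n, cd$creat_meanlog, cd$creat_sdlog)
  bmi <- stats::rlnorm(n, cd$bmi_meanlog, cd$bmi_sdlog)
  data.frame(sofa = sofa, creatinine = creatinine, bmi = bmi,
             aki = as.integer(creatinine > cd$aki_threshold))
}

#' Draw competing-risk hospital-course times
#'
#' Latent exponential times to discharge alive and to in-hospital death; the
#' first to occur before day 60 wins, times are rounded up to whole days
#' (day-granularity records, so ties are expected downstream).
#'
#' @keywords internal
#' @noRd
.draw_course <- function(arm, discharge_hazard, death_hazard) {
  n <- length(arm)
  rate_d <- ifelse(arm == 1L, discharge_hazard[["high"]],
                   discharge_hazard[["usual"]])
  rate_x <- ifelse(arm == 1L, death_hazard[["high"]], death_hazard[["usual"]])
  t_d <- ifelse(rate_d > 0, stats::rexp(n) / pmax(rate_d, 1e-300), Inf)
  t_x <- ifelse(rate_x > 0, stats::rexp(n) / pmax(rate_x, 1e-300), Inf)
  discharged <- t_d < t_x & t_d <= 60
  died <- !discharged & t_x <= 60
  t <- ifelse(discharged, t_d, ifelse(died, t_x, 60))
  data.frame(t_discharge = pmin(ceiling(t), 60),
             discharge_event = as.integer(discharged),
             died_in_hospital = as.integer(died))
}

#' Generate a fully synthetic trial cohort
#'
#' Simulates a multi-site two-arm trial from a [generator_config()]:
#' participants are spread over sites by [site_size_plan()], randomised 1:1
#' within site, given baseline covariates (SOFA, creatinine, BMI, AKI), a
#' 60-day mortality outcome drawn from the hierarchical logistic model
#' `logit P(death) = alpha_true + u_site + beta_true*arm + covariate and
#' interaction terms` (site effects `u ~ N(0, site_sd)`, zero at the
#' reference site), and a hospital course drawn from competing exponential
#' discharge/death hazards truncated at day 60. The configured numbers of
#' missing outcomes and creatinine values are then injected. The 60-day
#' mortality outcome and the hospital-course times are drawn from their own
#' generative laws and are conditionally independent given arm and site.
#'
#' @param config A [generator_config()].
#' @return A [trial_dataset()].
#' @examples
#' ds <- generate_cohort(generator_config(n_per_arm = c(50, 50), n_sites = 5,
#'                                        largest_site_size = 40,
#'                                        n_missing_outcome = 0,
#'                                        n_missing_creatinine = 0, seed = 1))
#' ds
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "generator_config"))
  .with_seed(config$seed, {
    n_total <- sum(config$n_per_arm)
    sizes <- site_size_plan(n_total, config$n_sites,
                            config$largest_site_size, config$site_size_decay)
    site_id <- rep(names(sizes), sizes)
    arm <- .allocate_arms(sizes, config$n_per_arm[1L], config$n_per_arm[2L])
    cov <- .draw_covariates(n_total)
    u <- c(0, stats::rnorm(length(sizes) - 1L, 0, config$site_sd))
    names(u) <- names(sizes)
    cd <- .covariate_defaults
    c_creat <- log2(cov$creatinine) - cd$centre_log2_creat
    c_sofa <- cov$sofa - cd$centre_sofa
    c_bmi <- cov$bmi - cd$centre_bmi
    eta <- config$alpha_true + u[site_id] + config$beta_true * arm +
      config$gamma_creatinine * c_creat + config$gamma_sofa * c_sofa +
      config$gamma_bmi * c_bmi +
      arm * (config$delta_creatinine * c_creat + config$delta_sofa * c_sofa +
               config$delta_bmi * c_bmi)
    death60 <- stats::rbinom(n_total, 1L, stats::plogis(eta))
    course <- .draw_course(arm, config$discharge_hazard, config$death_hazard)
    ds <- trial_dataset(data.frame(
      patient_id = sprintf("P%05d", seq_len(n_total)),
      site_id = site_id, arm = arm, death60 = death60, course, cov))
    inject_missingness(ds, config$n_missing_outcome,
                       config$n_missing_creatinine,
                       seed = config$seed + 1L)
  })
}

#' Arm-level summary of a published trial result
#'
#' Holds the printed arm sizes and point-estimate event risks used to
#' reconstruct an approximate patient-level cohort.
#'
#' @param n_high,n_usual Arm sizes.
#' @param risk_high,risk_usual Event proportions in `[0, 1]`.
#' @return An object of class `arm_summary`.
#' @export
arm_summary <- function(n_high, n_usual, risk_high, risk_usual) {
  stopifnot(n_high >= 0, n_usual >= 0)
  if (risk_high < 0 || risk_high > 1 || risk_usual < 0 || risk_usual > 1)
    stop("risks must lie in [0, 1]", call. = FALSE)
  structure(list(n_high = as.integer(n_high), n_usual = as.integer(n_usual),
                 risk_high = risk_high, risk_usual = risk_usual),
            class = "arm_summary")
}

#' Reconstruct an approximate cohort from printed arm-level summaries
#'
#' Builds a patient-level dataset whose arm sizes and death counts match a
#' published result: per-arm deaths are the nearest integer (ties to even) of
#' size times risk, assigned uniformly at random across the arm's
#' participants. Sites follow [site_size_plan()] with balanced within-site
#' allocation; covariates and hospital-course times are drawn from the
#' generator's default distributions (independent of the assigned outcome,
#' since the summaries carry no information about them). The result is
#' deterministic given the seed: the same summary and seed give a
#' byte-identical CSV.
#'
#' @param summary An [arm_summary()].
#' @param n_sites Number of sites (default 85).
#' @param largest_site_size Size of the dominant reference site (default 120).
#' @param seed Integer seed.
#' @param site_size_decay Geometric decay ratio of the site plan.
#' @return A [trial_dataset()].
#' @examples
#' ds <- reconstruct_from_summaries(arm_summary(645, 656, 0.345, 0.322),
#'                                  seed = 1)
#' sum(ds$death60[ds$arm == 1]) # 223 = round(645 * 0.345)
#' @export
reconstruct_from_summaries <- function(summary, n_sites = 85L,
                                       largest_site_size = 120L, seed,
                                       site_size_decay = 0.97) {
  stopifnot(inherits(summary, "arm_summary"), n_sites >= 1L)
  if (missing(seed)) stop("'seed' is mandatory", call. = FALSE)
  .with_seed(seed, {
    n_total <- summary$n_high + summary$n_usual
    sizes <- site_size_plan(n_total, n_sites, largest_site_size,
                            site_size_decay)
    site_id <- rep(names(sizes), sizes)
    arm <- .allocate_arms(sizes, summary$n_high, summary$n_usual)
    d_high <- as.integer(round(summary$n_high * summary$risk_high))
    d_usual <- as.integer(round(summary$n_usual * summary$risk_usual))
    death60 <- integer(n_total)
    idx_high <- which(arm == 1L)
    idx_usual <- which(arm == 0L)
    if (d_high > 0) death60[idx_high[sample.int(length(idx_high), d_high)]] <- 1L
    if (d_usual > 0) death60[idx_usual[sample.int(length(idx_usual), d_usual)]] <- 1L
    cov <- .draw_covariates(n_total)
    course <- .draw_course(arm, c(high = 0.0273, usual = 0.030),
                           c(high = 0.008, usual = 0.008))
    trial_dataset(data.frame(
      patient_id = sprintf("P%05d", seq_len(n_total)),
      site_id = site_id, arm = arm, death60 = death60, course, cov))
  })
}

#' Inject exact numbers of missing values into a cohort
#'
#' Sets the 60-day outcome of `n_missing_outcome` records and the baseline
#' creatinine of `n_missing_creatinine` records to missing, each set chosen
#' uniformly at random (seeded, independently of each other). The counts are
#' exact, not probabilistic; all other fields are untouched.
#'
#' @param ds A [trial_dataset()].
#' @param n_missing_outcome,n_missing_creatinine Numbers of records to blank.
#' @param seed Integer seed.
#' @return A [trial_dataset()].
#' @export
inject_missingness <- function(ds, n_missing_outcome, n_missing_creatinine,
                               seed) {
  stopifnot(inherits(ds, "trial_dataset"))
  if (missing(seed)) stop("'seed' is mandatory", call. = FALSE)
  n <- nrow(ds)
  if (n_missing_outcome > n || n_missing_creatinine > n)
    stop("missingness counts cannot exceed the cohort size", call. = FALSE)
  if (n_missing_outcome == 0 && n_missing_creatinine == 0) return(ds)
  .with_seed(seed, {
    if (n_missing_outcome > 0)
      ds$death60[sample.int(n, n_missing_outcome)] <- NA_integer_
    if (n_missing_creatinine > 0)
      ds$creatinine[sample.int(n, n_missing_creatinine)] <- NA_real_
    ds
  })
}
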