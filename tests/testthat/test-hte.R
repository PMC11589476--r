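test_that("covariate transforms follow the field conventions", {
  # a doubling of creatinine is exactly one unit on the log2 scale
  expect_equal(diff(transform_covariate(c(80, 160), "log2")), 1)
  expect_error(transform_covariate(c(-1, 80), "log2"), "positive")
  # SOFA >= 9 marks the high-severity stratum
  expect_equal(transform_covariate(c(8, 9), "indicator_ge", 9), c(0, 1))
  # BMI 30.0 belongs to the lower stratum ("<= 30")
  expect_equal(transform_covariate(c(30, 30.0001), "indicator_gt", 30),
               c(0, 1))
  expect_equal(transform_covariate(c(2, 5), "identity"), c(2, 5))
  expect_error(transform_covariate(1:3, "indicator_ge"), "threshold")
})

test_that("the interaction summariser reproduces closed-form probabilities", {
  d0 <- make_fake_draws(list(delta = rep(0, 1000)),
                        meta = list(outcome = "mortality",
                                    covariate = "creatinine",
                                    transform = "log2", n_analysed = 100L,
                                    n_excluded = 0L))
  s0 <- interaction_summary(d0)
  expect_equal(s0$delta_or[["median"]], 1)
  expect_equal(s0$p_positive_interaction, 0)  # strict inequality
  # draws around log 1.14 with the scale implied by the 0.98-1.31 CrI
  set.seed(77)
  sc <- log(1.31 / 0.98) / (2 * qnorm(0.975))
  expect_equal(sc, 0.0741, tolerance = 2e-2)
  d1 <- make_fake_draws(list(delta = rnorm(1e6, log(1.14), sc)),
                        meta = list(outcome = "mortality",
                                    covariate = "creatinine",
                                    transform = "log2", n_analysed = 1207L,
                                    n_excluded = 94L))
  s1 <- interaction_summary(d1)
  expect_equal(s1$p_positive_interaction, pnorm(log(1.14) / sc),
               tolerance = 2e-3)
  expect_equal(s1$delta_or[["median"]], 1.14, tolerance = 2e-3)
  expect_equal(s1$delta_or[["lower"]], exp(log(1.14) - qnorm(0.975) * sc),
               tolerance = 5e-3)
  expect_equal(s1$delta_or[["upper"]], exp(log(1.14) + qnorm(0.975) * sc),
               tolerance = 5e-3)
  # the two interaction directions always partition the draws
  set.seed(78)
  d2 <- make_fake_draws(list(delta = rnorm(5000, 0.05, 0.2)),
                        meta = d1$meta)
  s2 <- interaction_summary(d2)
  expect_equal(s2$p_positive_interaction + s2$p_negative_interaction, 1)
})

test_that("interaction fits use per-analysis complete cases", {
  cfg <- make_small_config(n_per_arm = c(150, 150), n_sites = 4,
                           largest_site_size = 120, seed = 81)
  ds <- generate_cohort(cfg)
  ds <- inject_missingness(ds, 5, 12, seed = 82)
  fit_cr <- fit_interaction(ds, "creatinine", n_chains = 2, n_iter = 200,
                            n_warmup = 300, seed = 2)
  expected_cr <- sum(!is.na(ds$death60) & !is.na(ds$creatinine))
  expect_equal(fit_cr$meta$n_analysed, expected_cr)
  expect_lte(fit_cr$meta$n_analysed, 295)
  fit_sofa <- fit_interaction(ds, "sofa", n_chains = 2, n_iter = 200,
                              n_warmup = 300, seed = 2)
  # SOFA is never missing here: only the missing outcomes are dropped
  expect_equal(fit_sofa$meta$n_analysed, 295)
})

test_that("a constant covariate is rejected as unidentifiable", {
  ds <- make_two_arm_cohort(30, 9, 30, 8)  # every covariate constant
  expect_error(fit_interaction(ds, "sofa", n_chains = 2, n_iter = 100,
                               n_warmup = 100, seed = 1),
               "unidentifiable")
})

test_that("interaction inference is invariant to covariate location shifts", {
  cfg <- make_small_config(n_per_arm = c(100, 100), n_sites = 3,
                           largest_site_size = 80, seed = 83)
  ds <- generate_cohort(cfg)
  ds2 <- ds
  ds2$bmi <- ds$bmi + 7.5
  f1 <- fit_interaction(ds, "bmi", n_chains = 2, n_iter = 300, n_warmup = 300,
                        seed = 3)
  f2 <- fit_interaction(ds2, "bmi", n_chains = 2, n_iter = 300,
                        n_warmup = 300, seed = 3)
  # median centring absorbs the shift: all draws coincide exactly
  expect_identical(param_draws(f1, "delta"), param_draws(f2, "delta"))
  expect_identical(param_draws(f1, "beta"), param_draws(f2, "beta"))
})

test_that("subgroup effects scale the stratum odds ratio by exp(delta) draw by draw", {
  set.seed(91)
  n <- 4000
  d <- make_fake_draws(list(alpha = rnorm(n, -0.8, 0.2),
                            beta = rep(0, n),
                            gamma = rnorm(n, 0.4, 0.1),
                            delta = rep(log(2), n),
                            u_S01 = rep(0, n)),
                       meta = list(outcome = "mortality",
                                   reference_site = "S01",
                                   covariate = "aki",
                                   transform = "indicator_ge",
                                   cov_centre = 0, n_analysed = 500L,
                                   n_excluded = 0L))
  sg <- subgroup_effects(d)
  expect_named(sg, c("stratum_0", "stratum_1"))
  # with beta = 0 and delta = log 2 the stratum-1 OR is exactly twice the
  # stratum-0 OR in every draw, so the medians are exactly 1 and 2
  expect_equal(sg$stratum_0$or_[["median"]], 1, tolerance = 1e-10)
  expect_equal(sg$stratum_1$or_[["median"]], 2, tolerance = 1e-10)
  # stratum effects equal the interaction-model conditional effects
  rk1 <- arm_risks(d, covariate_value = 1)
  manual_p_high <- plogis(qlogis(rk1$p_usual) + 0 + log(2))
  expect_equal(rk1$p_high, manual_p_high, tolerance = 1e-12)
  # with delta = 0 the strata coincide
  d0 <- d
  d0$draws[, , "delta"] <- 0
  sg0 <- subgroup_effects(d0)
  expect_equal(sg0$stratum_0$rr, sg0$stratum_1$rr, tolerance = 1e-12)
  # continuous fits are rejected
  dcont <- d
  dcont$meta$covariate <- "creatinine"; dcont$meta$transform <- "log2"
  expect_error(subgroup_effects(dcont), "binary")
})

test_that("interaction summaries serialise to JSON and subgroup tables tabulate", {
  set.seed(92)
  d <- make_fake_draws(list(alpha = rnorm(600, -0.8, 0.2),
                            beta = rnorm(600, 0.1, 0.1),
                            gamma = rnorm(600, 0.4, 0.1),
                            delta = rnorm(600, 0.2, 0.1),
                            u_S01 = rep(0, 600)),
                       meta = list(outcome = "mortality",
                                   reference_site = "S01",
                                   covariate = "aki",
                                   transform = "indicator_ge",
                                   cov_centre = 0, n_analysed = 500L,
                                   n_excluded = 4L))
  f <- withr::local_tempfile(fileext = ".json")
  write_interaction_summary_json(interaction_summary(d), f)
  parsed <- jsonlite::read_json(f)
  expect_equal(parsed$covariate, "aki")
  expect_equal(parsed$n_excluded, 4)
  tab <- as.data.frame(subgroup_effects(d))
  expect_equal(nrow(tab), 2)
  expect_true(all(c("stratum", "rr", "rd") %in% names(tab)))
})
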