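test_that("generated cohorts have the configured size and site structure", {
  cfg <- generator_config(n_per_arm = c(645, 656), n_sites = 85, seed = 7)
  ds <- generate_cohort(cfg)
  expect_s3_class(ds, "trial_dataset")
  expect_equal(nrow(ds), 1301)
  expect_equal(sum(ds$arm == 1), 645)
  expect_equal(sum(ds$arm == 0), 656)
  sizes <- site_sizes(ds)
  expect_length(sizes, 85)
  expect_equal(max(sizes), 120)
  expect_equal(reference_site(ds), names(sizes)[which.max(sizes)])
  # configured structured missingness is exact
  expect_equal(sum(is.na(ds$death60)), 4)
  expect_equal(sum(is.na(ds$creatinine)), 90)
})

test_that("allocation within every site is 1:1 up to one participant", {
  for (seed in 1:3) {
    cfg <- make_small_config(n_per_arm = c(101, 100), n_sites = 7,
                             largest_site_size = 60, seed = seed)
    ds <- generate_cohort(cfg)
    diff_by_site <- tapply(ds$arm, ds$site_id, function(a)
      abs(sum(a == 1) - sum(a == 0)))
    expect_true(all(diff_by_site <= 1))
    expect_equal(sum(ds$arm == 1), 101)
  }
})

test_that("site size plan decays geometrically with a dominant reference site", {
  plan <- site_size_plan(1301, 85, 120, 0.97)
  expect_equal(sum(plan), 1301)
  expect_length(plan, 85)
  expect_equal(plan[[1]], 120)
  expect_true(all(plan[-1] < 120))
  expect_true(all(plan >= 1))
  # monotone non-increasing among the decaying sites
  expect_true(all(diff(plan[-1]) <= 0))
})

test_that("zero cause-specific hazards switch off the corresponding events", {
  cfg <- make_small_config(n_per_arm = c(40, 40), n_sites = 2,
                           largest_site_size = 41, seed = 3,
                           death_hazard = c(high = 0, usual = 0))
  ds <- generate_cohort(cfg)
  expect_true(all(ds$died_in_hospital == 0))
  cfg2 <- make_small_config(n_per_arm = c(40, 40), n_sites = 2,
                            largest_site_size = 41, seed = 3,
                            discharge_hazard = c(high = 0, usual = 0),
                            death_hazard = c(high = 0, usual = 0))
  ds2 <- generate_cohort(cfg2)
  expect_true(all(ds2$discharge_event == 0))
  expect_true(all(ds2$t_discharge == 60))
})

test_that("generated outcomes follow the configured logistic and competing-risk laws", {
  # closed-form oracle needs no covariate effects and no site spread
  h_d <- 0.03; h_x <- 0.01
  cfg <- generator_config(n_per_arm = c(10000, 10000), n_sites = 10,
                          largest_site_size = 2500, site_sd = 0,
                          alpha_true = qlogis(0.3), beta_true = 0.2,
                          gamma_creatinine = 0, gamma_sofa = 0, gamma_bmi = 0,
                          discharge_hazard = c(high = h_d, usual = h_d),
                          death_hazard = c(high = h_x, usual = h_x),
                          n_missing_outcome = 0, n_missing_creatinine = 0,
                          seed = 11)
  ds <- generate_cohort(cfg)
  for (a in 0:1) {
    p_true <- plogis(qlogis(0.3) + 0.2 * a)
    n_a <- sum(ds$arm == a)
    p_emp <- mean(ds$death60[ds$arm == a])
    mc_se <- sqrt(p_true * (1 - p_true) / n_a)
    expect_lt(abs(p_emp - p_true), 3 * mc_se)
  }
  # cause-specific cumulative incidence of discharge: competing exponentials,
  # evaluated at integer days (times are recorded at day granularity)
  for (tt in c(10, 30, 60)) {
    cif_true <- h_d / (h_d + h_x) * (1 - exp(-(h_d + h_x) * tt))
    cif_emp <- mean(ds$discharge_event == 1 & ds$t_discharge <= tt)
    expect_lt(abs(cif_emp - cif_true), 0.02)
  }
})

test_that("reconstruction hits the printed arm sizes and death counts", {
  ds <- reconstruct_from_summaries(arm_summary(645, 656, 0.345, 0.322),
                                   seed = 42)
  expect_equal(nrow(ds), 1301)
  # nearest-integer death counts: 645 x 0.345 = 222.525 -> 223,
  # 656 x 0.322 = 211.232 -> 211
  expect_equal(sum(ds$death60[ds$arm == 1]), 223)
  expect_equal(sum(ds$death60[ds$arm == 0]), 211)
  expect_equal(length(unique(ds$site_id)), 85)
  expect_equal(max(site_sizes(ds)), 120)
  # zero risks give zero deaths
  ds0 <- reconstruct_from_summaries(arm_summary(10, 10, 0, 0), n_sites = 2,
                                    largest_site_size = 11, seed = 1)
  expect_equal(sum(ds0$death60), 0)
  expect_error(arm_summary(10, 10, 1.2, 0), "risks")
})

test_that("reconstruction is deterministic: same seed, byte-identical CSV", {
  s <- arm_summary(100, 100, 0.3, 0.25)
  f1 <- withr::local_tempfile(fileext = ".csv")
  f2 <- withr::local_tempfile(fileext = ".csv")
  write_cohort_csv(reconstruct_from_summaries(s, n_sites = 10,
                                              largest_site_size = 50,
                                              seed = 99), f1)
  write_cohort_csv(reconstruct_from_summaries(s, n_sites = 10,
                                              largest_site_size = 50,
                                              seed = 99), f2)
  expect_identical(readLines(f1), readLines(f2))
  # a different seed moves the deaths around but keeps the counts
  ds3 <- reconstruct_from_summaries(s, n_sites = 10, largest_site_size = 50,
                                    seed = 100)
  expect_equal(sum(ds3$death60[ds3$arm == 1]), 30)
})

test_that("missingness injection is exact and leaves other fields untouched", {
  cfg <- make_small_config(n_per_arm = c(60, 60), n_sites = 3,
                           largest_site_size = 50, seed = 5)
  ds <- generate_cohort(cfg)
  ds2 <- inject_missingness(ds, 7, 13, seed = 8)
  expect_equal(sum(is.na(ds2$death60)), 7)
  expect_equal(sum(is.na(ds2$creatinine)), 13)
  keep <- !is.na(ds2$death60)
  expect_identical(ds2$death60[keep], ds$death60[keep])
  expect_identical(ds2$arm, ds$arm)
  expect_identical(ds2$t_discharge, ds$t_discharge)
  # identity when no missingness requested
  expect_identical(inject_missingness(ds, 0, 0, seed = 1), ds)
  # counts larger than the cohort are rejected
  expect_error(inject_missingness(ds, nrow(ds) + 1, 0, seed = 1),
               "exceed")
})

test_that("cohort CSV round-trips values and missingness", {
  cfg <- make_small_config(n_per_arm = c(30, 30), n_sites = 3,
                           largest_site_size = 30, seed = 2)
  ds <- inject_missingness(generate_cohort(cfg), 3, 5, seed = 3)
  path <- withr::local_tempfile(fileext = ".csv")
  write_cohort_csv(ds, path)
  ds2 <- read_cohort_csv(path)
  expect_equal(as.data.frame(ds2), as.data.frame(ds), tolerance = 1e-12)
  expect_equal(sum(is.na(ds2$death60)), 3)
  expect_equal(sum(is.na(ds2$creatinine)), 5)
})

test_that("cohort CSV schema violations are caught", {
  cfg <- make_small_config(n_per_arm = c(10, 10), n_sites = 2,
                           largest_site_size = 11, seed = 2)
  ds <- generate_cohort(cfg)
  path <- withr::local_tempfile(fileext = ".csv")
  # unknown columns warn and are dropped
  df <- as.data.frame(ds); df$extra <- 1
  utils::write.csv(df, path, row.names = FALSE, na = "")
  expect_warning(ds2 <- read_cohort_csv(path), "unknown columns")
  expect_s3_class(ds2, "trial_dataset")
  # a non-binary arm is a hard error
  df2 <- as.data.frame(ds); df2$arm[1] <- 2L
  utils::write.csv(df2, path, row.names = FALSE, na = "")
  expect_error(read_cohort_csv(path), "arm")
  # missing mandatory columns fail
  df3 <- as.data.frame(ds); df3$site_id <- NULL
  utils::write.csv(df3, path, row.names = FALSE, na = "")
  expect_error(read_cohort_csv(path), "site_id")
  # an empty outcome cell flags the record as missing
  df4 <- as.data.frame(ds); df4$death60[2] <- NA
  utils::write.csv(df4, path, row.names = FALSE, na = "")
  expect_true(is.na(read_cohort_csv(path)$death60[2]))
})

test_that("impossible generator configurations are rejected", {
  expect_error(generator_config(n_per_arm = c(10, 10), n_missing_outcome = 30,
                                n_sites = 2, largest_site_size = 11,
                                seed = 1),
               "exceed")
  expect_error(generator_config(n_per_arm = c(10, 10), seed = 1,
                                n_sites = 2, largest_site_size = 50),
               "cohort size")
  expect_error(generator_config(n_per_arm = c(10, 10), n_sites = 2,
                                largest_site_size = 11),
               "seed")
})

test_that("generator configuration round-trips through YAML", {
  cfg <- make_small_config(seed = 4)
  path <- withr::local_tempfile(fileext = ".yaml")
  yaml::write_yaml(lapply(unclass(cfg), function(x)
    if (length(x) > 1) as.list(x) else x), path)
  cfg2 <- read_generator_config_yaml(path)
  expect_equal(unclass(cfg2)[order(names(cfg2))],
               unclass(cfg)[order(names(cfg))], tolerance = 1e-6)
  # the shipped example configuration is valid and generates
  shipped <- read_generator_config_yaml(
    system.file("extdata", "example-generator-config.yaml",
                package = "bayesrct"))
  ds <- generate_cohort(shipped)
  expect_equal(nrow(ds), 131)
  expect_equal(sum(is.na(ds$creatinine)), 9)
})
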