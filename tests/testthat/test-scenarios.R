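test_that("crossing_dose interpolates linearly in log dose", {
  curve <- structure(data.frame(dose = c(1, 2, 4, 8),
                                avg_sds = c(-1, 0.5, 1.5, 2.5)),
                     class = c("dose_response_curve", "data.frame"))
  hit <- crossing_dose(curve, 0.5)
  expect_equal(hit$dose, 2)                      # exact node
  expect_equal(hit$status, "crossed")
  cr <- crossing_dose(curve, 1.0)                # between nodes 2 and 4
  oracle <- exp(log(2) + (1.0 - 0.5) / (1.5 - 0.5) * (log(4) - log(2)))
  expect_equal(cr$dose, oracle, tolerance = 1e-9)
  expect_equal(crossing_dose(curve, 5)$status, "above_max")
  expect_equal(crossing_dose(curve, -2)$status, "below_min")
})

test_that("dose-response curves start at baseline and are non-decreasing", {
  pop <- reference_population()
  cov <- subject_covariates(age = 45, sex = "male", weight = 75)
  near0 <- somadose:::subject_avg_sds(pop, cov, 1e-4)
  base <- sds_from_conc(individual_params(pop, cov)$pd$R0, 45, "male")
  expect_equal(near0, base, tolerance = 1e-3)
  dr <- dose_response_curve(pop, "le60", doses = c(0.1, 0.5, 1, 2, 4, 8))
  expect_true(all(diff(dr$avg_sds) > 0))
  expect_equal(attr(dr, "drug"), "somapacitan")
})

test_that("missed-dose semantics: zero delay is exactly zero, deficit grows with delay", {
  pop <- reference_population()
  expect_identical(missed_dose_sim(pop, delay = 0), 0)
  expect_error(missed_dose_sim(pop, delay = -1), ">= 0")
  cov <- subject_covariates(age = 45, sex = "male", weight = 75)
  defs <- vapply(c(1, 2, 3), function(d) missed_dose_sim(pop, d, cov = cov),
                 numeric(1))
  expect_true(all(diff(defs) > 0))
  expect_true(all(defs > 0))
})

test_that("dose ratio analysis: printed means give 8.2, scaling is exact", {
  r <- dose_ratio_analysis(2.364, 0.289)
  expect_equal(round(r$mean_ratio, 1), 8.2)
  paired <- dose_ratio_analysis(c(2, 3, 4) * 8.2, c(2, 3, 4))
  expect_equal(unname(paired$ratios), rep(8.2, 3))
  expect_equal(paired$iqr[1], 8.2)
  expect_error(dose_ratio_analysis(2.4, 0), "> 0")
  expect_error(dose_ratio_analysis(c(1, 2), 1), "paired")
})

test_that("per-subject dose ratios of titrated virtual switchers are positive with
           a finite interquartile range", {
  soma <- reference_population()
  trop <- reference_population("somatropin")
  set.seed(21)
  cov_df <- generate_demographics(demographics_spec(n = 16), seed = 22)
  eta <- sample_eta(soma, 16, seed = 23)
  md_s <- md_t <- numeric(16)
  for (i in 1:16) {
    cv <- somadose:::df_row_covariates(cov_df, i)
    md_s[i] <- run_titration(cv, soma, eta = eta[i, ], seed = 300 + i)$maintenance_dose
    md_t[i] <- run_titration(cv, trop, eta = eta[i, ], seed = 300 + i)$maintenance_dose
  }
  r <- dose_ratio_analysis(md_s, md_t)
  expect_true(all(r$ratios > 0))
  expect_true(is.finite(diff(r$iqr)) && diff(r$iqr) >= 0)
  ex <- dose_ratio_analysis(c(md_s, 200), c(md_t, 1), exclude_outliers = TRUE)
  expect_gte(ex$n_excluded, 1L)                   # exclusion is flagged
})

test_that("sampling-window deviation is zero for a flat profile and peaks near day 2", {
  flat <- somadose:::new_sim_profile(seq(0, 7, 0.1), 0, 100, 0.5)
  expect_equal(sampling_window_check(flat), 0)
  pk <- quick_pk(); pd <- quick_pd()
  ss <- add_sds(steady_state_profile(pk, pd, 2.4, 7), 45, "male")
  avg <- weekly_average_sds(ss)
  dev_at <- function(d) abs(ss$sds[which.min(abs(ss$time - d))] - avg)
  expect_gt(dev_at(2), dev_at(3.5))
  expect_error(sampling_window_check(flat, window = c(10, 11)), "window")
})

test_that("identical subjects with no variability give degenerate tails", {
  pop <- reference_population()
  pop$omega[] <- 0
  cov_df <- generate_demographics(demographics_spec(n = 50), seed = 31)
  cov_df$age <- 45; cov_df$sex <- "male"; cov_df$oral_oestrogen <- FALSE
  cov_df$weight <- 75; cov_df$race <- "white_other"
  res <- starting_dose_distribution(cov_df, pop, policy = "low", seed = 32)
  expect_true(res$p_above_2 %in% c(0, 1))
  expect_true(res$p_below_m2 %in% c(0, 1))
  expect_equal(res$sd, 0, tolerance = 1e-9)
})

test_that("the population engine agrees with the single-subject steady-state path", {
  pop <- reference_population()
  cov_df <- generate_demographics(demographics_spec(n = 6), seed = 41)
  eta <- sample_eta(pop, 6, seed = 42)
  fast <- somadose:::population_avg_sds(pop, cov_df, rep(2.4, 6), eta)
  slow <- vapply(1:6, function(i) {
    somadose:::subject_avg_sds(pop, somadose:::df_row_covariates(cov_df, i),
                               2.4, eta[i, ])
  }, numeric(1))
  expect_equal(fast, slow, tolerance = 1e-8)
})

test_that("somatropin missed-dose simulation skips doses and recovers", {
  trop <- reference_population("somatropin")
  d1 <- missed_dose_sim(trop, delay = 1,
                        cov = subject_covariates(age = 45, sex = "male", weight = 75))
  d3 <- missed_dose_sim(trop, delay = 3,
                        cov = subject_covariates(age = 45, sex = "male", weight = 75))
  expect_gt(d3, d1)
  expect_gt(d1, 0)
})
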