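test_that("generated demographics match the specification moments", {
  spec <- demographics_spec(n = 10000)
  cov <- generate_demographics(spec, seed = 501)
  expect_identical(cov, generate_demographics(spec, seed = 501))  # determinism
  # truncated-normal oracle for the expected mean
  tn_mean <- function(mu, sd, lo, hi) {
    a <- (lo - mu) / sd; b <- (hi - mu) / sd
    mu + sd * (dnorm(a) - dnorm(b)) / (pnorm(b) - pnorm(a))
  }
  tn_sd <- function(mu, sd, lo, hi) {
    a <- (lo - mu) / sd; b <- (hi - mu) / sd
    z <- pnorm(b) - pnorm(a)
    sd * sqrt(1 + (a * dnorm(a) - b * dnorm(b)) / z - ((dnorm(a) - dnorm(b)) / z)^2)
  }
  m_age <- tn_mean(46.5, 15.1, 19, 77)
  s_age <- tn_sd(46.5, 15.1, 19, 77)
  expect_lt(abs(mean(cov$age) - m_age), 3 * s_age / sqrt(10000))
  m_wt <- tn_mean(75, 21.5, 34.5, 150.5)
  s_wt <- tn_sd(75, 21.5, 34.5, 150.5)
  expect_lt(abs(mean(cov$weight) - m_wt), 3 * s_wt / sqrt(10000))
  expect_lt(abs(mean(cov$sex == "female") - 0.506), 3 * sqrt(0.25 / 10000))
  expect_lt(abs(mean(cov$oral_oestrogen) - 0.218), 3 * sqrt(0.218 * 0.782 / 10000))
  expect_true(all(cov$age >= 19 & cov$age <= 77))
  expect_true(all(cov$weight >= 34.5 & cov$weight <= 150.5))
  expect_true(all(!cov$oral_oestrogen | cov$sex == "female"))
})

test_that("a trial-sized cohort has the right female fraction and age range", {
  cov <- generate_demographics(demographics_spec(n = 330), seed = 502)
  expect_lt(abs(mean(cov$sex == "female") - 0.506), 3 * sqrt(0.25 / 330))
  expect_true(all(cov$age >= 19 & cov$age <= 77))
})

test_that("infeasible specifications are rejected", {
  expect_error(demographics_spec(frac_oe = 0.6, frac_female = 0.5), "exceeds")
  expect_error(demographics_spec(age_mean = 10), "contain the means")
  expect_error(demographics_spec(race_fracs = c(white_other = 0.5,
                                                asian_japanese = 0.2,
                                                asian_nonjapanese = 0.2)),
               "sum to 1")
})

test_that("noise-free observations equal model predictions recomputed independently", {
  pop <- reference_population()
  pop$omega[] <- 0                       # no random effects
  cov <- generate_demographics(demographics_spec(n = 1), seed = 503)
  cov$prior_treatment <- "naive"
  ds <- generate_trial(cov, pop, seed = 504, noise = FALSE)
  sched <- ds[ds$EVID == 1, ]
  obs_pk <- ds[ds$EVID == 0 & ds$DVID == 1, ]
  obs_pd <- ds[ds$EVID == 0 & ds$DVID == 2 & ds$TIME > 0, ]
  pars <- individual_params(pop, somadose:::df_row_covariates(cov, 1))
  # same grid the generator integrates on (the turnover recurrence is
  # grid-consistent, not grid-free)
  tg <- sort(unique(c(seq(0, 34 * 7, by = 0.1), obs_pk$TIME, obs_pd$TIME,
                      sched$TIME)))
  prof <- simulate_pkpd(pars$pk, pars$pd, regimen(sched$TIME, sched$AMT), tg)
  prof <- add_sds(prof, cov$age, cov$sex)
  expect_equal(obs_pk$DV, prof$conc[match(obs_pk$TIME, tg)], tolerance = 1e-8)
  expect_equal(obs_pd$DV, prof$sds[match(obs_pd$TIME, tg)], tolerance = 1e-8)
})

test_that("a full-size virtual trial has phase-3-like observation counts", {
  pop <- reference_population()
  cov <- generate_demographics(demographics_spec(n = 330), seed = 505)
  ds <- generate_trial(cov, pop, seed = 506)
  n_pk <- sum(ds$EVID == 0 & ds$DVID == 1)
  n_pd <- sum(ds$EVID == 0 & ds$DVID == 2)
  expect_gt(n_pk, 3000); expect_lt(n_pk, 7000)
  expect_gt(n_pd, 3000); expect_lt(n_pd, 7000)
  expect_true(all(table(ds$ID[ds$EVID == 1]) >= 1))
  # dosing-diary delays at the configured frequency (binomial tolerance)
  doses <- ds[ds$EVID == 1, ]
  frac_off <- mean(doses$TIME %% 7 != 0)
  expect_lt(abs(frac_off - 0.08), 3 * sqrt(0.08 * 0.92 / nrow(doses)) + 0.01)
  # naive subjects carry a pre-dose baseline IGF-I record
  naive_ids <- unique(ds$ID[ds$NAIVE == 1])
  base_ids <- unique(ds$ID[ds$EVID == 0 & ds$TIME == 0 & ds$DVID == 2])
  expect_setequal(base_ids, naive_ids)
})

test_that("datasets survive a write -> read round trip", {
  pop <- reference_population()
  cov <- generate_demographics(demographics_spec(n = 3), seed = 507)
  ds <- generate_trial(cov, pop, seed = 508)
  tmp <- tempfile(fileext = ".csv")
  write_dataset(ds, tmp)
  back <- read_dataset(tmp)
  expect_equal(back$DV, ds$DV, tolerance = 1e-10)
  expect_equal(back$TIME, ds$TIME)
  expect_identical(back$BQL, ds$BQL)
  expect_identical(back$SEX, ds$SEX)
})

test_that("the validator names offending rows and flags baseline records", {
  pop <- reference_population()
  cov <- generate_demographics(demographics_spec(n = 2), seed = 509)
  ds <- generate_trial(cov, pop, seed = 510)
  expect_error(validate_dataset(ds[, setdiff(names(ds), "AMT")]), "missing column")
  no_dose <- ds[!(ds$ID == 1 & ds$EVID == 1), ]
  expect_error(validate_dataset(no_dose), "no dose record")
  scrambled <- ds
  scrambled$TIME[scrambled$ID == 1][2] <- 9999
  expect_error(validate_dataset(scrambled), "non-monotone")
  ok <- validate_dataset(ds)
  expect_true(all(ok$BASELINE[ok$EVID == 0 & ok$TIME == 0]))
  expect_false(any(ok$BASELINE[ok$TIME > 0.5]))
})
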