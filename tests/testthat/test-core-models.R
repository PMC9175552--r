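test_that("no dosing means no drug and a flat IGF-I baseline", {
  t <- seq(0, 14, 0.1)
  expect_equal(simulate_pk(quick_pk(), regimen(), t), rep(0, length(t)))
  prof <- simulate_pkpd(quick_pk(), quick_pd(), regimen(), t)
  expect_equal(prof$igf, rep(120, length(t)), tolerance = 1e-12)
})

test_that("linear single-dose solution matches the Bateman closed form to 1e-6", {
  pk <- quick_pk()
  t <- seq(0, 28, 0.05)
  conc <- simulate_pk(pk, regimen(0, 2.4), t)
  ke <- pk$CL / pk$V
  oracle <- pk$F * 2.4 * pk$ka / (pk$V * (pk$ka - ke)) *
    (exp(-ke * t) - exp(-pk$ka * t))
  expect_lt(max(abs(conc - oracle)) / max(oracle), 1e-6)
  expect_equal(conc[t < 0 + 1e-12][1], 0)  # zero at the dose instant
})

test_that("linear model obeys superposition to 1e-6", {
  pk <- quick_pk()
  t <- seq(0, 35, 0.05)
  both <- simulate_pk(pk, regimen(c(0, 7), c(2, 3)), t)
  d1 <- simulate_pk(pk, regimen(0, 2), t)
  d2 <- simulate_pk(pk, regimen(7, 3), t)
  expect_lt(max(abs(both - (d1 + d2))) / max(both), 1e-6)
})

test_that("turnover model reaches the analytic steady state under constant drug", {
  pd <- quick_pd()
  cstar <- 0.5
  t <- seq(0, 40, 0.01)
  igf <- somadose:::pd_solve(pd, t, rep(cstar, length(t)))
  expected <- pd$R0 * (1 + pd$Emax * cstar / (pd$EC50 + cstar))
  expect_equal(igf[length(igf)], expected, tolerance = 1e-4)
})

test_that("Hill term with gamma = 1 is scale invariant in (conc, EC50)", {
  pk <- quick_pk()
  t <- seq(0, 28, 0.02)
  reg <- uniform_regimen(2.4, 4)
  reg_half <- uniform_regimen(1.2, 4)
  a <- simulate_pkpd(pk, quick_pd(), reg, t)
  b <- simulate_pkpd(pk, quick_pd(EC50 = 0.33), reg_half, t)
  expect_equal(a$igf, b$igf, tolerance = 1e-10)
})

test_that("analytic linear path agrees with a fixed-step RK4 reference to 1e-5", {
  pk <- quick_pk()
  pd <- quick_pd()
  reg <- uniform_regimen(2.4, 4)
  t <- seq(0, 28, 0.005)
  prof <- simulate_pkpd(pk, pd, reg, t)
  # independent reference: RK4 at a halved fixed step on the joint ODE,
  # with bolus doses applied between steps
  h <- 0.0025
  tt <- seq(0, 28, h)
  deriv <- function(y, pk, pd) {
    C <- y[2] / pk$V
    E <- pd$Emax * C^pd$gamma / (pd$EC50^pd$gamma + C^pd$gamma)
    c(-pk$ka * y[1],
      pk$ka * y[1] - pk$CL * C,
      pd$kout * pd$R0 * (1 + E) - pd$kout * y[3])
  }
  y <- c(0, 0, pd$R0)
  out <- matrix(NA_real_, length(tt), 3)
  for (i in seq_along(tt)) {
    if (any(abs(reg$time - tt[i]) < h / 2)) {
      y[1] <- y[1] + pk$F * reg$amount[which.min(abs(reg$time - tt[i]))]
    }
    out[i, ] <- y
    k1 <- deriv(y, pk, pd); k2 <- deriv(y + h / 2 * k1, pk, pd)
    k3 <- deriv(y + h / 2 * k2, pk, pd); k4 <- deriv(y + h * k3, pk, pd)
    y <- y + h / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
  }
  idx <- match(round(t / h), round(tt / h))
  expect_lt(max(abs(prof$conc - out[idx, 2] / pk$V)) / max(prof$conc), 1e-5)
  expect_lt(max(abs(prof$igf - out[idx, 3])) / max(prof$igf), 1e-5)
})

test_that("total linear elimination balances absorbed dose to 0.1%", {
  pk <- quick_pk()
  reg <- regimen(c(0, 7, 14), c(2, 2, 2))
  t <- seq(0, 120, 0.02)
  conc <- simulate_pk(pk, reg, t)
  eliminated <- sum((conc[-1] + conc[-length(conc)]) / 2 * diff(t)) * pk$CL
  expect_equal(eliminated, pk$F * sum(reg$amount), tolerance = 1e-3)
})

test_that("saturable elimination yields supra-proportional exposure", {
  pk <- quick_pk(Vmax = 1.2, Km = 0.05)
  pd <- quick_pd()
  avg_per_dose <- vapply(c(1, 3, 8), function(d) {
    ss <- steady_state_profile(pk, pd, d, 7, n_points = 101)
    mean(ss$conc) / d
  }, numeric(1))
  expect_true(all(diff(avg_per_dose) > 0))
})

test_that("steady state: zero dose is flat, average concentration obeys F*D/(CL*tau)", {
  pk <- quick_pk(); pd <- quick_pd()
  flat <- steady_state_profile(pk, pd, 0, 7)
  expect_equal(unique(flat$conc), 0)
  expect_equal(unique(flat$igf), pd$R0)
  for (spec in list(list(pk = pk, dose = 2.4, tau = 7),
                    list(pk = quick_pk(ka = 12, CL = 6 * log(2) / 0.125, V = 6, F = 0.8),
                         dose = 0.3, tau = 1))) {
    ss <- steady_state_profile(spec$pk, pd, spec$dose, spec$tau, n_points = 4001)
    cavg <- somadose:::trapz_mean(ss$time, ss$conc)
    expect_equal(cavg, spec$pk$F * spec$dose / (spec$pk$CL * spec$tau),
                 tolerance = 1e-4)
  }
})

test_that("steady-state profile converges; IGF-I is at steady state within 2
           weekly doses at clinical (0.05 SDS) resolution", {
  pk <- quick_pk(); pd <- quick_pd()
  ss <- steady_state_profile(pk, pd, 2.4, 7)
  expect_true(attr(ss, "converged"))
  expect_lte(attr(ss, "n_intervals"), 10)
  # a titration sample drawn on days 3-4 after the second weekly dose
  # reads within 0.1 SDS of its steady-state value (well under the
  # 0.30-SDS observation noise)
  prof <- simulate_pkpd(pk, pd, uniform_regimen(2.4, 3), seq(0, 21, by = 7 / 240))
  prof <- add_sds(prof, 45, "male")
  ssc <- add_sds(steady_state_profile(pk, pd, 2.4, 7, tol = 1e-6), 45, "male")
  second <- prof$sds[prof$time >= 7 - 1e-9 & prof$time <= 14 + 1e-9]
  win <- ssc$time >= 3 & ssc$time <= 4
  expect_lt(max(abs(second[win] - ssc$sds[win])), 0.1)
})

test_that("steady-state averages are non-decreasing in dose", {
  pk <- quick_pk(); pd <- quick_pd()
  doses <- c(0.1, 0.5, 1, 2, 4, 8)
  res <- vapply(doses, function(d) {
    ss <- steady_state_profile(pk, pd, d, 7)
    c(mean(ss$conc), somadose:::trapz_mean(ss$time, ss$igf))
  }, numeric(2))
  expect_true(all(diff(res[1, ]) > 0))
  expect_true(all(diff(res[2, ]) > 0))
})

test_that("fast periodic steady state agrees with the run-in definition", {
  pk <- quick_pk(); pd <- quick_pd()
  run_in <- steady_state_profile(pk, pd, 2.4, 7, tol = 1e-6)
  fast <- somadose:::ss_profile_linear(pk, pd, 2.4, 7)
  expect_lt(max(abs(run_in$igf - fast$igf) / fast$igf), 1e-4)
})

test_that("interval-average IGF-I does not depend on the turnover rate", {
  pk <- quick_pk()
  a <- somadose:::ss_profile_linear(pk, quick_pd(kout = 0.3), 2.4, 7)
  b <- somadose:::ss_profile_linear(pk, quick_pd(kout = 1.4), 2.4, 7)
  expect_equal(somadose:::trapz_mean(a$time, a$igf),
               somadose:::trapz_mean(b$time, b$igf), tolerance = 1e-5)
})

test_that("weekly_average_sds is the exact trapezoidal time average", {
  prof <- somadose:::new_sim_profile(0:7, 0, 100, rep(0.7, 8))
  expect_equal(weekly_average_sds(prof), 0.7)
  prof$sds <- seq(-1, 2, length.out = 8)   # linear from a to b -> (a+b)/2
  expect_equal(weekly_average_sds(prof), 0.5)
  bad <- prof; bad$time <- c(0, 2, 1, 3:7)
  expect_error(weekly_average_sds(bad), "non-monotone")
})

test_that("profile_tmax returns the earliest maximiser", {
  t <- seq(0, 7, 0.5)
  dec <- somadose:::new_sim_profile(t, 0, 100, exp(-t))
  expect_equal(profile_tmax(dec), 0)
  pulse <- somadose:::new_sim_profile(t, 0, 100, -(t - 3)^2)
  expect_equal(profile_tmax(pulse), 3)
  tie <- somadose:::new_sim_profile(t, 0, 100, rep(1, length(t)))
  expect_equal(profile_tmax(tie), 0)
})

test_that("parameter containers reject invalid values", {
  expect_error(pk_params(ka = -1, CL = 3, V = 12), "positive")
  expect_error(pk_params(ka = 4, CL = 3, V = 12, F = 1.4), "F must lie")
  expect_error(pd_params(R0 = 100, kout = 0, Emax = 8, EC50 = 1), "positive")
  expect_error(regimen(times = -1, amounts = 2), ">= 0")
  expect_silent(validate_pk_params(pk_params(ka = 4, CL = 3, V = 12, Vmax = 0)))
})
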