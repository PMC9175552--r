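#' @importFrom stats approx filter optim rnorm runif setNames uniroot
NULL

# Closed-form concentration for the linear one-compartment model
# (first-order absorption, first-order elimination) under an arbitrary
# sequence of bolus depot doses, by superposition of Bateman terms.
conc_linear <- function(pk, dose_times, amounts, times) {
  ke <- pk$CL / pk$V
  ka <- pk$ka
  if (abs(ka - ke) < 1e-10 * ka) ka <- ka * (1 + 1e-8)  # flip-flop guard
  conc <- numeric(length(times))
  if (!length(dose_times)) return(conc)
  coef <- pk$F * pk$ka / (pk$V * (ka - ke))
  for (i in seq_along(dose_times)) {
    dt <- times - dose_times[i]
    on <- dt >= 0
    if (any(on)) {
      conc[on] <- conc[on] + coef * amounts[i] * (exp(-ke * dt[on]) - exp(-ka * dt[on]))
    }
  }
  pmax(conc, 0)
}

# Linear-model concentration over one dosing interval after n equal doses
# at interval tau (accumulation form), at local times t in [0, tau].
conc_linear_accum <- function(pk, dose, tau, tloc, n) {
  ke <- pk$CL / pk$V
  ka <- pk$ka
  if (abs(ka - ke) < 1e-10 * ka) ka <- ka * (1 + 1e-8)
  coef <- pk$F * dose * pk$ka / (pk$V * (ka - ke))
  acc_e <- (1 - exp(-n * ke * tau)) / (1 - exp(-ke * tau))
  acc_a <- (1 - exp(-n * ka * tau)) / (1 - exp(-ka * tau))
  pmax(coef * (exp(-ke * tloc) * acc_e - exp(-ka * tloc) * acc_a), 0)
}

# Periodic steady-state concentration (n -> Inf limit of conc_linear_accum).
conc_linear_ss <- function(pk, dose, tau, tloc) {
  ke <- pk$CL / pk$V
  ka <- pk$ka
  if (abs(ka - ke) < 1e-10 * ka) ka <- ka * (1 + 1e-8)
  coef <- pk$F * dose * pk$ka / (pk$V * (ka - ke))
  pmax(coef * (exp(-ke * tloc) / (1 - exp(-ke * tau)) -
                 exp(-ka * tloc) / (1 - exp(-ka * tau))), 0)
}

# Hill stimulation term.
hill_stim <- function(pd, conc) {
  cg <- conc^pd$gamma
  pd$Emax * cg / (pd$EC50^pd$gamma + cg)
}

# Exponential-time-differencing coefficients for one step of the linear
# turnover equation dR/dt = a(t) - k R with a(t) interpolated linearly
# on the step: R_{j+1} = d R_j + w0 a_j + w1 a_{j+1}.  Exact for
# constant a; O(h^3) local error otherwise.
etd_coeffs <- function(k, h) {
  kh <- k * h
  d <- exp(-kh)
  if (kh > 1e-4) {
    c1 <- (1 - d) / k
    c2 <- (h * c1 - (1 - d * (1 + kh)) / k^2) / h
  } else {  # series forms avoid cancellation for tiny k*h
    c1 <- h * (1 - kh / 2 + kh^2 / 6)
    c2 <- h / 2 * (1 - kh / 3)
  }
  list(d = d, w0 = c1 - c2, w1 = c2)
}

# Exact-in-R integration of the turnover equation given a concentration
# series on a time grid: dR/dt = kout*R0*(1 + E(C(t))) - kout*R is
# linear in R, so each step applies the exponential-time-differencing
# recurrence (stats::filter on uniform grids runs it in compiled code).
pd_solve <- function(pd, times, conc, R_init = pd$R0) {
  n <- length(times)
  if (n == 1L) return(R_init)
  a <- pd$kout * pd$R0 * (1 + hill_stim(pd, conc))
  h <- diff(times)
  if (any(h <= 0)) stop("pd_solve: time grid must be strictly increasing", call. = FALSE)
  uniform <- (max(h) - min(h)) < 1e-9 * max(h)
  if (uniform) {
    co <- etd_coeffs(pd$kout, h[1])
    u <- co$w0 * a[-n] + co$w1 * a[-1]
    R <- c(R_init, as.numeric(stats::filter(u, co$d, method = "recursive",
                                            init = R_init)))
  } else {
    R <- numeric(n)
    R[1] <- R_init
    for (j in seq_len(n - 1L)) {
      co <- etd_coeffs(pd$kout, h[j])
      R[j + 1L] <- R[j] * co$d + co$w0 * a[j] + co$w1 * a[j + 1L]
    }
  }
  R
}

new_sim_profile <- function(time, conc, igf = NA_real_, sds = NA_real_, ...) {
  structure(
    data.frame(time = time, conc = conc, igf = igf, sds = sds),
    class = c("sim_profile", "data.frame"), ...
  )
}

#' Simulate drug concentrations under a dosing regimen
#'
#' Deterministic solution of the depot-to-central model with elimination
#' rate `CL*C + Vmax*C/(Km + C)`.  For the linear model (`Vmax = 0`) the
#' closed-form Bateman superposition is evaluated; otherwise the ODE
#' system is integrated with [deSolve::lsoda()] with dose events adding
#' `F * amount` to the depot.
#'
#' @param pk A [pk_params()] object.
#' @param reg A [regimen()].
#' @param times Strictly increasing simulation grid (days).
#' @return Numeric vector of concentrations (mg/L), zero before the first
#'   dose and continuous in time.
#' @examples
#' pk <- pk_params(ka = 4, CL = 3.3, V = 12, F = 0.7)
#' conc <- simulate_pk(pk, uniform_regimen(2.4, 4), times = seq(0, 28, 0.1))
#' @export
simulate_pk <- function(pk, reg, times) {
  validate_pk_params(pk)
  if (any(diff(times) <= 0)) stop("simulate_pk: times must be strictly increasing", call. = FALSE)
  if (!nrow(reg)) return(numeric(length(times)))
  if (pk$Vmax == 0) {
    return(conc_linear(pk, reg$time, reg$amount, times))
  }
  simulate_pk_ode(pk, reg, times)
}

simulate_pk_ode <- function(pk, reg, times) {
  full_times <- sort(unique(c(times, reg$time)))
  deriv <- function(t, y, p) {
    C <- y[2] / p$V
    list(c(-p$ka * y[1],
           p$ka * y[1] - p$CL * C - p$Vmax * C / (p$Km + C)))
  }
  ev <- data.frame(var = "depot", time = reg$time,
                   value = pk$F * reg$amount, method = "add")
  ev <- ev[ev$value > 0, , drop = FALSE]
  out <- tryCatch(
    deSolve::lsoda(y = c(depot = 0, central = 0), times = full_times,
                   func = deriv, parms = pk,
                   events = if (nrow(ev)) list(data = ev) else NULL,
                   rtol = 1e-8, atol = 1e-10),
    warning = function(w) stop("ODE solver failed for pk parameters (ka=", pk$ka,
                               ", CL=", pk$CL, ", V=", pk$V, ", Vmax=", pk$Vmax,
                               ", Km=", pk$Km, "): ", conditionMessage(w), call. = FALSE),
    error = function(e) stop("ODE solver failed for pk parameters (ka=", pk$ka,
                             ", CL=", pk$CL, ", V=", pk$V, ", Vmax=", pk$Vmax,
                             ", Km=", pk$Km, "): ", conditionMessage(e), call. = FALSE)
  )
  conc <- out[match(times, full_times), "central"] / pk$V
  if (any(conc < -1e-6)) {
    stop("simulate_pk: negative concentrations beyond solver tolerance", call. = FALSE)
  }
  pmax(conc, 0)
}

#' Simulate the coupled PK and IGF-I response
#'
#' Chains [simulate_pk()] into the indirect-response turnover model
#' `dR/dt = kout*R0*(1 + Emax*C^gamma/(EC50^gamma + C^gamma)) - kout*R`
#' with initial condition `R(0) = R_init` (baseline `R0` by default).
#'
#' @inheritParams simulate_pk
#' @param pd A [pd_params()] object.
#' @param R_init Initial IGF-I concentration (ng/mL); defaults to `pd$R0`.
#' @return A `sim_profile` data frame with columns `time`, `conc` (mg/L),
#'   `igf` (ng/mL) and `sds` (`NA` until filled by [add_sds()]).
#' @examples
#' pk <- pk_params(ka = 4, CL = 3.3, V = 12, F = 0.7)
#' pd <- pd_params(R0 = 120, kout = 0.7, Emax = 8.6, EC50 = 0.66)
#' prof <- simulate_pkpd(pk, pd, uniform_regimen(2.4, 4), seq(0, 28, 0.05))
#' @export
simulate_pkpd <- function(pk, pd, reg, times, R_init = NULL) {
  validate_pd_params(pd)
  conc <- simulate_pk(pk, reg, times)
  if (is.null(R_init)) R_init <- pd$R0
  igf <- pd_solve(pd, times, conc, R_init = R_init)
  if (any(igf <= 0)) stop("simulate_pkpd: non-positive IGF-I encountered", call. = FALSE)
  new_sim_profile(times, conc, igf, drug = attr(reg, "drug"))
}

#' Fill the SDS column of a simulated profile
#'
#' @param profile A `sim_profile` from [simulate_pkpd()] or
#'   [steady_state_profile()].
#' @param age,sex Subject age (years) and sex for the normative transform.
#' @param grid Reference grid, see [default_reference_grid()].
#' @return The profile with `sds` computed from `igf` via [sds_from_conc()].
#' @export
add_sds <- function(profile, age, sex, grid = default_reference_grid()) {
  ms <- ref_mu_sigma(age, sex, grid)
  profile$sds <- (log(profile$igf) - ms$mu) / ms$sigma
  profile
}

#' Steady-state profile over one dosing interval
#'
#' Repeated-dosing run-in until two successive dosing-interval profiles
#' differ by less than `tol` (relative L-infinity norm on both
#' concentration and IGF-I), capped at `max_intervals` intervals.  For the
#' linear model each interval uses the closed-form accumulation solution;
#' for `Vmax > 0` the ODE state is propagated interval by interval.
#'
#' @inheritParams simulate_pkpd
#' @param dose Dose amount (mg) per administration, >= 0.
#' @param interval Dosing interval (days): 7 for weekly somapacitan, 1 for
#'   daily somatropin.
#' @param n_points Grid points across the interval.
#' @param tol Relative convergence tolerance (default 0.1%).
#' @param max_intervals Run-in cap; exceeding it is an error.
#' @return A `sim_profile` over `[0, interval]` (time measured from the
#'   dose) with attributes `n_intervals` (intervals simulated when the
#'   criterion was met), `converged`, `rel_diffs` (successive-interval
#'   differences), `dose` and `interval`.
#' @examples
#' pk <- pk_params(ka = 4, CL = 3.3, V = 12, F = 0.7)
#' pd <- pd_params(R0 = 120, kout = 0.7, Emax = 8.6, EC50 = 0.66)
#' ss <- steady_state_profile(pk, pd, dose = 2.4, interval = 7)
#' attr(ss, "n_intervals")
#' @export
steady_state_profile <- function(pk, pd, dose, interval, n_points = 241,
                                 tol = 1e-3, max_intervals = 52) {
  validate_pk_params(pk); validate_pd_params(pd)
  if (dose < 0) stop("steady_state_profile: dose must be >= 0", call. = FALSE)
  if (interval <= 0) stop("steady_state_profile: interval must be > 0", call. = FALSE)
  tloc <- seq(0, interval, length.out = n_points)
  if (dose == 0) {
    prof <- new_sim_profile(tloc, numeric(n_points), rep(pd$R0, n_points),
                            n_intervals = 2L, converged = TRUE,
                            rel_diffs = 0, dose = dose, interval = interval)
    return(prof)
  }
  linear <- pk$Vmax == 0
  R_prev_end <- pd$R0
  prev <- NULL
  rel_diffs <- numeric(0)
  state <- c(depot = 0, central = 0)  # nonlinear path only
  for (n in seq_len(max_intervals)) {
    if (linear) {
      conc <- conc_linear_accum(pk, dose, interval, tloc, n)
    } else {
      stepped <- ode_interval_step(pk, state, dose, tloc)
      conc <- stepped$conc
      state <- stepped$state
    }
    igf <- pd_solve(pd, tloc, conc, R_init = R_prev_end)
    R_prev_end <- igf[n_points]
    if (!is.null(prev)) {
      d_igf <- max(abs(igf - prev$igf) / pmax(abs(prev$igf), 1e-12))
      d_conc <- max(abs(conc - prev$conc) / max(max(prev$conc), 1e-12))
      rel_diffs <- c(rel_diffs, max(d_igf, d_conc))
      if (max(d_igf, d_conc) < tol) {
        return(new_sim_profile(tloc, conc, igf, n_intervals = n,
                               converged = TRUE, rel_diffs = rel_diffs,
                               dose = dose, interval = interval))
      }
    }
    prev <- list(conc = conc, igf = igf)
  }
  stop("steady_state_profile: no convergence within ", max_intervals,
       " intervals (last relative difference ",
       signif(utils::tail(rel_diffs, 1), 3), ")", call. = FALSE)
}

# One dosing interval of the nonlinear ODE, carrying (depot, central) state.
ode_interval_step <- function(pk, state, dose, tloc) {
  state["depot"] <- state["depot"] + pk$F * dose
  deriv <- function(t, y, p) {
    C <- y[2] / p$V
    list(c(-p$ka * y[1], p$ka * y[1] - p$CL * C - p$Vmax * C / (p$Km + C)))
  }
  out <- deSolve::lsoda(y = state, times = tloc, func = deriv, parms = pk,
                        rtol = 1e-8, atol = 1e-10)
  list(conc = pmax(out[, "central"] / pk$V, 0),
       state = c(depot = unname(out[nrow(out), "depot"]),
                 central = unname(out[nrow(out), "central"])))
}

# Fast periodic steady state for the linear model: the general solution
# over one interval is R(t) = c e^{-kout t} + G(t) with G the particular
# (zero-initial) ETD solution; the periodic boundary condition
# R(0) = R(tau) fixes c = G(tau) / (1 - e^{-kout tau}).
ss_profile_linear <- function(pk, pd, dose, interval, n_points = 241) {
  tloc <- seq(0, interval, length.out = n_points)
  if (dose == 0) return(new_sim_profile(tloc, numeric(n_points), rep(pd$R0, n_points),
                                        dose = dose, interval = interval))
  conc <- conc_linear_ss(pk, dose, interval, tloc)
  a <- pd$kout * pd$R0 * (1 + hill_stim(pd, conc))
  co <- etd_coeffs(pd$kout, tloc[2] - tloc[1])
  u <- co$w0 * a[-n_points] + co$w1 * a[-1]
  G <- c(0, as.numeric(stats::filter(u, co$d, method = "recursive", init = 0)))
  ch <- G[n_points] / (1 - exp(-pd$kout * interval))
  igf <- ch * exp(-pd$kout * tloc) + G
  new_sim_profile(tloc, conc, igf, dose = dose, interval = interval)
}

#' Time-weighted average IGF-I SDS over a dosing interval
#'
#' Trapezoidal time average of the `sds` series of a steady-state interval
#' profile; this is the dose-response response variable ("average IGF-I
#' SDS during maintenance treatment").
#'
#' @param profile A `sim_profile` spanning one dosing interval, with the
#'   `sds` column filled (see [add_sds()]).
#' @return Scalar average SDS.
#' @export
weekly_average_sds <- function(profile) {
  t <- profile$time
  if (any(diff(t) <= 0)) stop("weekly_average_sds: non-monotone time grid", call. = FALSE)
  s <- profile$sds
  if (any(is.na(s))) stop("weekly_average_sds: sds column not filled; see add_sds()", call. = FALSE)
  h <- diff(t)
  sum((s[-length(s)] + s[-1]) / 2 * h) / (t[length(t)] - t[1])
}

# Trapezoidal time average of an arbitrary series.
trapz_mean <- function(t, y) {
  h <- diff(t)
  sum((y[-length(y)] + y[-1]) / 2 * h) / (t[length(t)] - t[1])
}

#' Time of the IGF-I SDS maximum within a dosing interval
#'
#' @inheritParams weekly_average_sds
#' @return Grid time (days after the dose) at which `sds` attains its
#'   maximum; ties are broken by the earliest time.
#' @export
profile_tmax <- function(profile) {
  s <- profile$sds
  if (any(is.na(s))) stop("profile_tmax: sds column not filled; see add_sds()", call. = FALSE)
  profile$time[which.max(s)]
}
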