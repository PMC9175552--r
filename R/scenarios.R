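# Table 2 starting-dose group mix used by deterministic group summaries.
group_mix_weights <- function() c(le60 = 0.570, gt60 = 0.212, oe = 0.218)

# Covariate-typical subjects representing one starting-dose group: the
# age groups are represented by a sex-balanced male/female pair at the
# population mean weight, the oestrogen group by a 40-year-old female on
# oral oestrogen.
group_typical_covariates <- function(group = c("le60", "gt60", "oe"),
                                     weight = 75) {
  group <- match.arg(group)
  switch(group,
    le60 = list(
      list(cov = subject_covariates(age = 45, sex = "male", weight = weight), w = 0.5),
      list(cov = subject_covariates(age = 45, sex = "female", weight = weight), w = 0.5)),
    gt60 = list(
      list(cov = subject_covariates(age = 70, sex = "male", weight = weight), w = 0.5),
      list(cov = subject_covariates(age = 70, sex = "female", weight = weight), w = 0.5)),
    oe = list(
      list(cov = subject_covariates(age = 40, sex = "female",
                                    oral_oestrogen = TRUE, weight = weight), w = 1))
  )
}

# Steady-state interval average SDS for one subject at one dose, via the
# fast periodic solution (linear elimination) or the run-in loop.
subject_avg_sds <- function(pop, cov, dose, eta = NULL,
                            grid = default_reference_grid(), n_points = 241) {
  pars <- individual_params(pop, cov, eta %||% c(CL = 0, V = 0, EC50 = 0, R0 = 0), grid)
  tau <- if (pop$drug == "somapacitan") 7 else 1
  prof <- if (pars$pk$Vmax == 0) {
    ss_profile_linear(pars$pk, pars$pd, dose, tau, n_points)
  } else {
    steady_state_profile(pars$pk, pars$pd, dose, tau, n_points)
  }
  ms <- ref_mu_sigma(cov$age, cov$sex, grid)
  trapz_mean(prof$time, (log(prof$igf) - ms$mu) / ms$sigma)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Group-mean average SDS at one dose: typical-subject weighted mean.
group_avg_sds <- function(pop, group, dose, grid = default_reference_grid()) {
  typ <- group_typical_covariates(group)
  sum(vapply(typ, function(t) t$w * subject_avg_sds(pop, t$cov, dose, grid = grid),
             numeric(1)))
}

# Table-2-mix population summary of a per-group scalar.
mix_avg <- function(pop, f, ...) {
  w <- group_mix_weights()
  sum(vapply(names(w), function(g) w[[g]] * f(pop, g, ...), numeric(1)))
}

#' Steady-state dose-response curve
#'
#' Average IGF-I SDS over a steady-state dosing interval as a function of
#' dose, for a starting-dose group (the group's covariate-typical
#' subjects) or an individual subject.
#'
#' @param pop A (calibrated) [population_parameters()] object.
#' @param group `"le60"`, `"gt60"` or `"oe"`; ignored when `cov` is given.
#' @param doses Dose grid (mg per administration) within the legal range.
#' @param cov Optional [subject_covariates()] for an individual curve.
#' @param eta Optional named random-effect vector for an individual curve.
#' @param grid IGF-I reference grid.
#' @return A `dose_response_curve` data frame with columns `dose`,
#'   `avg_sds`, and attributes `drug` and `label`.
#' @examples
#' pop <- reference_population()
#' dr <- dose_response_curve(pop, "le60", doses = c(0.5, 1, 2, 4, 8))
#' @export
dose_response_curve <- function(pop, group = c("le60", "gt60", "oe"),
                                doses = exp(seq(log(0.1), log(8), length.out = 40)),
                                cov = NULL, eta = NULL,
                                grid = default_reference_grid()) {
  if (is.null(cov)) {
    group <- match.arg(group)
    vals <- vapply(doses, function(d) group_avg_sds(pop, group, d, grid), numeric(1))
    label <- group
  } else {
    vals <- vapply(doses, function(d) subject_avg_sds(pop, cov, d, eta, grid), numeric(1))
    label <- paste0("subject_", cov$id)
  }
  structure(data.frame(dose = doses, avg_sds = vals),
            class = c("dose_response_curve", "data.frame"),
            drug = pop$drug, label = label)
}

#' Dose at which a dose-response curve crosses a target SDS
#'
#' Linear interpolation in log dose between the bracketing grid nodes of
#' the first upward crossing.  If the curve never reaches the target the
#' status sentinel reports `"above_max"`; if the target lies below the
#' curve minimum, `"below_min"`.
#'
#' @param curve A [dose_response_curve()].
#' @param target Target IGF-I SDS.
#' @return `list(dose =, status =)` with `status` one of `"crossed"`,
#'   `"above_max"`, `"below_min"`; `dose` is `NA` unless crossed.
#' @export
crossing_dose <- function(curve, target) {
  d <- curve$dose; s <- curve$avg_sds
  hit <- which(abs(s - target) < 1e-12)
  if (length(hit)) return(list(dose = d[hit[1]], status = "crossed"))
  if (all(s < target)) return(list(dose = NA_real_, status = "above_max"))
  if (all(s > target)) return(list(dose = NA_real_, status = "below_min"))
  i <- which(s[-1] >= target & s[-length(s)] < target)[1]
  f <- (target - s[i]) / (s[i + 1] - s[i])
  list(dose = exp(log(d[i]) + f * (log(d[i + 1]) - log(d[i]))), status = "crossed")
}

# Root-found group crossing dose on a wide bracket (used by calibration
# and the acceptance summaries); NA if no crossing in the bracket.
group_crossing_dose <- function(pop, group, target, lower = 0.02, upper = 40,
                                grid = default_reference_grid(), tol = 1e-4) {
  f <- function(ld) group_avg_sds(pop, group, exp(ld), grid) - target
  flo <- f(log(lower)); fhi <- f(log(upper))
  if (flo >= 0 || fhi <= 0) return(NA_real_)
  exp(stats::uniroot(f, c(log(lower), log(upper)), tol = tol)$root)
}

#' Expected IGF-I SDS distribution at treatment initiation
#'
#' Simulates the steady-state average IGF-I SDS each virtual subject
#' would attain if kept at their assigned starting dose, and summarises
#' the population distribution (mean, tails beyond the normal range).
#'
#' @param cov_df Covariate data frame from [generate_demographics()].
#' @param pop A calibrated [population_parameters()] object.
#' @param policy Named starting doses `c(le60 =, gt60 =, oe =)` in mg per
#'   administration, or `"low"` (1.5 / 1.0 / 2.0 mg/week) or `"high"`
#'   (2.0 / 1.5 / 4.0 mg/week).
#' @param seed Integer seed for the random-effect draws.
#' @param eta Optional pre-drawn random-effect matrix (overrides `seed`).
#' @param grid IGF-I reference grid.
#' @return List with `mean`, `sd`, `p_above_2`, `p_below_m2` (fractions),
#'   `mcse_mean`, the per-subject `values` and assigned `doses`.
#' @export
starting_dose_distribution <- function(cov_df, pop, policy = "low", seed = NULL,
                                       eta = NULL,
                                       grid = default_reference_grid()) {
  if (is.character(policy)) {
    policy <- switch(match.arg(policy, c("low", "high")),
                     low = c(le60 = 1.5, gt60 = 1.0, oe = 2.0),
                     high = c(le60 = 2.0, gt60 = 1.5, oe = 4.0))
  }
  grp <- ifelse(cov_df$oral_oestrogen, "oe", ifelse(cov_df$age > 60, "gt60", "le60"))
  doses <- unname(policy[grp])
  if (is.null(eta)) eta <- sample_eta(pop, nrow(cov_df), seed)
  values <- population_avg_sds(pop, cov_df, doses, eta, grid)
  n <- length(values)
  list(mean = mean(values), sd = stats::sd(values),
       p_above_2 = mean(values > 2), p_below_m2 = mean(values < -2),
       mcse_mean = stats::sd(values) / sqrt(n), values = values, doses = doses)
}

# Steady-state interval-average SDS for many subjects, each at one or
# several doses (linear elimination fast path: the unit-dose periodic
# concentration profile is computed once per subject and scaled).
# `doses` is either a vector of per-subject doses (matrix_out = FALSE,
# returns a vector) or a common dose grid (matrix_out = TRUE, returns a
# subjects x doses matrix).
avg_sds_engine <- function(pop, cov_df, doses, eta = NULL, matrix_out = FALSE,
                           grid = default_reference_grid(), n_points = 241L) {
  tab <- indiv_param_table(pop, cov_df, eta, grid)
  tau <- if (pop$drug == "somapacitan") 7 else 1
  tloc <- seq(0, tau, length.out = n_points)
  h <- tloc[2] - tloc[1]
  th <- pop$theta
  ka <- th$ka; kout <- th$kout; Emax <- th$Emax; gam <- th$gamma; Fq <- th$F
  co <- etd_coeffs(kout, h)
  emk_t <- exp(-kout * tloc)
  denom_period <- 1 - exp(-kout * tau)
  n <- nrow(tab)
  out <- if (matrix_out) matrix(NA_real_, n, length(doses)) else numeric(n)
  half_h <- h / 2
  for (i in seq_len(n)) {
    ke <- tab$CL[i] / tab$V[i]
    kai <- if (abs(ka - ke) < 1e-10 * ka) ka * (1 + 1e-8) else ka
    coef <- Fq * kai / (tab$V[i] * (kai - ke))
    unit <- pmax(coef * (exp(-ke * tloc) / (1 - exp(-ke * tau)) -
                           exp(-kai * tloc) / (1 - exp(-kai * tau))), 0)
    kR0 <- kout * tab$R0[i]
    ec_g <- tab$EC50[i]^gam
    d_i <- if (matrix_out) doses else doses[i]
    for (j in seq_along(d_i)) {
      cg <- (d_i[j] * unit)^gam
      a <- kR0 * (1 + Emax * cg / (ec_g + cg))
      u <- co$w0 * a[-n_points] + co$w1 * a[-1]
      G <- c(0, as.numeric(stats::filter(u, co$d, method = "recursive", init = 0)))
      igf <- (G[n_points] / denom_period) * emk_t + G
      sds <- (log(igf) - tab$mu[i]) / tab$sig[i]
      val <- sum((sds[-n_points] + sds[-1]) * half_h) / tau
      if (matrix_out) out[i, j] <- val else out[i] <- val
    }
  }
  out
}

population_avg_sds <- function(pop, cov_df, doses, eta, grid = default_reference_grid()) {
  if (pop$theta$Vmax != 0) {
    return(vapply(seq_len(nrow(cov_df)), function(i) {
      cov <- df_row_covariates(cov_df, i)
      subject_avg_sds(pop, cov, doses[i], eta[i, ], grid)
    }, numeric(1)))
  }
  avg_sds_engine(pop, cov_df, doses, eta, matrix_out = FALSE, grid = grid)
}

# Covariate rows of the group-typical subjects with group labels and
# within-group weights.
typical_cov_df <- function(weight = 75) {
  data.frame(
    id = 1:5,
    age = c(45, 45, 70, 70, 40),
    sex = c("male", "female", "male", "female", "female"),
    oral_oestrogen = c(FALSE, FALSE, FALSE, FALSE, TRUE),
    weight = weight, race = "white_other", prior_treatment = "naive",
    baseline_sds = NA_real_,
    group = c("le60", "le60", "gt60", "gt60", "oe"),
    w = c(0.5, 0.5, 0.5, 0.5, 1)
  )
}

# Group-mean curves on a common dose grid: rows le60/gt60/oe.
group_curve_matrix <- function(pop, doses, grid = default_reference_grid()) {
  tc <- typical_cov_df()
  m <- avg_sds_engine(pop, tc, doses, matrix_out = TRUE, grid = grid)
  out <- rbind(le60 = tc$w[1] * m[1, ] + tc$w[2] * m[2, ],
               gt60 = tc$w[3] * m[3, ] + tc$w[4] * m[4, ],
               oe = m[5, ])
  out
}

df_row_covariates <- function(cov_df, i) {
  subject_covariates(id = cov_df$id[i], age = cov_df$age[i], sex = cov_df$sex[i],
                     oral_oestrogen = cov_df$oral_oestrogen[i],
                     weight = cov_df$weight[i], race = cov_df$race[i],
                     prior_treatment = cov_df$prior_treatment[i],
                     baseline_sds = cov_df$baseline_sds[i])
}

#' Mean IGF-I SDS deficit from delayed or missed dosing
#'
#' Somapacitan semantics: one weekly dose is delayed by `delay` days and
#' the schedule then resumes on the planned days.  Somatropin semantics:
#' `delay` consecutive daily doses are missed, then dosing resumes.  The
#' deficit is the time-average over `horizon` days, starting from the
#' first planned (missed) dosing day, of the difference between the
#' uninterrupted and the perturbed IGF-I SDS profiles.  The default
#' summary is the Table-2 group-mix weighted average over the
#' covariate-typical subjects (deterministic); supply `cov` (and
#' optionally `eta`) for a single subject.
#'
#' @param pop A calibrated [population_parameters()] object.
#' @param delay Days of delay (somapacitan) or number of missed daily
#'   doses (somatropin); >= 0.
#' @param dose Maintenance dose (mg per administration); defaults to the
#'   phase-3 mean maintenance dose (2.4 mg/week or 0.3 mg/day).
#' @param horizon Averaging window (days) from the planned dosing day.
#' @param cov,eta Optional single-subject covariates / random effects.
#' @param grid IGF-I reference grid.
#' @return Scalar mean SDS deficit (positive = IGF-I lost).
#' @examples
#' pop <- reference_population()
#' missed_dose_sim(pop, delay = 0)  # exactly zero
#' @export
missed_dose_sim <- function(pop, delay, dose = NULL, horizon = 14,
                            cov = NULL, eta = NULL,
                            grid = default_reference_grid()) {
  if (delay < 0) stop("missed_dose_sim: delay must be >= 0", call. = FALSE)
  if (is.null(dose)) dose <- if (pop$drug == "somapacitan") 2.4 else 0.3
  if (delay == 0) return(0)
  if (!is.null(cov)) {
    return(subject_missed_deficit(pop, cov, eta, delay, dose, horizon, grid))
  }
  w <- group_mix_weights()
  total <- 0
  for (g in names(w)) {
    typ <- group_typical_covariates(g)
    gval <- sum(vapply(typ, function(t) {
      t$w * subject_missed_deficit(pop, t$cov, NULL, delay, dose, horizon, grid)
    }, numeric(1)))
    total <- total + w[[g]] * gval
  }
  total
}

subject_missed_deficit <- function(pop, cov, eta, delay, dose, horizon, grid) {
  pars <- individual_params(pop, cov, eta %||% c(CL = 0, V = 0, EC50 = 0, R0 = 0), grid)
  tau <- if (pop$drug == "somapacitan") 7 else 1
  run_in <- if (pop$drug == "somapacitan") 12 * 7 else 35
  t_pert <- run_in                              # first planned dosing day perturbed
  t_end <- t_pert + horizon + 2 * tau
  planned <- seq(0, t_end - 1e-9, by = tau)
  if (pop$drug == "somapacitan") {
    pert_times <- planned
    pert_times[planned == t_pert] <- t_pert + delay
    pert_times <- sort(pert_times)
    pert_amt <- rep(dose, length(pert_times))
  } else {
    skip <- planned >= t_pert & planned < t_pert + delay
    pert_times <- planned[!skip]
    pert_amt <- rep(dose, length(pert_times))
  }
  dt <- if (tau == 7) 0.02 else 0.01
  tgrid <- seq(0, t_end, by = dt)
  ms <- ref_mu_sigma(cov$age, cov$sex, grid)
  sds_of <- function(times, amounts) {
    conc <- conc_series(pars$pk, times, amounts, tgrid)
    igf <- pd_solve(pars$pd, tgrid, conc)
    (log(igf) - ms$mu) / ms$sigma
  }
  sds_u <- sds_of(planned, rep(dose, length(planned)))
  sds_p <- sds_of(pert_times, pert_amt)
  win <- tgrid >= t_pert & tgrid <= t_pert + horizon
  trapz_mean(tgrid[win], sds_u[win] - sds_p[win])
}

#' Effective weekly-to-daily dose ratio
#'
#' Ratio between somapacitan maintenance doses (mg/week) and somatropin
#' maintenance doses (mg/day): the ratio of means for population-level
#' inputs plus, for paired per-subject doses, the distribution of
#' individual ratios with an optional flagged outlier exclusion (Tukey
#' far-out fences, 3 interquartile ranges).
#'
#' @param soma Somapacitan maintenance dose(s), mg/week.
#' @param trop Somatropin maintenance dose(s), mg/day; same length as
#'   `soma` (paired) or scalar means.
#' @param exclude_outliers Exclude far-out individual ratios (flagged in
#'   the output; never silent).
#' @return List with `mean_ratio` (ratio of mean doses), and for paired
#'   input `ratios`, `mean`, `median`, `iqr`, `range`, `n_excluded`.
#' @examples
#' dose_ratio_analysis(2.364, 0.289)$mean_ratio  # ~8.2
#' @export
dose_ratio_analysis <- function(soma, trop, exclude_outliers = FALSE) {
  if (length(soma) != length(trop)) {
    stop("dose_ratio_analysis: soma and trop must be paired (equal length)", call. = FALSE)
  }
  if (any(trop <= 0)) stop("dose_ratio_analysis: somatropin doses must be > 0", call. = FALSE)
  out <- list(mean_ratio = mean(soma) / mean(trop), n_excluded = 0L)
  if (length(soma) > 1) {
    r <- soma / trop
    if (exclude_outliers) {
      q <- stats::quantile(r, c(0.25, 0.75))
      iqr <- q[2] - q[1]
      keep <- r >= q[1] - 3 * iqr & r <= q[2] + 3 * iqr
      out$n_excluded <- sum(!keep)
      r <- r[keep]
    }
    out$ratios <- r
    out$mean <- mean(r)
    out$median <- stats::median(r)
    out$iqr <- unname(stats::quantile(r, c(0.25, 0.75)))
    out$range <- range(r)
  }
  out
}

#' Deviation of the IGF-I SDS profile from its weekly average in a
#' sampling window
#'
#' Supports the recommendation to sample IGF-I on days 3-4 after a weekly
#' dose, where the profile resembles the weekly average.
#'
#' @param profile A steady-state `sim_profile` over one weekly interval
#'   with the `sds` column filled.
#' @param window Sampling window (days after dosing).
#' @return Maximum absolute deviation of `sds` from the weekly average
#'   within the window.
#' @export
sampling_window_check <- function(profile, window = c(3, 4)) {
  avg <- weekly_average_sds(profile)
  sel <- profile$time >= window[1] & profile$time <= window[2]
  if (!any(sel)) stop("sampling_window_check: window outside profile", call. = FALSE)
  max(abs(profile$sds[sel] - avg))
}
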