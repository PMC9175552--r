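#' Dose-titration rule
#'
#' Encodes a trial titration algorithm: the IGF-I SDS target range, the
#' visit schedule, a step table mapping the observed SDS deviation from
#' the target range to a dose increment, the legal dose range, and the
#' dose rounding increment.  The packaged step table (0.5 / 1.0 / 1.5 mg
#' per week for deviations of up to 1, up to 2, and more than 2 SDS
#' outside the range) spans the titration steps used clinically; the
#' exact per-protocol adjustment table is a surrogate.  For somatropin
#' the steps are scaled by the effective weekly-to-daily dose ratio and
#' rounded to the 0.05 mg pen increment.
#'
#' @param target Numeric length-2 target range `(low, high)` for IGF-I SDS.
#' @param visits Number of titration visits.
#' @param visit_interval Days between titration visits.
#' @param steps Data frame with columns `deviation` (lower bounds of the
#'   deviation bands, first must be 0) and `step` (dose increment, mg).
#' @param bounds Legal dose range `(min, max)` in mg per administration.
#' @param rounding Dose rounding increment (mg).
#' @return A `titration_rule` object.
#' @export
titration_rule <- function(target = c(-0.5, 1.75), visits = 4,
                           visit_interval = 14,
                           steps = data.frame(deviation = c(0, 1, 2),
                                              step = c(0.5, 1.0, 1.5)),
                           bounds = c(0.1, 8), rounding = 0.1) {
  if (target[1] >= target[2]) stop("titration_rule: target low must be < high", call. = FALSE)
  if (bounds[1] >= bounds[2]) stop("titration_rule: bounds min must be < max", call. = FALSE)
  if (any(steps$step <= 0) || rounding <= 0) {
    stop("titration_rule: steps and rounding must be positive", call. = FALSE)
  }
  structure(list(target = target, visits = visits,
                 visit_interval = visit_interval, steps = steps,
                 bounds = bounds, rounding = rounding),
            class = "titration_rule")
}

#' @rdname titration_rule
#' @param drug Drug for which to build the default rule: the 4-visit,
#'   2-week-interval schedule with target range (-0.5, 1.75) used for
#'   treatment-naive patients.
#' @export
default_titration_rule <- function(drug = c("somapacitan", "somatropin")) {
  drug <- match.arg(drug)
  if (drug == "somapacitan") {
    titration_rule()
  } else {
    titration_rule(steps = data.frame(deviation = c(0, 1, 2),
                                      step = c(0.05, 0.10, 0.20)),
                   bounds = c(0.05, 1.1), rounding = 0.05)
  }
}

#' Protocol starting dose by patient group
#'
#' Somapacitan: 1.5 mg/week for patients 60 years or younger, 1.0 mg/week
#' for patients over 60, and 2.0 mg/week for females on oral oestrogen
#' replacement (the oestrogen classification takes precedence over age).
#' Somatropin: 0.20, 0.10 and 0.30 mg/day for the same three groups.
#'
#' @param cov A [subject_covariates()] object.
#' @param drug `"somapacitan"` or `"somatropin"`.
#' @return Starting dose (mg per administration).
#' @examples
#' assign_starting_dose(subject_covariates(age = 45, sex = "male"), "somapacitan")
#' @export
assign_starting_dose <- function(cov, drug = c("somapacitan", "somatropin")) {
  drug <- match.arg(drug)
  grp <- start_dose_group(cov)
  doses <- if (drug == "somapacitan") {
    c(le60 = 1.5, gt60 = 1.0, oe = 2.0)
  } else {
    c(le60 = 0.20, gt60 = 0.10, oe = 0.30)
  }
  unname(doses[grp])
}

# Start-dose group label: oral oestrogen takes precedence over age.
start_dose_group <- function(cov) {
  if (isTRUE(cov$oral_oestrogen)) "oe" else if (cov$age > 60) "gt60" else "le60"
}

#' One titration step
#'
#' Within the target range the dose is unchanged.  Outside it, the
#' deviation (distance from the nearest range edge) selects the increment
#' from the rule's step table -- larger deviations give larger steps --
#' applied upward when below range and downward when above, then clamped
#' to the legal dose range and rounded to the rounding increment.
#'
#' @param observed_sds Observed IGF-I SDS at the titration visit.
#' @param dose Current dose (mg per administration).
#' @param rule A [titration_rule()].
#' @return New dose (mg).
#' @examples
#' titrate_step(1.0, 2.0, titration_rule(target = c(0, 2)))   # in range
#' titrate_step(-1.2, 2.0, titration_rule(target = c(0, 2)))  # +1.0 mg
#' @export
titrate_step <- function(observed_sds, dose, rule) {
  lo <- rule$target[1]; hi <- rule$target[2]
  if (observed_sds >= lo && observed_sds <= hi) return(dose)
  dev <- if (observed_sds < lo) lo - observed_sds else observed_sds - hi
  band <- findInterval(dev, rule$steps$deviation, left.open = TRUE)
  band <- max(1L, min(band, nrow(rule$steps)))
  step <- rule$steps$step[band]
  new <- dose + if (observed_sds < lo) step else -step
  new <- min(max(new, rule$bounds[1]), rule$bounds[2])
  round(new / rule$rounding) * rule$rounding
}

#' Simulate dose titration for one subject
#'
#' Starts at the protocol starting dose, doses at the drug's nominal
#' interval, and at each titration visit observes a (noisy) IGF-I SDS
#' sampled 3 days after the most recent pre-visit dose (at the visit day
#' for daily dosing, where the profile is flat on that scale), applies
#' [titrate_step()], and fixes the dose after the final visit.
#'
#' @param cov A [subject_covariates()] object.
#' @param pop A (calibrated) [population_parameters()] object.
#' @param rule A [titration_rule()]; defaults to the drug's
#'   [default_titration_rule()].
#' @param eta Named random-effect vector for the subject (zeros by default).
#' @param seed Integer seed for the observation noise; `NULL` uses the
#'   current RNG state.
#' @param duration_days Total length of the generated dose schedule.
#' @param noise_sd SDS observation noise SD; defaults to `pop$sigma["pd"]`.
#' @param grid IGF-I reference grid.
#' @return A `titration_record`: list with `visits` (data frame `day`,
#'   `observed_sds`, `prev_dose`, `new_dose`), `maintenance_dose`,
#'   `n_changes`, `starting_dose` and the full `schedule` ([regimen()])
#'   over `duration_days`.
#' @export
run_titration <- function(cov, pop, rule = NULL, eta = NULL, seed = NULL,
                          duration_days = 238, noise_sd = NULL,
                          grid = default_reference_grid()) {
  drug <- pop$drug
  if (is.null(rule)) rule <- default_titration_rule(drug)
  if (is.null(noise_sd)) noise_sd <- pop$sigma[["pd"]]
  if (is.null(eta)) eta <- c(CL = 0, V = 0, EC50 = 0, R0 = 0)
  tau <- if (drug == "somapacitan") 7 else 1
  pars <- individual_params(pop, cov, eta, grid)
  ms <- ref_mu_sigma(cov$age, cov$sex, grid)

  with_seed(seed, {
    dose0 <- assign_starting_dose(cov, drug)
    dose_times <- seq(0, duration_days - 1e-9, by = tau)
    doses <- rep(dose0, length(dose_times))
    visits <- data.frame(day = numeric(0), observed_sds = numeric(0),
                         prev_dose = numeric(0), new_dose = numeric(0))
    n_changes <- 0L
    for (v in seq_len(rule$visits)) {
      day_v <- v * rule$visit_interval
      last_dose <- max(dose_times[dose_times <= day_v - 3])
      sample_t <- if (drug == "somapacitan") last_dose + 3 else day_v
      tgrid <- seq(0, sample_t, by = min(tau / 50, 0.05))
      if (utils::tail(tgrid, 1) < sample_t) tgrid <- c(tgrid, sample_t)
      keep <- dose_times < sample_t
      conc <- conc_series(pars$pk, dose_times[keep], doses[keep], tgrid)
      igf <- pd_solve(pars$pd, tgrid, conc)
      true_sds <- (log(igf[length(igf)]) - ms$mu) / ms$sigma
      obs <- true_sds + stats::rnorm(1, 0, noise_sd)
      future <- dose_times > day_v
      cur <- if (any(future)) doses[future][1] else doses[length(doses)]
      new <- titrate_step(obs, cur, rule)
      if (abs(new - cur) > 1e-9) n_changes <- n_changes + 1L
      if (any(future)) doses[future] <- new
      visits <- rbind(visits, data.frame(day = day_v, observed_sds = obs,
                                         prev_dose = cur, new_dose = new))
    }
    structure(list(visits = visits,
                   maintenance_dose = doses[length(doses)],
                   n_changes = n_changes, starting_dose = dose0,
                   schedule = regimen(dose_times, doses, drug = drug,
                                      interval = tau)),
              class = "titration_record")
  })
}

# Concentration series for arbitrary (times, amounts) dispatching on the
# elimination model.
conc_series <- function(pk, dose_times, amounts, tgrid) {
  if (pk$Vmax == 0) {
    conc_linear(pk, dose_times, amounts, tgrid)
  } else {
    simulate_pk_ode(pk, regimen(dose_times, amounts), tgrid)
  }
}

#' @export
print.titration_record <- function(x, ...) {
  cat("<titration_record> start", x$starting_dose, "mg ->",
      x$maintenance_dose, "mg after", x$n_changes, "change(s)\n")
  print(x$visits, row.names = FALSE)
  invisible(x)
}
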