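#' Demographics specification for the virtual AGHD population
#'
#' Defaults emulate the pooled phase-3 analysis population: n = 330,
#' 50.6% female, 21.8% of all patients females on oral oestrogen, age
#' 46.5 +/- 15.1 years truncated to 19-77, weight 75 +/- 21.5 kg
#' truncated to 34.5-150.5, race mix 63% White/other, 28.2% Asian
#' Japanese, 8.8% Asian non-Japanese, 68.2% treatment-naive.  Ages are
#' drawn from the stated truncated normal, so the fraction over 60 years
#' emerges from the age distribution rather than being forced.
#'
#' @param n Number of subjects.
#' @param frac_female Fraction female.
#' @param frac_oe Fraction of all subjects that are females on oral
#'   oestrogen (must not exceed `frac_female`).
#' @param age_mean,age_sd,age_range Age distribution (years).
#' @param weight_mean,weight_sd,weight_range Weight distribution (kg).
#' @param race_fracs Named fractions for `white_other`, `asian_japanese`,
#'   `asian_nonjapanese` (must sum to 1).
#' @param frac_naive Fraction GH treatment-naive.
#' @return A `demographics_spec` list.
#' @export
demographics_spec <- function(n = 330, frac_female = 0.506, frac_oe = 0.218,
                              age_mean = 46.5, age_sd = 15.1,
                              age_range = c(19, 77),
                              weight_mean = 75, weight_sd = 21.5,
                              weight_range = c(34.5, 150.5),
                              race_fracs = c(white_other = 0.630,
                                             asian_japanese = 0.282,
                                             asian_nonjapanese = 0.088),
                              frac_naive = 0.682) {
  fr <- c(frac_female, frac_oe, frac_naive, race_fracs)
  if (any(fr < 0 | fr > 1)) stop("demographics_spec: fractions must lie in [0, 1]", call. = FALSE)
  if (frac_oe > frac_female) {
    stop("demographics_spec: oral-oestrogen fraction exceeds the female fraction",
         call. = FALSE)
  }
  if (abs(sum(race_fracs) - 1) > 1e-6) {
    stop("demographics_spec: race fractions must sum to 1", call. = FALSE)
  }
  if (age_mean < age_range[1] || age_mean > age_range[2] ||
      weight_mean < weight_range[1] || weight_mean > weight_range[2]) {
    stop("demographics_spec: ranges must contain the means", call. = FALSE)
  }
  structure(list(n = n, frac_female = frac_female, frac_oe = frac_oe,
                 age_mean = age_mean, age_sd = age_sd, age_range = age_range,
                 weight_mean = weight_mean, weight_sd = weight_sd,
                 weight_range = weight_range, race_fracs = race_fracs,
                 frac_naive = frac_naive),
            class = "demographics_spec")
}

rtruncnorm <- function(n, mean, sd, lower, upper) {
  plo <- stats::pnorm(lower, mean, sd)
  phi <- stats::pnorm(upper, mean, sd)
  stats::qnorm(plo + stats::runif(n) * (phi - plo), mean, sd)
}

#' Generate virtual-subject covariates
#'
#' Truncated-normal age and weight within the specified ranges,
#' categorical draws for sex, race and prior treatment, and oral
#' oestrogen assigned only among females at the rate implied by the
#' overall fraction.  Reproducible given `seed`.
#'
#' @param spec A [demographics_spec()].
#' @param seed Integer seed; `NULL` uses the current RNG state.
#' @return A data frame of covariates (one row per subject) with columns
#'   `id`, `age`, `sex`, `oral_oestrogen`, `weight`, `race`,
#'   `prior_treatment`, `baseline_sds` (`NA`: baseline variability is
#'   carried by the random effect on R0).
#' @examples
#' head(generate_demographics(demographics_spec(n = 20), seed = 1))
#' @export
generate_demographics <- function(spec = demographics_spec(), seed = NULL) {
  with_seed(seed, {
    n <- spec$n
    sex <- ifelse(stats::runif(n) < spec$frac_female, "female", "male")
    p_oe_f <- spec$frac_oe / spec$frac_female
    oe <- sex == "female" & stats::runif(n) < p_oe_f
    age <- rtruncnorm(n, spec$age_mean, spec$age_sd,
                      spec$age_range[1], spec$age_range[2])
    weight <- rtruncnorm(n, spec$weight_mean, spec$weight_sd,
                         spec$weight_range[1], spec$weight_range[2])
    race <- sample(names(spec$race_fracs), n, replace = TRUE,
                   prob = spec$race_fracs)
    naive <- stats::runif(n) < spec$frac_naive
    data.frame(id = seq_len(n), age = age, sex = sex, oral_oestrogen = oe,
               weight = weight, race = race,
               prior_treatment = ifelse(naive, "naive", "switched"),
               baseline_sds = NA_real_)
  })
}

#' Default virtual-trial design
#'
#' Mirrors a 34-week main trial period for treatment-naive and switched
#' patients: four biweekly titration visits over weeks 2-8 with IGF-I
#' samples on day 3 after the pre-visit dose, plus paired PK/IGF-I
#' samples alternating between near-peak (day 2) and trough (day 6.5)
#' offsets at spread-out visit weeks, a pre-dose baseline IGF-I sample
#' for naive patients, and patient-diary dose delays of 1-3 days at a
#' configurable frequency.
#'
#' @param duration_weeks Trial duration.
#' @param peak_weeks,trough_weeks Weeks with near-peak (day 2) and trough
#'   (day 6.5) PK + IGF-I samples.
#' @param titration_weeks Weeks whose preceding dose gets a day-3
#'   titration sample (also used by the titration algorithm).
#' @param delay_fraction Fraction of doses delayed by 1-3 days in the
#'   dosing diary.
#' @param lloq Lower limit of quantification for concentration (mg/L).
#' @return A `trial_design` list.
#' @export
default_trial_design <- function(duration_weeks = 34,
                                 peak_weeks = c(1, 4, 9, 16, 25, 33),
                                 trough_weeks = c(2, 6, 12, 20, 30),
                                 titration_weeks = c(2, 4, 6, 8),
                                 delay_fraction = 0.08, lloq = 0.002) {
  structure(list(duration_weeks = duration_weeks, peak_weeks = peak_weeks,
                 trough_weeks = trough_weeks, titration_weeks = titration_weeks,
                 delay_fraction = delay_fraction, lloq = lloq),
            class = "trial_design")
}

#' Generate a synthetic virtual trial dataset
#'
#' For each subject: draws random effects, runs the dose-titration
#' algorithm with noisy day-3 IGF-I observations, perturbs the dosing
#' diary with occasional 1-3 day delays, simulates the full
#' concentration and IGF-I time course, and samples sparse PK and IGF-I
#' SDS observations at the design offsets with residual noise and
#' quantification-limit flagging.
#'
#' @param cov_df Covariates from [generate_demographics()].
#' @param pop A calibrated [population_parameters()] object.
#' @param design A [default_trial_design()].
#' @param seed Integer seed.
#' @param noise If `FALSE`, observations equal model predictions exactly
#'   (useful for validation).
#' @param grid IGF-I reference grid.
#' @return A dataset data frame in the event-record dialect of
#'   [write_dataset()]: columns `ID`, `TIME` (days), `EVID` (1 dose /
#'   0 observation), `AMT` (mg), `DV`, `DVID` (1 drug concentration in
#'   mg/L, 2 IGF-I SDS), `MDV`, `BQL`, plus covariate columns `AGE`,
#'   `SEX`, `OE`, `WT`, `RACE`, `NAIVE`.
#' @export
generate_trial <- function(cov_df, pop, design = default_trial_design(),
                           seed = NULL, noise = TRUE,
                           grid = default_reference_grid()) {
  with_seed(seed, {
    rows <- vector("list", nrow(cov_df))
    tau <- if (pop$drug == "somapacitan") 7 else 1
    rule <- default_titration_rule(pop$drug)
    dur <- design$duration_weeks * 7
    for (i in seq_len(nrow(cov_df))) {
      cov <- df_row_covariates(cov_df, i)
      eta <- drop(sample_eta(pop, 1))
      rec <- run_titration(cov, pop, rule = rule, eta = eta, seed = NULL,
                           duration_days = dur,
                           noise_sd = if (noise) pop$sigma[["pd"]] else 0,
                           grid = grid)
      sched <- rec$schedule
      delay <- stats::runif(nrow(sched)) < design$delay_fraction
      sched$time <- sched$time + ifelse(delay, sample(1:3, nrow(sched), TRUE), 0)
      ord <- order(sched$time)
      sched <- sched[ord, ]
      obs_t <- sort(unique(c(
        (design$peak_weeks - 1) * 7 + 2,
        (design$trough_weeks - 1) * 7 + 6.5,
        vapply(design$titration_weeks * 7, function(d) {
          max(sched$time[sched$time <= d - 3]) + 3
        }, numeric(1))
      )))
      obs_t <- obs_t[obs_t <= dur]
      tgrid <- sort(unique(c(seq(0, dur, by = tau / 70), obs_t, sched$time)))
      pars <- individual_params(pop, cov, eta, grid)
      conc <- conc_series(pars$pk, sched$time, sched$amount, tgrid)
      ms <- ref_mu_sigma(cov$age, cov$sex, grid)
      # switched patients arrive near their prior-treatment steady state
      # (IGF-I around the reference median, SDS ~ 0); naive start at baseline
      R_init <- if (cov$prior_treatment == "switched") exp(ms$mu) else pars$pd$R0
      igf <- pd_solve(pars$pd, tgrid, conc, R_init = R_init)
      sds <- (log(igf) - ms$mu) / ms$sigma
      idx <- match(obs_t, tgrid)
      n_o <- length(idx)
      eps_pk <- if (noise) stats::rnorm(n_o, 0, pop$sigma[["pk"]]) else numeric(n_o)
      eps_pd <- if (noise) stats::rnorm(n_o, 0, pop$sigma[["pd"]]) else numeric(n_o)
      conc_obs <- conc[idx] * (1 + eps_pk)
      sds_obs <- sds[idx] + eps_pd
      base <- if (cov$prior_treatment == "naive") {
        bsds <- sds[1] + if (noise) stats::rnorm(1, 0, pop$sigma[["pd"]]) else 0
        data.frame(TIME = 0, EVID = 0L, AMT = 0, DV = bsds, DVID = 2L,
                   MDV = 0L, BQL = FALSE)
      } else NULL
      sub <- rbind(
        base,
        data.frame(TIME = sched$time, EVID = 1L, AMT = sched$amount,
                   DV = NA_real_, DVID = 0L, MDV = 1L, BQL = FALSE),
        data.frame(TIME = obs_t, EVID = 0L, AMT = 0, DV = conc_obs, DVID = 1L,
                   MDV = 0L, BQL = conc_obs < design$lloq),
        data.frame(TIME = obs_t, EVID = 0L, AMT = 0, DV = sds_obs, DVID = 2L,
                   MDV = 0L, BQL = FALSE)
      )
      sub <- sub[order(sub$TIME, -sub$EVID, sub$DVID), ]
      sub <- cbind(ID = cov$id, sub,
                   AGE = cov$age, SEX = cov$sex, OE = as.integer(cov$oral_oestrogen),
                   WT = cov$weight, RACE = cov$race,
                   NAIVE = as.integer(cov$prior_treatment == "naive"))
      rows[[i]] <- sub
    }
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    validate_dataset(out)
  })
}

#' Read / write an event-record dataset
#'
#' CSV dialect with one row per event: `ID`, `TIME` (days from first
#' dose), `EVID` (1 dose, 0 observation), `AMT` (mg), `DV` (observation
#' value), `DVID` (1 drug concentration mg/L, 2 IGF-I SDS, 0 for dose
#' rows), `MDV`, `BQL`, and covariate columns `AGE`, `SEX`, `OE`, `WT`,
#' `RACE`, `NAIVE`.  Writing then reading is lossless.
#'
#' @param path File path.
#' @return `read_dataset()` returns the validated data frame.
#' @export
read_dataset <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  d$BQL <- as.logical(d$BQL)
  validate_dataset(d)
}

#' @rdname read_dataset
#' @param dataset A dataset data frame, see [generate_trial()].
#' @export
write_dataset <- function(dataset, path) {
  validate_dataset(dataset)
  utils::write.csv(dataset, path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}

#' Validate an event-record dataset
#'
#' Checks mandatory columns, per-subject dose presence, within-subject
#' time ordering, and flags pre-first-dose observations as baseline
#' records (column `BASELINE`).  Errors name the offending rows.
#'
#' @param dataset A dataset data frame.
#' @return The dataset (invisibly usable), with a `BASELINE` logical
#'   column added.
#' @export
validate_dataset <- function(dataset) {
  need <- c("ID", "TIME", "EVID", "AMT", "DV", "DVID", "MDV", "BQL",
            "AGE", "SEX", "OE", "WT", "RACE", "NAIVE")
  miss <- setdiff(need, names(dataset))
  if (length(miss)) {
    stop("dataset: missing column(s): ", paste(miss, collapse = ", "), call. = FALSE)
  }
  bad <- which(!is.finite(dataset$TIME) | !dataset$EVID %in% c(0L, 1L))
  if (length(bad)) {
    stop("dataset: malformed row(s): ", paste(utils::head(bad, 5), collapse = ", "),
         call. = FALSE)
  }
  dataset$BASELINE <- FALSE
  for (id in unique(dataset$ID)) {
    sel <- which(dataset$ID == id)
    d <- dataset[sel, ]
    if (!any(d$EVID == 1L)) {
      stop("dataset: subject ", id, " has no dose record (rows ",
           sel[1], "-", sel[length(sel)], ")", call. = FALSE)
    }
    if (any(diff(d$TIME) < 0)) {
      r <- sel[which(diff(d$TIME) < 0)[1] + 1L]
      stop("dataset: non-monotone times within subject ", id, " at row ", r,
           call. = FALSE)
    }
    for (nm in c("AGE", "SEX", "OE", "WT", "RACE", "NAIVE")) {
      if (length(unique(d[[nm]])) != 1L) {
        stop("dataset: covariate '", nm, "' varies within subject ", id, call. = FALSE)
      }
    }
    first_dose <- min(d$TIME[d$EVID == 1L])
    dataset$BASELINE[sel] <- d$EVID == 0L & d$TIME <= first_dose
  }
  dataset
}
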