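# Evaluate an expression with a temporary, restored RNG state.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  if (!is.numeric(seed) || length(seed) != 1L) stop("seed must be a scalar", call. = FALSE)
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

# Stable per-stage sub-seed derived from a global seed, kept below 2^31.
stage_seed <- function(seed, stage) {
  h <- sum(utf8ToInt(as.character(stage)) * seq_along(utf8ToInt(as.character(stage))))
  as.integer((as.numeric(seed) * 48271 + h) %% 2147483587)
}

#' Subject covariates
#'
#' @param id Subject identifier.
#' @param age Age in years.
#' @param sex `"male"` or `"female"`.
#' @param oral_oestrogen Oral oestrogen replacement therapy flag (females
#'   only).
#' @param weight Body weight (kg).
#' @param race `"white_other"`, `"asian_japanese"` or `"asian_nonjapanese"`.
#' @param prior_treatment `"naive"` (GH treatment-naive) or `"switched"`
#'   (previously on daily GH).
#' @param baseline_sds Optional known baseline IGF-I SDS; `NA` to use the
#'   population typical baseline model.
#' @return A `subject_covariates` list.
#' @export
subject_covariates <- function(id = 1L, age, sex, oral_oestrogen = FALSE,
                               weight = 75,
                               race = c("white_other", "asian_japanese",
                                        "asian_nonjapanese"),
                               prior_treatment = c("naive", "switched"),
                               baseline_sds = NA_real_) {
  race <- match.arg(race)
  prior_treatment <- match.arg(prior_treatment)
  if (!sex %in% c("male", "female")) stop("sex must be 'male' or 'female'", call. = FALSE)
  if (isTRUE(oral_oestrogen) && sex != "female") {
    stop("oral_oestrogen is only defined for females", call. = FALSE)
  }
  structure(list(id = id, age = age, sex = sex,
                 oral_oestrogen = isTRUE(oral_oestrogen), weight = weight,
                 race = race, prior_treatment = prior_treatment,
                 baseline_sds = baseline_sds),
            class = "subject_covariates")
}

#' Population parameter set
#'
#' Fixed effects (`theta`), covariate coefficients (`beta`), diagonal
#' log-normal inter-individual variances (`omega`, on CL, V, EC50 and R0)
#' and residual-error magnitudes (`sigma`) for one drug.  The reference
#' subject is male, White, 85 kg, age 40 years, treatment-naive, and with
#' `eta = 0` receives exactly `theta` (see [individual_params()]).
#'
#' @param drug `"somapacitan"` or `"somatropin"`.
#' @param theta Named list of typical values: all [pk_params()] fields plus
#'   `kout`, `Emax`, `EC50`, `gamma` and `R0` (baseline IGF-I of the
#'   reference subject, ng/mL).
#' @param beta Named list of covariate coefficients; see
#'   [default_covariate_beta()].
#' @param omega Named variances of the log-normal random effects
#'   (`CL`, `V`, `EC50`, `R0`), all >= 0.
#' @param sigma Named residual standard deviations: `pk` (proportional, on
#'   concentration) and `pd` (additive, on the SDS scale).
#' @return A `gh_population` object.
#' @seealso [reference_population()] for the packaged defaults.
#' @export
population_parameters <- function(drug = c("somapacitan", "somatropin"),
                                  theta, beta = default_covariate_beta(),
                                  omega = c(CL = 0.04, V = 0.04,
                                            EC50 = 0.04, R0 = 0.04),
                                  sigma = c(pk = 0.20, pd = 0.30)) {
  drug <- match.arg(drug)
  need <- c("ka", "CL", "V", "Vmax", "Km", "F", "kout", "Emax", "EC50", "gamma", "R0")
  miss <- setdiff(need, names(theta))
  if (length(miss)) stop("theta missing: ", paste(miss, collapse = ", "), call. = FALSE)
  if (any(unlist(theta[setdiff(need, "Vmax")]) <= 0) || theta$Vmax < 0) {
    stop("theta entries must be positive (Vmax >= 0)", call. = FALSE)
  }
  if (!all(c("CL", "V", "EC50", "R0") %in% names(omega)) || any(omega < 0)) {
    stop("omega must contain non-negative CL, V, EC50, R0 variances", call. = FALSE)
  }
  if (!all(c("pk", "pd") %in% names(sigma)) || any(sigma <= 0)) {
    stop("sigma must contain positive 'pk' and 'pd' entries", call. = FALSE)
  }
  structure(list(drug = drug, theta = theta, beta = beta,
                 omega = omega[c("CL", "V", "EC50", "R0")], sigma = sigma),
            class = "gh_population")
}

#' Default covariate coefficient set
#'
#' Multiplicative covariate model coefficients (log scale unless noted):
#' allometric body-weight exponents on CL (0.75) and V (1), a power of
#' weight on EC50 (negative: heavier patients respond at lower
#' concentrations, offsetting their lower exposure), additive log effects
#' of female sex and oral oestrogen on CL (higher clearance, hence lower
#' exposure per dose) and on EC50 (lower potency), per-year age effects on
#' CL (negative: exposure rises with age) and EC50, a per-year age slope
#' on baseline IGF-I SDS (positive: older patients start higher relative
#' to their reference range), and near-cancelling race effects on CL and
#' EC50.
#'
#' @return Named list of coefficients.
#' @export
default_covariate_beta <- function() {
  list(
    wt_CL = 0.75, wt_V = 1.0, wt_EC50 = -0.6,
    sex_CL = 0.10, sex_EC50 = 0.10,
    oe_CL = 0.70, oe_EC50 = 0.40,
    age_CL = -0.006, age_EC50 = 0.005, age_b = 0.0167,
    race_jp_CL = -0.10, race_jp_EC50 = 0.10,
    race_anj_CL = 0.08, race_anj_EC50 = -0.08
  )
}

#' Packaged reference population parameter sets
#'
#' Pre-calibration typical values for once-weekly somapacitan (absorption
#' 4/day, elimination half-life 2.5 days via CL/V, linear elimination,
#' bioavailability 0.7, IGF-I turnover 0.7/day) and once-daily somatropin
#' (half-life ~3 h).  The baseline `R0` corresponds to an IGF-I SDS of -2
#' for the reference subject (male, 40 years).  These values are the
#' starting point for [calibrate_mean_curves()] and friends, which own the
#' final reference set.
#'
#' @param drug `"somapacitan"` or `"somatropin"`.
#' @return A [population_parameters()] object.
#' @examples
#' pop <- reference_population()
#' pop$theta$CL / pop$theta$V  # elimination rate constant, 1/day
#' @export
reference_population <- function(drug = c("somapacitan", "somatropin")) {
  drug <- match.arg(drug)
  R0_ref <- conc_from_sds(-2, age = 40, sex = "male")
  if (drug == "somapacitan") {
    theta <- list(ka = 4, CL = 12 * log(2) / 2.5, V = 12, Vmax = 0, Km = 0.05,
                  F = 0.7, kout = 0.7, Emax = 8.6, EC50 = 0.66, gamma = 1,
                  R0 = R0_ref)
  } else {
    theta <- list(ka = 12, CL = 6 * log(2) / 0.125, V = 6, Vmax = 0, Km = 0.05,
                  F = 0.8, kout = 0.7, Emax = 8.6, EC50 = 0.065, gamma = 1,
                  R0 = R0_ref)
  }
  population_parameters(drug = drug, theta = theta)
}

#' Individual parameters from covariates and random effects
#'
#' Multiplicative covariate model: for example
#' `CL = theta_CL * (weight/85)^beta_wt_CL * exp(beta_sex_CL * female) *
#' exp(beta_oe_CL * oestrogen) * exp(beta_age_CL * (age - 40)) *
#' exp(beta_race_CL) * exp(eta_CL)`, and analogously for `V` and `EC50`.
#' The individual baseline is defined on the SDS scale:
#' `b = baseline_sds` when supplied, otherwise the typical baseline (the
#' reference subject's SDS plus `beta_age_b * (age - 40)`); then
#' `R0 = conc_from_sds(b, age, sex) * exp(eta_R0)`, so the baseline tracks
#' the age- and sex-specific normative range.  The reference subject
#' (male, White, 85 kg, 40 years, `eta = 0`) receives exactly `theta`.
#'
#' @param pop A [population_parameters()] object.
#' @param cov A [subject_covariates()] object.
#' @param eta Named random-effect vector with entries `CL`, `V`, `EC50`,
#'   `R0` (zeros by default).
#' @param grid IGF-I reference grid.
#' @return `list(pk = pk_params, pd = pd_params)`.
#' @examples
#' pop <- reference_population()
#' ref <- subject_covariates(age = 40, sex = "male", weight = 85)
#' individual_params(pop, ref)$pk$CL == pop$theta$CL
#' @export
individual_params <- function(pop, cov, eta = c(CL = 0, V = 0, EC50 = 0, R0 = 0),
                              grid = default_reference_grid()) {
  for (nm in c("age", "sex", "weight", "race")) {
    if (is.null(cov[[nm]]) || is.na(cov[[nm]])) {
      stop("individual_params: missing covariate '", nm, "'", call. = FALSE)
    }
  }
  eta <- eta[c("CL", "V", "EC50", "R0")]
  eta[is.na(eta)] <- 0
  th <- pop$theta; be <- pop$beta
  fem <- as.numeric(cov$sex == "female")
  oe <- as.numeric(cov$oral_oestrogen)
  da <- cov$age - 40
  race_CL <- switch(cov$race, white_other = 0,
                    asian_japanese = be$race_jp_CL,
                    asian_nonjapanese = be$race_anj_CL)
  race_EC50 <- switch(cov$race, white_other = 0,
                      asian_japanese = be$race_jp_EC50,
                      asian_nonjapanese = be$race_anj_EC50)
  wt <- cov$weight / 85
  CL <- th$CL * wt^be$wt_CL *
    exp(be$sex_CL * fem + be$oe_CL * oe + be$age_CL * da + race_CL + eta[["CL"]])
  V <- th$V * wt^be$wt_V * exp(eta[["V"]])
  EC50 <- th$EC50 * wt^be$wt_EC50 *
    exp(be$sex_EC50 * fem + be$oe_EC50 * oe + be$age_EC50 * da + race_EC50 +
          eta[["EC50"]])
  b <- if (!is.na(cov$baseline_sds)) {
    cov$baseline_sds
  } else {
    sds_from_conc(th$R0, 40, "male", grid) + be$age_b * da
  }
  R0 <- conc_from_sds(b, cov$age, cov$sex, grid) * exp(eta[["R0"]])
  list(
    pk = pk_params(ka = th$ka, CL = CL, V = V, Vmax = th$Vmax, Km = th$Km, F = th$F),
    pd = pd_params(R0 = R0, kout = th$kout, Emax = th$Emax, EC50 = EC50,
                   gamma = th$gamma)
  )
}

# Vectorised individual parameters for a covariate data frame and an eta
# matrix; returns a plain data frame of per-subject structural parameters
# (used by the population-scale simulators).
indiv_param_table <- function(pop, cov_df, eta = NULL,
                              grid = default_reference_grid()) {
  n <- nrow(cov_df)
  if (is.null(eta)) eta <- matrix(0, n, 4, dimnames = list(NULL, c("CL", "V", "EC50", "R0")))
  th <- pop$theta; be <- pop$beta
  fem <- as.numeric(cov_df$sex == "female")
  oe <- as.numeric(cov_df$oral_oestrogen)
  da <- cov_df$age - 40
  race_CL <- ifelse(cov_df$race == "asian_japanese", be$race_jp_CL,
                    ifelse(cov_df$race == "asian_nonjapanese", be$race_anj_CL, 0))
  race_EC50 <- ifelse(cov_df$race == "asian_japanese", be$race_jp_EC50,
                      ifelse(cov_df$race == "asian_nonjapanese", be$race_anj_EC50, 0))
  wt <- cov_df$weight / 85
  b_ref <- sds_from_conc(th$R0, 40, "male", grid)
  b <- ifelse(!is.na(cov_df$baseline_sds), cov_df$baseline_sds, b_ref + be$age_b * da)
  ms <- ref_mu_sigma(cov_df$age, cov_df$sex, grid)
  data.frame(
    id = cov_df$id,
    CL = th$CL * wt^be$wt_CL *
      exp(be$sex_CL * fem + be$oe_CL * oe + be$age_CL * da + race_CL + eta[, "CL"]),
    V = th$V * wt^be$wt_V * exp(eta[, "V"]),
    EC50 = th$EC50 * wt^be$wt_EC50 *
      exp(be$sex_EC50 * fem + be$oe_EC50 * oe + be$age_EC50 * da + race_EC50 +
            eta[, "EC50"]),
    R0 = exp(ms$mu + b * ms$sigma + eta[, "R0"]),
    mu = ms$mu, sig = ms$sigma
  )
}

#' Sample inter-individual random effects
#'
#' Mean-zero independent normal draws with variances `pop$omega`
#' (diagonal covariance), reproducible given `seed`.
#'
#' @param pop A [population_parameters()] object.
#' @param n Number of subjects (>= 1).
#' @param seed Integer seed; `NULL` uses (and advances) the current RNG
#'   state.
#' @return An `n x 4` matrix with columns `CL`, `V`, `EC50`, `R0`.
#' @export
sample_eta <- function(pop, n, seed = NULL) {
  if (n < 1) stop("sample_eta: n must be >= 1", call. = FALSE)
  with_seed(seed, {
    sd <- sqrt(pop$omega)
    m <- vapply(c("CL", "V", "EC50", "R0"),
                function(k) if (sd[[k]] > 0) stats::rnorm(n, 0, sd[[k]]) else numeric(n),
                numeric(n))
    if (n == 1L) m <- matrix(m, nrow = 1, dimnames = list(NULL, c("CL", "V", "EC50", "R0")))
    m
  })
}

#' Apply the residual-error model to a simulated profile
#'
#' Measurement model used by the virtual-trial generator: observed
#' concentration is `conc * (1 + eps)` with proportional
#' `eps ~ N(0, sigma_pk^2)`; observed SDS is `sds + eps'` with additive
#' `eps' ~ N(0, sigma_pd^2)`.  Concentrations below the lower limit of
#' quantification are flagged, not dropped.
#'
#' @param profile A `sim_profile` with the `sds` column filled.
#' @param pop A [population_parameters()] object (supplies `sigma`).
#' @param seed Integer seed; `NULL` uses the current RNG state.
#' @param lloq Lower limit of quantification for concentration (mg/L).
#' @return A data frame `time`, `conc_obs`, `sds_obs`, `bql` (logical).
#' @export
apply_residual <- function(profile, pop, seed = NULL, lloq = 0.002) {
  with_seed(seed, {
    n <- nrow(profile)
    conc_obs <- profile$conc * (1 + stats::rnorm(n, 0, pop$sigma[["pk"]]))
    sds_obs <- profile$sds + stats::rnorm(n, 0, pop$sigma[["pd"]])
    data.frame(time = profile$time, conc_obs = conc_obs, sds_obs = sds_obs,
               bql = conc_obs < lloq)
  })
}

#' @export
print.gh_population <- function(x, ...) {
  cat("<gh_population>", x$drug, "\n")
  cat("  theta:", paste(sprintf("%s=%.4g", names(x$theta), unlist(x$theta)),
                        collapse = ", "), "\n")
  cat("  omega:", paste(sprintf("%s=%.3g", names(x$omega), x$omega),
                        collapse = ", "), "\n")
  cat("  sigma:", paste(sprintf("%s=%.3g", names(x$sigma), x$sigma),
                        collapse = ", "), "\n")
  invisible(x)
}

#' Read / write a population parameter set as YAML
#'
#' Flat YAML serialisation of a [population_parameters()] object, used to
#' version calibrated reference sets.
#'
#' @param pop A `gh_population` object.
#' @param path File path.
#' @return `read_population_yaml()` returns the `gh_population`;
#'   `write_population_yaml()` returns `path` invisibly.
#' @export
write_population_yaml <- function(pop, path) {
  yaml::write_yaml(list(drug = pop$drug, theta = pop$theta, beta = pop$beta,
                        omega = as.list(pop$omega), sigma = as.list(pop$sigma)),
                   path, precision = 15)
  invisible(path)
}

#' @rdname write_population_yaml
#' @export
read_population_yaml <- function(path) {
  x <- yaml::read_yaml(path)
  population_parameters(drug = x$drug, theta = x$theta, beta = x$beta,
                        omega = unlist(x$omega), sigma = unlist(x$sigma))
}
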