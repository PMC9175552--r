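#' Structural pharmacokinetic parameters
#'
#' One-compartment disposition with first-order absorption from a
#' subcutaneous depot and parallel linear plus saturable
#' (Michaelis-Menten) elimination,
#' \deqn{dA/dt = -k_a A, \qquad V\,dC/dt = k_a A - CL\,C - V_{max} C/(K_m + C).}
#' Setting `Vmax = 0` recovers the classical linear one-compartment model,
#' for which closed-form superposition solutions are used throughout the
#' package.  The saturable pathway represents receptor-mediated drug
#' clearance, which grows less than proportionally with concentration.
#'
#' @param ka First-order absorption rate constant (1/day).
#' @param CL Linear clearance (L/day).
#' @param V Central volume of distribution (L).
#' @param Vmax Maximum saturable elimination rate (mg/day); `0` disables the
#'   saturable pathway.
#' @param Km Concentration at half-maximal saturable elimination (mg/L).
#' @param F Absolute bioavailability fraction, in (0, 1].
#'
#' @return An object of class `pk_params` (a validated named list).
#' @examples
#' pk <- pk_params(ka = 4, CL = 3.3, V = 12, F = 0.7)
#' pk$CL / pk$V  # elimination rate constant (1/day)
#' @export
pk_params <- function(ka, CL, V, Vmax = 0, Km = 1, F = 1) {
  p <- list(ka = ka, CL = CL, V = V, Vmax = Vmax, Km = Km, F = F)
  validate_pk_params(p)
  structure(p, class = "pk_params")
}

validate_pk_params <- function(p) {
  num1 <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)
  for (nm in c("ka", "CL", "V", "Vmax", "Km", "F")) {
    if (!num1(p[[nm]])) stop("pk_params: '", nm, "' must be a finite scalar", call. = FALSE)
  }
  if (p$ka <= 0 || p$CL <= 0 || p$V <= 0 || p$Km <= 0) {
    stop("pk_params: ka, CL, V and Km must be strictly positive", call. = FALSE)
  }
  if (p$Vmax < 0) stop("pk_params: Vmax must be >= 0", call. = FALSE)
  if (p$F <= 0 || p$F > 1) stop("pk_params: F must lie in (0, 1]", call. = FALSE)
  invisible(p)
}

#' Indirect-response (turnover) pharmacodynamic parameters
#'
#' IGF-I is produced at a zero-order rate `kin = kout * R0` stimulated by
#' drug concentration through a Hill function and lost first-order,
#' \deqn{dR/dt = k_{out} R_0 \left(1 + \frac{E_{max} C^\gamma}{EC_{50}^\gamma + C^\gamma}\right) - k_{out} R.}
#' In the absence of drug the biomarker sits at its baseline `R0`; the
#' attainable maximum is `R0 * (1 + Emax)`.
#'
#' @param R0 Baseline IGF-I concentration (ng/mL).
#' @param kout First-order IGF-I loss rate (1/day); the production rate
#'   `kin = kout * R0` is derived, not stored.
#' @param Emax Maximal fractional stimulation of IGF-I production
#'   (dimensionless, > 0).
#' @param EC50 Drug concentration at half-maximal stimulation (mg/L).
#' @param gamma Hill coefficient (dimensionless, > 0).
#'
#' @return An object of class `pd_params`.
#' @examples
#' pd <- pd_params(R0 = 120, kout = 0.7, Emax = 8.6, EC50 = 0.66)
#' @export
pd_params <- function(R0, kout, Emax, EC50, gamma = 1) {
  p <- list(R0 = R0, kout = kout, Emax = Emax, EC50 = EC50, gamma = gamma)
  validate_pd_params(p)
  structure(p, class = "pd_params")
}

validate_pd_params <- function(p) {
  num1 <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)
  for (nm in c("R0", "kout", "Emax", "EC50", "gamma")) {
    if (!num1(p[[nm]])) stop("pd_params: '", nm, "' must be a finite scalar", call. = FALSE)
  }
  if (any(unlist(p[c("R0", "kout", "Emax", "EC50", "gamma")]) <= 0)) {
    stop("pd_params: R0, kout, Emax, EC50 and gamma must be strictly positive",
         call. = FALSE)
  }
  invisible(p)
}

#' Dosing regimen
#'
#' An ordered table of subcutaneous dose events.  The nominal dosing
#' interval is 7 days for once-weekly somapacitan and 1 day for once-daily
#' somatropin.
#'
#' @param times Dose times (days since trial start, >= 0).
#' @param amounts Dose amounts (mg, >= 0); recycled to the length of `times`.
#' @param drug `"somapacitan"` or `"somatropin"`.
#' @param interval Nominal dosing interval in days; defaults to 7 for
#'   somapacitan and 1 for somatropin.
#'
#' @return A `regimen` object: a data frame with columns `time`, `amount`
#'   and attributes `drug` and `interval`, sorted by time.
#' @examples
#' regimen(times = seq(0, 21, by = 7), amounts = 2.4)
#' @export
regimen <- function(times = numeric(0), amounts = numeric(0),
                    drug = c("somapacitan", "somatropin"), interval = NULL) {
  drug <- match.arg(drug)
  if (length(times)) amounts <- rep_len(amounts, length(times))
  if (any(times < 0)) stop("regimen: dose times must be >= 0", call. = FALSE)
  if (any(amounts < 0)) stop("regimen: dose amounts must be >= 0", call. = FALSE)
  if (is.null(interval)) interval <- if (drug == "somapacitan") 7 else 1
  if (interval <= 0) stop("regimen: interval must be > 0", call. = FALSE)
  ord <- order(times)
  structure(
    data.frame(time = as.numeric(times[ord]), amount = as.numeric(amounts[ord])),
    drug = drug, interval = as.numeric(interval),
    class = c("regimen", "data.frame")
  )
}

#' Uniform repeated-dosing regimen
#'
#' @param dose Dose amount (mg) given at every administration.
#' @param n_doses Number of doses.
#' @param drug,interval Passed to [regimen()].
#' @param start First dose time (days).
#' @return A [regimen()] with doses at `start + 0:(n_doses-1) * interval`.
#' @export
uniform_regimen <- function(dose, n_doses, drug = c("somapacitan", "somatropin"),
                            interval = NULL, start = 0) {
  drug <- match.arg(drug)
  if (is.null(interval)) interval <- if (drug == "somapacitan") 7 else 1
  regimen(times = start + (seq_len(n_doses) - 1) * interval,
          amounts = rep(dose, n_doses), drug = drug, interval = interval)
}
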