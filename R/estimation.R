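# ---- Generic Laplace machinery -------------------------------------------
#
# A "subject model" is a list with
#   predict(eta) -> list(mean, sd)   observation means and SDs given eta
#   omega                            random-effect variances (named)
# Random-effect dimensions with zero variance are held at zero.  The
# Hessian of the negative joint log density at the mode is approximated
# Gauss-Newton style, H = J' S^{-1} J + Omega^{-1}, which is exact when
# the mean is linear in eta and the SDs do not depend on eta -- the
# regime in which the Laplace approximation itself is exact.

subject_nll <- function(model, y, eta_free, free) {
  eta <- stats::setNames(numeric(length(model$omega)), names(model$omega))
  eta[free] <- eta_free
  p <- tryCatch(model$predict(eta), error = function(e) NULL)
  if (is.null(p) || any(!is.finite(p$mean)) || any(p$sd <= 0)) return(1e10)
  0.5 * sum(((y - p$mean) / p$sd)^2) + sum(log(p$sd)) +
    0.5 * length(y) * log(2 * pi) +
    0.5 * sum(eta_free^2 / model$omega[free]) +
    0.5 * sum(log(2 * pi * model$omega[free]))
}

laplace_eta_mode <- function(model, y, eta0 = NULL) {
  om <- model$omega
  free <- names(om)[om > 0]
  nm <- names(om)
  if (!length(free)) {
    eta <- stats::setNames(numeric(length(om)), nm)
    return(list(eta = eta, free = free, nll = subject_nll(model, y, numeric(0), free),
                hessian = matrix(0, 0, 0), convergence = 0L))
  }
  ef <- if (is.null(eta0)) numeric(length(free)) else unname(eta0[free])
  fn <- function(e) subject_nll(model, y, e, free)
  # damped Gauss-Newton on the penalised least-squares objective; the
  # same J / H are reused for the Laplace curvature at the mode
  Dinv <- 1 / om[free]
  nll <- fn(ef)
  H <- NULL
  converged <- FALSE
  for (it in seq_len(30)) {
    eta_full <- stats::setNames(numeric(length(om)), nm)
    eta_full[free] <- ef
    p <- tryCatch(model$predict(eta_full), error = function(e) NULL)
    if (is.null(p)) break
    J <- Jsd <- matrix(0, length(y), length(free))
    hstep <- 1e-4
    for (j in seq_along(free)) {
      e2 <- eta_full
      e2[free[j]] <- e2[free[j]] + hstep
      p2 <- model$predict(e2)
      J[, j] <- (p2$mean - p$mean) / hstep
      Jsd[, j] <- (p2$sd - p$sd) / hstep
    }
    W <- 1 / p$sd^2
    r <- y - p$mean
    H <- t(J) %*% (J * W) + diag(Dinv, length(free))
    # the second term carries the eta-dependence of the residual SDs
    # (proportional error), making the fixed point the true mode
    g <- drop(t(J) %*% (r * W)) + drop(t(Jsd) %*% (r^2 / p$sd^3 - 1 / p$sd)) -
      Dinv * ef
    delta <- tryCatch(solve(H, g), error = function(e) NULL)
    if (is.null(delta)) break
    if (max(abs(delta)) < 1e-5) { converged <- TRUE; break }
    step <- 1
    improved <- FALSE
    for (k in 1:6) {
      cand <- ef + step * delta
      nll_c <- fn(cand)
      if (nll_c < nll + 1e-12) { improved <- TRUE; break }
      step <- step / 2
    }
    if (improved) {
      moved <- max(abs(step * delta))
      ef <- cand
      nll <- nll_c
      if (moved < 1e-5) { converged <- TRUE; break }
    } else {
      converged <- max(abs(delta)) < 1e-4
      break
    }
  }
  if (!converged || is.null(H)) {
    opt <- stats::optim(ef, fn, method = "BFGS",
                        control = list(maxit = 200, reltol = 1e-10))
    conv <- opt$convergence
    ef <- opt$par
    nll <- opt$value
    eta <- stats::setNames(numeric(length(om)), nm)
    eta[free] <- ef
    H <- gn_hessian(model, y, eta, free)
  } else {
    # the mode moved < 1e-5 in the last step, so the last Gauss-Newton
    # curvature is the curvature at the mode to working precision
    conv <- 0L
    eta <- stats::setNames(numeric(length(om)), nm)
    eta[free] <- ef
  }
  list(eta = eta, free = free, nll = nll, hessian = H, convergence = conv)
}

gn_hessian <- function(model, y, eta, free, h = 1e-4) {
  p0 <- model$predict(eta)
  J <- matrix(0, length(y), length(free))
  for (j in seq_along(free)) {
    e <- eta
    e[free[j]] <- e[free[j]] + h
    J[, j] <- (model$predict(e)$mean - p0$mean) / h
  }
  t(J) %*% (J / p0$sd^2) + diag(1 / model$omega[free], length(free))
}

laplace_subject_loglik <- function(model, y, eta0 = NULL) {
  m <- laplace_eta_mode(model, y, eta0)
  q <- length(m$free)
  if (q == 0) return(list(loglik = -m$nll, eta = m$eta, mode = m))
  ld <- determinant(m$hessian, logarithm = TRUE)
  if (ld$sign <= 0 || !is.finite(ld$modulus)) {
    stop("laplace: non-finite or non-positive curvature at the mode", call. = FALSE)
  }
  list(loglik = -m$nll + 0.5 * q * log(2 * pi) - 0.5 * as.numeric(ld$modulus),
       eta = m$eta, mode = m)
}

# ---- PK/PD subject models from an event-record dataset -------------------

# Split a dataset into per-subject structures used by the likelihood.
parse_subjects <- function(dataset, grid = default_reference_grid()) {
  dataset <- validate_dataset(dataset)
  ids <- unique(dataset$ID)
  lapply(ids, function(id) {
    d <- dataset[dataset$ID == id, ]
    cov <- subject_covariates(
      id = id, age = d$AGE[1], sex = d$SEX[1],
      oral_oestrogen = d$OE[1] == 1, weight = d$WT[1], race = d$RACE[1],
      prior_treatment = if (d$NAIVE[1] == 1) "naive" else "switched"
    )
    doses <- d[d$EVID == 1L, c("TIME", "AMT")]
    obs <- d[d$EVID == 0L & d$MDV == 0L & !(d$DVID == 1L & d$BQL), ]
    tau_guess <- if (nrow(doses) > 1) stats::median(diff(doses$TIME)) else 7
    t_end <- max(obs$TIME, doses$TIME)
    # prefer a uniform grid (compiled recurrence in pd_solve): use the
    # coarsest step that hits every event and observation time exactly
    tgrid <- NULL
    ev_t <- c(obs$TIME, doses$TIME)
    for (dt in max(min(tau_guess, 7) / 70, 0.01) / c(1, 2, 4)) {
      if (all(abs(ev_t / dt - round(ev_t / dt)) < 1e-6)) {
        tgrid <- seq(0, ceiling(t_end / dt + 1e-9) * dt, by = dt)
        break
      }
    }
    if (is.null(tgrid)) {
      dt <- max(min(tau_guess, 7) / 70, 0.01)
      tgrid <- sort(unique(c(seq(0, t_end, by = dt), t_end, obs$TIME, doses$TIME)))
    }
    ms <- ref_mu_sigma(cov$age, cov$sex, grid)
    idx <- vapply(obs$TIME, function(t) which.min(abs(tgrid - t)), integer(1))
    if (any(abs(tgrid[idx] - obs$TIME) > 1e-6)) {
      stop("parse_subjects: observation time off the simulation grid", call. = FALSE)
    }
    list(id = id, cov = cov, doses = doses, obs = obs, tgrid = tgrid,
         idx = idx, mu = ms$mu, sig = ms$sigma,
         switched = cov$prior_treatment == "switched")
  })
}

# Observation means and SDs for one subject given pop and eta.  The
# covariate-level parameters `base` (eta = 0 row of indiv_param_table)
# are precomputed by the caller; eta enters multiplicatively.  The
# absorption-phase superposition sum is eta-independent and cached at
# model construction; the elimination-phase sum is evaluated in the
# separable form e^(-ke t) * cumsum(A_i e^(ke t_i)) (one exponential
# vector per call).
subject_model <- function(subj, pop, base = NULL,
                          grid = default_reference_grid(), lloq = 0.002) {
  if (is.null(base)) {
    base <- indiv_param_table(pop, subjects_cov_df(list(subj)), NULL, grid)[1, ]
  }
  th <- pop$theta
  ka <- th$ka; Fq <- th$F
  tg <- subj$tgrid
  dt_ev <- subj$doses$TIME
  amt <- subj$doses$AMT
  ev_idx <- findInterval(tg, dt_ev)
  # S_a(t) = sum_i A_i e^{-ka (t - t_i)} over past doses (looped once)
  S_a <- numeric(length(tg))
  for (i in seq_along(dt_ev)) {
    on <- tg >= dt_ev[i]
    S_a[on] <- S_a[on] + amt[i] * exp(-ka * (tg[on] - dt_ev[i]))
  }
  nonlinear <- th$Vmax > 0
  is_pk <- subj$obs$DVID == 1L
  idx <- subj$idx
  sig_pk <- pop$sigma[["pk"]]; sig_pd <- pop$sigma[["pd"]]
  R_init_switched <- exp(subj$mu)
  list(
    omega = pop$omega,
    predict = function(eta) {
      CL <- base$CL * exp(eta[["CL"]])
      V <- base$V * exp(eta[["V"]])
      EC50 <- base$EC50 * exp(eta[["EC50"]])
      R0 <- base$R0 * exp(eta[["R0"]])
      if (nonlinear) {
        pk <- pk_params(ka = ka, CL = CL, V = V, Vmax = th$Vmax, Km = th$Km, F = Fq)
        conc <- simulate_pk_ode(pk, regimen(dt_ev, amt), tg)
      } else {
        ke <- CL / V
        kai <- if (abs(ka - ke) < 1e-10 * ka) ka * (1 + 1e-8) else ka
        if (ke * tg[length(tg)] < 600) {
          W <- c(0, cumsum(amt * exp(ke * dt_ev)))[ev_idx + 1L]
          S_e <- exp(-ke * tg) * W
        } else {
          S_e <- numeric(length(tg))
          for (i in seq_along(dt_ev)) {
            on <- tg >= dt_ev[i]
            S_e[on] <- S_e[on] + amt[i] * exp(-ke * (tg[on] - dt_ev[i]))
          }
        }
        conc <- pmax(Fq * kai / (V * (kai - ke)) * (S_e - S_a), 0)
      }
      pd <- list(R0 = R0, kout = th$kout, Emax = th$Emax, EC50 = EC50,
                 gamma = th$gamma)
      R_init <- if (subj$switched) R_init_switched else R0
      igf <- pd_solve(pd, tg, conc, R_init = R_init)
      co <- conc[idx]
      mean <- ifelse(is_pk, co, (log(igf[idx]) - subj$mu) / subj$sig)
      sd <- ifelse(is_pk, sig_pk * pmax(co, lloq), sig_pd)
      list(mean = mean, sd = sd)
    }
  )
}

# One covariate row per subject, in indiv_param_table's expected layout.
subjects_cov_df <- function(subjects) {
  do.call(rbind, lapply(subjects, function(s) {
    data.frame(id = s$cov$id, age = s$cov$age, sex = s$cov$sex,
               oral_oestrogen = s$cov$oral_oestrogen, weight = s$cov$weight,
               race = s$cov$race, prior_treatment = s$cov$prior_treatment,
               baseline_sds = s$cov$baseline_sds)
  }))
}

#' Empirical Bayes random-effect mode for one subject
#'
#' Maximises the joint density `p(data | eta) p(eta)` over the subject's
#' random effects and returns the mode together with the (Gauss-Newton)
#' curvature used by the Laplace approximation.  Random effects with zero
#' population variance are held at zero.
#'
#' @param pop A [population_parameters()] object.
#' @param subject_data Event-record rows for one subject (dataset
#'   dialect, see [generate_trial()]); must contain at least one
#'   non-missing observation.
#' @param eta0 Optional named starting values.
#' @param grid IGF-I reference grid.
#' @return List with `eta` (named mode), `hessian`, `nll` (negative joint
#'   log density at the mode), `convergence` (0 = success) and `flagged`
#'   (`TRUE` when the inner optimisation did not converge).
#' @export
map_eta <- function(pop, subject_data, eta0 = NULL,
                    grid = default_reference_grid()) {
  subj <- parse_subjects(subject_data, grid)[[1]]
  if (!nrow(subj$obs)) stop("map_eta: subject has no usable observations", call. = FALSE)
  model <- subject_model(subj, pop, grid = grid)
  m <- laplace_eta_mode(model, subj$obs$DV, eta0)
  m$flagged <- m$convergence != 0L
  m
}

#' Laplace-approximate marginal log likelihood of a dataset
#'
#' Sum over subjects of the Laplace approximation to
#' `log integral p(data_i | eta) p(eta) d eta`, each term evaluated at the
#' subject's empirical Bayes mode.  Exact whenever the observation means
#' are linear in the random effects (the linear-Gaussian case).
#' Below-quantification concentration records are excluded, so subjects
#' with only such records contribute IGF-I likelihood only.
#'
#' @param pop A [population_parameters()] object.
#' @param dataset Event-record dataset, or the pre-parsed subject list
#'   from the internal parser (used internally for speed).
#' @param eta_warm Optional environment caching per-subject starting
#'   modes between calls.
#' @param grid IGF-I reference grid.
#' @return Scalar log likelihood; attribute `by_subject` holds the
#'   per-subject contributions.
#' @export
marginal_loglik <- function(pop, dataset, eta_warm = NULL,
                            grid = default_reference_grid()) {
  subjects <- if (is.data.frame(dataset)) parse_subjects(dataset, grid) else dataset
  base_tab <- indiv_param_table(pop, subjects_cov_df(subjects), NULL, grid)
  lls <- numeric(length(subjects))
  for (i in seq_along(subjects)) {
    subj <- subjects[[i]]
    model <- subject_model(subj, pop, base_tab[i, ], grid)
    eta0 <- if (!is.null(eta_warm)) eta_warm[[as.character(subj$id)]] else NULL
    res <- tryCatch(laplace_subject_loglik(model, subj$obs$DV, eta0),
                    error = function(e) {
                      stop("marginal_loglik: subject ", subj$id, ": ",
                           conditionMessage(e), call. = FALSE)
                    })
    lls[i] <- res$loglik
    if (!is.null(eta_warm)) eta_warm[[as.character(subj$id)]] <- res$eta
  }
  structure(sum(lls), by_subject = lls)
}

# Free-parameter transforms for fit_population: thetas / omegas / sigmas
# are optimised on the log scale, covariate betas untransformed.
pop_get_par <- function(pop, free) {
  vapply(free, function(nm) {
    if (nm %in% names(pop$theta)) log(pop$theta[[nm]])
    else if (startsWith(nm, "omega_")) log(pop$omega[[sub("omega_", "", nm)]])
    else if (startsWith(nm, "sigma_")) log(pop$sigma[[sub("sigma_", "", nm)]])
    else if (nm %in% names(pop$beta)) pop$beta[[nm]]
    else stop("fit_population: unknown parameter '", nm, "'", call. = FALSE)
  }, numeric(1))
}

pop_set_par <- function(pop, free, par) {
  par <- unname(par)
  for (j in seq_along(free)) {
    nm <- free[j]
    if (nm %in% names(pop$theta)) pop$theta[[nm]] <- exp(par[j])
    else if (startsWith(nm, "omega_")) pop$omega[[sub("omega_", "", nm)]] <- exp(par[j])
    else if (startsWith(nm, "sigma_")) pop$sigma[[sub("sigma_", "", nm)]] <- exp(par[j])
    else pop$beta[[nm]] <- par[j]
  }
  pop
}

#' Fit population parameters by Laplace-approximate maximum likelihood
#'
#' Nelder-Mead maximisation of [marginal_loglik()] over the requested
#' free parameters (positive parameters on the log scale, covariate
#' coefficients untransformed); all other parameters stay at their
#' initial values (the fixed-parameter mask).  Bioavailability `F` is not
#' estimable from extravascular data and should remain masked.  With no
#' free parameters the initials are returned with the objective
#' evaluated.  Empirical Bayes modes are warm-started across objective
#' evaluations.
#'
#' @param dataset Event-record dataset (see [generate_trial()]).
#' @param pop_init Initial [population_parameters()].
#' @param free Character vector of free parameters: names of `theta`
#'   entries (e.g. `"CL"`, `"EC50"`, `"R0"`), `"omega_<name>"`,
#'   `"sigma_pk"` / `"sigma_pd"`, or covariate coefficient names.
#' @param control Passed to [stats::optim()]; the default stops at a
#'   relative objective change below 1e-6.
#' @param stage1_n Optional integer: when set, a first optimisation pass
#'   runs on this many evenly spaced subjects to locate the optimum
#'   cheaply before the full-data fit (a standard two-stage strategy for
#'   expensive marginal likelihoods); `NULL` fits the full data directly.
#' @param grid IGF-I reference grid.
#' @return A `gh_fit` list: `pop` (estimates), `eta` (per-subject
#'   empirical Bayes modes), `objective` (-2 log approximate marginal
#'   likelihood), `loglik`, `convergence` (0 = converged; non-zero
#'   results are flagged, with partial estimates returned), `counts` and
#'   `flagged_subjects`.
#' @export
fit_population <- function(dataset, pop_init, free = c("CL", "EC50", "R0"),
                           control = list(maxit = 250, reltol = 1e-6),
                           stage1_n = NULL,
                           grid = default_reference_grid()) {
  subjects <- parse_subjects(dataset, grid)
  n_obs_subj <- vapply(subjects, function(s) nrow(s$obs), integer(1))
  subjects <- subjects[n_obs_subj > 0]
  eta_warm <- new.env(parent = emptyenv())
  objective <- function(par) {
    pop <- pop_set_par(pop_init, free, par)
    -as.numeric(marginal_loglik(pop, subjects, eta_warm, grid))
  }
  if (!length(free)) {
    ll <- as.numeric(marginal_loglik(pop_init, subjects, eta_warm, grid))
    opt <- list(par = numeric(0), value = -ll, convergence = 0L,
                counts = c(`function` = 1L, gradient = NA))
    pop_hat <- pop_init
  } else {
    p0 <- pop_get_par(pop_init, free)
    if (!is.null(stage1_n) && stage1_n < length(subjects)) {
      sub1 <- subjects[unique(round(seq(1, length(subjects), length.out = stage1_n)))]
      warm1 <- new.env(parent = emptyenv())
      obj1 <- function(par) {
        pop <- pop_set_par(pop_init, free, par)
        -as.numeric(marginal_loglik(pop, sub1, warm1, grid))
      }
      p0 <- stats::optim(p0, obj1, method = "Nelder-Mead",
                         control = list(maxit = 200, reltol = 1e-5))$par
    }
    opt <- stats::optim(p0, objective, method = "Nelder-Mead", control = control)
    pop_hat <- pop_set_par(pop_init, free, opt$par)
  }
  base_tab <- indiv_param_table(pop_hat, subjects_cov_df(subjects), NULL, grid)
  modes <- lapply(seq_along(subjects), function(i) {
    s <- subjects[[i]]
    model <- subject_model(s, pop_hat, base_tab[i, ], grid)
    laplace_eta_mode(model, s$obs$DV, eta_warm[[as.character(s$id)]])
  })
  eta <- do.call(rbind, lapply(modes, function(m) m$eta))
  rownames(eta) <- vapply(subjects, function(s) as.character(s$id), character(1))
  flagged <- vapply(modes, function(m) m$convergence != 0L, logical(1))
  structure(list(pop = pop_hat, eta = eta, objective = 2 * opt$value,
                 loglik = -opt$value, convergence = opt$convergence,
                 counts = opt$counts,
                 flagged_subjects = rownames(eta)[flagged],
                 free = free),
            class = "gh_fit")
}

#' @export
print.gh_fit <- function(x, ...) {
  cat("<gh_fit> -2 log L =", format(x$objective, digits = 8),
      if (x$convergence == 0L) "(converged)" else "(NOT converged)", "\n")
  if (length(x$free)) {
    est <- vapply(x$free, function(nm) {
      if (nm %in% names(x$pop$theta)) x$pop$theta[[nm]]
      else if (startsWith(nm, "omega_")) x$pop$omega[[sub("omega_", "", nm)]]
      else if (startsWith(nm, "sigma_")) x$pop$sigma[[sub("sigma_", "", nm)]]
      else x$pop$beta[[nm]]
    }, numeric(1))
    cat("  estimates:", paste(sprintf("%s=%.4g", x$free, est), collapse = ", "), "\n")
  }
  cat("  subjects:", nrow(x$eta),
      " flagged:", length(x$flagged_subjects), "\n")
  invisible(x)
}

#' Write a fit result to disk
#'
#' Writes the estimated parameters and diagnostics as JSON and the
#' per-subject empirical Bayes modes as CSV.
#'
#' @param fit A `gh_fit` from [fit_population()].
#' @param json_path,eta_csv_path Output paths.
#' @return `json_path`, invisibly.
#' @export
write_fit_result <- function(fit, json_path, eta_csv_path = NULL) {
  jsonlite::write_json(
    list(drug = fit$pop$drug, theta = fit$pop$theta, beta = fit$pop$beta,
         omega = as.list(fit$pop$omega), sigma = as.list(fit$pop$sigma),
         objective = fit$objective, convergence = fit$convergence,
         free = fit$free, flagged_subjects = fit$flagged_subjects),
    json_path, auto_unbox = TRUE, digits = NA)
  if (!is.null(eta_csv_path)) {
    utils::write.csv(data.frame(ID = rownames(fit$eta), fit$eta),
                     eta_csv_path, row.names = FALSE)
  }
  invisible(json_path)
}
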