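# The Laplace approximation must be exact for linear-Gaussian subject
# models: log p(y) = log N(y; b, X Omega X' + S).  Random toys across
# dimensions exercise mode, curvature and normalising constants.
test_that("Laplace equals the exact marginal likelihood on linear-Gaussian toys", {
  set.seed(42)
  for (rep in 1:6) {
    q <- sample(1:3, 1)
    n <- sample(4:8, 1)
    X <- matrix(rnorm(n * q), n, q)
    b0 <- rnorm(n)
    sdv <- runif(n, 0.3, 1.5)
    omega <- setNames(runif(q, 0.1, 0.8), paste0("e", seq_len(q)))
    eta_true <- rnorm(q, 0, sqrt(omega))
    y <- drop(X %*% eta_true) + b0 + rnorm(n, 0, sdv)
    model <- list(omega = omega,
                  predict = function(eta) list(mean = drop(X %*% eta) + b0, sd = sdv))
    lap <- somadose:::laplace_subject_loglik(model, y)$loglik
    Sig <- X %*% diag(omega, q) %*% t(X) + diag(sdv^2, n)
    r <- y - b0
    exact <- -0.5 * (n * log(2 * pi) + determinant(Sig)$modulus[1] +
                       drop(r %*% solve(Sig, r)))
    expect_equal(lap, exact, tolerance = 1e-8)
  }
})

test_that("single-parameter linear-Gaussian mode equals the ridge estimate", {
  set.seed(7)
  x <- rnorm(6); b0 <- rnorm(6); s <- 0.8; omega <- c(e = 0.4)
  y <- 0.5 * x + b0 + rnorm(6, 0, s)
  model <- list(omega = omega,
                predict = function(eta) list(mean = x * eta[1] + b0, sd = rep(s, 6)))
  m <- somadose:::laplace_eta_mode(model, y)
  ridge <- sum(x * (y - b0)) / s^2 / (sum(x^2) / s^2 + 1 / omega)
  expect_equal(unname(m$eta[1]), unname(ridge), tolerance = 1e-8)
})

test_that("the mode is invariant to observation ordering", {
  set.seed(8)
  X <- matrix(rnorm(12), 6, 2); b0 <- rnorm(6); sdv <- runif(6, 0.4, 1)
  omega <- c(a = 0.3, b = 0.5)
  y <- drop(X %*% c(0.2, -0.3)) + b0 + rnorm(6, 0, sdv)
  model_for <- function(ord) {
    list(omega = omega,
         predict = function(eta) list(mean = drop(X[ord, ] %*% eta) + b0[ord],
                                      sd = sdv[ord]))
  }
  m1 <- somadose:::laplace_eta_mode(model_for(1:6), y[1:6])
  m2 <- somadose:::laplace_eta_mode(model_for(6:1), y[6:1])
  expect_equal(m1$eta, m2$eta, tolerance = 1e-6)
})

test_that("zero-variance random effects stay at zero", {
  pop <- reference_population()
  pop$omega[] <- 0
  ds <- small_trial(n = 2, seed = 77, pop = reference_population())
  m <- map_eta(pop, ds[ds$ID == 1, ])
  expect_equal(unname(m$eta), rep(0, 4))
  expect_equal(m$convergence, 0L)
})

test_that("marginal likelihood drops when the residual model is badly wrong", {
  pop <- reference_population()
  ds <- small_trial(n = 6, seed = 55)
  ll_true <- as.numeric(marginal_loglik(pop, ds))
  bad <- pop; bad$sigma[["pd"]] <- pop$sigma[["pd"]] * 5
  expect_lt(as.numeric(marginal_loglik(bad, ds)), ll_true)
})

test_that("only F * dose is identified in the linear limit", {
  pop <- reference_population()
  ds <- small_trial(n = 4, seed = 66)
  ds2 <- ds
  ds2$AMT <- ds$AMT * 2
  pop2 <- pop; pop2$theta$F <- pop$theta$F / 2
  expect_equal(as.numeric(marginal_loglik(pop, ds)),
               as.numeric(marginal_loglik(pop2, ds2)), tolerance = 1e-8)
})

test_that("fully masked fit returns the initials with the objective evaluated", {
  pop <- reference_population()
  ds <- small_trial(n = 4, seed = 88)
  fit <- fit_population(ds, pop, free = character(0))
  expect_equal(fit$pop$theta, pop$theta)
  expect_true(is.finite(fit$objective))
  expect_equal(fit$convergence, 0L)
  expect_equal(fit$objective, -2 * as.numeric(marginal_loglik(pop, ds)),
               tolerance = 1e-6)
})

test_that("subjects without observations are excluded from the fit", {
  pop <- reference_population()
  ds <- small_trial(n = 3, seed = 99)
  dose_only <- ds[ds$ID == 1 & ds$EVID == 1, ]
  dose_only$ID <- 4L
  ds2 <- rbind(ds, dose_only)
  fit <- fit_population(ds2, pop, free = character(0))
  expect_equal(nrow(fit$eta), 3)
})

test_that("a small simulation-estimation round trip recovers CL and R0", {
  pop <- reference_population()
  ds <- small_trial(n = 14, seed = 111)
  init <- pop
  init$theta$CL <- pop$theta$CL * 1.25
  init$theta$R0 <- pop$theta$R0 * 1.2
  fit <- fit_population(ds, init, free = c("CL", "R0"))
  expect_equal(fit$convergence, 0L)
  expect_lt(abs(fit$pop$theta$CL - pop$theta$CL) / pop$theta$CL, 0.3)
  expect_lt(abs(fit$pop$theta$R0 - pop$theta$R0) / pop$theta$R0, 0.3)
  # objective at the optimum is no worse than at the initials
  expect_lte(fit$objective, fit_population(ds, init, free = character(0))$objective + 1e-6)
})

test_that("fit results serialise to JSON and an eta CSV", {
  pop <- reference_population()
  ds <- small_trial(n = 3, seed = 121)
  fit <- fit_population(ds, pop, free = character(0))
  jp <- tempfile(fileext = ".json"); cp <- tempfile(fileext = ".csv")
  write_fit_result(fit, jp, cp)
  back <- jsonlite::read_json(jp)
  expect_equal(back$objective, fit$objective, tolerance = 1e-9)
  expect_equal(nrow(utils::read.csv(cp)), nrow(fit$eta))
})
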