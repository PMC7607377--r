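kn0 <- knot_set(c(log(0.01), log(50)))

test_that("baseline and covariate cumulative hazards match closed forms", {
  m_exp <- flexph_model(c(0, 1), kn0)                  # unit-rate exponential
  expect_equal(baseline_cum_hazard(m_exp, 3), 3)
  m_rate <- flexph_model(c(log(0.2), 1), kn0)
  expect_equal(baseline_cum_hazard(m_rate, 5), 1)

  kn1 <- knot_set(c(0, 2), internal = 1)
  m_spline <- flexph_model(c(0, 1, 0.3), kn1)
  # nu1(1) = -0.5 by hand, so log Lambda0(e) = 1 + 0.3 * (-0.5)
  expect_equal(baseline_cum_hazard(m_spline, exp(1)), exp(1 - 0.15))

  m_cov <- flexph_model(c(0, 1), kn0, beta = c(x = log(2)))
  expect_equal(cum_hazard(m_cov, x = 1, t = 1), 2)
  expect_equal(cum_hazard(m_cov, x = 0, t = 1), baseline_cum_hazard(m_cov, 1))
  # proportional-hazards structure: shifting a covariate scales Lambda
  m_half <- flexph_model(c(0, 1), kn0, beta = c(x = 0.5))
  expect_equal(cum_hazard(m_half, x = 3, t = 2) / cum_hazard(m_half, x = 1, t = 2),
               exp(0.5 * 2))
  expect_error(baseline_cum_hazard(m_exp, 0), "positive")
  expect_error(cum_hazard(m_cov, x = c(1, 2), t = 1), "length 2")
})

test_that("event probability is the 1 - exp(-Lambda) transform", {
  m_exp <- flexph_model(c(0, 1), kn0)
  expect_equal(event_probability(m_exp, t = 1), 1 - exp(-1))
  m_tiny <- flexph_model(c(-50, 1), kn0)
  expect_equal(event_probability(m_tiny, t = 1), 0, tolerance = 1e-20)
  m_huge <- flexph_model(c(20, 1), kn0)
  expect_equal(event_probability(m_huge, t = 5), 1)
})

test_that("hazard equals the exact time derivative of the cumulative hazard", {
  m_exp <- flexph_model(c(0, 1), kn0)
  expect_equal(hazard(m_exp, t = c(0.5, 1, 7)), rep(1, 3))
  # Weibull Lambda0 = 0.2 t^2, so h(1) = 0.4
  m_wb <- flexph_model(c(log(0.2), 2), kn0)
  expect_equal(hazard(m_wb, t = 1), 0.4)

  kn1 <- knot_set(c(log(0.2), log(8)), internal = log(2))
  m_spline <- flexph_model(c(-1, 1.2, 0.15), kn1, beta = c(x = 0.4))
  h <- 1e-6
  for (t in c(0.5, 1, 2, 5)) {
    fd <- (cum_hazard(m_spline, 1, t + h) - cum_hazard(m_spline, 1, t - h)) / (2 * h)
    expect_equal(hazard(m_spline, 1, t), fd, tolerance = 1e-5)
  }
})

test_that("log likelihood matches hand-computed censored and event terms", {
  m_exp <- flexph_model(c(0, 1), kn0)
  expect_equal(flexph_loglik(m_exp, data.frame(time = 2, event = 0)), -2)
  expect_equal(flexph_loglik(m_exp, data.frame(time = 2, event = 1)), -2)

  # exponential likelihood is maximised at the closed-form MLE d / sum(t)
  set.seed(31)
  t <- rexp(400, 0.5)
  dat <- data.frame(time = t, event = 1)
  rate_hat <- length(t) / sum(t)
  ll_at <- function(rate) flexph_loglik(flexph_model(c(log(rate), 1), kn0), dat)
  expect_gt(ll_at(rate_hat), ll_at(rate_hat * 1.05))
  expect_gt(ll_at(rate_hat), ll_at(rate_hat * 0.95))
  # and equals the closed-form exponential log likelihood there
  expect_equal(ll_at(rate_hat), length(t) * log(rate_hat) - rate_hat * sum(t))
})

test_that("fit recovers a Weibull model and matches an independent MLE", {
  dat <- rweibull_ph(5000, shape = 1.5, scale = 2, seed = 32)
  fit <- fit_flexph(dat, m = 0)
  expect_true(fit$fit$converged)
  expect_true(fit$fit$baseline_monotone)

  # survreg oracle: Lambda0(t) = (t / b)^a with a = 1/scale, b = exp(intercept)
  sr <- survival::survreg(survival::Surv(time, event) ~ 1, data = dat,
                          dist = "weibull")
  a <- 1 / sr$scale; b <- exp(coef(sr)[[1]])
  expect_equal(fit$gamma[2], a, tolerance = 1e-3)
  expect_equal(fit$gamma[1], -a * log(b), tolerance = 1e-3)
})

test_that("fit recovers covariate effects under censoring", {
  set.seed(33)
  X <- cbind(grp = rbinom(5000, 1, 0.5))
  dat <- cbind(rweibull_ph(5000, shape = 1.5, scale = 2,
                           beta = 0.7, X = X, censor = 2.2, seed = 133),
               as.data.frame(X))
  expect_gt(mean(dat$event == 0), 0.2)   # meaningful censoring present
  fit <- fit_flexph(dat, covariates = "grp", m = 0)
  expect_equal(unname(fit$beta[["grp"]]), 0.7, tolerance = 0.1)
})

test_that("refitting is deterministic and invariant to covariate centring", {
  set.seed(34)
  X <- cbind(x = rnorm(800))
  dat <- cbind(rweibull_ph(800, 1.3, 3, beta = 0.5, X = X, censor = 4,
                           seed = 134), as.data.frame(X))
  f1 <- fit_flexph(dat, "x", m = 1)
  f2 <- fit_flexph(dat, "x", m = 1)
  expect_identical(f1$gamma, f2$gamma)
  expect_identical(f1$beta, f2$beta)

  shifted <- dat; shifted$x <- shifted$x + 10
  f3 <- fit_flexph(shifted, "x", m = 1)
  t_eval <- c(0.5, 1, 2, 4)
  for (i in c(1, 50, 400)) {
    lam1 <- cum_hazard(f1, dat$x[i], t_eval)
    lam3 <- cum_hazard(f3, shifted$x[i], t_eval)
    expect_equal(lam1, lam3, tolerance = 1e-4)
  }
})

test_that("estimation bias shrinks with sample size", {
  err <- sapply(c(500, 5000), function(n) {
    set.seed(35)
    X <- cbind(x = rnorm(n))
    dat <- cbind(rweibull_ph(n, 1.4, 2.5, beta = 0.6, X = X, censor = 5,
                             seed = 135), as.data.frame(X))
    abs(fit_flexph(dat, "x", m = 0)$beta[["x"]] - 0.6)
  })
  expect_lt(err[2], err[1])
})

test_that("fitted spline model agrees with an independent flexible parametric fitter", {
  skip_if_not_installed("flexsurv")
  set.seed(36)
  X <- cbind(x = rnorm(2000))
  dat <- cbind(rweibull_ph(2000, 1.5, 2, beta = 0.5, X = X, censor = 3,
                           seed = 136), as.data.frame(X))
  ours <- fit_flexph(dat, "x", m = 1)
  theirs <- flexsurv::flexsurvspline(survival::Surv(time, event) ~ x,
                                     data = dat, k = 1, scale = "hazard")
  # same knot convention (quantiles of uncensored log event times), so the
  # maximised likelihoods and coefficients must agree
  expect_equal(ours$fit$loglik, theirs$loglik, tolerance = 1e-5)
  expect_equal(unname(ours$beta[["x"]]),
               unname(theirs$res["x", "est"]), tolerance = 1e-3)
})

test_that("degenerate inputs are rejected with informative errors", {
  expect_error(fit_flexph(data.frame(time = c(1, 2), event = c(0, 0))),
               "no events")
  expect_error(fit_flexph(data.frame(time = c(0, 1), event = c(1, 1))),
               "positive")
  dat <- data.frame(time = rexp(50) + 0.1, event = 1, a = 1:50, b = 2 * (1:50))
  expect_error(fit_flexph(dat, c("a", "b"), m = 0), "collinear")
  m <- flexph_model(c(0, 1), kn0)
  expect_error(flexph_loglik(m, data.frame(time = 1, event = 2)), "0")
})
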