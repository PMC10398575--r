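test_that("exponential MLE equals events over person-time", {
  # closed form: rate = #events / total follow-up, censored or not
  ipd <- make_ipd(time = c(1, 2, 3, rep(1, 9)),
                  event = c(1, 1, 1, rep(0, 9)))
  fit <- fit_family(ipd, "exponential")
  expect_equal(unname(fit$params["rate"]), 3 / sum(ipd$time),
               tolerance = 1e-5)

  # and with pure event data
  ipd2 <- make_ipd(time = 1:10, event = rep(1, 10))
  fit2 <- fit_family(ipd2, "exponential")
  expect_equal(unname(fit2$params["rate"]), 10 / 55, tolerance = 1e-5)
})

test_that("information criteria follow their definitions", {
  set.seed(21)
  ipd <- make_ipd(time = rexp(100, 0.2), event = rep(1, 100))
  for (fam in c("exponential", "weibull", "log-logistic",
                "generalized-gamma")) {
    fit <- fit_family(ipd, fam)
    expect_equal(fit$aic, 2 * fit$k - 2 * fit$loglik)
    expect_equal(fit$bic, fit$k * log(100) - 2 * fit$loglik)
  }
  # k = 2 at loglik -100, n = 100 gives the textbook 204 / 209.21
  expect_equal(2 * 2 - 2 * (-100), 204)
  expect_equal(2 * log(100) - 2 * (-100), 209.21, tolerance = 1e-4)
})

test_that("fitting validates its inputs", {
  ipd <- make_ipd(time = 1:12, event = rep(0, 12))
  expect_error(fit_family(ipd, "weibull"), "censored")
  small <- make_ipd(time = 1:5, event = rep(1, 5))
  expect_error(fit_family(small, "weibull"), "at least 10")
  expect_error(fit_family(make_ipd(1:20, rep(1, 20)), "cauchy"),
               "unknown family")
})

test_that("log-logistic parameters are recovered from simulated data", {
  spec <- arm_spec("a", 6.2, 1.8, 13.9, 1.5, n_patients = 2000,
                   censor_rate = 0)
  ipd <- generate_arm(spec, seed = 99)$pfs
  fit <- fit_family(ipd, "log-logistic")
  expect_lt(abs(fit$params[["scale"]] - 6.2), 0.3)
  expect_lt(abs(fit$params[["shape"]] - 1.8), 0.15)
})

test_that("model selection returns the AIC argmin and reports BIC splits", {
  fake <- function(family, aic, bic) {
    structure(list(family = family, aic = aic, bic = bic),
              class = "survival_fit")
  }
  fits <- list(fake("weibull", 210, 215), fake("log-logistic", 204, 209),
               fake("exponential", 230, 232))
  expect_equal(select_model(fits)$family, "log-logistic")
  expect_equal(select_model(fits[2])$family, "log-logistic") # singleton
  expect_error(select_model(list()), "no fits")
  disagree <- list(fake("a", 100, 210), fake("b", 101, 200))
  expect_message(sel <- select_model(disagree), "BIC selects")
  expect_equal(sel$family, "a")
})

test_that("survival functions honor their closed forms and invariants", {
  llog <- survival_fit_from_params("log-logistic",
                                   c(shape = 1.8, scale = 6.2))
  expect_equal(survival_at(llog, 0), 1)
  expect_equal(survival_at(llog, 6.2), 0.5)   # median identity
  expect_equal(median_survival(llog), 6.2)

  ex <- survival_fit_from_params("exponential", c(rate = 0.5))
  expect_equal(survival_at(ex, 2), exp(-1))
  expect_equal(median_survival(ex), log(2) / 0.5)

  expect_error(survival_at(ex, -1), "negative")

  set.seed(4)
  ipd <- make_ipd(time = rweibull(300, 1.4, 8), event = rep(1, 300))
  for (fam in survival_families()) {
    fit <- tryCatch(fit_family(ipd, fam), error = function(e) NULL)
    if (is.null(fit)) next
    t <- seq(0, 400, by = 2)
    s <- survival_at(fit, t)
    expect_equal(s[1], 1)
    expect_true(all(diff(s) <= 1e-12))
    expect_lt(survival_at(fit, 1e5), 0.01)   # proper: S -> 0
    # numeric root agrees with the analytic median where one exists
    num <- uniroot(function(x) survival_at(fit, x) - 0.5, c(0, 4000),
                   tol = 1e-8)$root
    expect_equal(median_survival(fit), num, tolerance = 1e-5)
  }
})

test_that("richer nesting families never lose log-likelihood", {
  set.seed(31)
  ipd <- make_ipd(time = rweibull(400, 1.3, 10),
                  event = rbinom(400, 1, 0.9))
  ll <- function(fam) fit_family(ipd, fam)$loglik
  expect_gte(ll("weibull"), ll("exponential") - 1e-4)
  expect_gte(ll("gamma"), ll("exponential") - 1e-4)
  expect_gte(ll("generalized-gamma"), ll("weibull") - 1e-4)
})

test_that("defective gompertz extrapolations are rejected", {
  # strongly decreasing hazard drives the gompertz shape negative
  set.seed(8)
  ipd <- make_ipd(time = exp(rnorm(300, 1, 1.5)), event = rep(1, 300))
  expect_error(fit_family(ipd, "gompertz"), "defective")
})
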