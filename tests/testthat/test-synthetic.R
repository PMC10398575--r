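test_that("generated event times follow the intended log-logistic law", {
  spec <- arm_spec("a", pfs_scale = 6.2, pfs_shape = 1.8,
                   os_scale = 13.9, os_shape = 1.5,
                   n_patients = 10000, censor_rate = 0)
  ipd <- generate_arm(spec, seed = 42)

  # no censoring process: everything is an event
  expect_true(all(ipd$pfs$event == 1))
  expect_true(all(ipd$os$event == 1))

  # the log-logistic median equals the scale parameter
  expect_equal(median(ipd$pfs$time), 6.2, tolerance = 0.03)
  expect_equal(median(ipd$os$time), 13.9, tolerance = 0.03)

  # KM of the generated data converges pointwise to the true survival
  km <- km_estimator(ipd$pfs)
  for (t in c(3, 6, 12, 24)) {
    expect_lt(abs(km_step(km, t) - llogis_survival(t, 6.2, 1.8)), 0.02)
  }
})

test_that("generation is reproducible under a fixed seed and censors as asked", {
  spec <- arm_spec("a", 6.2, 1.8, 13.9, 1.5, n_patients = 200,
                   censor_rate = 0.05)
  a <- generate_arm(spec, seed = 7)
  b <- generate_arm(spec, seed = 7)
  expect_identical(a, b)
  # exponential censoring at a positive rate produces some censored records
  expect_gt(sum(a$pfs$event == 0), 0)
  c2 <- generate_arm(spec, seed = 8)
  expect_false(identical(a$pfs$time, c2$pfs$time))
})

test_that("arm specifications are validated", {
  expect_error(arm_spec("a", -1, 1.8, 13.9, 1.5, 100), "positive")
  expect_error(arm_spec("a", 6.2, 0, 13.9, 1.5, 100), "positive")
  expect_error(arm_spec("a", 6.2, 1.8, 13.9, 1.5, 0), "positive integer")
  expect_error(arm_spec("a", 6.2, 1.8, 13.9, 1.5, 100, censor_rate = -1),
               ">= 0")
})

test_that("digitization emulation reads the KM step function off a grid", {
  # no events: flat at 1 everywhere
  flat <- make_ipd(time = rep(10, 5), event = rep(0, 5))
  cv <- emulate_digitization(flat, grid = c(0, 6, 12), risk_times = c(0, 12))
  expect_equal(cv$survival, c(1, 1, 1))

  # single drop of half the cohort
  two <- make_ipd(time = c(3, 10), event = c(1, 0))
  cv2 <- emulate_digitization(two, grid = c(0, 3), risk_times = c(0, 10))
  expect_equal(cv2$survival, c(1, 0.5))

  # read-off beyond the last observation carries the last value forward
  cv3 <- emulate_digitization(two, grid = c(0, 3, 50), risk_times = c(0, 10))
  expect_equal(cv3$survival[3], 0.5)

  # at-risk counts are the true numbers still under observation
  expect_equal(cv2$n_at_risk, c(2L, 1L))
  expect_error(emulate_digitization(two, grid = c(5, 0)), "sorted")
})

test_that("KM curves and IPD round-trip through delimited text", {
  spec <- arm_spec("a", 6.2, 1.8, 13.9, 1.5, 50, censor_rate = 0.02)
  ipd <- generate_arm(spec, seed = 3)$os
  cv <- emulate_digitization(ipd, grid = seq(0, 30, 0.5),
                             risk_times = seq(0, 36, 6))
  stem <- file.path(tempdir(), "curve_a")
  write_km_curve(cv, stem)
  back <- read_km_curve(stem, endpoint = "OS", arm = "a")
  expect_equal(back$survival, cv$survival)
  expect_equal(back$n_at_risk, cv$n_at_risk)

  path <- file.path(tempdir(), "ipd_a.csv")
  write_ipd(ipd, path)
  d <- read.csv(path)
  expect_equal(d$time_months, ipd$time)
  expect_equal(d$event, ipd$event)
})

test_that("the base-case fixture carries the published values and flags the rest", {
  p <- base_case_fixture()
  expect_equal(p$utilities$pfs$value, 0.673)
  expect_equal(p$utilities$pd$value, 0.473)
  expect_equal(p$utilities$death$value, 0)
  expect_equal(p$settings$discount_rate_annual$value, 0.03)
  expect_equal(p$settings$horizon_months, 200)
  expect_equal(p$settings$cycle_months, 1)
  expect_equal(p$settings$bsa$value, 1.86)
  expect_equal(p$second_line$prop_tdct$value, 0.408)
  expect_equal(p$second_line$prop_ct$value, 0.602)
  expect_equal(p$drugs$durvalumab_per_admin$value, 11693.25)
  expect_equal(p$drugs$tremelimumab_per_admin$value, 10981.60)
  # published price floors are the lower one-way bounds (downward-only)
  expect_equal(p$drugs$durvalumab_per_admin$low, 9354.60)
  expect_equal(p$drugs$durvalumab_per_admin$high, 11693.25)

  tab <- param_table(p)
  expect_true(all(c("paper", "derived", "calibrated", "placeholder") %in%
                    tab$provenance))
  # every supportive-care cost that lacks a published source is flagged
  expect_true(all(tab$provenance[grepl("^costs\\.", tab$id)] == "placeholder"))
  expect_silent(validate_params(p))
})

test_that("parameter sets survive YAML round trips and path-based edits", {
  p <- base_case_fixture()
  path <- file.path(tempdir(), "params.yaml")
  write_params(p, path)
  q <- read_params(path)
  expect_equal(param_table(q), param_table(p))
  expect_equal(q$settings$horizon_months, 200)

  r <- set_param(p, "utilities.pfs", 0.5)
  expect_equal(get_param(r, "utilities.pfs")$value, 0.5)
  expect_equal(get_param(r, "utilities.pfs")$dist, "beta")
  expect_equal(get_param(p, "utilities.pfs")$value, 0.673) # original untouched
  expect_error(get_param(p, "utilities.nope"), "unknown parameter")
})
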