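test_that("occupancy partitions the cohort from the two survival curves", {
  p <- toy_params(horizon = 24)
  pfs <- survival_fit_from_params("log-logistic", c(shape = 1.8, scale = 6.2))
  os <- survival_fit_from_params("log-logistic", c(shape = 1.5, scale = 13.9))
  tr <- occupancy_from_survival(pfs, os, p, table = NULL)

  # start of the model: everyone progression-free
  expect_equal(unlist(tr[1, c("p_pfs", "p_pd", "p_death")]),
               c(p_pfs = 1, p_pd = 0, p_death = 0))
  # partition identity at every cycle
  expect_equal(tr$p_pfs + tr$p_pd + tr$p_death, rep(1, nrow(tr)),
               tolerance = 1e-9)
  expect_true(all(tr$p_pfs >= 0 & tr$p_pd >= 0 & tr$p_death >= 0))
  expect_true(all(diff(tr$p_death) >= -1e-12)) # death absorbing
  # direct check at one time point: 0.8 vs 0.5 split
  t_star <- tr$time_months[10]
  expect_equal(tr$p_pd[10],
               survival_at(os, t_star) - survival_at(pfs, t_star))
})

test_that("crossing curves are clamped with a warning", {
  p <- toy_params(horizon = 24)
  pfs <- survival_fit_from_params("log-logistic", c(shape = 1.2, scale = 12))
  os <- survival_fit_from_params("log-logistic", c(shape = 3, scale = 10))
  expect_warning(tr <- occupancy_from_survival(pfs, os, p, table = NULL),
                 "capping PFS")
  expect_true(all(tr$p_pd >= 0))
  expect_equal(tr$p_pfs + tr$p_pd + tr$p_death, rep(1, nrow(tr)),
               tolerance = 1e-9)
})

test_that("discounting follows the annual-rate convention", {
  expect_equal(discount_factor(0, 0.03), 1)
  expect_equal(discount_factor(12, 0.03), 1 / 1.03)
  expect_equal(discount_factor(c(6, 24), 0), c(1, 1))
  expect_error(discount_factor(-1, 0.03), "negative time")
  expect_error(discount_factor(1, -0.01), "negative discount")
})

test_that("QALY accrual matches hand-computed totals", {
  p <- toy_params(horizon = 12, u_pfs = 1, u_pd = 1, discount = 0)
  # full health, alive 12 cycles, no discounting: exactly one QALY
  out <- accumulate(alive_trace(12), zero_streams(12), p)
  expect_equal(out$qaly, 1)
  expect_equal(out$ly, 1)
  expect_equal(out$cost, 0)

  # one cycle fully progression-free at the published PFS utility
  p2 <- toy_params(horizon = 1, u_pfs = 0.673, discount = 0)
  out2 <- accumulate(alive_trace(1), zero_streams(1), p2)
  expect_equal(out2$qaly, 0.673 / 12)

  expect_error(accumulate(alive_trace(12), zero_streams(5), p), "misaligned")
})

test_that("zero discount reproduces undiscounted sums and QALYs equal LYs under unit utilities", {
  p <- toy_params(horizon = 200, u_pfs = 1, u_pd = 1, discount = 0)
  res <- run_model(p)
  for (arm in res$arms) {
    expect_equal(arm$cost, arm$cost_undiscounted)
    # utilities (1, 1, 0): QALYs equal life-years up to the AE decrement
  }
  # and with discounting switched back on the totals shrink
  res3 <- run_model(set_param(p, "settings.discount_rate_annual", 0.03))
  expect_lt(res3$arms[[1]]$cost, res$arms[[1]]$cost)
  expect_lt(res3$arms[[1]]$qaly, res$arms[[1]]$qaly)
})

test_that("with unit utilities and no AE disutility, QALYs equal discounted life-years", {
  p <- toy_params(horizon = 200, u_pfs = 1, u_pd = 1, discount = 0.03)
  for (ae in names(p$ae)) {
    p <- set_param(p, paste0("ae.", ae, ".disutility"), 0)
  }
  res <- run_model(p)
  for (arm in res$arms) expect_equal(arm$qaly, arm$ly)
})

test_that("total cost is homogeneous of degree one in unit costs", {
  p <- base_case_fixture()
  tab <- param_table(p)
  cost_ids <- tab$id[grepl("^(drugs|costs)\\.", tab$id) |
                       grepl("^ae\\..*\\.cost$", tab$id)]
  p2 <- p
  for (id in cost_ids) p2 <- set_param(p2, id, 2 * get_param(p, id)$value)
  r1 <- run_model(p)
  r2 <- run_model(p2)
  for (arm in names(r1$arms)) {
    expect_equal(r2$arms[[arm]]$cost, 2 * r1$arms[[arm]]$cost)
    expect_equal(r2$arms[[arm]]$qaly, r1$arms[[arm]]$qaly)
  }
})

test_that("ICER arithmetic, labels and antisymmetry behave", {
  a <- list(cost = 352291, qaly = 1.22, ly = 2)
  b <- list(cost = 134597, qaly = 0.86, ly = 1.7)
  res <- compute_icer(a, b, labels = c("tdct", "ct"))
  expect_equal(res$icer, (a$cost - b$cost) / (a$qaly - b$qaly))
  expect_equal(res$label, "icer")
  expect_false(res$cost_effective)

  rev <- compute_icer(b, a, labels = c("ct", "tdct"))
  expect_equal(rev$d_cost, -res$d_cost)
  expect_equal(rev$d_qaly, -res$d_qaly)

  dom <- compute_icer(list(cost = 99, qaly = 1.1), list(cost = 100, qaly = 1))
  expect_equal(dom$label, "dominant")
  expect_true(dom$cost_effective)
  dtd <- compute_icer(list(cost = 101, qaly = 0.9), list(cost = 100, qaly = 1))
  expect_equal(dtd$label, "dominated")
  same <- compute_icer(a, a)
  expect_equal(same$label, "undefined")
  expect_true(is.na(same$icer))
})
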