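test_that("doses follow the body-surface-area convention", {
  bsa <- 1.86
  expect_equal(dose_amount(drug_spec("pemetrexed", 500, "per_m2"), bsa), 930)
  expect_equal(dose_amount(drug_spec("cisplatin", 75, "per_m2"), bsa), 139.5)
  expect_equal(dose_amount(drug_spec("durvalumab", 1500, "flat"), bsa), 1500)
  expect_error(dose_amount(drug_spec("x", 10, "flat"), 0), "positive")
  expect_error(drug_spec("x", -5, "flat"), "negative dose")
  # tremelimumab calendar: five administrations of 75 mg
  expect_equal(5 * dose_amount(drug_spec("tremelimumab", 75, "flat"), bsa),
               375)
})

test_that("induction cost equals the dose calendar when the cohort stays progression-free", {
  p <- base_case_fixture()
  p$regimen$pemetrexed_maintenance <- FALSE
  st <- arm_cost_streams("ct", p)
  mgmt <- p$costs$disease_management$value
  H <- p$settings$horizon_months
  admin <- p$costs$administration$value
  per_admin <- 930 * p$drugs$pemetrexed_per_mg$value +
    139.5 * p$drugs$cisplatin_per_mg$value + admin
  # survival identically 1 through induction: undiscounted drug spend is
  # administrations x (dose x unit cost + fee)
  expect_equal(sum(st$pfs_cost) - H * mgmt, 4 * per_admin)

  # the chemotherapy arm never carries antibody costs
  p_no_chemo <- p
  for (id in c("drugs.pemetrexed_per_mg", "drugs.cisplatin_per_mg")) {
    p_no_chemo <- set_param(p_no_chemo, id, 0)
  }
  p_no_chemo <- set_param(p_no_chemo, "costs.administration", 0)
  p_no_chemo <- set_param(p_no_chemo, "costs.disease_management", 0)
  st0 <- arm_cost_streams("ct", p_no_chemo)
  expect_true(all(st0$pfs_cost == 0))
})

test_that("the intensified arm adds the antibody calendar on the monthly grid", {
  p <- base_case_fixture()
  p$regimen$pemetrexed_maintenance <- FALSE
  st_ct <- arm_cost_streams("ct", p)
  st_td <- arm_cost_streams("tdct", p)
  extra <- st_td$pfs_cost - st_ct$pfs_cost
  admin <- p$costs$administration$value
  durva <- p$drugs$durvalumab_per_admin$value
  treme <- p$drugs$tremelimumab_per_admin$value

  # induction (months 1-4): 6 durvalumab + 5 tremelimumab administrations
  dpm <- p$settings$days_per_month
  maint_monthly <- (durva + admin) * dpm / 28
  expect_equal(sum(extra[1:4]), 6 * (durva + admin) + 5 * (treme + admin))
  # maintenance from month 5: every-4-week durvalumab as a monthly rate
  expect_equal(extra[5], maint_monthly)
  expect_equal(extra[200], maint_monthly)
})

test_that("post-progression stream blends second line with supportive care", {
  p <- base_case_fixture()
  st <- arm_cost_streams("tdct", p)
  # constant stream: proportion on second line, remainder on BSC, plus
  # disease management for everyone progressed
  expect_equal(length(unique(st$pd_cost)), 1L)

  p0 <- set_param(p, "second_line.prop_tdct", 0)
  st0 <- arm_cost_streams("tdct", p0)
  expect_equal(unique(st0$pd_cost),
               p$costs$bsc$value + p$costs$disease_management$value)

  # second-line proportions move post-progression cost but never QALYs
  r <- run_model(p)
  r0 <- run_model(p0)
  expect_equal(r$arms$tdct$qaly, r0$arms$tdct$qaly)
  expect_gt(r$arms$tdct$cost, r0$arms$tdct$cost)
  expect_equal(r$arms$ct$cost, r0$arms$ct$cost)
})

test_that("adverse-event burden is an incidence-weighted one-off", {
  p <- base_case_fixture()
  for (ae in names(p$ae)) {
    p <- set_param(p, paste0("ae.", ae, ".incidence_tdct"), 0)
  }
  z <- ae_first_cycle("tdct", p)
  expect_equal(z$cost, 0)
  expect_equal(z$qaly_loss, 0)

  p1 <- set_param(p, "ae.anemia.incidence_tdct", 0.10)
  p1 <- set_param(p1, "ae.anemia.cost", 1000)
  one <- ae_first_cycle("tdct", p1)
  expect_equal(one$cost, 100)
  expect_equal(one$qaly_loss,
               0.10 * p1$ae$anemia$disutility$value / 12)

  # linear in incidence
  p2 <- set_param(p1, "ae.anemia.incidence_tdct", 0.20)
  expect_equal(ae_first_cycle("tdct", p2)$cost, 2 * one$cost)
  expect_equal(ae_first_cycle("tdct", p2)$qaly_loss, 2 * one$qaly_loss)
})
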