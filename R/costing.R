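#' Drug dose specification
#'
#' @param name drug name.
#' @param dose dose per administration, in mg (flat or per m2) — or ignored
#'   when the price is quoted per administration.
#' @param basis `"flat"` (mg as given) or `"per_m2"` (mg scaled by body
#'   surface area). No vial-wastage rounding: cost is linear in mg.
#' @return a `drug_spec`.
#' @export
drug_spec <- function(name, dose, basis = c("flat", "per_m2")) {
  basis <- match.arg(basis)
  if (dose < 0) stop("negative dose")
  structure(list(name = name, dose = dose, basis = basis),
            class = "drug_spec")
}

#' Administered dose in mg
#' @param drug a [drug_spec()].
#' @param bsa body surface area in m2 (> 0).
#' @export
dose_amount <- function(drug, bsa) {
  stopifnot(inherits(drug, "drug_spec"))
  if (bsa <= 0) stop("bsa must be positive")
  switch(drug$basis,
         flat = drug$dose,
         per_m2 = drug$dose * bsa,
         stop("unknown dosing basis ", drug$basis))
}

# model cycle (1..H) containing treatment day d (day 0 = start of cycle 1)
model_cycle_of_day <- function(day, days_per_month) {
  floor(day / days_per_month) + 1L
}

#' Per-cycle cost streams for one arm
#'
#' Resolves the arm's dose calendar onto the monthly model grid and returns
#' the cost streams the cohort engine consumes:
#' \describe{
#'   \item{pfs_cost}{length-H vector: cost per unit of progression-free
#'     occupancy in each cycle. Induction administrations (21-day treatment
#'     cycles) land on the model cycle containing their calendar day;
#'     maintenance (durvalumab every 28 days, pemetrexed every 21 days, for
#'     the applicable arm/histology) accrues as a per-month rate from its
#'     start day, scaled by the treatment-to-model cycle-length ratio so
#'     dose intensity is preserved; disease management is added every
#'     cycle.}
#'   \item{pd_cost}{scalar-per-cycle vector for the progressed state:
#'     second-line proportion times the blended
#'     pembrolizumab/docetaxel monthly cost, best supportive care for the
#'     remainder, plus disease management; follow-up therapy runs until
#'     death.}
#'   \item{terminal_cost}{one-time terminal palliative care cost applied to
#'     the dying fraction.}
#'   \item{ae_cost, ae_qaly_loss}{one-time first-cycle adverse-event expected
#'     cost and QALY decrement (incidence-weighted; disutility applied for
#'     one month).}
#' }
#'
#' The T+D+CT arm carries tremelimumab 75 mg at treatment cycles 1-4 and 6,
#' durvalumab 1,500 mg at cycles 1-6 then every 4 weeks until progression,
#' and the platinum doublet for 4 cycles; the CT arm carries the doublet
#' alone (4 cycles). Pemetrexed maintenance until progression applies to the
#' non-squamous fraction of both arms when enabled.
#'
#' @param arm `"tdct"` or `"ct"`.
#' @param params a `model_params`.
#' @return list of streams as described.
#' @export
arm_cost_streams <- function(arm, params) {
  arm <- match.arg(arm, c("tdct", "ct"))
  s <- params$settings
  H <- s$horizon_months / s$cycle_months
  dpm <- s$days_per_month
  tc <- params$regimen$treatment_cycle_days
  bsa <- s$bsa$value
  admin <- params$costs$administration$value
  nonsq <- params$regimen$nonsquamous_fraction

  pfs_cost <- rep(params$costs$disease_management$value, H)

  add_admins <- function(days, cost_per_admin) {
    cyc <- model_cycle_of_day(days, dpm)
    for (cy in cyc[cyc <= H]) {
      pfs_cost[cy] <<- pfs_cost[cy] + cost_per_admin + admin
    }
  }
  add_maintenance <- function(start_day, interval_days, cost_per_admin) {
    start_cycle <- model_cycle_of_day(start_day, dpm)
    if (start_cycle > H) return(invisible())
    monthly <- (cost_per_admin + admin) * dpm / interval_days
    pfs_cost[start_cycle:H] <<- pfs_cost[start_cycle:H] + monthly
  }

  # platinum doublet (non-squamous backbone: cisplatin + pemetrexed)
  n_ct <- params$regimen$ct_induction_cycles
  chemo_days <- (seq_len(n_ct) - 1L) * tc
  pem <- drug_spec("pemetrexed", 500, "per_m2")
  cis <- drug_spec("cisplatin", 75, "per_m2")
  chemo_cost <- nonsq * (dose_amount(pem, bsa) * params$drugs$pemetrexed_per_mg$value +
                           dose_amount(cis, bsa) * params$drugs$cisplatin_per_mg$value)
  add_admins(chemo_days, chemo_cost)

  if (arm == "tdct") {
    durva_days <- (0:5) * tc                       # treatment cycles 1-6
    treme_days <- c(0:3, 5) * tc                   # cycles 1-4 and 6
    add_admins(durva_days, params$drugs$durvalumab_per_admin$value)
    add_admins(treme_days, params$drugs$tremelimumab_per_admin$value)
    # durvalumab maintenance from treatment cycle 7 until progression
    add_maintenance(6 * tc, params$regimen$maintenance_interval_days,
                    params$drugs$durvalumab_per_admin$value)
  }
  if (isTRUE(params$regimen$pemetrexed_maintenance) && nonsq > 0) {
    pem_cost <- dose_amount(pem, bsa) * params$drugs$pemetrexed_per_mg$value
    add_maintenance(n_ct * tc, tc, nonsq * pem_cost)
  }

  # post-progression stream
  p2 <- params$second_line[[paste0("prop_", arm)]]$value
  share <- params$second_line$pembrolizumab_share$value
  pembro_monthly <- (params$drugs$pembrolizumab_per_admin$value + admin) *
    dpm / tc
  doce <- drug_spec("docetaxel", 75, "per_m2")
  doce_monthly <- (dose_amount(doce, bsa) *
                     params$drugs$docetaxel_per_mg$value + admin) * dpm / tc
  second_line_monthly <- share * pembro_monthly + (1 - share) * doce_monthly
  pd_cost <- rep(p2 * second_line_monthly +
                   (1 - p2) * params$costs$bsc$value +
                   params$costs$disease_management$value, H)

  ae <- ae_first_cycle(arm, params)

  list(pfs_cost = pfs_cost, pd_cost = pd_cost,
       terminal_cost = params$costs$terminal_care$value,
       ae_cost = ae$cost, ae_qaly_loss = ae$qaly_loss)
}

#' First-cycle adverse-event burden for an arm
#'
#' Expected one-time cost and QALY decrement of the grade >= 3 adverse
#' events in the model (anemia, neutropenia, thrombocytopenia): the
#' incidence-weighted sum of management costs, and of disutilities applied
#' for one model cycle (one month).
#'
#' @param arm `"tdct"` or `"ct"`.
#' @param params a `model_params`.
#' @return list with `cost` (USD) and `qaly_loss` (QALYs).
#' @export
ae_first_cycle <- function(arm, params) {
  arm <- match.arg(arm, c("tdct", "ct"))
  inc_field <- paste0("incidence_", arm)
  cyc_frac <- params$settings$cycle_months / 12
  cost <- 0; qloss <- 0
  for (ae in params$ae) {
    inc <- ae[[inc_field]]$value
    cost <- cost + inc * ae$cost$value
    qloss <- qloss + inc * ae$disutility$value * cyc_frac
  }
  list(cost = cost, qaly_loss = qloss)
}
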