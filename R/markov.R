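#' State occupancy of the three-state partitioned-survival model
#'
#' Reads state membership directly off the endpoint survival curves at
#' monthly cycle boundaries: progression-free = S_PFS(t), dead =
#' 1 - S_OS(t) (after the background-mortality floor), progressed = the
#' difference. Where extrapolated PFS exceeds adjusted OS, PFS is capped at
#' OS and the progressed share clamped at zero, with a warning.
#'
#' @param pfs_fit,os_fit `survival_fit` objects (fitted or imposed).
#' @param params a `model_params`.
#' @param table optional [life_table()] for background mortality (hazard
#'   floor on OS); `NULL` disables the adjustment.
#' @return a data.frame of class `state_trace` with columns `cycle`
#'   (0..H), `time_months`, `p_pfs`, `p_pd`, `p_death`; rows sum to 1.
#' @export
occupancy_from_survival <- function(pfs_fit, os_fit, params, table = NULL) {
  s <- params$settings
  if (s$horizon_months %% s$cycle_months != 0) {
    stop("horizon must be a multiple of the cycle length")
  }
  H <- s$horizon_months / s$cycle_months
  t <- seq(0, s$horizon_months, by = s$cycle_months)
  s_pfs <- survival_at(pfs_fit, t)
  s_os <- survival_at(os_fit, t)
  s_os <- apply_background(s_os, s$start_age, table)
  if (any(s_pfs > s_os + 1e-12)) {
    warning("PFS exceeds adjusted OS at ",
            sum(s_pfs > s_os + 1e-12),
            " cycle(s); capping PFS at OS and clamping PD at 0")
  }
  p_pfs <- pmin(s_pfs, s_os)
  p_pd <- pmax(s_os - p_pfs, 0)
  p_death <- 1 - s_os
  trace <- data.frame(cycle = 0:H, time_months = t,
                      p_pfs = p_pfs, p_pd = p_pd, p_death = p_death)
  class(trace) <- c("state_trace", "data.frame")
  trace
}

#' Discount factor at a time point
#'
#' Annual-rate discounting applied at monthly resolution:
#' (1 + r)^(-t/12). Accrual happens at cycle start and no half-cycle
#' correction is applied, matching the model convention.
#'
#' @param time_months non-negative time; vectorized.
#' @param annual_rate annual discount rate (>= 0).
#' @export
discount_factor <- function(time_months, annual_rate) {
  if (any(time_months < 0)) stop("negative time")
  if (annual_rate < 0) stop("negative discount rate")
  (1 + annual_rate)^(-time_months / 12)
}

#' Accumulate discounted costs, QALYs and life-years over a trace
#'
#' Per-cycle accrual at cycle start: QALYs weight the start-of-cycle state
#' mix by the health-state utilities over the cycle length; costs combine
#' the arm's per-cycle cost streams (see [arm_cost_streams()]) with the
#' state mix; terminal care is charged to the fraction dying within each
#' cycle; adverse-event cost and QALY decrement hit the first cycle only.
#'
#' @param trace a `state_trace`.
#' @param streams output of [arm_cost_streams()] for the same horizon.
#' @param params a `model_params`.
#' @return list with `cost`, `qaly`, `ly` (all discounted totals) and an
#'   undiscounted cost for reference.
#' @export
accumulate <- function(trace, streams, params) {
  s <- params$settings
  H <- nrow(trace) - 1L
  if (length(streams$pfs_cost) != H || length(streams$pd_cost) != H) {
    stop("cost streams and trace are misaligned")
  }
  cyc_frac <- s$cycle_months / 12
  rate <- params$settings$discount_rate_annual$value
  t_start <- trace$time_months[seq_len(H)]          # cycle starts
  df <- discount_factor(t_start, rate)
  p_pfs <- trace$p_pfs[seq_len(H)]
  p_pd <- trace$p_pd[seq_len(H)]
  d_death <- diff(trace$p_death)

  u_pfs <- params$utilities$pfs$value
  u_pd <- params$utilities$pd$value

  qaly_cycles <- df * (p_pfs * u_pfs + p_pd * u_pd) * cyc_frac
  ly_cycles <- df * (p_pfs + p_pd) * cyc_frac

  cost_cycles <- df * (p_pfs * streams$pfs_cost + p_pd * streams$pd_cost +
                         d_death * streams$terminal_cost)
  cost_undisc <- sum(p_pfs * streams$pfs_cost + p_pd * streams$pd_cost +
                       d_death * streams$terminal_cost) + streams$ae_cost

  list(
    cost = sum(cost_cycles) + streams$ae_cost,          # AE cost at cycle 1, df = 1
    qaly = sum(qaly_cycles) - streams$ae_qaly_loss,     # AE disutility, cycle 1
    ly = sum(ly_cycles),
    cost_undiscounted = cost_undisc
  )
}

#' Incremental cost-effectiveness comparison of two arms
#'
#' @param arm_a,arm_b outputs of [accumulate()] (intervention and
#'   comparator, respectively).
#' @param labels character vector of the two arm names.
#' @param wtp_range willingness-to-pay interval used for the verdict.
#' @return a list of class `ce_result`: per-arm totals, incremental cost and
#'   QALYs, `icer` (NA when incremental QALYs are 0), and a `label` among
#'   `"icer"`, `"dominant"`, `"dominated"`, `"undefined"`.
#' @export
compute_icer <- function(arm_a, arm_b, labels = c("A", "B"),
                         wtp_range = c(100000, 150000)) {
  d_cost <- arm_a$cost - arm_b$cost
  d_qaly <- arm_a$qaly - arm_b$qaly
  if (d_qaly == 0) {
    label <- "undefined"; icer <- NA_real_
  } else if (d_cost <= 0 && d_qaly > 0) {
    label <- "dominant"; icer <- d_cost / d_qaly
  } else if (d_cost > 0 && d_qaly < 0) {
    label <- "dominated"; icer <- NA_real_
  } else {
    label <- "icer"; icer <- d_cost / d_qaly
  }
  cost_effective <- if (label == "dominant") TRUE
    else if (label %in% c("dominated", "undefined")) FALSE
    else icer <= max(wtp_range)
  structure(list(
    arms = stats::setNames(list(arm_a, arm_b), labels),
    d_cost = d_cost, d_qaly = d_qaly, icer = icer, label = label,
    wtp_range = wtp_range, cost_effective = cost_effective
  ), class = "ce_result")
}

#' @export
print.ce_result <- function(x, ...) {
  nm <- names(x$arms)
  for (i in 1:2) {
    cat(sprintf("%-12s cost $%s  QALYs %.3f  LY %.3f\n", nm[i],
                format(round(x$arms[[i]]$cost), big.mark = ","),
                x$arms[[i]]$qaly, x$arms[[i]]$ly))
  }
  cat(sprintf("incremental  cost $%s  QALYs %.3f\n",
              format(round(x$d_cost), big.mark = ","), x$d_qaly))
  if (x$label == "icer") {
    cat(sprintf("ICER $%s per QALY (WTP $%s-%s: %s)\n",
                format(round(x$icer, 2), big.mark = ",", scientific = FALSE),
                format(x$wtp_range[1], big.mark = ",", scientific = FALSE),
                format(x$wtp_range[2], big.mark = ",", scientific = FALSE),
                if (x$cost_effective) "cost-effective" else "not cost-effective"))
  } else {
    cat("verdict:", x$label, "\n")
  }
  invisible(x)
}

#' Run the full deterministic model for both arms
#'
#' Builds each arm's survival curves (from the calibrated parameters in
#' `params$survival` unless explicit fits are supplied), the state traces,
#' the cost streams, and the incremental comparison of the
#' immunochemotherapy arm against chemotherapy.
#'
#' @param params a `model_params`.
#' @param fits optional list `list(tdct = list(pfs=, os=), ct = ...)` of
#'   `survival_fit` objects overriding the calibrated curves.
#' @param table optional [life_table()]; default [synthetic_life_table()].
#'   Pass `NULL` to disable background mortality.
#' @return a `ce_result` with the per-arm traces attached.
#' @export
run_model <- function(params, fits = NULL,
                      table = synthetic_life_table()) {
  validate_params(params)
  if (is.null(fits)) {
    fits <- lapply(params$survival, function(armp) {
      lapply(armp, function(ep) {
        survival_fit_from_params(
          "log-logistic",
          c(shape = ep$shape$value, scale = ep$scale$value))
      })
    })
  }
  arms <- names(fits)
  totals <- list()
  traces <- list()
  for (arm in arms) {
    trace <- occupancy_from_survival(fits[[arm]]$pfs, fits[[arm]]$os,
                                     params, table)
    streams <- arm_cost_streams(arm, params)
    totals[[arm]] <- accumulate(trace, streams, params)
    traces[[arm]] <- trace
  }
  res <- compute_icer(totals[[arms[1]]], totals[[arms[2]]],
                      labels = arms, wtp_range = params$settings$wtp_range)
  res$traces <- traces
  res
}
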