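#' Digitized Kaplan-Meier curve with at-risk table
#'
#' Container for one endpoint/arm: read-off coordinates of the published
#' step function plus the printed numbers-at-risk row.
#'
#' @param time read-off times (months), strictly increasing, starting at 0.
#' @param survival survival at those times, in [0, 1], non-increasing,
#'   starting at 1.
#' @param risk_time,n_at_risk the at-risk table; counts non-increasing.
#' @param endpoint `"PFS"` or `"OS"`.
#' @param arm arm label.
#' @return an object of class `km_curve`.
#' @export
km_curve <- function(time, survival, risk_time, n_at_risk,
                     endpoint = "OS", arm = "") {
  stopifnot(length(time) == length(survival),
            length(risk_time) == length(n_at_risk))
  if (is.unsorted(time, strictly = TRUE)) stop("times must be strictly increasing")
  if (time[1] != 0 || abs(survival[1] - 1) > 1e-9) {
    stop("curve must start at (0, 1)")
  }
  if (any(diff(survival) > 1e-9)) stop("survival must be non-increasing")
  if (any(survival < 0 | survival > 1)) stop("survival outside [0, 1]")
  if (any(diff(n_at_risk) > 0)) stop("n_at_risk must be non-increasing")
  if (any(n_at_risk < 0)) stop("n_at_risk must be non-negative")
  structure(list(time = as.numeric(time), survival = as.numeric(survival),
                 risk_time = as.numeric(risk_time),
                 n_at_risk = as.integer(round(n_at_risk)),
                 endpoint = endpoint, arm = arm),
            class = "km_curve")
}

#' @export
print.km_curve <- function(x, ...) {
  cat(sprintf("<km_curve> %s/%s: %d read-off points over [0, %.3g] months, %d at-risk entries\n",
              x$arm, x$endpoint, length(x$time), max(x$time),
              length(x$risk_time)))
  invisible(x)
}

#' Kaplan-Meier estimate of pseudo individual patient data
#'
#' Product-limit estimate via [survival::survfit()]. Right-continuous step
#' function; at tied times events are processed before censorings (the
#' standard convention).
#'
#' @param ipd a `pseudo_ipd`.
#' @return a `km_fit` list with the event-time grid, survival values and
#'   number at risk; use [km_step()] to evaluate it at arbitrary times.
#' @export
km_estimator <- function(ipd) {
  stopifnot(inherits(ipd, "pseudo_ipd"))
  if (length(ipd$time) == 0L) stop("empty ipd")
  sf <- survival::survfit(survival::Surv(ipd$time, ipd$event) ~ 1,
                          conf.type = "none")
  structure(list(time = c(0, sf$time), survival = c(1, sf$surv),
                 n_risk = c(length(ipd$time), sf$n.risk),
                 endpoint = ipd$endpoint, arm = ipd$arm),
            class = "km_fit")
}

#' Evaluate a Kaplan-Meier step function
#'
#' Left-continuous in the sense of carrying the last value forward: S(t) is
#' the estimate at the largest tabulated time `<= t`; beyond the final
#' observation the last value is carried forward.
#'
#' @param km a `km_fit` from [km_estimator()].
#' @param t times at which to read the curve.
#' @return survival probabilities.
#' @export
km_step <- function(km, t) {
  idx <- findInterval(t, km$time)
  idx[idx == 0L] <- 1L
  km$survival[idx]
}

#' Reconstruct pseudo individual patient data from a digitized curve
#'
#' Interval-wise integer allocation of event and censoring counts that
#' reproduces the digitized Kaplan-Meier step function while matching the
#' published number at risk at each at-risk time — the reconstruction scheme
#' used to recover analyzable patient-level records from published survival
#' figures. Within each inter-risk-time interval the number of censorings is
#' found by a deterministic fixed-point iteration: censoring times are
#' spread uniformly across the interval, event counts at each read-off time
#' are chosen to match the published survival ratio given the current
#' at-risk count, and the censoring total is adjusted until the implied
#' number at risk at the next at-risk time equals the published one.
#' Patients still at risk at the final at-risk time are censored there
#' (administrative censoring at the end of follow-up). The procedure is
#' fully deterministic.
#'
#' @param curve a [km_curve()].
#' @return a `pseudo_ipd` whose Kaplan-Meier estimate matches `curve` at the
#'   read-off times up to integer-allocation rounding.
#' @export
reconstruct_ipd <- function(curve) {
  stopifnot(inherits(curve, "km_curve"))
  if (length(curve$risk_time) < 2L) {
    stop("risk table must have at least 2 entries")
  }
  if (max(curve$risk_time) < max(curve$time)) {
    stop("risk table must span the digitized curve")
  }
  t_read <- curve$time
  s_read <- curve$survival
  rt <- curve$risk_time
  nr <- curve$n_at_risk
  J <- length(rt)

  ev_time <- numeric(0)
  cn_time <- numeric(0)

  n_cur <- nr[1]       # number at risk entering the current interval
  km_hat <- 1          # running reconstructed KM value

  for (j in seq_len(J - 1L)) {
    lo <- rt[j]; hi <- rt[j + 1L]
    in_int <- which(t_read > lo & t_read <= hi & t_read > 0)
    s_int <- s_read[in_int]
    width <- hi - lo

    alloc <- function(c_guess) {
      # place c_guess censor times uniformly strictly inside the interval
      ct <- if (c_guess > 0) lo + seq_len(c_guess) * width / (c_guess + 1)
            else numeric(0)
      n <- n_cur
      km <- km_hat
      d_times <- numeric(0)
      d_counts <- integer(0)
      prev_t <- lo
      for (k in seq_along(in_int)) {
        tk <- t_read[in_int[k]]
        n <- n - sum(ct > prev_t & ct <= tk)  # censored before this read-off
        if (n > 0 && km > 0 && s_int[k] < km * (1 - 1e-12)) {
          d <- round(n * (1 - s_int[k] / km))
          d <- max(0L, min(d, n))
          if (d > 0) {
            km <- km * (1 - d / n)
            d_times <- c(d_times, tk)
            d_counts <- c(d_counts, d)
            n <- n - d
          }
        }
        prev_t <- tk
      }
      n <- n - sum(ct > prev_t & ct <= hi)
      list(n_end = n, km = km, ct = ct, d_times = d_times,
           d_counts = d_counts)
    }

    c_guess <- 0L
    best <- NULL
    seen <- integer(0)
    repeat {
      res <- alloc(c_guess)
      diff <- res$n_end - nr[j + 1L]
      if (is.null(best) || abs(diff) < abs(best$diff)) {
        best <- c(res, list(diff = diff, c_guess = c_guess))
      }
      if (diff == 0L || c_guess %in% seen) break
      seen <- c(seen, c_guess)
      c_new <- c_guess + diff
      if (c_new < 0L || c_new > n_cur) break
      c_guess <- c_new
    }
    if (best$diff != 0L) {
      # rounding of event counts can make n_end(c) skip the target by one;
      # fall back to an exhaustive scan over feasible censoring totals
      for (c_try in 0:n_cur) {
        res <- alloc(c_try)
        diff <- res$n_end - nr[j + 1L]
        if (abs(diff) < abs(best$diff)) {
          best <- c(res, list(diff = diff, c_guess = c_try))
        }
        if (diff == 0L) break
      }
    }
    if (abs(best$diff) == 1L) {
      # off-by-one left by integer rounding: absorb it in the censoring
      # stream at the end of the interval (KM effect is O(1/n))
      if (best$diff > 0L) {
        best$ct <- c(best$ct, hi)
        best$n_end <- best$n_end - 1L
      } else if (length(best$ct) > 0L) {
        best$ct <- best$ct[-length(best$ct)]
        best$n_end <- best$n_end + 1L
      } else if (length(best$d_counts) > 0L) {
        last <- length(best$d_counts)
        best$d_counts[last] <- best$d_counts[last] - 1L
        best$n_end <- best$n_end + 1L
      }
      best$diff <- best$n_end - nr[j + 1L]
    }
    if (best$diff != 0L) {
      stop(sprintf(
        "cannot reconcile interval [%g, %g]: survival drop incompatible with at-risk counts (residual %d)",
        rt[j], rt[j + 1L], best$diff))
    }
    ev_time <- c(ev_time, rep(best$d_times, best$d_counts))
    cn_time <- c(cn_time, best$ct)
    n_cur <- best$n_end
    km_hat <- best$km
  }

  # administrative censoring of the survivors at the end of follow-up
  if (n_cur > 0) cn_time <- c(cn_time, rep(rt[J], n_cur))

  new_pseudo_ipd(
    time = c(ev_time, cn_time),
    event = c(rep(1L, length(ev_time)), rep(0L, length(cn_time))),
    endpoint = curve$endpoint, arm = curve$arm,
    provenance = "reconstructed")
}
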