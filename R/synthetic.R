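#' Log-logistic survival function
#'
#' Survival convention used throughout: S(t) = 1 / (1 + (t/scale)^shape),
#' so the median equals `scale` and `shape > 1` gives a unimodal hazard.
#'
#' @param t non-negative times (months).
#' @param scale,shape strictly positive parameters.
#' @return survival probabilities.
#' @export
llogis_survival <- function(t, scale, shape) {
  stopifnot(scale > 0, shape > 0, all(t >= 0))
  1 / (1 + (t / scale)^shape)
}

# inverse-CDF sampler for the log-logistic above
rllogis_sim <- function(n, scale, shape) {
  u <- stats::runif(n)
  # S(t) = u  =>  t = scale * ((1 - u)/u)^(1/shape)
  scale * ((1 - u) / u)^(1 / shape)
}

#' Specification of one synthetic trial arm
#'
#' True (generating) log-logistic parameters for progression-free and
#' overall survival, sample size and an independent exponential censoring
#' rate. Used to emulate a two-arm trial whose published Kaplan-Meier
#' figures downstream stages must reproduce.
#'
#' @param name arm label.
#' @param pfs_scale,pfs_shape,os_scale,os_shape log-logistic parameters
#'   (months / dimensionless), all strictly positive.
#' @param n_patients number of patients in the arm.
#' @param censor_rate monthly exponential censoring hazard (>= 0).
#' @return an object of class `arm_spec`.
#' @export
arm_spec <- function(name, pfs_scale, pfs_shape, os_scale, os_shape,
                     n_patients, censor_rate = 0) {
  for (v in c(pfs_scale, pfs_shape, os_scale, os_shape)) {
    if (!is.numeric(v) || length(v) != 1L || v <= 0) {
      stop("scale and shape parameters must be strictly positive scalars")
    }
  }
  if (n_patients < 1 || n_patients != round(n_patients)) {
    stop("n_patients must be a positive integer")
  }
  if (censor_rate < 0) stop("censor_rate must be >= 0")
  structure(list(name = name, pfs_scale = pfs_scale, pfs_shape = pfs_shape,
                 os_scale = os_scale, os_shape = os_shape,
                 n_patients = as.integer(n_patients),
                 censor_rate = censor_rate),
            class = "arm_spec")
}

new_pseudo_ipd <- function(time, event, endpoint, arm,
                           provenance = "synthetic") {
  stopifnot(length(time) == length(event), all(time > 0), all(is.finite(time)),
            all(event %in% c(0, 1)), length(time) >= 1L)
  structure(list(time = as.numeric(time), event = as.integer(event),
                 endpoint = endpoint, arm = arm, provenance = provenance),
            class = "pseudo_ipd")
}

#' @export
print.pseudo_ipd <- function(x, ...) {
  cat(sprintf("<pseudo_ipd> %s/%s: %d records, %d events (%s)\n",
              x$arm, x$endpoint, length(x$time), sum(x$event), x$provenance))
  invisible(x)
}

#' Simulate patient-level data for one arm
#'
#' Draws PFS and OS event times from the arm's log-logistic laws and an
#' independent exponential censoring time, recording observed time
#' `min(event, censor)` and the event indicator. PFS and OS are drawn
#' independently: ordering between the endpoints is enforced later at the
#' state-occupancy level, not in the generator.
#'
#' @param spec an [arm_spec()].
#' @param seed integer seed; the draw is reproducible given the seed.
#' @return list with elements `pfs` and `os`, each a `pseudo_ipd`.
#' @examples
#' arm <- arm_spec("A", 6.2, 1.8, 13.9, 1.5, n_patients = 100)
#' ipd <- generate_arm(arm, seed = 1)
#' @export
generate_arm <- function(spec, seed) {
  stopifnot(inherits(spec, "arm_spec"))
  set.seed(seed)
  draw <- function(scale, shape, endpoint) {
    t_event <- rllogis_sim(spec$n_patients, scale, shape)
    t_cens <- if (spec$censor_rate > 0) {
      stats::rexp(spec$n_patients, rate = spec$censor_rate)
    } else {
      rep(Inf, spec$n_patients)
    }
    new_pseudo_ipd(pmin(t_event, t_cens), as.integer(t_event <= t_cens),
                   endpoint, spec$name)
  }
  list(pfs = draw(spec$pfs_scale, spec$pfs_shape, "PFS"),
       os = draw(spec$os_scale, spec$os_shape, "OS"))
}

#' Emulate figure digitization of a Kaplan-Meier curve
#'
#' Computes the Kaplan-Meier estimate of `ipd`, reads it off at the given
#' grid times (step-function convention: the last value is carried forward
#' beyond the final observation), and tabulates the true number at risk at
#' each requested risk time — i.e. exactly the information a graph digitizer
#' plus the printed at-risk row extracts from a published figure.
#'
#' @param ipd a `pseudo_ipd`.
#' @param grid non-negative, sorted read-off times (months).
#' @param risk_times times of the published at-risk row.
#' @return a `km_curve` (see [km_curve()]).
#' @export
emulate_digitization <- function(ipd, grid,
                                 risk_times = pretty(c(0, max(ipd$time)))) {
  stopifnot(inherits(ipd, "pseudo_ipd"))
  if (length(ipd$time) == 0L) stop("empty ipd")
  if (any(grid < 0) || is.unsorted(grid)) {
    stop("grid times must be non-negative and sorted")
  }
  km <- km_estimator(ipd)
  surv <- km_step(km, grid)
  n_at_risk <- vapply(risk_times, function(tt) sum(ipd$time >= tt), 0L)
  km_curve(time = grid, survival = surv,
           risk_time = risk_times, n_at_risk = n_at_risk,
           endpoint = ipd$endpoint, arm = ipd$arm)
}

#' Generate a complete synthetic two-arm trial
#'
#' Patient-level PFS/OS data for both arms plus their digitized-figure-like
#' Kaplan-Meier curves and at-risk tables, reproducible under the seed.
#'
#' @param spec_a,spec_b [arm_spec()] objects for the two arms.
#' @param seed integer seed.
#' @param grid_by spacing (months) of the digitization read-off grid.
#' @param risk_by spacing (months) of the at-risk table.
#' @return list with per-arm `ipd` and `curves`, and the generation metadata.
#' @export
synthetic_trial <- function(spec_a, spec_b, seed, grid_by = 0.25,
                            risk_by = 3) {
  arms <- list(spec_a, spec_b)
  names(arms) <- vapply(arms, `[[`, "", "name")
  ipd <- list(generate_arm(spec_a, seed = seed),
              generate_arm(spec_b, seed = seed + 1L))
  names(ipd) <- names(arms)
  curves <- lapply(ipd, function(arm_ipd) {
    lapply(arm_ipd, function(x) {
      tmax <- max(x$time)
      emulate_digitization(
        x, grid = seq(0, tmax, by = grid_by),
        risk_times = seq(0, ceiling(tmax / risk_by) * risk_by, by = risk_by))
    })
  })
  list(ipd = ipd, curves = curves,
       meta = list(specs = arms, seed = seed, grid_by = grid_by,
                   risk_by = risk_by))
}

#' Write a Kaplan-Meier curve and its at-risk table as delimited text
#'
#' Two CSV files: `<stem>_km.csv` with columns `time_months, survival` and
#' `<stem>_risk.csv` with columns `time_months, n_at_risk`.
#' @param curve a `km_curve`.
#' @param stem output path stem.
#' @export
write_km_curve <- function(curve, stem) {
  utils::write.csv(data.frame(time_months = curve$time,
                              survival = curve$survival),
                   paste0(stem, "_km.csv"), row.names = FALSE)
  utils::write.csv(data.frame(time_months = curve$risk_time,
                              n_at_risk = curve$n_at_risk),
                   paste0(stem, "_risk.csv"), row.names = FALSE)
  invisible(stem)
}

#' Read a Kaplan-Meier curve written by [write_km_curve()]
#' @param stem path stem used when writing.
#' @param endpoint,arm labels attached to the curve.
#' @return a `km_curve`.
#' @export
read_km_curve <- function(stem, endpoint = "OS", arm = "") {
  km <- utils::read.csv(paste0(stem, "_km.csv"))
  risk <- utils::read.csv(paste0(stem, "_risk.csv"))
  km_curve(km$time_months, km$survival, risk$time_months, risk$n_at_risk,
           endpoint = endpoint, arm = arm)
}

#' Write pseudo individual patient data as delimited text
#' @param ipd a `pseudo_ipd`.
#' @param path CSV path; columns `time_months, event`.
#' @export
write_ipd <- function(ipd, path) {
  utils::write.csv(data.frame(time_months = ipd$time, event = ipd$event),
                   path, row.names = FALSE)
  invisible(path)
}
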