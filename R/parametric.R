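#' @importFrom stats AIC coef qnorm runif setNames uniroot
NULL

# supported families and their flexsurv names / free-parameter counts
.families <- data.frame(
  family = c("exponential", "weibull", "log-normal", "log-logistic",
             "gamma", "generalized-gamma", "gompertz"),
  flexsurv = c("exp", "weibull", "lnorm", "llogis", "gamma", "gengamma",
               "gompertz"),
  k = c(1L, 2L, 2L, 2L, 2L, 3L, 2L),
  stringsAsFactors = FALSE
)

#' Supported parametric survival families
#' @return character vector of family names accepted by [fit_family()].
#' @export
survival_families <- function() .families$family

family_row <- function(family) {
  i <- match(family, .families$family)
  if (is.na(i)) {
    stop("unknown family '", family, "'; see survival_families()")
  }
  .families[i, ]
}

#' Fit one parametric family to right-censored patient data
#'
#' Maximum-likelihood fit of the right-censored log-likelihood
#' sum(events) log f(t) + sum(censored) log S(t), via
#' [flexsurv::flexsurvreg()], with up to three jittered restarts for the
#' numerically fragile families. The log-logistic uses
#' S(t) = 1/(1 + (t/scale)^shape); the generalized gamma uses the
#' stable location/scale/shape (Prentice) form. Gompertz fits with a
#' negative shape parameter are rejected as defective (survival does not
#' reach zero), since the model is used for lifetime extrapolation.
#'
#' @param ipd a `pseudo_ipd` with at least 10 records and 1 event.
#' @param family one of [survival_families()].
#' @return an object of class `survival_fit` with natural-scale `params`,
#'   `loglik`, `aic`, `bic` (k log n - 2 loglik), `n`, and labels.
#' @export
fit_family <- function(ipd, family) {
  stopifnot(inherits(ipd, "pseudo_ipd"))
  fam <- family_row(family)
  n <- length(ipd$time)
  if (n < 10L) stop("need at least 10 records, got ", n)
  if (sum(ipd$event) < 1L) stop("all records censored; cannot fit")

  fit <- NULL
  errors <- character(0)
  for (attempt in 1:3) {
    fit <- tryCatch({
      if (attempt == 1L) {
        flexsurv::flexsurvreg(
          survival::Surv(ipd$time, ipd$event) ~ 1, dist = fam$flexsurv)
      } else {
        # jittered restart on the optimizer's natural scale
        base <- flexsurv::flexsurvreg(
          survival::Surv(ipd$time, ipd$event) ~ 1, dist = fam$flexsurv,
          control = list(maxit = 50))
        inits <- base$res[, "est"] * exp(stats::rnorm(fam$k, 0, 0.2))
        flexsurv::flexsurvreg(
          survival::Surv(ipd$time, ipd$event) ~ 1, dist = fam$flexsurv,
          inits = inits)
      }
    }, error = function(e) {
      errors <<- c(errors, conditionMessage(e))
      NULL
    })
    if (!is.null(fit) && isTRUE(fit$opt$convergence == 0)) break
  }
  if (is.null(fit) || !isTRUE(fit$opt$convergence == 0)) {
    stop("fit of ", family, " did not converge: ",
         paste(unique(errors), collapse = "; "))
  }
  params <- fit$res[, "est"]
  names(params) <- rownames(fit$res)
  if (family == "gompertz" && params[["shape"]] < 0) {
    stop("gompertz fit is defective (negative shape); rejected for extrapolation")
  }
  ll <- fit$loglik
  structure(list(
    family = family, params = params, loglik = ll,
    aic = 2 * fam$k - 2 * ll,
    bic = fam$k * log(n) - 2 * ll,
    k = fam$k, n = n,
    endpoint = ipd$endpoint, arm = ipd$arm,
    converged = TRUE, flexsurv = fit
  ), class = "survival_fit")
}

#' @export
print.survival_fit <- function(x, ...) {
  cat(sprintf("<survival_fit> %s (%s/%s), n=%d: %s | loglik=%.2f AIC=%.2f BIC=%.2f\n",
              x$family, x$arm, x$endpoint, x$n,
              paste(sprintf("%s=%.4g", names(x$params), x$params),
                    collapse = ", "),
              x$loglik, x$aic, x$bic))
  invisible(x)
}

#' Build a survival_fit from known parameters
#'
#' Wraps externally supplied (e.g. calibrated) parameters in the same object
#' used for fitted models, so the cohort engine is agnostic to whether the
#' curve was estimated or imposed. No likelihood quantities are available.
#'
#' @param family family name.
#' @param params named natural-scale parameter vector as returned by
#'   [fit_family()] for that family (e.g. `c(scale=, shape=)` for the
#'   log-logistic).
#' @param endpoint,arm labels.
#' @export
survival_fit_from_params <- function(family, params, endpoint = "OS",
                                     arm = "") {
  fam <- family_row(family)
  structure(list(family = family, params = params, loglik = NA_real_,
                 aic = NA_real_, bic = NA_real_, k = fam$k, n = NA_integer_,
                 endpoint = endpoint, arm = arm, converged = NA,
                 flexsurv = NULL),
            class = "survival_fit")
}

#' Fit all candidate families
#'
#' Fits every family in `families`, skipping (with a message) those that
#' fail to converge or are rejected as defective.
#'
#' @inheritParams fit_family
#' @param families families to try; defaults to all seven.
#' @return list of `survival_fit` objects.
#' @export
fit_all_families <- function(ipd, families = survival_families()) {
  fits <- list()
  for (fam in families) {
    f <- tryCatch(fit_family(ipd, fam), error = function(e) {
      message("skipping ", fam, ": ", conditionMessage(e))
      NULL
    })
    if (!is.null(f)) fits[[fam]] <- f
  }
  fits
}

#' Select the best-fitting family by information criterion
#'
#' Returns the fit minimizing AIC. If the BIC ranking disagrees, the AIC
#' choice is kept and the disagreement is reported as a message.
#'
#' @param fits non-empty list of `survival_fit` objects on the same data.
#' @return the selected `survival_fit`.
#' @export
select_model <- function(fits) {
  if (length(fits) == 0L) stop("no fits to select from")
  aics <- vapply(fits, `[[`, 0, "aic")
  bics <- vapply(fits, `[[`, 0, "bic")
  best_aic <- which.min(aics)
  best_bic <- which.min(bics)
  if (best_aic != best_bic) {
    message("AIC selects ", fits[[best_aic]]$family, " but BIC selects ",
            fits[[best_bic]]$family, "; keeping the AIC choice")
  }
  fits[[best_aic]]
}

#' Parametric survival function
#'
#' Closed-form S(t) of the fitted family; S(0) = 1 and S is non-increasing.
#'
#' @param fit a `survival_fit`.
#' @param t non-negative times (months); vectorized.
#' @return survival probabilities.
#' @export
survival_at <- function(fit, t) {
  stopifnot(inherits(fit, "survival_fit"))
  if (any(t < 0)) stop("negative time")
  p <- fit$params
  switch(fit$family,
    "exponential" = exp(-p[["rate"]] * t),
    "weibull" = exp(-(t / p[["scale"]])^p[["shape"]]),
    "log-normal" = stats::plnorm(t, p[["meanlog"]], p[["sdlog"]],
                                 lower.tail = FALSE),
    "log-logistic" = 1 / (1 + (t / p[["scale"]])^p[["shape"]]),
    "gamma" = stats::pgamma(t, shape = p[["shape"]], rate = p[["rate"]],
                            lower.tail = FALSE),
    "generalized-gamma" = flexsurv::pgengamma(
      t, mu = p[["mu"]], sigma = p[["sigma"]], Q = p[["Q"]],
      lower.tail = FALSE),
    "gompertz" = flexsurv::pgompertz(
      t, shape = p[["shape"]], rate = p[["rate"]], lower.tail = FALSE),
    stop("unknown family ", fit$family)
  )
}

#' Median survival time of a fitted model
#'
#' Analytic where the family admits it (log-logistic: the scale;
#' exponential: log(2)/rate; weibull: scale log(2)^(1/shape)); otherwise the
#' smallest t with S(t) <= 0.5 by bracketed root finding to 1e-6 months.
#'
#' @param fit a `survival_fit`.
#' @param horizon search horizon in months; an error is raised if survival
#'   stays above 0.5 out to 10 times this.
#' @return median in months.
#' @export
median_survival <- function(fit, horizon = 200) {
  p <- fit$params
  med <- switch(fit$family,
    "log-logistic" = p[["scale"]],
    "exponential" = log(2) / p[["rate"]],
    "weibull" = p[["scale"]] * log(2)^(1 / p[["shape"]]),
    NULL)
  if (!is.null(med)) return(unname(med))
  upper <- 10 * horizon
  if (survival_at(fit, upper) > 0.5) {
    stop("survival does not reach 0.5 within ", upper, " months")
  }
  stats::uniroot(function(t) survival_at(fit, t) - 0.5,
                 lower = 0, upper = upper, tol = 1e-6)$root
}
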