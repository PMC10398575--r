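#' One-way (univariate) sensitivity analysis of a single parameter
#'
#' Re-runs the full deterministic model twice with one parameter at its low
#' and high bound (all others at base case) and returns both ICERs and the
#' span for tornado ordering. Prices encoded with `high = value` are thereby
#' only varied downward.
#'
#' @param params base-case `model_params`.
#' @param id parameter id as in [param_table()].
#' @param ... passed to [run_model()].
#' @return list with `id`, `icer_low`, `icer_high`, `icer_base`, `span`.
#' @export
one_way <- function(params, id, ...) {
  p <- get_param(params, id)
  base <- run_model(params, ...)
  at <- function(v) run_model(set_param(params, id, v), ...)$icer
  icer_low <- at(p$low)
  icer_high <- at(p$high)
  list(id = id, icer_low = icer_low, icer_high = icer_high,
       icer_base = base$icer,
       span = abs(icer_high - icer_low))
}

#' Tornado analysis over all uncertain parameters
#'
#' Runs [one_way()] for every non-fixed parameter and orders the results by
#' decreasing ICER span.
#'
#' @param params base-case `model_params`.
#' @param ids parameter ids to vary; default all non-fixed, non-degenerate
#'   entries of [param_table()].
#' @param ... passed to [run_model()].
#' @return data.frame with columns `id, low, high, icer_low, icer_high,
#'   icer_base, span`, sorted by span.
#' @export
tornado <- function(params, ids = NULL, ...) {
  tab <- param_table(params)
  if (is.null(ids)) {
    ids <- tab$id[tab$dist != "fixed" & tab$high > tab$low]
  }
  rows <- lapply(ids, function(id) {
    ow <- one_way(params, id, ...)
    p <- get_param(params, id)
    data.frame(id = id, low = p$low, high = p$high,
               icer_low = ow$icer_low, icer_high = ow$icer_high,
               icer_base = ow$icer_base, span = ow$span,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out[order(-out$span), , drop = FALSE]
}

#' Draw one probabilistic parameter set
#'
#' Samples every uncertain parameter from its assigned distribution by the
#' method of moments: gamma for costs with shape = 1/cv^2 and
#' scale = mean cv^2; beta for utilities, probabilities and proportions with
#' sd = cv times the mean. Fixed parameters are left untouched. The default
#' cv of 0.2 mirrors the 20 percent one-way ranges. Survival-curve
#' parameters are fixed (their leaves carry `dist = "fixed"`).
#'
#' @param params base-case `model_params`.
#' @param cv coefficient of variation for all varying parameters.
#' @return a sampled `model_params`.
#' @export
draw_params <- function(params, cv = 0.2) {
  sample_leaf <- function(x, path) {
    if (x$dist == "fixed" || x$value == 0) return(x)
    if (x$dist == "gamma") {
      x$value <- stats::rgamma(1, shape = 1 / cv^2, scale = x$value * cv^2)
    } else if (x$dist == "beta") {
      m <- x$value
      sd <- cv * m
      if (sd^2 >= m * (1 - m)) {
        stop("infeasible beta moments for parameter ",
             paste(path, collapse = "."), " (mean ", m, ", sd ", sd, ")")
      }
      nu <- m * (1 - m) / sd^2 - 1
      x$value <- stats::rbeta(1, m * nu, (1 - m) * nu)
    }
    x
  }
  walk <- function(node, path) {
    if (is_ce_param(node)) return(sample_leaf(node, path))
    if (is.list(node)) {
      for (nm in names(node)) node[[nm]] <- walk(node[[nm]], c(path, nm))
    }
    node
  }
  out <- walk(unclass(params), character(0))
  class(out) <- class(params)
  out
}

#' Probabilistic sensitivity analysis
#'
#' Monte Carlo re-runs of the full deterministic model under joint parameter
#' draws. Draws whose sampled parameter set fails validation are recorded
#' and excluded with a warning.
#'
#' @param params base-case `model_params`.
#' @param n number of draws (the analysis convention is 1,000).
#' @param seed integer seed; draws are reproducible.
#' @param cv coefficient of variation passed to [draw_params()].
#' @param ... passed to [run_model()].
#' @return list of class `psa_result`: `draws` data.frame (`d_cost`,
#'   `d_qaly`, per-arm totals), `n_requested`, `n_excluded`, `seed` and the
#'   base-case result.
#' @export
run_psa <- function(params, n = 1000, seed = 1, cv = 0.2, ...) {
  set.seed(seed)
  base <- run_model(params, ...)
  rows <- vector("list", n)
  excluded <- 0L
  for (i in seq_len(n)) {
    res <- tryCatch({
      pi <- draw_params(params, cv = cv)
      r <- run_model(pi, ...)
      nm <- names(r$arms)
      data.frame(d_cost = r$d_cost, d_qaly = r$d_qaly,
                 cost_a = r$arms[[1]]$cost, qaly_a = r$arms[[1]]$qaly,
                 cost_b = r$arms[[2]]$cost, qaly_b = r$arms[[2]]$qaly)
    }, error = function(e) NULL)
    if (is.null(res)) excluded <- excluded + 1L else rows[[i]] <- res
  }
  if (excluded > 0L) {
    warning(excluded, " of ", n, " draws failed validation and were excluded")
  }
  draws <- do.call(rbind, rows[!vapply(rows, is.null, TRUE)])
  structure(list(draws = draws, n_requested = n, n_excluded = excluded,
                 seed = seed, base = base),
            class = "psa_result")
}

#' Cost-effectiveness acceptability curve
#'
#' At each willingness-to-pay value, the probability of cost-effectiveness
#' is the fraction of PSA draws with positive net monetary benefit
#' (lambda dQALY - dCost > 0).
#'
#' @param psa a `psa_result`.
#' @param wtp_grid willingness-to-pay values (USD/QALY); default 0 to
#'   300,000 in steps of 5,000.
#' @return data.frame with columns `wtp`, `prob_cost_effective`.
#' @export
ceac <- function(psa, wtp_grid = seq(0, 300000, by = 5000)) {
  stopifnot(inherits(psa, "psa_result"))
  if (length(wtp_grid) == 0L) stop("empty willingness-to-pay grid")
  if (nrow(psa$draws) == 0L) stop("no retained PSA draws")
  prob <- vapply(wtp_grid, function(l) {
    mean(l * psa$draws$d_qaly - psa$draws$d_cost > 0)
  }, 0)
  data.frame(wtp = wtp_grid, prob_cost_effective = prob)
}
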