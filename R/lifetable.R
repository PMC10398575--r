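#' Period life table
#'
#' Age-indexed annual death probabilities q(x) used to floor extrapolated
#' disease mortality at general-population mortality.
#'
#' @param age integer ages, contiguous, covering at least up to 100.
#' @param qx annual death probabilities in [0, 1).
#' @param source,year metadata strings.
#' @return an object of class `life_table`.
#' @export
life_table <- function(age, qx, source = "", year = NA) {
  stopifnot(length(age) == length(qx))
  if (any(diff(age) != 1L)) stop("ages must be contiguous")
  if (any(qx < 0 | qx >= 1)) stop("q must lie in [0, 1)")
  if (max(age) < 100) stop("table must extend to age 100")
  structure(list(age = as.integer(age), qx = as.numeric(qx),
                 source = source, year = year),
            class = "life_table")
}

#' Synthetic period life table
#'
#' A Gompertz–Makeham style schedule q(x) = min(a + b e^{cx}, 0.95) with
#' a = 4e-4, b = 7e-5, c = 0.083, which tracks the shape and magnitude of a
#' recent U.S. all-population period table (q ~ 0.015 at 64, ~ 0.08 at 85).
#' Synthetic: a stand-in for a real national table, which the user can
#' supply as delimited text via [read_life_table()].
#'
#' @param max_age last age row (>= 100).
#' @return a [life_table()].
#' @export
synthetic_life_table <- function(max_age = 110) {
  age <- 0:max_age
  qx <- pmin(4e-4 + 7e-5 * exp(0.083 * age), 0.95)
  life_table(age, qx, source = "synthetic Gompertz-Makeham schedule")
}

#' Read a life table from delimited text
#' @param path CSV with columns `age, qx`.
#' @param ... metadata passed to [life_table()].
#' @export
read_life_table <- function(path, ...) {
  d <- utils::read.csv(path)
  life_table(d$age, d$qx, ...)
}

#' Monthly background mortality hazard at a given age
#'
#' Converts the annual death probability at the attained (integer) age to a
#' constant monthly hazard: h = -log(1 - q(floor(age))) / 12.
#'
#' @param table a [life_table()].
#' @param age_years attained age (may be fractional); vectorized.
#' @return monthly hazard(s).
#' @export
monthly_background_hazard <- function(table, age_years) {
  stopifnot(inherits(table, "life_table"))
  a <- floor(age_years)
  if (any(a < min(table$age)) || any(a > max(table$age))) {
    stop("age outside life-table range [", min(table$age), ", ",
         max(table$age), "]")
  }
  q <- table$qx[match(a, table$age)]
  -log(1 - q) / 12
}

#' Floor disease mortality at background mortality
#'
#' Given modelled overall survival at monthly cycle boundaries, rebuilds the
#' curve using per-cycle effective hazards
#' h_eff = max(h_disease, h_background(attained age)), where the disease
#' hazard comes from consecutive survival ratios and the cohort ages 1/12
#' year per cycle. This prevents extrapolated mortality from falling below
#' general-population mortality; it never increases survival.
#'
#' @param os_surv survival probabilities at times 0, 1, ..., H months;
#'   non-increasing, starting at 1.
#' @param start_age cohort age (years) at time 0.
#' @param table a [life_table()]; `NULL` returns `os_surv` unchanged.
#' @return adjusted survival sequence of the same length.
#' @export
apply_background <- function(os_surv, start_age, table) {
  stopifnot(abs(os_surv[1] - 1) < 1e-12, all(diff(os_surv) <= 1e-12))
  if (is.null(table)) return(os_surv)
  H <- length(os_surv) - 1L
  ages <- start_age + (seq_len(H) - 1L) / 12
  h_bg <- monthly_background_hazard(table, ages)
  ratio <- os_surv[-1] / os_surv[-length(os_surv)]
  ratio[!is.finite(ratio)] <- 0
  h_dis <- -log(pmax(ratio, 0))
  h_eff <- pmax(h_dis, h_bg)
  adj <- cumprod(c(1, exp(-h_eff)))
  adj
}
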