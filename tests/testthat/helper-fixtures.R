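# shared fixtures built in code

make_ipd <- function(time, event, endpoint = "OS", arm = "test") {
  psmcea:::new_pseudo_ipd(time, event, endpoint, arm)
}

# parameter set with all distributions frozen (degenerate PSA)
freeze_params <- function(params) {
  walk <- function(node) {
    if (inherits(node, "ce_param")) {
      node$dist <- "fixed"
      return(node)
    }
    if (is.list(node)) for (nm in names(node)) node[[nm]] <- walk(node[[nm]])
    node
  }
  out <- walk(unclass(params))
  class(out) <- class(params)
  out
}

# zero-cost stream bundle for a given number of cycles
zero_streams <- function(H) {
  list(pfs_cost = rep(0, H), pd_cost = rep(0, H), terminal_cost = 0,
       ae_cost = 0, ae_qaly_loss = 0)
}

# trace with the whole cohort progression-free for H cycles
alive_trace <- function(H) {
  tr <- data.frame(cycle = 0:H, time_months = 0:H,
                   p_pfs = 1, p_pd = 0, p_death = 0)
  class(tr) <- c("state_trace", "data.frame")
  tr
}

# small parameter set for fast cohort tests
toy_params <- function(horizon = 12, u_pfs = 1, u_pd = 1, discount = 0) {
  p <- base_case_fixture()
  p$settings$horizon_months <- horizon
  p <- set_param(p, "utilities.pfs", u_pfs)
  p <- set_param(p, "utilities.pd", u_pd)
  p <- set_param(p, "settings.discount_rate_annual", discount)
  p
}
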