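# Shared fixtures and the individual-level microsimulation oracle.

base_params <- caries_parameters()

# A parameter set with every distribution degenerate (PSA collapse checks).
fixed_params <- local({
  p <- base_params
  p$params$dist <- "fixed"
  p
})

# Build a caries_params object directly from a synth_truth (the "truth"
# route, independent of the estimation stage).
params_from_truth <- function(truth, template = base_params) {
  frag <- do.call(rbind, c(lapply(c("intervention", "comparison"), function(arm) {
    rbind(
      cariescua:::.param_row("p_caries", arm, truth$prevalence[[arm]],
                             NA, NA, "beta", "probability", "truth"),
      cariescua:::.param_row("p_new_caries_2y", arm, truth$incidence_2y[[arm]],
                             NA, NA, "beta", "probability", "truth"),
      cariescua:::.param_row("p_seek_treatment", arm, truth$seek[[arm]],
                             NA, NA, "triangular", "probability", "truth")
    )
  }), make.row.names = FALSE))
  merge_parameters(template, frag)
}

# Monte-Carlo microsimulation of the same decision model: individual children
# walk the transition matrix; costs/QALYs accrue at cycle end with the same
# discounting as accrue(). Returns means and standard errors across children.
microsim <- function(params, arm, n = 1e5, seed = 1) {
  set.seed(seed)
  s <- params$settings
  tmat <- transition_matrix(params, arm)
  cmat <- t(apply(tmat, 1, cumsum))
  init <- initial_state(params, arm)
  costs <- state_costs(params, arm)
  utils <- state_utilities(params)
  dc <- (1 + s$discount_cost)^-(0:(s$horizon - 1))
  dq <- (1 + s$discount_qaly)^-(0:(s$horizon - 1))
  state <- sample.int(3L, n, replace = TRUE, prob = init)
  totc <- totq <- numeric(n)
  for (t in seq_len(s$horizon)) {
    u <- stats::runif(n)
    state <- 1L + (u > cmat[state, 1]) + (u > cmat[state, 2])
    totc <- totc + dc[t] * costs[state]
    totq <- totq + dq[t] * utils[state]
  }
  list(cost = mean(totc), cost_se = stats::sd(totc) / sqrt(n),
       qalys = mean(totq), qalys_se = stats::sd(totq) / sqrt(n))
}

# Random admissible parameter perturbations for property-style loops.
random_params <- function(template = base_params) {
  p <- template
  for (arm in c("intervention", "comparison")) {
    p <- set_param(p, "p_caries", runif(1, 0.1, 0.9), arm = arm)
    p <- set_param(p, "p_new_caries_2y", runif(1, 0.1, 0.8), arm = arm)
    p <- set_param(p, "p_seek_treatment", runif(1, 0.3, 1.0), arm = arm)
  }
  p <- set_param(p, "utility_caries", runif(1, 0.5, 0.99))
  p
}
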