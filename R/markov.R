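# Three-state Markov cohort engine.
# State order is fixed for matrix indexing:
#   1 healthy        ("No active dental caries")
#   2 active_caries  ("New Active Caries", ICDAS-II 3-6)
#   3 untreated      ("Caries Untreated")

#' Health-state labels, in matrix order
#' @export
caries_states <- function() c("healthy", "active_caries", "untreated")

#' Annual new-caries transition probability for an arm
#'
#' Converts the stored two-year new-caries probability to the annual cycle
#' scale using the conversion selected by the `rate_conversion` setting.
#'
#' @param params a `caries_params` object.
#' @param arm `"intervention"` or `"comparison"`.
#' @keywords internal
annual_new_caries <- function(params, arm) {
  p2 <- param_value(params, "p_new_caries_2y", arm)
  prob_interval_to_annual(p2, 2, method = params$settings$rate_conversion)
}

#' Build the annual transition matrix for one arm
#'
#' Rows are from-states, columns to-states, in [caries_states()] order.
#' Structural zeros: healthy children cannot become untreated without first
#' developing caries, and untreated children do not return to health without
#' passing through the active-caries (treatment) state.
#'
#' The active-caries exit probability follows the `treated_return` setting:
#' * `"seek_mix"` (default): p_seek × (p_restoration + p_extraction +
#'   p_pulp_therapy) — children who both seek care and receive one of the
#'   three treatments return to health;
#' * `"seek"`: p_seek alone;
#' * `"mix"`: the treatment-mix sum alone.
#'
#' @param params a validated `caries_params` object.
#' @param arm `"intervention"` or `"comparison"`.
#' @return 3×3 stochastic matrix with state dimnames.
#' @examples
#' transition_matrix(caries_parameters(), "intervention")
#' @export
transition_matrix <- function(params, arm) {
  arm <- match.arg(arm, .ARMS)
  p_c <- annual_new_caries(params, arm)
  p_seek <- param_value(params, "p_seek_treatment", arm)
  p_mix <- param_value(params, "p_restoration") +
    param_value(params, "p_extraction") +
    param_value(params, "p_pulp_therapy")
  p_return <- switch(params$settings$treated_return,
    seek_mix = p_seek * p_mix,
    seek = p_seek,
    mix = p_mix
  )
  m <- matrix(c(
    1 - p_c, p_c,      0,
    p_return, 0,       1 - p_return,
    0,        p_c,     1 - p_c
  ), nrow = 3, byrow = TRUE, dimnames = list(caries_states(), caries_states()))
  if (any(m < 0) || any(m > 1)) {
    stop("transition probability outside [0, 1] for arm '", arm, "'")
  }
  m
}

#' Initial state occupancy for one arm
#'
#' The cohort starts split between healthy and active caries according to the
#' arm's baseline caries prevalence; nobody starts untreated.
#'
#' @inheritParams transition_matrix
#' @return named occupancy vector summing to 1.
#' @export
initial_state <- function(params, arm) {
  arm <- match.arg(arm, .ARMS)
  p0 <- param_value(params, "p_caries", arm)
  c(healthy = 1 - p0, active_caries = p0, untreated = 0)
}

#' Run the deterministic cohort simulation
#'
#' Propagates the occupancy vector through the transition matrix for
#' `n_cycles` annual cycles.
#'
#' @param tmat 3×3 stochastic matrix (rows sum to 1).
#' @param init occupancy vector summing to 1.
#' @param n_cycles number of cycles (>= 1).
#' @param arm optional arm label stored on the result.
#' @return a `cohort_trace`: numeric matrix with `n_cycles + 1` rows (cycle 0
#'   is the initial distribution) and one column per state.
#' @export
run_cohort <- function(tmat, init, n_cycles, arm = NULL) {
  stopifnot(n_cycles >= 1, length(init) == nrow(tmat))
  if (max(abs(rowSums(tmat) - 1)) > 1e-12) stop("transition matrix rows must sum to 1")
  if (abs(sum(init) - 1) > 1e-10) stop("initial occupancies must sum to 1")
  tr <- matrix(NA_real_, nrow = n_cycles + 1L, ncol = ncol(tmat),
               dimnames = list(0:n_cycles, colnames(tmat)))
  tr[1, ] <- init
  for (t in seq_len(n_cycles)) tr[t + 1L, ] <- tr[t, ] %*% tmat
  structure(tr, class = c("cohort_trace", "matrix"), arm = arm)
}

#' Per-person per-cycle state costs for one arm
#'
#' Healthy-state cost is the annual prevention bundle (examination,
#' radiography, `fraction_sealant` × fissure sealant, varnish) in the
#' intervention arm and zero under usual care. The active-caries state cost is
#' incurred only by the fraction who seek treatment: clinic costs
#' (examination, radiography, `fraction_plaque_calculus` × (plaque + calculus
#' removal), `fraction_ohi_diet` × (oral-hygiene instructions + dietary
#' advice)) plus the expected treatment cost
#' `p_restoration × cost_restoration + p_extraction × cost_extraction +
#' p_pulp_therapy × cost_pulp_therapy`. Untreated caries accrues no cost.
#'
#' @inheritParams transition_matrix
#' @return named numeric vector of per-person cycle costs by state.
#' @export
state_costs <- function(params, arm) {
  arm <- match.arg(arm, .ARMS)
  s <- params$settings
  v <- function(nm) param_value(params, nm)
  healthy <- if (arm == "intervention") {
    v("cost_examination") + v("cost_radiography") +
      s$fraction_sealant * v("cost_fissure_sealant") + v("cost_varnish")
  } else 0
  p_seek <- param_value(params, "p_seek_treatment", arm)
  treat <- v("p_restoration") * v("cost_restoration") +
    v("p_extraction") * v("cost_extraction") +
    v("p_pulp_therapy") * v("cost_pulp_therapy")
  active <- p_seek * (
    v("cost_examination") + v("cost_radiography") +
      s$fraction_plaque_calculus * (v("cost_plaque_removal") + v("cost_calculus_removal")) +
      s$fraction_ohi_diet * (v("cost_oral_hygiene") + v("cost_dietary_advice")) +
      treat
  )
  out <- c(healthy = healthy, active_caries = active, untreated = 0)
  if (any(out < 0)) stop("negative state cost computed for arm '", arm, "'")
  out
}

#' Per-state utility weights
#'
#' Both caries states (active and untreated) carry the caries utility; the
#' healthy state carries the full-health utility.
#'
#' @param params a `caries_params` object.
#' @return named numeric vector of utilities by state.
#' @export
state_utilities <- function(params) {
  uc <- param_value(params, "utility_caries")
  c(healthy = param_value(params, "utility_healthy"),
    active_caries = uc, untreated = uc)
}

#' Accrue discounted costs, QALYs and caries events over a trace
#'
#' Rewards accrue at the end of each cycle: cycle `t` (t = 1..H) weights the
#' post-transition occupancies by the state payoffs and the discount factor
#' `(1 + r)^-(t - 1)` (the first cycle is undiscounted). Caries events are the
#' undiscounted sum of active-caries occupancy over cycles 1..H; with
#' `include_initial_lesions = TRUE` the prevalent cycle-0 mass is added.
#'
#' @param trace a `cohort_trace`.
#' @param costs per-person cycle costs by state, as from [state_costs()].
#' @param utilities per-state utilities, as from [state_utilities()].
#' @param settings the model settings list.
#' @return list with per-person `cost`, `qalys` and `lesions`.
#' @export
accrue <- function(trace, costs, utilities, settings) {
  h <- nrow(trace) - 1L
  cyc <- 2:(h + 1L)                      # rows for cycles 1..H
  dc <- (1 + settings$discount_cost)^-(0:(h - 1L))
  dq <- (1 + settings$discount_qaly)^-(0:(h - 1L))
  cost <- sum(dc * (trace[cyc, , drop = FALSE] %*% costs)) * settings$cycle_length
  qalys <- sum(dq * (trace[cyc, , drop = FALSE] %*% utilities)) * settings$cycle_length
  lesions <- sum(trace[cyc, "active_caries"])
  if (isTRUE(settings$include_initial_lesions)) {
    lesions <- lesions + trace[1, "active_caries"]
  }
  list(cost = cost, qalys = qalys, lesions = lesions)
}

#' @export
print.cohort_trace <- function(x, digits = 4, ...) {
  arm <- attr(x, "arm")
  cat("Cohort trace", if (!is.null(arm)) paste0(" (", arm, ")"), ": ",
      nrow(x) - 1L, " cycles\n", sep = "")
  print(round(unclass(x), digits))
  invisible(x)
}

#' Export a trace as a long-format data frame
#'
#' @param x a `cohort_trace`.
#' @param ... unused.
#' @return data frame with columns cycle, arm, state, occupancy.
#' @export
as.data.frame.cohort_trace <- function(x, ...) {
  arm <- attr(x, "arm") %||% NA_character_
  data.frame(
    cycle = rep(0:(nrow(x) - 1L), times = ncol(x)),
    arm = arm,
    state = rep(colnames(x), each = nrow(x)),
    occupancy = as.vector(unclass(x)),
    stringsAsFactors = FALSE
  )
}
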