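# Cost-utility evaluation: per-arm accruals, increments, ICER, NMB.

#' Evaluate one arm of the model
#'
#' Composes the engine: transition matrix → cohort trace → state payoffs →
#' discounted accrual, then scales per-person results by the cohort size.
#'
#' @param params a validated `caries_params` object.
#' @param arm `"intervention"` or `"comparison"`.
#' @return a `caries_arm` list: `arm`, `trace`, `tmat`, per-person `cost`,
#'   `qalys`, `lesions`, and cohort-scaled `total_cost`, `total_qalys`,
#'   `total_lesions`.
#' @export
evaluate_arm <- function(params, arm) {
  arm <- match.arg(arm, .ARMS)
  s <- params$settings
  tmat <- transition_matrix(params, arm)
  trace <- run_cohort(tmat, initial_state(params, arm), s$horizon, arm = arm)
  acc <- accrue(trace, state_costs(params, arm), state_utilities(params), s)
  n <- s$cohort_size
  structure(list(
    arm = arm, tmat = tmat, trace = trace,
    cost = acc$cost, qalys = acc$qalys, lesions = acc$lesions,
    total_cost = acc$cost * n, total_qalys = acc$qalys * n,
    total_lesions = acc$lesions * n
  ), class = "caries_arm")
}

#' Incremental comparison of two evaluated arms
#'
#' Increments are intervention minus comparison; prevented caries is
#' comparison lesions minus intervention lesions. The ICER is computed from
#' unrounded increments; when the QALY increment is zero it is flagged
#' undefined (`NA` with `icer_defined = FALSE`); when the intervention
#' dominates (cheaper and more effective) or is dominated, the corresponding
#' flag is set. Net monetary benefit is reported per person:
#' `wtp × qalys - cost`.
#'
#' @param intervention,comparison `caries_arm` objects from [evaluate_arm()].
#' @param wtp willingness-to-pay per QALY.
#' @return a list of increments, `icer`, dominance flags, and per-person
#'   `nmb_intervention` / `nmb_comparison`.
#' @export
incremental <- function(intervention, comparison, wtp) {
  d_cost <- intervention$total_cost - comparison$total_cost
  d_qalys <- intervention$total_qalys - comparison$total_qalys
  prevented <- comparison$total_lesions - intervention$total_lesions
  icer_defined <- d_qalys != 0
  icer <- if (icer_defined) d_cost / d_qalys else NA_real_
  list(
    d_cost = d_cost, d_qalys = d_qalys, prevented_caries = prevented,
    icer = icer, icer_defined = icer_defined,
    dominant = d_qalys > 0 && d_cost < 0,
    dominated = d_qalys < 0 && d_cost > 0,
    wtp = wtp,
    nmb_intervention = wtp * intervention$qalys - intervention$cost,
    nmb_comparison = wtp * comparison$qalys - comparison$cost
  )
}

#' Cost-utility analysis of the preventive intervention vs usual care
#'
#' The package's central evaluator. Runs the three-state Markov cohort model
#' for both arms over the configured horizon and returns per-arm discounted
#' costs, QALYs and caries-lesion counts together with the incremental
#' results (ICER, net monetary benefit, prevented caries).
#'
#' @param params a `caries_params` object, default [caries_parameters()].
#' @param wtp willingness-to-pay per QALY; defaults to the configured setting.
#' @return an object of class `caries_cua` with elements `params`,
#'   `intervention`, `comparison` (see [evaluate_arm()]) and `incremental`
#'   (see [incremental()]). Methods: `print`, `summary`, `plot`,
#'   `as.data.frame`, `simulate` (probabilistic sensitivity analysis).
#' @examples
#' fit <- cua(caries_parameters())
#' fit
#' as.data.frame(fit)
#' @export
cua <- function(params = caries_parameters(), wtp = NULL) {
  validate_parameters(params)
  wtp <- wtp %||% params$settings$wtp
  iv <- evaluate_arm(params, "intervention")
  cp <- evaluate_arm(params, "comparison")
  structure(list(
    params = params,
    intervention = iv, comparison = cp,
    incremental = incremental(iv, cp, wtp)
  ), class = "caries_cua")
}

.fmt_money <- function(x) formatC(round(x), format = "d", big.mark = ",")

#' @export
print.caries_cua <- function(x, ...) {
  inc <- x$incremental
  n <- x$params$settings$cohort_size
  cat("Markov cohort cost-utility analysis (cohort of ", n, ", ",
      x$params$settings$horizon, "-year horizon)\n\n", sep = "")
  tab <- as.data.frame(x)
  tab$cost <- .fmt_money(tab$cost)
  tab$qalys <- round(tab$qalys)
  tab$lesions <- round(tab$lesions)
  print(tab, row.names = FALSE)
  cat("\nIncremental cost:  $", .fmt_money(inc$d_cost), "\n", sep = "")
  cat("Incremental QALYs: ", round(inc$d_qalys, 1), "\n", sep = "")
  cat("Prevented caries:  ", round(inc$prevented_caries), "\n", sep = "")
  if (inc$dominant) {
    cat("ICER: intervention dominates (cheaper and more effective)\n")
  } else if (inc$dominated) {
    cat("ICER: intervention dominated\n")
  } else if (!inc$icer_defined) {
    cat("ICER: undefined (zero QALY increment)\n")
  } else {
    cat("ICER: $", .fmt_money(inc$icer), " per QALY gained\n", sep = "")
  }
  cat("NMB per person at $", .fmt_money(inc$wtp), "/QALY: intervention $",
      .fmt_money(inc$nmb_intervention), ", comparison $",
      .fmt_money(inc$nmb_comparison), "\n", sep = "")
  invisible(x)
}

#' @export
summary.caries_cua <- function(object, ...) {
  structure(list(fit = object), class = "summary.caries_cua")
}

#' @export
print.summary.caries_cua <- function(x, ...) {
  fit <- x$fit
  print(fit)
  for (arm in .ARMS) {
    a <- fit[[arm]]
    cat("\nTransition matrix (", arm, "):\n", sep = "")
    print(round(a$tmat, 4))
    h <- nrow(a$trace)
    cat("End-of-horizon occupancy: ",
        paste(sprintf("%s %.1f%%", colnames(a$trace), 100 * a$trace[h, ]),
              collapse = ", "), "\n", sep = "")
  }
  invisible(x)
}

#' Results table in the per-cohort reporting shape
#'
#' One row per arm with cohort-scaled cost, QALYs and lesion counts, plus the
#' increments and the ICER on the intervention row.
#'
#' @param x a `caries_cua` object.
#' @param ... unused.
#' @export
as.data.frame.caries_cua <- function(x, ...) {
  inc <- x$incremental
  data.frame(
    arm = c("comparison", "intervention"),
    cost = c(x$comparison$total_cost, x$intervention$total_cost),
    qalys = c(x$comparison$total_qalys, x$intervention$total_qalys),
    lesions = c(x$comparison$total_lesions, x$intervention$total_lesions),
    d_cost = c(NA, inc$d_cost),
    d_qalys = c(NA, inc$d_qalys),
    prevented_caries = c(NA, inc$prevented_caries),
    icer = c(NA, inc$icer),
    stringsAsFactors = FALSE
  )
}

#' Plot cohort traces of a fitted analysis
#'
#' State-occupancy fractions by cycle, one panel per arm.
#'
#' @param x a `caries_cua` object.
#' @param ... passed to `matplot`.
#' @export
plot.caries_cua <- function(x, ...) {
  op <- graphics::par(mfrow = c(1, 2), mar = c(4, 4, 2, 1))
  on.exit(graphics::par(op))
  for (arm in .ARMS) {
    tr <- x[[arm]]$trace
    graphics::matplot(0:(nrow(tr) - 1L), unclass(tr), type = "l", lty = 1,
                      lwd = 2, col = c("forestgreen", "firebrick", "grey40"),
                      xlab = "cycle (years)", ylab = "occupancy", ylim = c(0, 1),
                      main = arm, ...)
    graphics::legend("topright", legend = colnames(tr), lty = 1, lwd = 2,
                     col = c("forestgreen", "firebrick", "grey40"), bty = "n",
                     cex = 0.8)
  }
  invisible(x)
}
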