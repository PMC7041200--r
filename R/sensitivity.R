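# One-way deterministic sensitivity analysis, tornado ordering, scenarios,
# and the two-way null/extreme validation grid.

.bounded_rows <- function(params) {
  p <- params$params
  p[is.finite(p$low) & is.finite(p$high) & (p$high > p$low), c("name", "arm")]
}

#' One-way deterministic sensitivity analysis
#'
#' Re-runs the full cost-utility analysis with each selected parameter set to
#' its low and then its high bound, all other inputs at base. Substitution is
#' arm-specific: varying e.g. the intervention arm's seek-treatment
#' probability leaves the comparison arm untouched. Two-year-scale
#' probabilities are re-converted to annual after substitution.
#'
#' @param params a `caries_params` object.
#' @param param_names optional character vector of parameter names to vary
#'   (matched against both arm-specific and shared rows); default: every
#'   parameter with finite low/high bounds. Named parameters without bounds
#'   are skipped with a warning.
#' @return a `caries_dsa` data frame with one row per parameter × direction:
#'   parameter, arm, direction, value, cohort-scaled `d_cost`, `d_qalys`,
#'   `prevented_caries`, and `icer`. The base-case ICER is attached as
#'   `attr(x, "base_icer")`.
#' @export
dsa_one_way <- function(params, param_names = NULL) {
  validate_parameters(params)
  sel <- .bounded_rows(params)
  if (!is.null(param_names)) {
    missing_bounds <- setdiff(param_names, sel$name)
    if (length(missing_bounds)) {
      warning("skipping parameter(s) without low/high bounds: ",
              paste(missing_bounds, collapse = ", "))
    }
    sel <- sel[sel$name %in% param_names, , drop = FALSE]
  }
  base <- cua(params)
  rows <- vector("list", 2L * nrow(sel))
  k <- 0L
  for (i in seq_len(nrow(sel))) {
    nm <- sel$name[i]; arm <- sel$arm[i]
    prow <- params$params[params$params$name == nm & params$params$arm == arm, ]
    for (direction in c("low", "high")) {
      value <- prow[[direction]]
      arm_arg <- if (arm == "shared") NULL else arm
      fit <- cua(set_param(params, nm, value, arm = arm_arg))
      inc <- fit$incremental
      k <- k + 1L
      rows[[k]] <- data.frame(
        parameter = nm, arm = arm, direction = direction, value = value,
        d_cost = inc$d_cost, d_qalys = inc$d_qalys,
        prevented_caries = inc$prevented_caries, icer = inc$icer,
        stringsAsFactors = FALSE
      )
    }
  }
  out <- do.call(rbind, rows)
  structure(out, class = c("caries_dsa", "data.frame"),
            base_icer = base$incremental$icer)
}

#' Tornado ordering of one-way sensitivity results
#'
#' Pairs each parameter's low/high runs and sorts descending by the absolute
#' ICER range `|ICER_high - ICER_low|`; ties are broken alphabetically by
#' parameter label so the ordering is deterministic.
#'
#' @param dsa a `caries_dsa` object from [dsa_one_way()].
#' @param base_icer base-case ICER for the pivot line; defaults to the value
#'   attached to `dsa`.
#' @return a `caries_tornado` data frame with columns parameter, arm,
#'   icer_low, icer_high, range, ordered by decreasing range.
#' @export
tornado <- function(dsa, base_icer = attr(dsa, "base_icer")) {
  key <- paste(dsa$parameter, dsa$arm, sep = ":")
  out <- do.call(rbind, lapply(unique(key), function(k) {
    d <- dsa[key == k, ]
    lo <- d$icer[d$direction == "low"]
    hi <- d$icer[d$direction == "high"]
    data.frame(parameter = d$parameter[1], arm = d$arm[1],
               icer_low = lo, icer_high = hi, range = abs(hi - lo),
               stringsAsFactors = FALSE)
  }))
  lab <- paste(out$parameter, out$arm)
  out <- out[order(-out$range, lab), ]
  rownames(out) <- NULL
  structure(out, class = c("caries_tornado", "data.frame"),
            base_icer = base_icer)
}

#' @export
plot.caries_tornado <- function(x, ...) {
  d <- x[rev(seq_len(nrow(x))), ]
  lab <- ifelse(d$arm == "shared", d$parameter, paste0(d$parameter, " (", d$arm, ")"))
  op <- graphics::par(mar = c(4, 12, 2, 1))
  on.exit(graphics::par(op))
  base <- attr(x, "base_icer")
  xlim <- range(c(d$icer_low, d$icer_high, base))
  graphics::plot(NA, xlim = xlim, ylim = c(0.5, nrow(d) + 0.5), yaxt = "n",
                 xlab = "ICER ($/QALY)", ylab = "", ...)
  graphics::axis(2, at = seq_len(nrow(d)), labels = lab, las = 1, cex.axis = 0.7)
  graphics::segments(d$icer_low, seq_len(nrow(d)), d$icer_high, lwd = 8,
                     col = "steelblue", lend = 1)
  graphics::abline(v = base, lty = 2)
  invisible(x)
}

#' Scenario analysis
#'
#' Applies a set of parameter overrides, then runs the full cost-utility
#' analysis. An empty override set reproduces the base case exactly.
#'
#' @param params a `caries_params` object.
#' @param overrides a data frame with columns `name`, `arm` (`NA` or
#'   `"shared"` for shared parameters) and `value`, or a list of
#'   `list(name =, arm =, value =)` records, or `NULL`/empty for the base
#'   case. Unknown parameter names are an error.
#' @param label optional scenario name stored on the result.
#' @return a `caries_cua` object with the scenario label attached.
#' @export
scenario <- function(params, overrides = NULL, label = NULL) {
  if (is.data.frame(overrides)) {
    overrides <- lapply(seq_len(nrow(overrides)), function(i) as.list(overrides[i, ]))
  }
  for (ov in overrides) {
    if (is.null(ov$name) || is.null(ov$value)) {
      stop("each override needs 'name' and 'value'")
    }
    arm <- ov$arm
    if (is.null(arm) || is.na(arm) || identical(arm, "shared")) arm <- NULL
    params <- set_param(params, ov$name, ov$value, arm = arm)
  }
  fit <- cua(params)
  attr(fit, "scenario") <- label
  fit
}

#' Two-way validation grid
#'
#' Crosses two parameters over supplied value grids, re-running the full
#' analysis in every cell — used to check the model against null and extreme
#' inputs (for instance, setting the caries utility equal to full health must
#' yield a zero QALY increment). Values outside a parameter's admissible
#' range are an error.
#'
#' @param params a `caries_params` object.
#' @param name1,name2 parameter names.
#' @param arm1,arm2 arm of each parameter (`NULL` for shared).
#' @param values1,values2 numeric grids.
#' @return data frame with one row per grid cell: the two values, `d_cost`,
#'   `d_qalys`, `icer`, and a `zero_qaly_gain` flag marking cells where the
#'   QALY increment vanishes (ICER undefined there).
#' @export
two_way_grid <- function(params, name1, values1, name2, values2,
                         arm1 = NULL, arm2 = NULL) {
  grid <- expand.grid(value1 = values1, value2 = values2,
                      KEEP.OUT.ATTRS = FALSE)
  res <- lapply(seq_len(nrow(grid)), function(i) {
    p <- set_param(params, name1, grid$value1[i], arm = arm1)
    p <- set_param(p, name2, grid$value2[i], arm = arm2)
    inc <- cua(p)$incremental
    data.frame(value1 = grid$value1[i], value2 = grid$value2[i],
               d_cost = inc$d_cost, d_qalys = inc$d_qalys, icer = inc$icer,
               zero_qaly_gain = abs(inc$d_qalys) < 1e-9)
  })
  out <- do.call(rbind, res)
  names(out)[1:2] <- c(paste0(name1, if (!is.null(arm1)) paste0(".", arm1)),
                       paste0(name2, if (!is.null(arm2)) paste0(".", arm2)))
  out
}
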