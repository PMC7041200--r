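# Probabilistic sensitivity analysis: distribution fitting from interval
# bounds, joint sampling, per-draw re-evaluation, cost-effectiveness plane
# and acceptability curve.

#' Fit a sampling distribution from base/low/high values
#'
#' Beta and gamma distributions are matched by the method of moments to
#' mean = base and SD = (high - low) / 3.92, i.e. the bounds are read as a
#' 95\% interval. Triangular distributions take (min, mode, max) =
#' (low, base, high). Parameters without bounds, tagged `fixed`, or whose
#' implied SD is zero collapse to a degenerate (point-mass) spec.
#'
#' @param row one row of a parameter table (data frame or list with fields
#'   name, arm, base, low, high, dist).
#' @return a `dist_spec` list: `name`, `arm`, `family`, and family
#'   parameters (`shape1`/`shape2`, `shape`/`rate`, `min`/`mode`/`max`, or
#'   `value`).
#' @export
dist_from_bounds <- function(row) {
  row <- as.list(row)
  fam <- row$dist %||% "fixed"
  has_bounds <- is.finite(row$low) && is.finite(row$high)
  if (has_bounds && row$high <= row$low) {
    stop("parameter '", row$name, "': high bound must exceed low bound")
  }
  spec <- list(name = row$name, arm = row$arm %||% "shared")
  if (fam == "fixed" || !has_bounds) {
    return(structure(c(spec, list(family = "fixed", value = row$base)),
                     class = "dist_spec"))
  }
  s <- (row$high - row$low) / 3.92
  m <- row$base
  if (s <= 0) {
    return(structure(c(spec, list(family = "fixed", value = m)), class = "dist_spec"))
  }
  out <- switch(fam,
    beta = {
      nu <- m * (1 - m) / s^2 - 1
      if (nu <= 0) stop("parameter '", row$name, "': implied beta variance too large")
      list(family = "beta", shape1 = m * nu, shape2 = (1 - m) * nu)
    },
    gamma = list(family = "gamma", shape = (m / s)^2, rate = m / s^2),
    triangular = list(family = "triangular", min = row$low, mode = m, max = row$high)
  )
  structure(c(spec, out), class = "dist_spec")
}

#' Triangular random deviates
#'
#' Inverse-CDF sampling from a triangular distribution.
#'
#' @param n number of draws.
#' @param min,mode,max distribution support and mode, `min <= mode <= max`.
#' @export
rtriangular <- function(n, min, mode, max) {
  stopifnot(min <= mode, mode <= max, max > min)
  u <- stats::runif(n)
  f <- (mode - min) / (max - min)
  ifelse(u < f,
         min + sqrt(u * (max - min) * (mode - min)),
         max - sqrt((1 - u) * (max - min) * (max - mode)))
}

.sample_spec <- function(spec, n) {
  switch(spec$family,
    fixed = rep(spec$value, n),
    beta = stats::rbeta(n, spec$shape1, spec$shape2),
    gamma = stats::rgamma(n, spec$shape, spec$rate),
    triangular = rtriangular(n, spec$min, spec$mode, spec$max)
  )
}

#' Distribution specs for all PSA parameters
#'
#' Returns the fitted spec for every parameter whose `dist` tag names a
#' distribution (beta, gamma or triangular); parameters tagged `fixed` are
#' held at base in the PSA.
#'
#' @param params a `caries_params` object.
#' @return named list of `dist_spec` objects (names `parameter.arm`).
#' @export
fit_psa_dists <- function(params) {
  p <- params$params
  idx <- which(p$dist != "fixed")
  specs <- lapply(idx, function(i) dist_from_bounds(p[i, ]))
  names(specs) <- paste(p$name[idx], p$arm[idx], sep = ".")
  specs
}

# flat named-value lookup used by the fast per-draw evaluator
.flat_values <- function(params) {
  p <- params$params
  stats::setNames(p$base, paste(p$name, p$arm, sep = "."))
}

.fv <- function(vals, name, arm) {
  k <- paste(name, arm, sep = ".")
  if (!is.na(vals[k])) return(unname(vals[k]))
  unname(vals[paste(name, "shared", sep = ".")])
}

# evaluate both arms from a flat value vector; returns increments + per-arm
# accruals. Mirrors evaluate_arm()/accrue() without per-call validation so the
# PSA loop stays fast; equivalence is covered by tests.
.eval_flat <- function(vals, s, dc, dq) {
  h <- s$horizon
  out <- lapply(.ARMS, function(arm) {
    p2 <- .fv(vals, "p_new_caries_2y", arm)
    if (p2 < 0 || p2 > 1) return(NULL)
    pc <- prob_interval_to_annual(p2, 2, method = s$rate_conversion)
    p_seek <- .fv(vals, "p_seek_treatment", arm)
    p_mix <- .fv(vals, "p_restoration", arm) + .fv(vals, "p_extraction", arm) +
      .fv(vals, "p_pulp_therapy", arm)
    p_ret <- switch(s$treated_return, seek_mix = p_seek * p_mix,
                    seek = p_seek, mix = p_mix)
    p0 <- .fv(vals, "p_caries", arm)
    if (any(c(pc, p_seek, p_ret, p0) < 0) || any(c(pc, p_seek, p_ret, p0) > 1)) {
      return(NULL)
    }
    m <- matrix(c(1 - pc, pc, 0, p_ret, 0, 1 - p_ret, 0, pc, 1 - pc),
                3, 3, byrow = TRUE)
    tr <- matrix(0, h + 1L, 3); tr[1, ] <- c(1 - p0, p0, 0)
    for (t in seq_len(h)) tr[t + 1L, ] <- tr[t, ] %*% m
    healthy_cost <- if (arm == "intervention") {
      .fv(vals, "cost_examination", arm) + .fv(vals, "cost_radiography", arm) +
        s$fraction_sealant * .fv(vals, "cost_fissure_sealant", arm) +
        .fv(vals, "cost_varnish", arm)
    } else 0
    treat <- .fv(vals, "p_restoration", arm) * .fv(vals, "cost_restoration", arm) +
      .fv(vals, "p_extraction", arm) * .fv(vals, "cost_extraction", arm) +
      .fv(vals, "p_pulp_therapy", arm) * .fv(vals, "cost_pulp_therapy", arm)
    active_cost <- p_seek * (
      .fv(vals, "cost_examination", arm) + .fv(vals, "cost_radiography", arm) +
        s$fraction_plaque_calculus * (.fv(vals, "cost_plaque_removal", arm) +
                                      .fv(vals, "cost_calculus_removal", arm)) +
        s$fraction_ohi_diet * (.fv(vals, "cost_oral_hygiene", arm) +
                               .fv(vals, "cost_dietary_advice", arm)) + treat)
    uc <- .fv(vals, "utility_caries", arm)
    u <- c(.fv(vals, "utility_healthy", arm), uc, uc)
    cyc <- 2:(h + 1L)
    list(cost = sum(dc * (tr[cyc, ] %*% c(healthy_cost, active_cost, 0))),
         qalys = sum(dq * (tr[cyc, ] %*% u)))
  })
  if (is.null(out[[1]]) || is.null(out[[2]])) return(NULL)
  names(out) <- .ARMS
  c(d_cost = out$intervention$cost - out$comparison$cost,
    d_qalys = out$intervention$qalys - out$comparison$qalys)
}

#' Run the probabilistic sensitivity analysis
#'
#' Samples all distribution-tagged parameters independently from their fitted
#' distributions, re-converts sampled two-year probabilities to the annual
#' scale per draw, re-runs both arms of the cohort model, and records the
#' per-person cost and QALY increments. Draws that would imply a probability
#' outside \[0, 1\] are rejected and resampled (count reported in the
#' result; cannot occur with the shipped configuration).
#'
#' @param params a `caries_params` object.
#' @param n_draws number of parameter draws (>= 1); the study design uses
#'   10,000.
#' @param seed integer seed; required for reproducibility.
#' @return a `caries_psa` object: `draws` (data frame with `draw`, `d_cost`,
#'   `d_qalys`, `icer` — per-person increments), `n_draws`, `seed`, `wtp`,
#'   `specs`, `n_resampled`, and the deterministic `base` fit.
#' @examples
#' psa <- run_psa(caries_parameters(), n_draws = 200, seed = 1)
#' summary(psa)
#' @export
run_psa <- function(params, n_draws = 10000, seed = 20180101) {
  validate_parameters(params)
  stopifnot(n_draws >= 1)
  specs <- fit_psa_dists(params)
  s <- params$settings
  set.seed(seed)
  samples <- lapply(specs, .sample_spec, n = n_draws)
  dc <- (1 + s$discount_cost)^-(0:(s$horizon - 1L))
  dq <- (1 + s$discount_qaly)^-(0:(s$horizon - 1L))
  base_vals <- .flat_values(params)
  d_cost <- d_qalys <- numeric(n_draws)
  n_resampled <- 0L
  for (i in seq_len(n_draws)) {
    vals <- base_vals
    for (k in names(specs)) vals[k] <- samples[[k]][i]
    res <- .eval_flat(vals, s, dc, dq)
    while (is.null(res)) {
      n_resampled <- n_resampled + 1L
      for (k in names(specs)) vals[k] <- .sample_spec(specs[[k]], 1L)
      res <- .eval_flat(vals, s, dc, dq)
    }
    d_cost[i] <- res["d_cost"]; d_qalys[i] <- res["d_qalys"]
  }
  draws <- data.frame(draw = seq_len(n_draws), d_cost = d_cost, d_qalys = d_qalys,
                      icer = ifelse(d_qalys != 0, d_cost / d_qalys, NA_real_))
  structure(list(draws = draws, n_draws = n_draws, seed = seed, wtp = s$wtp,
                 specs = specs, n_resampled = n_resampled,
                 cohort_size = s$cohort_size, base = cua(params)),
            class = "caries_psa")
}

#' Probabilistic sensitivity analysis of a fitted model
#'
#' `simulate()` method wrapping [run_psa()] on the fit's own parameters.
#'
#' @param object a `caries_cua` object.
#' @param nsim number of draws.
#' @param seed integer seed.
#' @param ... unused.
#' @export
simulate.caries_cua <- function(object, nsim = 10000, seed = 20180101, ...) {
  run_psa(object$params, n_draws = nsim, seed = seed)
}

#' Cost-effectiveness plane summary
#'
#' @param object a `caries_psa` object.
#' @param wtp willingness-to-pay per QALY (default: the configured setting).
#' @param ... unused.
#' @return list with `fraction_cost_effective` (share of draws with positive
#'   incremental net monetary benefit at `wtp`), `mean_d_cost`,
#'   `mean_d_qalys` (per person), and `quadrants` (draw counts by plane
#'   quadrant: NE more costly/more effective, SE cost-saving/more effective,
#'   NW dominated, SW cost-saving/less effective).
#' @export
summary.caries_psa <- function(object, wtp = object$wtp, ...) {
  d <- object$draws
  nmb <- wtp * d$d_qalys - d$d_cost
  quad <- c(
    NE = sum(d$d_qalys >= 0 & d$d_cost >= 0),
    SE = sum(d$d_qalys >= 0 & d$d_cost < 0),
    NW = sum(d$d_qalys < 0 & d$d_cost >= 0),
    SW = sum(d$d_qalys < 0 & d$d_cost < 0)
  )
  out <- list(
    n_draws = object$n_draws, seed = object$seed, wtp = wtp,
    fraction_cost_effective = mean(nmb > 0),
    mean_d_cost = mean(d$d_cost), mean_d_qalys = mean(d$d_qalys),
    quadrants = quad, n_resampled = object$n_resampled
  )
  class(out) <- "summary.caries_psa"
  out
}

#' @export
print.summary.caries_psa <- function(x, ...) {
  cat("PSA: ", x$n_draws, " draws (seed ", x$seed, ")\n", sep = "")
  cat(sprintf("Cost-effective at $%s/QALY: %.1f%% of draws\n",
              .fmt_money(x$wtp), 100 * x$fraction_cost_effective))
  cat(sprintf("Mean increments per person: cost $%.2f, QALYs %.4f\n",
              x$mean_d_cost, x$mean_d_qalys))
  cat("Plane quadrants: ", paste(names(x$quadrants), x$quadrants, collapse = ", "),
      "\n", sep = "")
  invisible(x)
}

#' @export
print.caries_psa <- function(x, ...) {
  print(summary(x))
  invisible(x)
}

#' Cost-effectiveness acceptability curve
#'
#' Probability that the intervention is cost-effective (positive incremental
#' net monetary benefit) as a function of the willingness-to-pay threshold.
#'
#' @param psa a `caries_psa` object.
#' @param wtp_grid thresholds to evaluate.
#' @return data frame with columns `wtp`, `probability_cost_effective`.
#' @export
ceac <- function(psa, wtp_grid = seq(0, 100000, by = 10000)) {
  d <- psa$draws
  data.frame(
    wtp = wtp_grid,
    probability_cost_effective =
      vapply(wtp_grid, function(w) mean(w * d$d_qalys - d$d_cost > 0), numeric(1))
  )
}

#' Plot the cost-effectiveness plane
#'
#' Scatter of per-person (ΔQALY, Δcost) draws with the willingness-to-pay
#' line through the origin.
#'
#' @param x a `caries_psa` object.
#' @param wtp threshold for the reference line.
#' @param ... passed to `plot`.
#' @export
plot.caries_psa <- function(x, wtp = x$wtp, ...) {
  d <- x$draws
  graphics::plot(d$d_qalys, d$d_cost, pch = 16, cex = 0.3,
                 col = grDevices::adjustcolor("steelblue", 0.4),
                 xlab = "incremental QALYs per person",
                 ylab = "incremental cost per person ($)", ...)
  graphics::abline(h = 0, v = 0, col = "grey70")
  graphics::abline(a = 0, b = wtp, lty = 2)
  invisible(x)
}
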