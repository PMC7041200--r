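.ARMS <- c("intervention", "comparison")
.PARAM_COLS <- c("name", "arm", "base", "low", "high", "dist", "scale", "source")
.DISTS <- c("beta", "gamma", "triangular", "fixed")
.SCALES <- c("probability", "currency", "utility")

# parameters that must exist once per arm / once shared for the model to build
.REQUIRED_ARM <- c("p_caries", "p_new_caries_2y", "p_seek_treatment")
.REQUIRED_SHARED <- c(
  "p_restoration", "p_extraction", "p_pulp_therapy",
  "cost_examination", "cost_restoration", "cost_extraction",
  "cost_pulp_therapy", "cost_fissure_sealant", "cost_radiography",
  "cost_varnish", "cost_plaque_removal", "cost_calculus_removal",
  "cost_oral_hygiene", "cost_dietary_advice",
  "utility_caries", "utility_healthy"
)

.default_settings <- function() {
  list(
    horizon = 10L,              # cycles (years)
    cycle_length = 1,           # years per cycle
    discount_cost = 0.05,       # per year
    discount_qaly = 0,          # per year (reproduction default; see vignette)
    cohort_size = 500L,
    wtp = 50000,                # AUD per QALY
    fraction_plaque_calculus = 0.50,
    fraction_ohi_diet = 0.25,
    fraction_sealant = 1.0,
    treated_return = "seek_mix",   # "seek_mix" | "seek" | "mix"
    rate_conversion = "rate",      # "rate" | "hazard"
    include_initial_lesions = FALSE
  )
}

.param_row <- function(name, arm, base, low = NA_real_, high = NA_real_,
                       dist = "fixed", scale, source = "") {
  data.frame(name = name, arm = arm, base = base, low = low, high = high,
             dist = dist, scale = scale, source = source,
             stringsAsFactors = FALSE)
}

#' Default model parameter set
#'
#' Builds the shipped parameter configuration: arm-specific caries prevalence,
#' two-year new-caries probabilities and treatment-seeking probabilities, the
#' shared treatment-mix proportions, the public fee-schedule costs (AUD, 2018)
#' and the health-state utility weights, together with the global model
#' settings (10-year horizon, annual cycles, 5\% cost discounting, cohort of
#' 500, willingness-to-pay of $50,000 per QALY).
#'
#' Probabilities of restoration, extraction and pulp therapy carry low/high
#' bounds at +/-15\% of the base value, computed here rather than stored.
#' New-caries probabilities are stored on the observed two-year scale and
#' converted to annual transition probabilities at model-build time (see
#' [prob_interval_to_annual()] and the `rate_conversion` setting).
#'
#' @param ... named settings overriding the defaults, e.g. `cohort_size = 1`,
#'   `discount_qaly = 0.05`, `rate_conversion = "hazard"`.
#' @return An object of class `caries_params`: a list with elements `params`
#'   (a data frame with columns name, arm, base, low, high, dist, scale,
#'   source) and `settings`.
#' @examples
#' p <- caries_parameters()
#' param_value(p, "cost_restoration")
#' param_value(p, "p_caries", "comparison")
#' @export
caries_parameters <- function(...) {
  mix_bounds <- function(b) c(low = b * 0.85, high = b * 1.15)
  sd <- "study data"; qh <- "fee schedule"
  rows <- rbind(
    .param_row("p_caries", "comparison", 0.80, 0.74, 0.85, "beta", "probability", sd),
    .param_row("p_caries", "intervention", 0.71, 0.65, 0.78, "beta", "probability", sd),
    .param_row("p_new_caries_2y", "comparison", 0.637, 0.357, 0.714, "beta", "probability", sd),
    .param_row("p_new_caries_2y", "intervention", 0.479, 0.316, 0.545, "beta", "probability", sd),
    .param_row("p_seek_treatment", "comparison", 0.68, 0.63, 0.73, "triangular", "probability", "national survey"),
    .param_row("p_seek_treatment", "intervention", 0.90, 0.68, 1.00, "triangular", "probability", sd),
    .param_row("p_restoration", "shared", 0.40, 0.34, 0.46, "fixed", "probability", sd),
    .param_row("p_extraction", "shared", 0.06, 0.051, 0.069, "fixed", "probability", sd),
    .param_row("p_pulp_therapy", "shared", 0.04, 0.034, 0.046, "fixed", "probability", sd),
    .param_row("cost_examination", "shared", 53, 48, 78, "fixed", "currency", qh),
    .param_row("cost_restoration", "shared", 145, 117, 229, "gamma", "currency", qh),
    .param_row("cost_extraction", "shared", 195, 84, 442, "fixed", "currency", qh),
    .param_row("cost_pulp_therapy", "shared", 77, 31, 538, "fixed", "currency", qh),
    .param_row("cost_fissure_sealant", "shared", 47, 42, 47, "fixed", "currency", qh),
    .param_row("cost_radiography", "shared", 38, 31, 95, "fixed", "currency", qh),
    .param_row("cost_varnish", "shared", 30, NA, NA, "fixed", "currency", qh),
    .param_row("cost_plaque_removal", "shared", 55, NA, NA, "fixed", "currency", qh),
    .param_row("cost_calculus_removal", "shared", 91, 82, 91, "fixed", "currency", qh),
    .param_row("cost_oral_hygiene", "shared", 50, NA, NA, "fixed", "currency", qh),
    .param_row("cost_dietary_advice", "shared", 37, NA, NA, "fixed", "currency", qh),
    .param_row("utility_caries", "shared", 0.87, 0.80, 0.90, "fixed", "utility", "CHU-9D"),
    .param_row("utility_healthy", "shared", 1.00, 0.95, 1.00, "fixed", "utility", "CHU-9D")
  )
  # treatment-mix bounds are +/-15% of base, recomputed rather than hard-coded
  for (nm in c("p_restoration", "p_extraction", "p_pulp_therapy")) {
    i <- rows$name == nm
    b <- mix_bounds(rows$base[i])
    rows$low[i] <- b["low"]; rows$high[i] <- b["high"]
  }
  settings <- .default_settings()
  dots <- list(...)
  if (length(dots)) {
    bad <- setdiff(names(dots), names(settings))
    if (length(bad)) stop("unknown setting(s): ", paste(bad, collapse = ", "))
    settings[names(dots)] <- dots
  }
  validate_parameters(structure(list(params = rows, settings = settings),
                                class = "caries_params"))
}

#' Validate a parameter set
#'
#' Checks the schema and the invariants: bounds ordered around the base value,
#' probabilities and utilities in \[0, 1\], non-negative costs, admissible
#' distribution and scale tags, all required parameters present for both arms,
#' and settings within range.
#'
#' @param x a `caries_params` object.
#' @return `x`, invisibly, if valid; otherwise an error naming the offending
#'   parameter, value and bound.
#' @export
validate_parameters <- function(x) {
  if (!inherits(x, "caries_params")) stop("not a caries_params object")
  p <- x$params
  if (!all(.PARAM_COLS %in% names(p))) {
    stop("parameter table must have columns ", paste(.PARAM_COLS, collapse = ", "))
  }
  if (anyDuplicated(p[, c("name", "arm")])) {
    stop("duplicated parameter definition: ",
         paste(p$name[duplicated(p[, c("name", "arm")])], collapse = ", "))
  }
  bad_arm <- setdiff(unique(p$arm), c(.ARMS, "shared"))
  if (length(bad_arm)) stop("unknown arm label(s): ", paste(bad_arm, collapse = ", "))
  bad_dist <- setdiff(unique(p$dist), .DISTS)
  if (length(bad_dist)) stop("unknown distribution tag(s): ", paste(bad_dist, collapse = ", "))
  bad_scale <- setdiff(unique(p$scale), .SCALES)
  if (length(bad_scale)) stop("unknown scale tag(s): ", paste(bad_scale, collapse = ", "))
  for (i in seq_len(nrow(p))) {
    r <- p[i, ]
    lab <- if (r$arm == "shared") r$name else paste0(r$name, " [", r$arm, "]")
    if (!is.finite(r$base)) stop("parameter ", lab, ": base value is not finite")
    if (is.finite(r$low) && r$low > r$base) {
      stop("parameter ", lab, ": base ", r$base, " below low bound ", r$low)
    }
    if (is.finite(r$high) && r$high < r$base) {
      stop("parameter ", lab, ": base ", r$base, " above high bound ", r$high)
    }
    vals <- c(r$base, r$low, r$high); vals <- vals[is.finite(vals)]
    if (r$scale %in% c("probability", "utility") && any(vals < 0 | vals > 1)) {
      stop("parameter ", lab, ": ", r$scale, " value outside [0, 1]: ",
           paste(vals[vals < 0 | vals > 1], collapse = ", "))
    }
    if (r$scale == "currency" && any(vals < 0)) {
      stop("parameter ", lab, ": negative cost")
    }
  }
  for (arm in .ARMS) {
    have <- p$name[p$arm %in% c(arm, "shared")]
    miss <- setdiff(c(.REQUIRED_ARM, .REQUIRED_SHARED), have)
    if (length(miss)) {
      stop("missing required parameter(s) for arm '", arm, "': ",
           paste(miss, collapse = ", "))
    }
  }
  s <- x$settings
  miss <- setdiff(names(.default_settings()), names(s))
  if (length(miss)) stop("missing setting(s): ", paste(miss, collapse = ", "))
  if (s$horizon < 1) stop("horizon must be >= 1 cycle")
  if (s$cohort_size < 1) stop("cohort_size must be >= 1")
  for (nm in c("discount_cost", "discount_qaly")) {
    if (s[[nm]] < 0 || s[[nm]] >= 1) stop(nm, " must lie in [0, 1)")
  }
  for (nm in c("fraction_plaque_calculus", "fraction_ohi_diet", "fraction_sealant")) {
    if (s[[nm]] < 0 || s[[nm]] > 1) stop(nm, " must lie in [0, 1]")
  }
  if (!s$treated_return %in% c("seek_mix", "seek", "mix")) {
    stop("treated_return must be one of seek_mix, seek, mix")
  }
  if (!s$rate_conversion %in% c("rate", "hazard")) {
    stop("rate_conversion must be 'rate' or 'hazard'")
  }
  invisible(x)
}

#' Look up a parameter's base value
#'
#' Arm-specific rows take precedence over shared rows.
#'
#' @param x a `caries_params` object.
#' @param name parameter name.
#' @param arm `"intervention"`, `"comparison"`, or `NULL` for shared-only lookup.
#' @return the base value (length-1 numeric).
#' @export
param_value <- function(x, name, arm = NULL) {
  p <- x$params
  if (!is.null(arm)) {
    i <- which(p$name == name & p$arm == arm)
    if (length(i) == 1L) return(p$base[i])
  }
  i <- which(p$name == name & p$arm == "shared")
  if (length(i) == 1L) return(p$base[i])
  stop("unknown parameter: ", name, if (!is.null(arm)) paste0(" [", arm, "]"))
}

#' Override a parameter value
#'
#' Replaces the base value (and optionally the bounds) of an existing
#' parameter; used by scenario and sensitivity analyses. The target row is
#' matched like [param_value()]: an arm-specific row if one exists for `arm`,
#' else the shared row.
#'
#' @inheritParams param_value
#' @param base new base value.
#' @param low,high optional new bounds.
#' @return the modified, revalidated `caries_params` object.
#' @export
set_param <- function(x, name, base, arm = NULL, low = NULL, high = NULL) {
  p <- x$params
  i <- if (!is.null(arm)) which(p$name == name & p$arm == arm) else integer()
  if (!length(i)) i <- which(p$name == name & p$arm == "shared")
  if (length(i) != 1L) {
    stop("unknown parameter: ", name, if (!is.null(arm)) paste0(" [", arm, "]"))
  }
  p$base[i] <- base
  if (!is.null(low)) p$low[i] <- low
  if (!is.null(high)) p$high[i] <- high
  # keep bounds consistent when only the base moves outside them
  if (is.finite(p$low[i]) && p$low[i] > p$base[i]) p$low[i] <- p$base[i]
  if (is.finite(p$high[i]) && p$high[i] < p$base[i]) p$high[i] <- p$base[i]
  x$params <- p
  validate_parameters(x)
}

#' Convert an interval probability to an annual transition probability
#'
#' Two readings of the observed two-year cumulative incidence are supported.
#' `"hazard"` treats the input as a probability over the interval and applies
#' the constant-hazard identity: `r = -log(1 - p) / t`, `p_annual = 1 - exp(-r)`
#' (equivalently `1 - (1 - p)^(1/t)`). `"rate"` treats the printed value as a
#' rate accrued over the interval, `p_annual = 1 - exp(-p / t)` — the
#' convention of decision-tree software rate-to-probability helpers applied
#' directly to the observed proportion, and the package's model-building
#' default (`rate_conversion` setting) because it reproduces the published
#' cohort traces (see the methods vignette).
#'
#' @param p_interval probability (or rate, for `method = "rate"`) observed
#'   over `interval_years`; in \[0, 1).
#' @param interval_years positive interval length in years.
#' @param method `"hazard"` (default) or `"rate"`.
#' @return annual probability in \[0, `p_interval`\]; equals `p_interval`
#'   when `interval_years == 1` under `"hazard"`.
#' @examples
#' prob_interval_to_annual(0.637, 2)            # 0.39752
#' prob_interval_to_annual(0.637, 2, "rate")    # 0.27278
#' @export
prob_interval_to_annual <- function(p_interval, interval_years = 2,
                                    method = c("hazard", "rate")) {
  method <- match.arg(method)
  if (any(interval_years <= 0)) stop("interval_years must be > 0")
  if (any(p_interval < 0)) stop("p_interval must be >= 0")
  if (method == "hazard") {
    if (any(p_interval >= 1)) stop("p_interval = 1 implies an infinite hazard rate")
    1 - (1 - p_interval)^(1 / interval_years)
  } else {
    if (any(p_interval > 1)) stop("p_interval must be <= 1")
    1 - exp(-p_interval / interval_years)
  }
}

#' Wald confidence interval for a proportion
#'
#' Normal-approximation interval `p +/- z * sqrt(p (1 - p) / n)`, truncated to
#' \[0, 1\]. With the study's group sizes this reproduces the published bounds
#' for the baseline caries prevalences.
#'
#' @param p_hat observed proportion in \[0, 1\].
#' @param n denominator (>= 1).
#' @param conf confidence level, default 0.95.
#' @return named numeric `c(low, high)`.
#' @examples
#' prop_ci(0.80, 212)  # c(0.746, 0.854)
#' @export
prop_ci <- function(p_hat, n, conf = 0.95) {
  if (n < 1) stop("n must be >= 1")
  if (p_hat < 0 || p_hat > 1) stop("p_hat must lie in [0, 1]")
  z <- stats::qnorm(1 - (1 - conf) / 2)
  half <- z * sqrt(p_hat * (1 - p_hat) / n)
  c(low = max(0, p_hat - half), high = min(1, p_hat + half))
}
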