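# Synthetic individual-level study data: two arms followed for two years,
# baseline caries status, new-caries incidence, treatment seeking and the
# treatment received. Used to exercise the parameter-estimation stage
# end-to-end; no real participant data are included or required.

#' Ground-truth container for the synthetic cohort generator
#'
#' Defaults emulate the study design: 196 intervention and 212 comparison
#' children, baseline prevalence of established (ICDAS-II 3–6) lesions
#' 0.719/0.792, two-year new-caries incidence 0.479/0.637, treatment-seeking
#' probabilities 0.90/0.68, and a treatment mix of 40\% restorations, 6\%
#' extractions and 4\% pulp therapy among caries-positive children (the
#' remainder untreated).
#'
#' @param n named integer vector, children per arm.
#' @param prevalence named vector, baseline caries prevalence per arm.
#' @param incidence_2y named vector, probability of new caries within the
#'   two-year follow-up per arm (denominator: all followed children).
#' @param seek named vector, probability a caries-positive child seeks
#'   treatment, per arm.
#' @param mix named vector of treatment proportions among caries-positive
#'   children; must sum to <= 1, remainder untreated.
#' @return a `synth_truth` list.
#' @export
synth_truth <- function(n = c(intervention = 196, comparison = 212),
                        prevalence = c(intervention = 0.719, comparison = 0.792),
                        incidence_2y = c(intervention = 0.479, comparison = 0.637),
                        seek = c(intervention = 0.90, comparison = 0.68),
                        mix = c(restoration = 0.40, extraction = 0.06,
                                pulp_therapy = 0.04)) {
  for (v in list(prevalence, incidence_2y, seek)) {
    stopifnot(all(names(.ARMS) %in% names(v) | .ARMS %in% names(v)),
              all(v >= 0 & v <= 1))
  }
  stopifnot(all(n >= 1), all(mix >= 0), sum(mix) <= 1)
  structure(list(n = n, prevalence = prevalence, incidence_2y = incidence_2y,
                 seek = seek, mix = mix), class = "synth_truth")
}

#' Simulate an individual-level two-year follow-up
#'
#' Independent Bernoulli draws per child for baseline caries and new caries
#' within two years; caries-positive children (baseline or new) additionally
#' draw a treatment-seeking indicator and a treatment category from the
#' truth's mix (unconditional on seeking, since the mix is defined over all
#' diagnosed caries). Deterministic given `seed`.
#'
#' @param truth a [synth_truth()] object.
#' @param seed integer seed, or `NULL` to use the current RNG state.
#' @return data frame with columns `child_id`, `arm`, `baseline_caries`,
#'   `new_caries_2y`, `sought_treatment` (`NA` for caries-free children) and
#'   `treatment` (`"none"`, `"restoration"`, `"extraction"`,
#'   `"pulp_therapy"`).
#' @export
simulate_followup <- function(truth, seed = NULL) {
  stopifnot(inherits(truth, "synth_truth"))
  if (!is.null(seed)) set.seed(seed)
  cats <- c(names(truth$mix), "none")
  probs <- c(truth$mix, none = 1 - sum(truth$mix))
  out <- lapply(.ARMS, function(arm) {
    n <- truth$n[[arm]]
    baseline <- stats::rbinom(n, 1, truth$prevalence[[arm]])
    newc <- stats::rbinom(n, 1, truth$incidence_2y[[arm]])
    caries <- baseline == 1 | newc == 1
    sought <- rep(NA_integer_, n)
    sought[caries] <- stats::rbinom(sum(caries), 1, truth$seek[[arm]])
    treatment <- rep("none", n)
    if (any(caries)) {
      treatment[caries] <- sample(cats, sum(caries), replace = TRUE, prob = probs)
    }
    data.frame(child_id = paste0(substr(arm, 1, 1), seq_len(n)), arm = arm,
               baseline_caries = baseline, new_caries_2y = newc,
               sought_treatment = sought, treatment = treatment,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Estimate model inputs from follow-up records
#'
#' Re-derives the parameter table entries the model needs from
#' individual-level data: per-arm baseline prevalence and two-year new-caries
#' incidence with Wald 95\% bounds (see [prop_ci()]), the treatment-seeking
#' proportion among caries-positive children, and the observed treatment-mix
#' proportions (bounds at ±15\% of the estimate, per the reporting
#' convention for those inputs).
#'
#' @param records a data frame as returned by [simulate_followup()].
#' @param conf confidence level for the proportion intervals.
#' @return list with `estimates` (tidy per-arm table) and `fragment`, a
#'   parameter table in the [caries_parameters()] schema that can be merged
#'   into a full configuration with [merge_parameters()].
#' @export
estimate_parameters <- function(records, conf = 0.95) {
  rows <- list(); est <- list()
  for (arm in .ARMS) {
    r <- records[records$arm == arm, ]
    if (!nrow(r)) stop("no records for arm '", arm, "'")
    n <- nrow(r)
    prev <- mean(r$baseline_caries)
    ci_prev <- prop_ci(prev, n, conf)
    inc <- mean(r$new_caries_2y)
    ci_inc <- prop_ci(inc, n, conf)
    caries <- r$baseline_caries == 1 | r$new_caries_2y == 1
    seek <- if (any(caries)) mean(r$sought_treatment[caries]) else NA_real_
    ci_seek <- if (any(caries)) prop_ci(seek, sum(caries), conf) else c(NA, NA)
    est[[arm]] <- data.frame(arm = arm, n = n, prevalence = prev,
                             incidence_2y = inc, seek = seek,
                             stringsAsFactors = FALSE)
    rows[[paste0("prev.", arm)]] <-
      .param_row("p_caries", arm, prev, ci_prev[1], ci_prev[2], "beta",
                 "probability", "synthetic data")
    rows[[paste0("inc.", arm)]] <-
      .param_row("p_new_caries_2y", arm, inc, ci_inc[1], ci_inc[2], "beta",
                 "probability", "synthetic data")
    rows[[paste0("seek.", arm)]] <-
      .param_row("p_seek_treatment", arm, seek, ci_seek[1], ci_seek[2],
                 "triangular", "probability", "synthetic data")
  }
  caries <- records$baseline_caries == 1 | records$new_caries_2y == 1
  for (tx in c("restoration", "extraction", "pulp_therapy")) {
    p <- mean(records$treatment[caries] == tx)
    rows[[tx]] <- .param_row(paste0("p_", tx), "shared", p,
                             p * 0.85, p * 1.15, "fixed", "probability",
                             "synthetic data")
  }
  list(estimates = do.call(rbind, c(est, make.row.names = FALSE)),
       fragment = do.call(rbind, c(rows, make.row.names = FALSE)))
}

#' Merge an estimated parameter fragment into a full configuration
#'
#' Rows of `fragment` replace rows of `base$params` with the same
#' (name, arm); other parameters and all settings are kept.
#'
#' @param base a `caries_params` object.
#' @param fragment a parameter table in the same schema (e.g. from
#'   [estimate_parameters()]).
#' @return the merged, revalidated `caries_params` object.
#' @export
merge_parameters <- function(base, fragment) {
  p <- base$params
  for (i in seq_len(nrow(fragment))) {
    j <- which(p$name == fragment$name[i] & p$arm == fragment$arm[i])
    if (length(j) == 1L) {
      p[j, ] <- fragment[i, ]
    } else {
      p <- rbind(p, fragment[i, ])
    }
  }
  base$params <- p
  validate_parameters(base)
}
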