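base_fit <- cua(base_params)

test_that("one-way DSA substituting a base value for both bounds is a no-op", {
  p <- base_params
  i <- which(p$params$name == "cost_restoration")
  p$params$low[i] <- p$params$high[i] <- NA  # drop real bounds
  p <- set_param(p, "cost_restoration", 145, low = 145 - 1e-9, high = 145 + 1e-9)
  d <- dsa_one_way(p, "cost_restoration")
  expect_equal(nrow(d), 2)
  expect_equal(d$icer, rep(base_fit$incremental$icer, 2), tolerance = 1e-6)
})

test_that("DSA covers every bounded parameter arm-specifically and stays positive", {
  d <- dsa_one_way(base_params)
  # one low and one high row per bounded parameter row
  bounded <- subset(base_params$params, is.finite(low) & is.finite(high) & high > low)
  expect_equal(nrow(d), 2 * nrow(bounded))
  expect_true(all(is.finite(d$icer)))
  expect_true(all(d$icer > 0))
  # arm-specific substitution: the comparison arm's run is untouched when an
  # intervention parameter moves
  row <- d[d$parameter == "p_seek_treatment" & d$arm == "intervention" &
             d$direction == "low", ]
  manual <- cua(set_param(base_params, "p_seek_treatment", 0.68,
                          arm = "intervention"))
  expect_equal(row$icer, manual$incremental$icer, tolerance = 1e-9)
  expect_warning(dsa_one_way(base_params, c("cost_varnish", "cost_restoration")),
                 "without low/high")
})

test_that("ICER is monotone in comparison incidence and caries utility", {
  icer_at <- function(nm, vals, arm = NULL) {
    vapply(vals, function(v) {
      cua(set_param(base_params, nm, v, arm = arm))$incremental$icer
    }, numeric(1))
  }
  dec <- icer_at("p_new_caries_2y", c(0.357, 0.5, 0.637, 0.714), arm = "comparison")
  expect_true(all(diff(dec) < 0))
  inc <- icer_at("utility_caries", c(0.80, 0.87, 0.90))
  expect_true(all(diff(inc) > 0))
})

test_that("tornado orders parameters by ICER range with deterministic ties", {
  d <- dsa_one_way(base_params)
  tor <- tornado(d)
  # a permutation of the DSA parameters
  expect_setequal(paste(tor$parameter, tor$arm),
                  unique(paste(d$parameter, d$arm)))
  expect_true(all(diff(tor$range) <= 1e-12))
  expect_equal(tor$range, abs(tor$icer_high - tor$icer_low))
  # the two published key drivers lead the ordering
  top2 <- paste(tor$parameter[1:2], tor$arm[1:2])
  expect_setequal(top2, c("p_seek_treatment intervention",
                          "p_new_caries_2y comparison"))
  # zero-width ranges tie-break alphabetically
  flat <- d
  flat$icer <- 1000
  tflat <- tornado(flat, base_icer = 1000)
  lab <- paste(tflat$parameter, tflat$arm)
  expect_equal(lab, sort(lab))
})

test_that("scenario analysis applies overrides and an empty scenario is the base case", {
  empty <- scenario(base_params, NULL)
  expect_equal(empty$incremental$icer, base_fit$incremental$icer)
  eq <- scenario(base_params,
                 list(list(name = "p_caries", arm = "intervention", value = 0.80)))
  expect_equal(param_value(eq$params, "p_caries", "intervention"), 0.80)
  expect_gt(eq$incremental$icer, base_fit$incremental$icer)
  expect_error(scenario(base_params,
                        list(list(name = "no_such", value = 1))),
               "unknown parameter")
  # shipped config carries the named scenario definitions
  shipped <- read_parameters(default_config_path())
  defs <- attr(shipped, "scenarios")
  expect_setequal(names(defs), c("equal_initial_caries", "zero_initial_caries"))
})

test_that("two-way validation grid matches direct scenario runs and null values", {
  g <- two_way_grid(base_params,
                    "utility_caries", c(0.80, 0.87, 1.00),
                    "cost_restoration", c(117, 145, 229))
  expect_equal(nrow(g), 9)
  for (i in seq_len(nrow(g))) {
    direct <- scenario(base_params, list(
      list(name = "utility_caries", value = g[i, 1]),
      list(name = "cost_restoration", value = g[i, 2])
    ))
    expect_equal(g$d_qalys[i], direct$incremental$d_qalys, tolerance = 1e-9)
    if (!g$zero_qaly_gain[i]) {
      expect_equal(g$icer[i], direct$incremental$icer, tolerance = 1e-9)
    }
  }
  # null value: caries utility equal to full health removes the QALY gain
  null_cells <- g[g[, 1] == 1.00, ]
  expect_true(all(abs(null_cells$d_qalys) < 1e-9))
  expect_true(all(null_cells$zero_qaly_gain))
  # extreme: equal epidemiology and free prevention — any residual increment
  # must come through the treatment-seeking pathway alone, and vanishes once
  # seeking is equalized as well
  p <- set_param(base_params, "p_new_caries_2y",
                 param_value(base_params, "p_new_caries_2y", "comparison"),
                 arm = "intervention")
  p <- set_param(p, "p_caries", 0.80, arm = "intervention")
  for (nm in c("cost_examination", "cost_radiography", "cost_fissure_sealant",
               "cost_varnish")) {
    p <- set_param(p, nm, 0)
  }
  inc <- cua(p)$incremental
  expect_gt(inc$d_cost, 0)  # more seeking means more treated care
  p2 <- set_param(p, "p_seek_treatment", 0.68, arm = "intervention")
  inc2 <- cua(p2)$incremental
  expect_equal(inc2$d_cost, 0, tolerance = 1e-9)
  expect_equal(inc2$d_qalys, 0, tolerance = 1e-9)
  expect_error(two_way_grid(base_params, "utility_caries", c(0.5, 1.5),
                            "cost_restoration", 145),
               "outside \\[0, 1\\]")
})
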