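test_that("transition matrices are stochastic with the required structural zeros", {
  set.seed(11)
  cases <- c(list(base_params), replicate(25, random_params(), simplify = FALSE))
  for (p in cases) {
    for (arm in c("intervention", "comparison")) {
      m <- transition_matrix(p, arm)
      expect_equal(unname(rowSums(m)), c(1, 1, 1), tolerance = 1e-12)
      expect_true(all(m >= 0 & m <= 1))
      expect_identical(m["healthy", "untreated"], 0)
      expect_identical(m["untreated", "healthy"], 0)
      expect_identical(m["active_caries", "active_caries"], 0)
      # untreated children develop new caries at the same annual probability
      expect_equal(m["untreated", "active_caries"], m["healthy", "active_caries"])
    }
  }
})

test_that("base-case transition probabilities follow the stated conventions", {
  m <- transition_matrix(base_params, "intervention")
  # treated return: seek 0.90 x treatment-mix sum 0.50
  expect_equal(m["active_caries", "healthy"], 0.90 * (0.40 + 0.06 + 0.04))
  expect_equal(m["healthy", "active_caries"],
               prob_interval_to_annual(0.479, 2, "rate"))
  mc <- transition_matrix(base_params, "comparison")
  expect_equal(mc["active_caries", "healthy"], 0.68 * 0.5)
  # hazard conversion selectable
  ph <- caries_parameters(rate_conversion = "hazard")
  mh <- transition_matrix(ph, "intervention")
  expect_equal(mh["healthy", "active_caries"], 1 - (1 - 0.479)^0.5)
  # alternative treated-return conventions
  expect_equal(transition_matrix(caries_parameters(treated_return = "seek"),
                                 "intervention")["active_caries", "healthy"], 0.90)
  expect_equal(transition_matrix(caries_parameters(treated_return = "mix"),
                                 "intervention")["active_caries", "healthy"], 0.50)
})

test_that("initial distributions come from baseline prevalence", {
  expect_equal(unname(initial_state(base_params, "intervention")),
               c(0.29, 0.71, 0))
  expect_equal(unname(initial_state(base_params, "comparison")),
               c(0.20, 0.80, 0))
  p0 <- set_param(base_params, "p_caries", 0, arm = "intervention")
  expect_equal(unname(initial_state(p0, "intervention")), c(1, 0, 0))
})

test_that("cohort traces conserve mass and start at the initial distribution", {
  set.seed(12)
  for (p in c(list(base_params), replicate(10, random_params(), simplify = FALSE))) {
    for (arm in c("intervention", "comparison")) {
      tr <- run_cohort(transition_matrix(p, arm), initial_state(p, arm), 10)
      expect_equal(unname(rowSums(tr)), rep(1, 11), tolerance = 1e-10)
      expect_true(all(tr >= 0 & tr <= 1))
      expect_equal(unname(tr[1, ]), unname(initial_state(p, arm)))
    }
  }
  # identity matrix leaves any initial distribution untouched
  id <- diag(3); dimnames(id) <- list(caries_states(), caries_states())
  tr <- run_cohort(id, c(healthy = 0.2, active_caries = 0.5, untreated = 0.3), 5)
  for (t in 1:6) expect_equal(unname(tr[t, ]), c(0.2, 0.5, 0.3))
})

test_that("state costs assemble the fee-schedule components", {
  expect_equal(unname(state_costs(base_params, "intervention")["healthy"]),
               53 + 38 + 47 + 30)
  expect_equal(unname(state_costs(base_params, "comparison")["healthy"]), 0)
  expect_equal(unname(state_costs(base_params, "comparison")["untreated"]), 0)
  # expected treatment cost inside the active-state cost, before seeking
  treat <- 0.40 * 145 + 0.06 * 195 + 0.04 * 77
  expect_equal(treat, 72.78)
  clinic <- 53 + 38 + 0.5 * (55 + 91) + 0.25 * (50 + 37)
  expect_equal(unname(state_costs(base_params, "intervention")["active_caries"]),
               0.90 * (clinic + treat))
  expect_equal(unname(state_costs(base_params, "comparison")["active_caries"]),
               0.68 * (clinic + treat))
  # sealant fraction scales only the sealant item
  p <- caries_parameters(fraction_sealant = 0.5)
  expect_equal(unname(state_costs(p, "intervention")["healthy"]),
               53 + 38 + 0.5 * 47 + 30)
})

test_that("accrual reproduces closed-form totals on degenerate traces", {
  s <- base_params$settings
  flat <- function(occ) {
    tr <- matrix(rep(occ, 11), nrow = 11, byrow = TRUE,
                 dimnames = list(0:10, caries_states()))
    structure(tr, class = c("cohort_trace", "matrix"))
  }
  u <- state_utilities(base_params)
  # everyone healthy, QALYs undiscounted: 10 full years
  expect_equal(accrue(flat(c(1, 0, 0)), c(0, 0, 0), u, s)$qalys, 10)
  # everyone with caries utility 0.87
  expect_equal(accrue(flat(c(0, 1, 0)), c(0, 0, 0), u, s)$qalys, 8.7)
  # first cycle undiscounted, then geometric: cost 100/cycle in healthy state
  expect_equal(accrue(flat(c(1, 0, 0)), c(100, 0, 0), u, s)$cost,
               100 * sum(1.05^-(0:9)))
  # QALY discounting honoured when configured
  s2 <- caries_parameters(discount_qaly = 0.05)$settings
  expect_equal(accrue(flat(c(1, 0, 0)), c(0, 0, 0), u, s2)$qalys,
               sum(1.05^-(0:9)))
  # lesion counting: active occupancy over cycles 1..10, cycle 0 optional
  expect_equal(accrue(flat(c(0, 1, 0)), c(0, 0, 0), u, s)$lesions, 10)
  s3 <- caries_parameters(include_initial_lesions = TRUE)$settings
  expect_equal(accrue(flat(c(0, 1, 0)), c(0, 0, 0), u, s3)$lesions, 11)
})

test_that("microsimulation oracle reproduces the cohort model accruals", {
  for (arm in c("intervention", "comparison")) {
    cohort <- evaluate_arm(base_params, arm)
    ms <- microsim(base_params, arm, n = 1e5, seed = 99)
    expect_lt(abs(ms$cost - cohort$cost), 3 * ms$cost_se)
    expect_lt(abs(ms$qalys - cohort$qalys), 3 * ms$qalys_se)
  }
})

test_that("identical arm inputs differ only by the prevention cost", {
  p <- base_params
  for (nm in c("p_caries", "p_new_caries_2y", "p_seek_treatment")) {
    p <- set_param(p, nm, param_value(p, nm, "comparison"), arm = "intervention")
  }
  iv <- evaluate_arm(p, "intervention")
  cp <- evaluate_arm(p, "comparison")
  expect_equal(unclass(iv$trace), unclass(cp$trace), ignore_attr = TRUE)
  expect_equal(iv$qalys, cp$qalys)
  expect_equal(iv$lesions, cp$lesions)
  prevention <- state_costs(p, "intervention")["healthy"]
  disc_healthy <- sum(1.05^-(0:9) * iv$trace[2:11, "healthy"])
  expect_equal(iv$cost - cp$cost, unname(prevention * disc_healthy))
})

test_that("accruals respond monotonically to utilities and seeking", {
  q_at <- function(u, arm) {
    evaluate_arm(set_param(base_params, "utility_caries", u), arm)$qalys
  }
  for (arm in c("intervention", "comparison")) {
    qs <- vapply(c(0.80, 0.87, 0.95), q_at, numeric(1), arm = arm)
    expect_true(all(diff(qs) > 0))
  }
  res <- lapply(c(0.68, 0.80, 0.90, 1.0), function(ps) {
    evaluate_arm(set_param(base_params, "p_seek_treatment", ps,
                           arm = "intervention"), "intervention")
  })
  expect_true(all(diff(vapply(res, `[[`, numeric(1), "cost")) >= 0))
  expect_true(all(diff(vapply(res, `[[`, numeric(1), "qalys")) >= 0))
})
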