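test_that("tornado covers every bounded parameter and reproduces base at base bounds", {
  ps <- default_parameters()
  ow <- owsa(ps, "NRLF", "delta_cost")
  n_bounded <- sum(ps$specs$family != "fixed" & !is.na(ps$specs$lo))
  expect_equal(nrow(ow), n_bounded)
  expect_equal(sum(ow$top10), 10)
  expect_true(all(diff(ow$span) <= 1e-9))
  expect_equal(ow$span, abs(ow$outcome_at_high - ow$outcome_at_low))
  # degenerate bounds equal to the base value give zero span and the base outcome
  ps2 <- ps
  i <- match("cost_explant", ps2$specs$name)
  ps2$specs$lo[i] <- ps2$specs$hi[i] <- ps2$values[["cost_explant"]]
  ow2 <- owsa(ps2, "NRLF", "delta_cost")
  row <- ow2[ow2$parameter == "cost_explant", ]
  expect_equal(row$span, 0, tolerance = 1e-9)
  expect_equal(row$outcome_at_low, attr(ow2, "base_outcome"), tolerance = 1e-9)
})

test_that("incremental cost responds linearly to a unit implant price", {
  # cost accrual is linear in the implant price (implantation + replacement
  # weighting), so the tornado endpoints must interpolate exactly
  ps <- default_parameters()
  f <- function(x) {
    outcome_value(set_parameters(ps, c(hf10.cost_implant = x), refit = FALSE),
                  "NRLF", "delta_cost")
  }
  lo <- 13116; hi <- 21421
  mid <- f((lo + hi) / 2)
  expect_equal(mid, (f(lo) + f(hi)) / 2, tolerance = 1e-9)
  # slope equals the implanted fraction times (1 + discounted replacement mass)
  slope <- (f(hi) - f(lo)) / (hi - lo)
  st <- run_decision_tree(ps, "HF10")
  lt <- run_markov(ps, "HF10", st$entering_state)
  repl_mass <- sum(lt$trace$replacements * discount_factor(
    lt$trace$time_years - 0.25, 0.035))
  expect_equal(-slope, 0.928 + repl_mass, tolerance = 1e-6)
})

test_that("threshold search is self-consistent to the pound and reports failures", {
  ps <- default_parameters()
  th <- threshold_search(ps, "hf10.cost_implant", "cost_neutral", "NRLF",
                         bracket = c(13116, 40000))
  expect_true(th$bracketed)
  expect_lte(abs(th$achieved_objective_residual), 1)
  # re-running the model at the threshold value reproduces cost-neutrality
  ps_at <- set_parameters(ps, c(hf10.cost_implant = th$threshold_value), refit = FALSE)
  dc <- evaluate_arm(ps_at, "NRLF")$total_cost - evaluate_arm(ps_at, "HF10")$total_cost
  expect_lte(abs(dc), 1)
  # widening the bracket does not move the threshold materially
  th2 <- threshold_search(ps, "hf10.cost_implant", "cost_neutral", "NRLF",
                          bracket = c(10000, 60000))
  expect_lt(abs(th2$threshold_value - th$threshold_value), 2)
  # utilities cannot change costs: no cost-neutral threshold exists
  th3 <- threshold_search(ps, "u_no_relief", "cost_neutral", "NRLF")
  expect_false(th3$bracketed)
  expect_true(is.na(th3$threshold_value))
  # parameter already at the objective returns an endpoint with residual <= tol
  th4 <- threshold_search(ps_at, "hf10.cost_implant", "cost_neutral", "NRLF",
                          bracket = c(th$threshold_value, 40000))
  expect_lte(abs(th4$achieved_objective_residual), 1)
  expect_equal(th4$threshold_value, th$threshold_value, tolerance = 1e-6)
  expect_error(threshold_search(ps, "no_such_par"), "unknown parameter")
})

test_that("icer-at-wtp threshold uses the net-benefit residual", {
  ps <- default_parameters()
  th <- threshold_search(ps, "hf10.explant_yr3plus", "icer_equals_wtp", "RLF")
  expect_true(th$bracketed)
  expect_lte(abs(th$achieved_objective_residual), 1)
  ps_at <- set_parameters(ps, c(hf10.explant_yr3plus = th$threshold_value), refit = FALSE)
  ref <- evaluate_arm(ps_at, "HF10"); comp <- evaluate_arm(ps_at, "RLF")
  dc <- comp$total_cost - ref$total_cost
  dq <- comp$total_qalys - ref$total_qalys
  expect_lte(abs(dc - 20000 * dq), 1)
})

test_that("scenario runner applies named overrides and rejects unknown names", {
  ps <- default_parameters()
  base <- evaluate_all(ps)
  same <- run_scenario(ps, overrides = NULL)
  expect_equal(same$arms$HF10$total_cost, base$arms$HF10$total_cost)
  expect_equal(same$arms$NRLF$total_qalys, base$arms$NRLF$total_qalys)
  expect_error(run_scenario(ps, "nonexistent"), "equal_explant_3.2")

  eq <- run_scenario(ps, "equal_explant_3.2")
  psx <- set_parameters(ps, scenario_overrides("equal_explant_3.2"), refit = FALSE)
  expect_equal(arm_parameters(psx, "NRLF")$explant_yr1, 0.032)
  expect_equal(eq$arms$HF10$total_cost, evaluate_arm(psx, "HF10")$total_cost)

  hz <- run_scenario(ps, "horizon_10y")
  expect_equal(nrow(hz$arms$HF10$long_term$trace), 38)
  expect_lt(hz$arms$HF10$total_cost, base$arms$HF10$total_cost)

  alt <- run_scenario(ps, "alternative_system_costs")
  psalt <- set_parameters(ps, scenario_overrides("alternative_system_costs"), refit = FALSE)
  expect_equal(arm_parameters(psalt, "RLF")$cost_reimplant, 14201)
  expect_equal(arm_parameters(psalt, "RLF")$cost_implant, 16648)
  expect_lt(alt$arms$RLF$total_cost, base$arms$RLF$total_cost)
})
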