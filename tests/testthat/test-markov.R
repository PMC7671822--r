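test_that("explant schedule maps cycles to the annual rates", {
  ps <- default_parameters()
  hf <- arm_parameters(ps, "HF10")
  lf <- arm_parameters(ps, "NRLF")
  # year 3+ (cycles from month 24): 1 - (1 - 0.032)^0.25
  expect_equal(explant_prob_cycle(hf, 10), 0.008098, tolerance = 1e-4)
  # LF year 2 (months 12-24): 1 - (1 - 0.097)^0.25
  expect_equal(explant_prob_cycle(lf, 3), 0.025186, tolerance = 1e-4)
  expect_equal(explant_prob_cycle(lf, 6), explant_prob_cycle(lf, 3))
  # cycles 1-2 draw the residual year-1 rate
  expect_equal(explant_prob_cycle(hf, 1), annual_to_cycle_prob(0.044, 0.25))
  lf0 <- lf; lf0$explant_yr2 <- 0
  expect_equal(explant_prob_cycle(lf0, 4), 0)
  expect_error(explant_prob_cycle(hf, 0), ">= 1")
})

test_that("replacement schedule puts procedures at longevity multiples inside the horizon", {
  # cycle k starts at 0.5 + (k-1)/4 years, so year y maps to cycle 4y - 1
  expect_equal(replacement_cycles(4, 15), c(15L, 31L, 47L))
  expect_equal(replacement_cycles(10, 15), 39L)
  expect_equal(replacement_cycles(20, 15), integer(0))
  # longevity rounds to the nearest whole cycle
  expect_equal(replacement_cycles(3.9, 15), replacement_cycles(4, 15))
  expect_equal(replacement_cycles(15, 15), integer(0))
  expect_error(replacement_cycles(0, 15), "> 0")
})

test_that("transition matrices are row-stochastic with the stated structure", {
  ps <- default_parameters()
  hf <- arm_parameters(ps, "HF10")
  # all hazards zero: identity
  ps0 <- set_parameters(ps, c(annual_mortality = 0, hf10.explant_yr1 = 0,
                              hf10.explant_yr2 = 0, hf10.explant_yr3plus = 0,
                              hf10.p_complication_late = 0, p_reoperation = 0),
                        refit = FALSE)
  M0 <- transition_matrix(ps0, arm_parameters(ps0, "HF10"), 1)
  # identity on every persistent state; with-complication status is re-drawn
  # each cycle, so with a zero late-complication hazard the C states revert
  # to their no-complication counterparts
  keep <- c("SCS_OPT_NC", "SCS_SUBOPT_NC", "CMM_OPT", "CMM_NO_RELIEF", "DEAD")
  expect_equal(M0[keep, keep], diag(5), ignore_attr = TRUE)
  expect_equal(unname(M0["SCS_OPT_C", "SCS_OPT_NC"]), 1)
  expect_equal(unname(M0["SCS_SUBOPT_C", "SCS_SUBOPT_NC"]), 1)
  # mortality-only: every living state sends the per-cycle rate to DEAD
  psm <- set_parameters(ps0, c(annual_mortality = 0.0081), refit = FALSE)
  Mm <- transition_matrix(psm, arm_parameters(psm, "HF10"), 1)
  p <- annual_to_cycle_prob(0.0081, 0.25)
  expect_equal(unname(Mm[1:6, "DEAD"]), rep(p, 6), tolerance = 1e-15)
  # row sums always one, DEAD absorbing, under random parameter draws
  set.seed(7)
  for (i in 1:25) {
    psr <- sample_parameter_set(ps, seed = 99, draw_index = i)
    for (k in c(1, 3, 9, 40)) {
      M <- transition_matrix(psr, arm_parameters(psr, "NRLF"), k)
      expect_equal(unname(rowSums(M)), rep(1, 7), tolerance = 1e-12)
      expect_true(all(M >= 0))
      expect_equal(unname(M["DEAD", "DEAD"]), 1)
    }
  }
})

test_that("cohort iteration conserves mass and death is non-decreasing", {
  ps <- default_parameters()
  for (arm in c("HF10", "NRLF")) {
    st <- run_decision_tree(ps, arm)
    lt <- run_markov(ps, arm, st$entering_state)
    occ <- as.matrix(lt$trace[, health_states()])
    expect_true(all(abs(rowSums(occ) - 1) <= 1e-12))
    expect_true(all(occ >= 0))
    expect_true(all(diff(lt$trace$DEAD) >= -1e-15))
    expect_true(all(lt$trace$cost_disc <= lt$trace$cost_undisc + 1e-9))
    expect_equal(sum(lt$trace$cost_disc), lt$total_cost, tolerance = 1e-9)
    expect_equal(sum(lt$trace$qalys_disc), lt$total_qalys, tolerance = 1e-9)
    # 15-year horizon with a 6-month tree leaves 58 quarterly cycles
    expect_equal(nrow(lt$trace), 58)
  }
})

test_that("hazard-free single-state run equals the closed-form annuity", {
  ps <- default_parameters()
  ps0 <- set_parameters(ps, c(annual_mortality = 0, hf10.explant_yr1 = 0,
                              hf10.explant_yr2 = 0, hf10.explant_yr3plus = 0,
                              hf10.p_complication_late = 0, p_reoperation = 0,
                              cost_trial = 0, cost_failed_trial_removal = 0,
                              hf10.cost_implant = 0, cost_explant = 0,
                              cost_complication = 0, cost_drug_scs_6mo = 0,
                              cost_nondrug_scs_6mo = 0, cost_drug_cmm_6mo = 0,
                              cost_nondrug_cmm_6mo = 0, hf10.device_longevity = 100),
                        refit = FALSE)
  init <- stats::setNames(c(1, 0, 0, 0, 0, 0, 0), health_states())
  # undiscounted: utility times remaining years
  psr0 <- set_parameters(ps0, c(discount_rate = 0), refit = FALSE)
  lt0 <- run_markov(psr0, "HF10", init)
  expect_equal(lt0$total_qalys, 0.598 * 14.5, tolerance = 1e-9)
  expect_equal(lt0$total_cost, 0)
  # discounted: independent midpoint-annuity summation
  lt <- run_markov(ps0, "HF10", init)
  mids <- 0.5 + (seq_len(58) - 1) * 0.25 + 0.125
  annuity <- sum(0.25 * 1.035^(-mids))
  expect_equal(lt$total_qalys, 0.598 * annuity, tolerance = 1e-9)
})

test_that("initial vector of all deaths accrues nothing", {
  ps <- default_parameters()
  init <- stats::setNames(c(0, 0, 0, 0, 0, 0, 1), health_states())
  lt <- run_markov(ps, "HF10", init)
  expect_equal(lt$total_cost, 0)
  expect_equal(lt$total_qalys, 0)
})

test_that("removing discounting strictly increases totals", {
  ps <- default_parameters()
  ps0 <- set_parameters(ps, c(discount_rate = 0), refit = FALSE)
  for (arm in c("HF10", "RLF")) {
    a <- evaluate_arm(ps, arm)
    a0 <- evaluate_arm(ps0, arm)
    expect_gt(a0$total_cost, a$total_cost)
    expect_gt(a0$total_qalys, a$total_qalys)
  }
})

test_that("shorter device longevity costs at least one extra discounted replacement", {
  ps <- default_parameters()
  # NRLF vs RLF differ in longevity (4 vs 10) and implant cost; equalize cost
  pseq <- set_parameters(ps, c(nrlf.cost_implant = ps$values[["rlf.cost_implant"]]),
                         refit = FALSE)
  nr <- evaluate_arm(pseq, "NRLF")
  rl <- evaluate_arm(pseq, "RLF")
  st <- run_decision_tree(pseq, "NRLF")
  lt <- run_markov(pseq, "NRLF", st$entering_state)
  surviving_at_4y <- sum(lt$trace[lt$trace$cycle == 15, health_states()[1:4]])
  one_repl <- surviving_at_4y * pseq$values[["rlf.cost_implant"]] * discount_factor(4, 0.035)
  expect_gt(nr$total_cost - rl$total_cost, one_repl * 0.999)
})

test_that("cohort totals match the per-patient microsimulation oracle", {
  ps <- default_parameters()
  n <- 2e5
  for (arm in c("HF10", "NRLF")) {
    res <- evaluate_arm(ps, arm)
    o <- microsim_summary(ps, arm, n, seed = 7)
    expect_lt(abs(res$total_cost - o$mean_cost), 3 * o$se_cost)
    expect_lt(abs(res$total_qalys - o$mean_qaly), 3 * o$se_qaly)
  }
})
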