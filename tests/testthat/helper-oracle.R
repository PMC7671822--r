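# Independent per-patient microsimulation oracle for the decision tree and
# Markov model. Deliberately written as straight patient-level simulation
# (integer state codes, per-event RNG) rather than reusing any cohort code,
# so cohort results can be checked against it to Monte-Carlo error.

ORACLE_STATES <- c("SCS_OPT_NC", "SCS_OPT_C", "SCS_SUBOPT_NC", "SCS_SUBOPT_C",
                   "CMM_OPT", "CMM_NO_RELIEF", "DEAD")

# Simulate the 6-month tree for n patients; returns per-patient cost, qaly
# and state code at month 6.
microsim_tree <- function(ps, arm, n, seed = 1) {
  set.seed(seed)
  a <- arm_parameters(ps, arm)
  v <- ps$values
  cost <- rep(v[["cost_trial"]], n)
  state <- integer(n)

  success <- runif(n) < a$trial_success
  cmm <- !success
  cost[cmm] <- cost[cmm] + v[["cost_failed_trial_removal"]]

  early_ex <- success & (runif(n) < 1 - (1 - a$explant_yr1)^0.5)
  cost[success] <- cost[success] + a$cost_implant
  cost[early_ex] <- cost[early_ex] + v[["cost_explant"]]
  cmm <- cmm | early_ex
  implanted <- success & !early_ex

  responder <- runif(n) < a$p_optimal_6mo
  comp <- runif(n) < a$p_complication_6mo
  state[implanted & responder & !comp] <- 1L
  state[implanted & responder & comp] <- 2L
  state[implanted & !responder & !comp] <- 3L
  state[implanted & !responder & comp] <- 4L
  cost[implanted & comp] <- cost[implanted & comp] + v[["cost_complication"]]
  cost[implanted] <- cost[implanted] +
    v[["cost_drug_scs_6mo"]] + v[["cost_nondrug_scs_6mo"]]

  cmm_opt <- cmm & (runif(n) < v[["p_optimal_cmm_6mo"]])
  state[cmm_opt] <- 5L
  state[cmm & !cmm_opt] <- 6L
  cost[cmm] <- cost[cmm] + v[["cost_drug_cmm_6mo"]] + v[["cost_nondrug_cmm_6mo"]]

  u <- c(v[["u_opt_nc"]], v[["u_opt_c"]], v[["u_subopt_nc"]], v[["u_subopt_c"]],
         v[["u_opt_nc"]], v[["u_no_relief"]], 0)
  qaly <- u[state] * 0.5 * (1 + v[["discount_rate"]])^(-0.25)
  list(cost = cost, qaly = qaly, state = state)
}

# Full per-patient simulation of tree + Markov phase with identical hazards
# and accrual conventions; returns per-patient totals.
microsim_full <- function(ps, arm, n, seed = 1) {
  tree <- microsim_tree(ps, arm, n, seed)
  set.seed(seed + 1)
  a <- arm_parameters(ps, arm)
  v <- ps$values
  cyc <- v[["cycle_length_years"]]
  rate <- v[["discount_rate"]]
  n_cycles <- as.integer(round((v[["horizon_years"]] - 0.5) / cyc))
  p_die <- 1 - (1 - v[["annual_mortality"]])^cyc
  p_reop <- v[["p_reoperation"]]; p_opt_reop <- v[["p_optimal_post_reop"]]
  p_opt_cmm <- v[["p_optimal_cmm_6mo"]]
  p_c <- 1 - (1 - a$p_complication_late_annual)^cyc
  therapy_imp <- (v[["cost_drug_scs_6mo"]] + v[["cost_nondrug_scs_6mo"]]) / 2
  therapy_cmm <- (v[["cost_drug_cmm_6mo"]] + v[["cost_nondrug_cmm_6mo"]]) / 2
  u <- c(v[["u_opt_nc"]], v[["u_opt_c"]], v[["u_subopt_nc"]], v[["u_subopt_c"]],
         v[["u_opt_nc"]], v[["u_no_relief"]], 0)
  repl <- replacement_cycles(a$device_longevity_years, v[["horizon_years"]], cyc)

  state <- tree$state
  cost <- tree$cost
  qaly <- tree$qaly
  for (k in seq_len(n_cycles)) {
    t_start <- 0.5 + (k - 1) * cyc
    t_mid <- t_start + cyc / 2
    df_mid <- (1 + rate)^(-t_mid)
    df_start <- (1 + rate)^(-t_start)
    t_yr <- if (t_start < 1) a$explant_yr1 else if (t_start < 2) a$explant_yr2
            else a$explant_yr3plus
    p_ex <- 1 - (1 - t_yr)^cyc

    alive <- state != 7L
    dies <- alive & (runif(n) < p_die)
    state[dies] <- 7L

    was_nr <- state == 6L
    reop <- was_nr & (runif(n) < p_reop)
    cost[reop] <- cost[reop] + v[["cost_reoperation"]] * df_mid
    reop_ok <- reop & (runif(n) < p_opt_reop)
    state[reop_ok] <- 5L

    imp <- state %in% 1:4
    expl <- imp & (runif(n) < p_ex)
    cost[expl] <- cost[expl] + v[["cost_explant"]] * df_mid
    to_opt <- expl & (runif(n) < p_opt_cmm)
    state[to_opt] <- 5L
    state[expl & !to_opt] <- 6L

    imp <- state %in% 1:4
    comp <- imp & (runif(n) < p_c)
    cost[comp] <- cost[comp] + v[["cost_complication"]] * df_mid
    opt <- state %in% 1:2
    state[opt & comp] <- 2L; state[opt & !comp & imp] <- 1L
    sub <- state %in% 3:4
    state[sub & comp] <- 4L; state[sub & !comp] <- 3L

    imp <- state %in% 1:4
    cmm <- state %in% 5:6
    cost[imp] <- cost[imp] + therapy_imp * df_mid
    cost[cmm] <- cost[cmm] + therapy_cmm * df_mid
    if (k %in% repl) cost[imp] <- cost[imp] + a$cost_reimplant * df_start
    qaly <- qaly + u[state] * cyc * df_mid
  }
  list(cost = cost, qaly = qaly, state = state)
}

# Convenience: oracle means with Monte-Carlo standard errors.
microsim_summary <- function(ps, arm, n, seed = 1) {
  m <- microsim_full(ps, arm, n, seed)
  list(mean_cost = mean(m$cost), se_cost = sd(m$cost) / sqrt(n),
       mean_qaly = mean(m$qaly), se_qaly = sd(m$qaly) / sqrt(n))
}
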