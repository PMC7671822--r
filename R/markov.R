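# Long-term Markov cohort engine: 3-month cycles from month 6 to the horizon
# with explants, transient complications, scheduled device replacement,
# reoperation on entry to the no-relief CMM state, and all-cause mortality.

#' Per-cycle explant probability
#'
#' Cycle 1 begins at month 6. Cycles covering months 6-12 draw the residual
#' Year-1 explant rate (the first half-year was consumed in the decision
#' tree), months 12-24 the Year-2 rate, and months 24+ the common Year-3+
#' rate; each annual rate is converted per-cycle under a constant hazard.
#'
#' @param arm_pars Arm parameter list from [arm_parameters()].
#' @param cycle_index Integer cycle index (>= 1).
#' @param cycle_length_years Cycle length in years.
#' @return Per-cycle explant probability.
#' @export
explant_prob_cycle <- function(arm_pars, cycle_index, cycle_length_years = 0.25) {
  if (any(cycle_index < 1)) stop("cycle_index must be >= 1")
  t_start <- 0.5 + (cycle_index - 1) * cycle_length_years
  annual <- ifelse(t_start < 1, arm_pars$explant_yr1,
                   ifelse(t_start < 2, arm_pars$explant_yr2,
                          arm_pars$explant_yr3plus))
  annual_to_cycle_prob(annual, cycle_length_years)
}

#' Scheduled device replacement cycles
#'
#' Replacements fall at integer multiples of the device longevity strictly
#' inside the horizon. Longevity is rounded to the nearest whole cycle (and
#' floored at one cycle) because procedures are scheduled on cycle
#' boundaries; replacement times before month 6 cannot be scheduled in the
#' Markov phase and are dropped.
#'
#' @param device_longevity_years Device service life in years (> 0).
#' @param horizon_years Model horizon in years.
#' @param cycle_length_years Cycle length in years.
#' @return Integer vector of Markov cycle indices whose start coincides with a
#'   replacement date.
#' @export
replacement_cycles <- function(device_longevity_years, horizon_years,
                               cycle_length_years = 0.25) {
  if (device_longevity_years <= 0) stop("device_longevity_years must be > 0")
  L <- max(round(device_longevity_years / cycle_length_years), 1) * cycle_length_years
  times <- seq(L, by = L, length.out = floor((horizon_years - 1e-9) / L))
  times <- times[times < horizon_years - 1e-9 & times >= 0.5]
  as.integer(round((times - 0.5) / cycle_length_years)) + 1L
}

# Shared per-cycle hazards.
cycle_hazards <- function(ps, arm_pars, cycle_index) {
  v <- ps$values
  cyc <- v[["cycle_length_years"]]
  p_die <- annual_to_cycle_prob(v[["annual_mortality"]], cyc)
  p_ex <- explant_prob_cycle(arm_pars, cycle_index, cyc)
  p_c <- annual_to_cycle_prob(arm_pars$p_complication_late_annual, cyc)
  list(p_die = p_die, p_ex = p_ex, p_c = p_c,
       p_opt_cmm = v[["p_optimal_cmm_6mo"]],
       p_reop = v[["p_reoperation"]],
       p_opt_reop = v[["p_optimal_post_reop"]])
}

#' Per-cycle transition matrix
#'
#' Row-stochastic matrix over the model's health states for one cycle.
#' Within a cycle, mortality applies first; surviving implanted patients
#' explant with the cycle's explant probability (explanted mass splits
#' between the two CMM states by the CMM optimal-relief probability);
#' remaining implanted patients re-draw complication status with the
#' per-cycle late-complication probability (complication status does not
#' persist unless re-drawn). Surviving patients in the no-relief CMM state
#' may receive spinal reoperation in each cycle (`p_reoperation`), a fraction
#' of whom (`p_optimal_post_reop`) move to optimal relief under CMM.
#' Pain-relief level on SCS (optimal / sub-optimal) is fixed at month 6 and
#' never migrates. Death is absorbing.
#'
#' @param ps An `scs_params` object.
#' @param arm_pars Arm parameter list from [arm_parameters()].
#' @param cycle_index Integer cycle index (>= 1).
#' @return A 7x7 row-stochastic matrix with dimnames [health_states()].
#' @export
transition_matrix <- function(ps, arm_pars, cycle_index) {
  h <- cycle_hazards(ps, arm_pars, cycle_index)
  s <- health_states()
  M <- matrix(0, 7, 7, dimnames = list(s, s))

  surv <- 1 - h$p_die
  stay <- surv * (1 - h$p_ex)
  to_cmm_opt <- surv * h$p_ex * h$p_opt_cmm
  to_cmm_nr <- surv * h$p_ex * (1 - h$p_opt_cmm)
  for (lvl in c("OPT", "SUBOPT")) {
    nc <- paste0("SCS_", lvl, "_NC"); cc <- paste0("SCS_", lvl, "_C")
    for (from in c(nc, cc)) {
      M[from, nc] <- stay * (1 - h$p_c)
      M[from, cc] <- stay * h$p_c
      M[from, "CMM_OPT"] <- to_cmm_opt
      M[from, "CMM_NO_RELIEF"] <- to_cmm_nr
      M[from, "DEAD"] <- h$p_die
    }
  }
  M["CMM_OPT", "CMM_OPT"] <- surv
  M["CMM_OPT", "DEAD"] <- h$p_die
  p_reop_opt <- h$p_reop * h$p_opt_reop
  M["CMM_NO_RELIEF", "CMM_OPT"] <- surv * p_reop_opt
  M["CMM_NO_RELIEF", "CMM_NO_RELIEF"] <- surv * (1 - p_reop_opt)
  M["CMM_NO_RELIEF", "DEAD"] <- h$p_die
  M["DEAD", "DEAD"] <- 1

  bad <- abs(rowSums(M) - 1) > 1e-12
  if (any(bad)) {
    stop("internal consistency error: transition rows do not sum to 1: ",
         paste(s[bad], collapse = ", "))
  }
  M
}

#' Run the Markov cohort model from month 6 to the horizon
#'
#' Iterates the cohort in 3-month cycles. Each cycle the state vector is
#' advanced by [transition_matrix()]; the post-transition occupancy then
#' accrues state utilities (cycle length x utility, discounted at the cycle
#' midpoint), therapy costs (SCS+CMM rates for implanted states, CMM-alone
#' rates for CMM states, at half the 6-month figures per cycle), and event
#' costs (explant, complication, reoperation at the cycle midpoint;
#' scheduled device replacement at the cycle start, priced on surviving
#' implanted occupancy).
#'
#' @param ps An `scs_params` object.
#' @param arm `"HF10"`, `"NRLF"` or `"RLF"`.
#' @param initial Named occupancy vector over [health_states()] at month 6
#'   (typically `run_decision_tree(ps, arm)$entering_state`).
#' @return A list of class `scs_long_term` with `total_cost`, `total_qalys`
#'   (both discounted), a per-cycle `trace` data.frame, and a cost
#'   `breakdown` by category.
#' @export
run_markov <- function(ps, arm, initial) {
  a <- arm_parameters(ps, arm)
  v <- ps$values
  u <- state_utilities(ps)
  s <- health_states()
  stopifnot(length(initial) == 7)
  if (any(initial < -1e-12)) stop("initial occupancies must be non-negative")
  if (abs(sum(initial) - 1) > 1e-9) stop("initial state vector must sum to 1")
  initial <- stats::setNames(as.numeric(initial), s)

  cyc <- v[["cycle_length_years"]]
  horizon <- v[["horizon_years"]]
  if (horizon < 0.5 + cyc) stop("horizon_years must extend beyond the 6-month decision tree")
  n_cycles <- as.integer(round((horizon - 0.5) / cyc))
  rate <- v[["discount_rate"]]
  imp_states <- s[1:4]
  cmm_states <- s[5:6]

  therapy_imp <- (v[["cost_drug_scs_6mo"]] + v[["cost_nondrug_scs_6mo"]]) / 2
  therapy_cmm <- (v[["cost_drug_cmm_6mo"]] + v[["cost_nondrug_cmm_6mo"]]) / 2
  drug_imp <- v[["cost_drug_scs_6mo"]] / 2; nondrug_imp <- v[["cost_nondrug_scs_6mo"]] / 2
  drug_cmm <- v[["cost_drug_cmm_6mo"]] / 2; nondrug_cmm <- v[["cost_nondrug_cmm_6mo"]] / 2

  repl <- replacement_cycles(a$device_longevity_years, horizon, cyc)
  state <- initial

  trace <- matrix(0, n_cycles, 7 + 10,
                  dimnames = list(NULL, c("cycle", "time_years", s,
                                          "cost_undisc", "cost_disc", "qalys_disc",
                                          "explants", "replacements", "complications",
                                          "reoperations", "deaths")))
  breakdown <- c(trial = 0, device_implant = 0, device_replacement = 0,
                 therapy_drug = 0, therapy_nondrug = 0, complications = 0,
                 explants = 0, reoperations = 0)

  for (k in seq_len(n_cycles)) {
    t_start <- 0.5 + (k - 1) * cyc
    t_mid <- t_start + cyc / 2
    h <- cycle_hazards(ps, a, k)
    M <- transition_matrix(ps, a, k)

    imp0 <- sum(state[imp_states])
    alive0 <- 1 - state[["DEAD"]]
    new_state <- as.numeric(state %*% M)
    names(new_state) <- s

    deaths <- alive0 * h$p_die
    explants <- imp0 * (1 - h$p_die) * h$p_ex
    stay_imp <- imp0 * (1 - h$p_die) * (1 - h$p_ex)
    complications <- stay_imp * h$p_c
    reops <- state[["CMM_NO_RELIEF"]] * (1 - h$p_die) * h$p_reop

    imp1 <- sum(new_state[imp_states])
    cmm1 <- sum(new_state[cmm_states])

    df_mid <- discount_factor(t_mid, rate)
    df_start <- discount_factor(t_start, rate)

    c_drug <- imp1 * drug_imp + cmm1 * drug_cmm
    c_nondrug <- imp1 * nondrug_imp + cmm1 * nondrug_cmm
    c_expl <- explants * v[["cost_explant"]]
    c_comp <- complications * v[["cost_complication"]]
    c_reop <- reops * v[["cost_reoperation"]]
    c_repl <- if (k %in% repl) imp1 * a$cost_reimplant else 0
    replacements <- if (k %in% repl) imp1 else 0

    cost_undisc <- c_drug + c_nondrug + c_expl + c_comp + c_reop + c_repl
    cost_disc <- (c_drug + c_nondrug + c_expl + c_comp + c_reop) * df_mid +
      c_repl * df_start
    qalys <- sum(new_state * u) * cyc * df_mid

    breakdown[["therapy_drug"]] <- breakdown[["therapy_drug"]] + c_drug * df_mid
    breakdown[["therapy_nondrug"]] <- breakdown[["therapy_nondrug"]] + c_nondrug * df_mid
    breakdown[["complications"]] <- breakdown[["complications"]] + c_comp * df_mid
    breakdown[["explants"]] <- breakdown[["explants"]] + c_expl * df_mid
    breakdown[["reoperations"]] <- breakdown[["reoperations"]] + c_reop * df_mid
    breakdown[["device_replacement"]] <- breakdown[["device_replacement"]] + c_repl * df_start

    trace[k, ] <- c(k, t_start + cyc, new_state, cost_undisc, cost_disc, qalys,
                    explants, replacements, complications, reops, deaths)
    state <- new_state
  }

  trace <- as.data.frame(trace)
  structure(list(
    arm = a$arm,
    total_cost = sum(trace$cost_disc),
    total_qalys = sum(trace$qalys_disc),
    trace = trace,
    breakdown = breakdown,
    event_totals = c(explants = sum(trace$explants),
                     replacements = sum(trace$replacements),
                     complications = sum(trace$complications),
                     reoperations = sum(trace$reoperations),
                     deaths = sum(trace$deaths))
  ), class = "scs_long_term")
}
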