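# Six-month decision tree: screening trial, permanent implantation or CMM
# alone, response/complication branching, early explants. Produces the
# discounted 6-month cost and QALY block and the state distribution handed to
# the Markov model.

#' Markov health states
#'
#' Order of the six living states plus death used throughout the model:
#' optimal / sub-optimal pain relief with SCS, each with or without
#' complications; conventional medical management (CMM) alone split into
#' optimal relief and no perceived relief; and death (absorbing).
#'
#' @return Character vector of state names.
#' @export
health_states <- function() {
  c("SCS_OPT_NC", "SCS_OPT_C", "SCS_SUBOPT_NC", "SCS_SUBOPT_C",
    "CMM_OPT", "CMM_NO_RELIEF", "DEAD")
}

state_utilities <- function(ps) {
  v <- ps$values
  c(SCS_OPT_NC = v[["u_opt_nc"]], SCS_OPT_C = v[["u_opt_c"]],
    SCS_SUBOPT_NC = v[["u_subopt_nc"]], SCS_SUBOPT_C = v[["u_subopt_c"]],
    CMM_OPT = v[["u_opt_nc"]], CMM_NO_RELIEF = v[["u_no_relief"]],
    DEAD = 0)
}

#' Run the six-month decision tree for one arm
#'
#' Pathway: all patients undergo a screening trial (`cost_trial`). Successes
#' receive a permanent implant (`cost_implant`); failures pay the failed-trial
#' electrode removal and follow CMM alone. Implanted patients may explant
#' within the first 6 months with probability `1 - (1 - explant_yr1)^0.5`
#' (the half-year share of the Year-1 rate), paying `cost_explant` and joining
#' the CMM pathway. Remaining implanted patients split into optimal vs
#' sub-optimal relief (`p_optimal_6mo`) independently crossed with
#' with/without complications (`p_complication_6mo`; a complication prices
#' `cost_complication` and maps to the with-complication utility). CMM-alone
#' patients reach optimal relief with `p_optimal_cmm_6mo`, otherwise occupy
#' the no-perceived-relief state.
#'
#' Every branch accrues 6 months of the applicable drug/non-drug therapy cost
#' (SCS+CMM rates for implanted patients, CMM-alone rates otherwise; early
#' explants take the CMM rates for the full period). Up-front and event costs
#' are booked undiscounted (they fall at or near time zero); QALYs are half a
#' year of state utility discounted at the 0.25-year mid-period factor.
#' Mortality is not applied within the tree.
#'
#' @param ps An `scs_params` object.
#' @param arm `"HF10"`, `"NRLF"` or `"RLF"`.
#' @return A list of class `scs_short_term` with elements `arm`, `cost_6mo`,
#'   `qalys_6mo`, `entering_state` (named occupancy vector at month 6),
#'   `fraction_implanted`, `fraction_cmm`, `event_counts`, and cost
#'   `breakdown` by category.
#' @export
run_decision_tree <- function(ps, arm) {
  a <- arm_parameters(ps, arm)
  v <- ps$values
  u <- state_utilities(ps)

  p_ts <- a$trial_success
  p_ex_early <- 1 - (1 - a$explant_yr1)^0.5
  p_opt <- a$p_optimal_6mo
  p_c <- a$p_complication_6mo
  p_opt_cmm <- v[["p_optimal_cmm_6mo"]]

  m_fail <- 1 - p_ts                  # failed screening trial -> CMM alone
  m_expl <- p_ts * p_ex_early         # implanted, early explant -> CMM
  m_imp <- p_ts * (1 - p_ex_early)    # implanted at month 6
  m_cmm <- m_fail + m_expl

  state <- stats::setNames(numeric(7), health_states())
  state["SCS_OPT_NC"] <- m_imp * p_opt * (1 - p_c)
  state["SCS_OPT_C"] <- m_imp * p_opt * p_c
  state["SCS_SUBOPT_NC"] <- m_imp * (1 - p_opt) * (1 - p_c)
  state["SCS_SUBOPT_C"] <- m_imp * (1 - p_opt) * p_c
  state["CMM_OPT"] <- m_cmm * p_opt_cmm
  state["CMM_NO_RELIEF"] <- m_cmm * (1 - p_opt_cmm)

  therapy_scs_drug <- v[["cost_drug_scs_6mo"]]
  therapy_scs_nondrug <- v[["cost_nondrug_scs_6mo"]]
  therapy_cmm_drug <- v[["cost_drug_cmm_6mo"]]
  therapy_cmm_nondrug <- v[["cost_nondrug_cmm_6mo"]]

  breakdown <- c(
    trial = v[["cost_trial"]] + m_fail * v[["cost_failed_trial_removal"]],
    device_implant = p_ts * a$cost_implant,
    device_replacement = 0,
    therapy_drug = m_imp * therapy_scs_drug + m_cmm * therapy_cmm_drug,
    therapy_nondrug = m_imp * therapy_scs_nondrug + m_cmm * therapy_cmm_nondrug,
    complications = m_imp * p_c * v[["cost_complication"]],
    explants = m_expl * v[["cost_explant"]],
    reoperations = 0
  )
  cost_6mo <- sum(breakdown)

  df_mid <- discount_factor(0.25, v[["discount_rate"]])
  qalys_6mo <- sum(state * u) * 0.5 * df_mid

  structure(list(
    arm = a$arm,
    cost_6mo = cost_6mo,
    qalys_6mo = qalys_6mo,
    entering_state = state,
    fraction_implanted = p_ts,
    fraction_cmm = 1 - p_ts,
    event_counts = c(trial_failures = m_fail, explants = m_expl,
                     complications = m_imp * p_c),
    breakdown = breakdown
  ), class = "scs_short_term")
}
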