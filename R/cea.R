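# Cost-consequence and cost-utility layer: per-arm totals, category
# breakdowns, incremental comparisons, ICER and dominance classification.

#' Evaluate one comparator arm deterministically
#'
#' Runs the six-month decision tree and the long-term Markov model and
#' combines them into per-arm discounted totals with a cost breakdown by
#' category and by health state.
#'
#' @param ps An `scs_params` object.
#' @param arm `"HF10"`, `"NRLF"` or `"RLF"`.
#' @return A list of class `scs_arm_result` with `arm`, `total_cost`,
#'   `total_qalys`, `breakdown` (named GBP per category, summing to
#'   `total_cost`), `by_state` (GBP per health state), `short_term`,
#'   `long_term`.
#' @export
#' @examples
#' res <- evaluate_arm(default_parameters(), "HF10")
#' round(res$total_cost)
evaluate_arm <- function(ps, arm) {
  arm <- match.arg(arm, c("HF10", "NRLF", "RLF"))
  st <- run_decision_tree(ps, arm)
  lt <- run_markov(ps, arm, st$entering_state)
  breakdown <- st$breakdown + lt$breakdown
  total_cost <- st$cost_6mo + lt$total_cost
  stopifnot(abs(sum(breakdown) - total_cost) < 1e-6 * max(1, total_cost))

  # by-state attribution: up-front tree costs to the month-6 entry states
  # (proportional to entering mass), cycle therapy costs to the occupying
  # state, event costs to the source state group.
  s <- health_states()
  by_state <- stats::setNames(numeric(7), s)
  w <- st$entering_state / sum(st$entering_state)
  by_state <- by_state + w * st$cost_6mo
  v <- ps$values
  tr <- lt$trace
  rate <- v[["discount_rate"]]
  df_mid <- discount_factor(tr$time_years - v[["cycle_length_years"]] / 2, rate)
  therapy_imp <- (v[["cost_drug_scs_6mo"]] + v[["cost_nondrug_scs_6mo"]]) / 2
  therapy_cmm <- (v[["cost_drug_cmm_6mo"]] + v[["cost_nondrug_cmm_6mo"]]) / 2
  for (nm in s[1:4]) by_state[nm] <- by_state[nm] + sum(tr[[nm]] * therapy_imp * df_mid)
  for (nm in s[5:6]) by_state[nm] <- by_state[nm] + sum(tr[[nm]] * therapy_cmm * df_mid)
  imp_mass <- rowSums(tr[, s[1:4]])
  imp_share <- function(col) ifelse(imp_mass > 0, tr[[col]] / pmax(imp_mass, 1e-300), 0)
  event_cost <- (tr$explants * v[["cost_explant"]] +
                 tr$complications * v[["cost_complication"]] +
                 tr$reoperations * v[["cost_reoperation"]]) * df_mid
  repl_cost <- lt$breakdown[["device_replacement"]]
  for (nm in s[1:4]) {
    by_state[nm] <- by_state[nm] + sum(event_cost * imp_share(nm)) +
      repl_cost * (sum(tr[[nm]]) / max(sum(imp_mass), 1e-300))
  }

  structure(list(
    arm = arm,
    total_cost = total_cost,
    total_qalys = st$qalys_6mo + lt$total_qalys,
    breakdown = breakdown,
    by_state = by_state,
    short_term = st,
    long_term = lt
  ), class = "scs_arm_result")
}

#' @export
print.scs_arm_result <- function(x, ...) {
  cat(sprintf("<scs_arm_result> %s: total cost £%s, total QALYs %.3f\n",
              x$arm, format(round(x$total_cost), big.mark = ","), x$total_qalys))
  invisible(x)
}

#' Compare two evaluated arms
#'
#' Deltas are comparator minus reference. An ICER is reported only when the
#' cost and QALY deltas share a sign; otherwise one strategy dominates
#' (strictly lower cost and strictly more QALYs). Exact ties are flagged.
#' Also returns the net-monetary-benefit difference (reference NMB minus
#' comparator NMB) at the willingness-to-pay threshold.
#'
#' @param reference,comparator `scs_arm_result` objects evaluated under the
#'   same parameter set.
#' @param wtp Willingness to pay, GBP per QALY.
#' @return A list of class `scs_comparison` with `delta_cost`, `delta_qalys`,
#'   `icer`, `classification` (`"reference_dominant"`,
#'   `"comparator_dominant"` or `"icer_reported"`), `nmb_difference`, `tie`.
#' @export
compare_arms <- function(reference, comparator, wtp = 20000) {
  dc <- comparator$total_cost - reference$total_cost
  dq <- comparator$total_qalys - reference$total_qalys
  tie <- (dc == 0) || (dq == 0)
  if (dq == 0) {
    icer <- if (dc == 0) 0 else sign(dc) * Inf
    classification <- if (dc > 0) "reference_dominant"
      else if (dc < 0) "comparator_dominant" else "icer_reported"
  } else if (dc > 0 && dq < 0) {
    icer <- NA_real_
    classification <- "reference_dominant"
  } else if (dc < 0 && dq > 0) {
    icer <- NA_real_
    classification <- "comparator_dominant"
  } else {
    icer <- dc / dq
    classification <- "icer_reported"
  }
  nmb_ref <- wtp * reference$total_qalys - reference$total_cost
  nmb_comp <- wtp * comparator$total_qalys - comparator$total_cost
  structure(list(
    reference = reference$arm, comparator = comparator$arm,
    delta_cost = dc, delta_qalys = dq, icer = icer,
    classification = classification,
    nmb_difference = nmb_ref - nmb_comp, wtp = wtp, tie = tie
  ), class = "scs_comparison")
}

#' @export
print.scs_comparison <- function(x, ...) {
  lab <- switch(x$classification,
                reference_dominant = sprintf("%s dominated by %s", x$comparator, x$reference),
                comparator_dominant = sprintf("%s dominated by %s", x$reference, x$comparator),
                icer_reported = sprintf("ICER £%.0f/QALY", x$icer))
  cat(sprintf("<scs_comparison> %s vs %s: Δcost £%.0f, ΔQALY %.3f — %s\n",
              x$comparator, x$reference, x$delta_cost, x$delta_qalys, lab))
  invisible(x)
}

#' Evaluate all three arms and both comparisons
#'
#' @param ps An `scs_params` object.
#' @return A list with `arms` (named list of `scs_arm_result`) and
#'   `comparisons` (named list of `scs_comparison`, each LF arm versus the
#'   10 kHz reference).
#' @export
evaluate_all <- function(ps) {
  arms <- lapply(stats::setNames(nm = c("HF10", "NRLF", "RLF")),
                 function(a) evaluate_arm(ps, a))
  wtp <- ps$values[["wtp_per_qaly"]]
  comparisons <- list(
    NRLF_vs_HF10 = compare_arms(arms$HF10, arms$NRLF, wtp),
    RLF_vs_HF10 = compare_arms(arms$HF10, arms$RLF, wtp)
  )
  list(arms = arms, comparisons = comparisons)
}

#' Tidy summary tables for a full deterministic run
#'
#' @param res Result of [evaluate_all()].
#' @return A list of two data.frames: `arms` (one row per arm) and
#'   `comparisons` (one row per comparison).
#' @export
summary_tables <- function(res) {
  arms <- do.call(rbind, lapply(res$arms, function(a) {
    data.frame(arm = a$arm, total_cost = a$total_cost, total_qalys = a$total_qalys,
               t(as.matrix(a$breakdown)), row.names = NULL)
  }))
  comparisons <- do.call(rbind, lapply(res$comparisons, function(cmp) {
    data.frame(reference = cmp$reference, comparator = cmp$comparator,
               delta_cost = cmp$delta_cost, delta_qalys = cmp$delta_qalys,
               icer = cmp$icer, classification = cmp$classification,
               nmb_difference = cmp$nmb_difference, row.names = NULL)
  }))
  list(arms = arms, comparisons = comparisons)
}
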