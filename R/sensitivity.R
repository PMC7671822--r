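# Deterministic sensitivity analyses: one-way (tornado) over the 95% CI
# bounds, threshold (bisection) search, and the named multiway scenarios.

# Outcome of a full deterministic run for one comparison, as a scalar.
#   delta_cost : comparator cost minus 10 kHz cost (positive = 10 kHz saves)
#   nmb        : 10 kHz NMB minus comparator NMB at the configured WTP
#                (the sign-stable representation of the ICER/dominance axis)
outcome_value <- function(ps, comparator, outcome = c("delta_cost", "nmb")) {
  outcome <- match.arg(outcome)
  ref <- evaluate_arm(ps, "HF10")
  comp <- evaluate_arm(ps, comparator)
  cmp <- compare_arms(ref, comp, ps$values[["wtp_per_qaly"]])
  switch(outcome, delta_cost = cmp$delta_cost, nmb = cmp$nmb_difference)
}

#' One-way (tornado) sensitivity analysis
#'
#' Sets each parameter with CI/range bounds to its lower then upper bound,
#' all others at base case, and records the resulting outcome: the
#' incremental cost of the comparator versus 10 kHz SCS (cost-consequence
#' analysis) or the net-monetary-benefit difference (10 kHz minus comparator;
#' the sign-stable axis for the cost-utility analysis). All bounded
#' parameters are tested; entries are sorted by descending span and the ten
#' most influential are flagged for plotting.
#'
#' @param ps An `scs_params` object.
#' @param comparator `"NRLF"` or `"RLF"`.
#' @param outcome `"delta_cost"` or `"nmb"`.
#' @return A data.frame with one row per parameter: bounds, outcomes at each
#'   bound, `span`, and `top10`.
#' @export
owsa <- function(ps, comparator = "NRLF", outcome = c("delta_cost", "nmb")) {
  outcome <- match.arg(outcome)
  comparator <- match.arg(comparator, c("NRLF", "RLF"))
  sp <- ps$specs[ps$specs$family != "fixed" & !is.na(ps$specs$lo), ]
  base_out <- outcome_value(ps, comparator, outcome)
  rows <- lapply(seq_len(nrow(sp)), function(i) {
    nm <- sp$name[i]
    at <- function(x) {
      outcome_value(set_parameters(ps, stats::setNames(x, nm), refit = FALSE),
                    comparator, outcome)
    }
    lo_out <- at(sp$lo[i]); hi_out <- at(sp$hi[i])
    data.frame(parameter = nm, low_input = sp$lo[i], high_input = sp$hi[i],
               outcome_at_low = lo_out, outcome_at_high = hi_out,
               span = abs(hi_out - lo_out), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- out[order(-out$span), ]
  out$top10 <- seq_len(nrow(out)) <= 10
  attr(out, "base_outcome") <- base_out
  attr(out, "outcome") <- outcome
  attr(out, "comparator") <- comparator
  rownames(out) <- NULL
  out
}

#' Threshold search on one parameter
#'
#' Bisection for the parameter value at which 10 kHz SCS is cost-neutral
#' versus the comparator (`objective = "cost_neutral"`: incremental cost
#' zero) or at which the incremental position equals the willingness-to-pay
#' threshold (`objective = "icer_equals_wtp"`: `delta_cost - wtp *
#' delta_qalys = 0`, the NMB form, which is well defined under dominance).
#' If the objective does not change sign across the bracket, a
#' "no threshold within plausible range" result is returned rather than an
#' error.
#'
#' @param ps An `scs_params` object.
#' @param parameter Registry parameter name.
#' @param objective `"cost_neutral"` or `"icer_equals_wtp"`.
#' @param comparator `"NRLF"` or `"RLF"`.
#' @param bracket Numeric length-2 search interval; defaults to the
#'   parameter's CI bounds.
#' @param tolerance Absolute residual tolerance in GBP (default £1).
#' @param max_iter Bisection iteration cap.
#' @return A list of class `scs_threshold` with `parameter`, `objective`,
#'   `threshold_value`, `achieved_objective_residual`, `bracketed`.
#' @export
threshold_search <- function(ps, parameter, objective = c("cost_neutral", "icer_equals_wtp"),
                             comparator = "NRLF", bracket = NULL, tolerance = 1,
                             max_iter = 100) {
  objective <- match.arg(objective)
  comparator <- match.arg(comparator, c("NRLF", "RLF"))
  i <- match(parameter, ps$specs$name)
  if (is.na(i)) stop("unknown parameter: ", parameter)
  if (is.null(bracket)) {
    if (is.na(ps$specs$lo[i])) stop("parameter '", parameter, "' has no bounds; supply a bracket")
    bracket <- c(ps$specs$lo[i], ps$specs$hi[i])
  }
  wtp <- ps$values[["wtp_per_qaly"]]
  resid <- function(x) {
    cmp_ps <- set_parameters(ps, stats::setNames(x, parameter), refit = FALSE)
    ref <- evaluate_arm(cmp_ps, "HF10")
    comp <- evaluate_arm(cmp_ps, comparator)
    dc <- comp$total_cost - ref$total_cost
    dq <- comp$total_qalys - ref$total_qalys
    if (objective == "cost_neutral") dc else dc - wtp * dq
  }
  f_lo <- resid(bracket[1]); f_hi <- resid(bracket[2])
  done <- function(x, fx, ok) {
    structure(list(parameter = parameter, objective = objective,
                   comparator = comparator, threshold_value = x,
                   achieved_objective_residual = fx, bracketed = ok),
              class = "scs_threshold")
  }
  if (abs(f_lo) <= tolerance) return(done(bracket[1], f_lo, TRUE))
  if (abs(f_hi) <= tolerance) return(done(bracket[2], f_hi, TRUE))
  if (sign(f_lo) == sign(f_hi)) return(done(NA_real_, NA_real_, FALSE))
  lo <- bracket[1]; hi <- bracket[2]
  for (it in seq_len(max_iter)) {
    mid <- (lo + hi) / 2
    f_mid <- resid(mid)
    if (abs(f_mid) <= tolerance) return(done(mid, f_mid, TRUE))
    if (sign(f_mid) == sign(f_lo)) { lo <- mid; f_lo <- f_mid } else hi <- mid
  }
  mid <- (lo + hi) / 2
  done(mid, resid(mid), TRUE)
}

#' @export
print.scs_threshold <- function(x, ...) {
  if (!x$bracketed) {
    cat(sprintf("<scs_threshold> %s (%s vs %s): no threshold within plausible range\n",
                x$parameter, x$objective, x$comparator))
  } else {
    cat(sprintf("<scs_threshold> %s (%s vs %s): %.6g (residual £%.3g)\n",
                x$parameter, x$objective, x$comparator, x$threshold_value,
                x$achieved_objective_residual))
  }
  invisible(x)
}

#' Named scenario overrides
#'
#' Packaged multiway scenarios:
#' \describe{
#'   \item{`equal_explant_3.2`}{All explant rates (Years 1, 2, 3+) set to
#'     3.2% per annum for every device.}
#'   \item{`equal_complications`}{Low-frequency complication rates (6-month
#'     and late annual) set equal to the 10 kHz values.}
#'   \item{`alternative_system_costs`}{Alternative system costing: RLF
#'     implantation priced at the 10 kHz system cost and explicit (lower)
#'     reimplantation prices for all devices.}
#'   \item{`horizon_<N>y`}{Time horizon changed to N years, e.g.
#'     `horizon_10y`.}
#' }
#'
#' @param name Scenario identifier.
#' @return Named numeric vector of parameter overrides.
#' @export
scenario_overrides <- function(name) {
  known <- c("equal_explant_3.2", "equal_complications", "alternative_system_costs",
             "horizon_<N>y")
  if (grepl("^horizon_[0-9]+y$", name)) {
    n <- as.numeric(sub("^horizon_([0-9]+)y$", "\\1", name))
    return(c(horizon_years = n))
  }
  switch(name,
    "equal_explant_3.2" = c(
      hf10.explant_yr1 = 0.032, hf10.explant_yr2 = 0.032, hf10.explant_yr3plus = 0.032,
      lf.explant_yr1 = 0.032, lf.explant_yr2 = 0.032, lf.explant_yr3plus = 0.032),
    "equal_complications" = c(
      lf.p_complication_6mo = NA, lf.p_complication_late = NA),  # filled from HF10 at run time
    "alternative_system_costs" = c(
      rlf.cost_implant = 16648,
      hf10.cost_reimplant = 14201, nrlf.cost_reimplant = 10499,
      rlf.cost_reimplant = 14201),
    stop("unknown scenario '", name, "'; available: ", paste(known, collapse = ", "))
  )
}

#' Run a named or ad hoc scenario
#'
#' Applies the overrides of a packaged scenario (see [scenario_overrides()])
#' or a custom named vector and re-runs the full deterministic analysis.
#'
#' @param ps An `scs_params` object.
#' @param scenario Scenario name, or `NULL` to use `overrides` directly.
#' @param overrides Optional named numeric vector of custom overrides.
#' @return As [evaluate_all()], with a `scenario` element.
#' @export
run_scenario <- function(ps, scenario = NULL, overrides = NULL) {
  if (!is.null(scenario)) {
    overrides <- scenario_overrides(scenario)
    if (scenario == "equal_complications") {
      overrides[["lf.p_complication_6mo"]] <- ps$values[["hf10.p_complication_6mo"]]
      overrides[["lf.p_complication_late"]] <- ps$values[["hf10.p_complication_late"]]
    }
  }
  ps2 <- if (length(overrides) > 0) set_parameters(ps, overrides, refit = FALSE) else ps
  res <- evaluate_all(ps2)
  res$scenario <- if (is.null(scenario)) "custom" else scenario
  res$overrides <- overrides
  res
}
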