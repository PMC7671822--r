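# Synthetic patient-level trial generator and input re-estimation: a
# parameter-recovery surface standing in for the patient-level RCT analysis
# from which the model's clinical inputs were derived. The generated records
# are synthetic; no real patient data are used anywhere in this package.

#' Simulate patient-level trial records
#'
#' Generates per-patient records for a two-arm trial (10 kHz high-frequency
#' SCS vs pooled low-frequency SCS) with the probabilistic structure the
#' model consumes: Bernoulli screening-trial success; among implanted
#' patients, independent Bernoulli 6-month responder status (>= 50% leg-pain
#' reduction) and 6-month complication, a Bernoulli late complication over a
#' one-year observation window, and a 24-month explant time drawn from a
#' two-piece constant-hazard model matching the Year-1 and Year-2 annual
#' explant probabilities. Explant reasons are paresthesia-weighted in Year 1
#' and ineffective-pain-weighted in Year 2, reflecting the reported pattern
#' of early paresthesia-driven removals.
#'
#' @param ps An `scs_params` object supplying the true probabilities
#'   (`hf10.*` for the HF10 arm, `lf.*` for the LF arm).
#' @param n_per_arm Patients per arm (>= 1).
#' @param seed Integer seed; identical seeds give identical record lists.
#' @return A data.frame with one row per patient: `patient_id`, `arm`
#'   (`"HF10"`/`"LF"`), `trial_success`, `responder_6mo`,
#'   `complication_6mo`, `complication_late`, `explant_month` (integer month
#'   1-24 or `NA`), `explant_reason` (`"ineffective_pain"`, `"paresthesia"`,
#'   `"other"` or `NA`). Responder/complication/explant fields are `NA` for
#'   screening-trial failures.
#' @export
simulate_trial <- function(ps, n_per_arm, seed = 1) {
  if (n_per_arm < 1) stop("n_per_arm must be >= 1")
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()), add = TRUE)
  set.seed(seed)
  v <- ps$values
  one_arm <- function(arm, prefix) {
    g <- function(f) v[[paste0(prefix, ".", f)]]
    n <- n_per_arm
    success <- stats::rbinom(n, 1, g("trial_success")) == 1
    responder <- ifelse(success, stats::rbinom(n, 1, g("p_optimal_6mo")) == 1, NA)
    comp6 <- ifelse(success, stats::rbinom(n, 1, g("p_complication_6mo")) == 1, NA)
    comp_late <- ifelse(success, stats::rbinom(n, 1, g("p_complication_late")) == 1, NA)
    # two-piece exponential explant time (months): hazard from the Year-1
    # annual probability over months 0-12, Year-2 over months 12-24
    h1 <- -log(1 - g("explant_yr1")) / 12
    h2 <- -log(1 - g("explant_yr2")) / 12
    t1 <- stats::rexp(n, rate = max(h1, 1e-300))
    t2 <- 12 + stats::rexp(n, rate = max(h2, 1e-300))
    t <- ifelse(t1 <= 12, t1, t2)
    explant_month <- ifelse(success & t <= 24, pmax(ceiling(t), 1), NA)
    reason <- rep(NA_character_, n)
    has <- !is.na(explant_month)
    yr1 <- has & explant_month <= 12
    reasons <- c("ineffective_pain", "paresthesia", "other")
    n1 <- sum(yr1); n2 <- sum(has & !yr1)
    if (n1 > 0) reason[yr1] <- sample(reasons, n1, TRUE, prob = c(0.3, 0.5, 0.2))
    if (n2 > 0) reason[has & !yr1] <- sample(reasons, n2, TRUE, prob = c(0.6, 0.2, 0.2))
    data.frame(arm = arm, trial_success = success, responder_6mo = responder,
               complication_6mo = comp6, complication_late = comp_late,
               explant_month = as.integer(explant_month), explant_reason = reason,
               stringsAsFactors = FALSE)
  }
  out <- rbind(one_arm("HF10", "hf10"), one_arm("LF", "lf"))
  out$patient_id <- sprintf("P%05d", seq_len(nrow(out)))
  out[, c("patient_id", "arm", "trial_success", "responder_6mo",
          "complication_6mo", "complication_late", "explant_month", "explant_reason")]
}

wald_ci <- function(k, n) {
  if (is.na(n) || n == 0) return(c(est = NA_real_, lo = NA_real_, hi = NA_real_))
  p <- k / n
  half <- 1.96 * sqrt(p * (1 - p) / n)
  c(est = p, lo = max(0, p - half), hi = min(1, p + half))
}

#' Re-estimate model inputs from patient-level records
#'
#' Computes, per arm, simple proportions with Wald 95% CIs (clipped to
#' \[0, 1\], mirroring the symmetric CI presentation of trial-derived model
#' inputs): screening-trial success among all randomized; 6-month responder,
#' 6-month complication and late-complication proportions among implanted;
#' Year-1 explant probability among implanted and Year-2 explant probability
#' among patients still at risk at month 12. A zero denominator yields `NA`
#' estimates (flagged undefined) rather than zero.
#'
#' @param records Data.frame from [simulate_trial()].
#' @return A data.frame with columns `arm`, `parameter`, `estimate`,
#'   `ci_low`, `ci_high`, `n` (denominator).
#' @export
estimate_inputs <- function(records) {
  stopifnot(all(c("arm", "trial_success", "responder_6mo", "complication_6mo",
                  "complication_late", "explant_month") %in% names(records)))
  arms <- unique(records$arm)
  if (length(arms) == 0) stop("no records supplied")
  rows <- list()
  for (arm in arms) {
    r <- records[records$arm == arm, ]
    n_all <- nrow(r)
    imp <- r[r$trial_success %in% TRUE, ]
    n_imp <- nrow(imp)
    ex1 <- sum(!is.na(imp$explant_month) & imp$explant_month <= 12)
    at_risk_yr2 <- n_imp - ex1
    ex2 <- sum(!is.na(imp$explant_month) & imp$explant_month > 12)
    add <- function(parameter, k, n) {
      ci <- wald_ci(k, n)
      rows[[length(rows) + 1]] <<- data.frame(
        arm = arm, parameter = parameter, estimate = ci[["est"]],
        ci_low = ci[["lo"]], ci_high = ci[["hi"]], n = n, stringsAsFactors = FALSE)
    }
    add("trial_success", sum(r$trial_success), n_all)
    add("p_optimal_6mo", sum(imp$responder_6mo), n_imp)
    add("p_complication_6mo", sum(imp$complication_6mo), n_imp)
    add("p_complication_late", sum(imp$complication_late), n_imp)
    add("explant_yr1", ex1, n_imp)
    add("explant_yr2", ex2, at_risk_yr2)
  }
  do.call(rbind, rows)
}

#' Apply re-estimated inputs to a parameter set
#'
#' Writes the point estimates (and CIs) from [estimate_inputs()] into the
#' corresponding `hf10.*` / `lf.*` parameters, leaving every other parameter
#' at its configured value. Undefined (`NA`) estimates are skipped.
#'
#' @param ps An `scs_params` object.
#' @param estimates Data.frame from [estimate_inputs()].
#' @return A new validated `scs_params` object.
#' @export
apply_estimates <- function(ps, estimates) {
  prefix <- c(HF10 = "hf10", LF = "lf")
  specs <- ps$specs[, c("name", "base", "lo", "hi", "family")]
  specs$family[specs$family == "uniform"] <- "beta"
  vals <- ps$values
  for (i in seq_len(nrow(estimates))) {
    e <- estimates[i, ]
    if (is.na(e$estimate)) next
    nm <- paste0(prefix[[e$arm]], ".", e$parameter)
    if (!nm %in% names(vals)) next
    vals[[nm]] <- e$estimate
    j <- match(nm, specs$name)
    if (!is.na(e$ci_low) && e$ci_low < e$ci_high) {
      specs$lo[j] <- e$ci_low; specs$hi[j] <- e$ci_high
    }
  }
  new_scs_params(vals, specs, ps$schema_version)
}
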