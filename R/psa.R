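# Probabilistic sensitivity analysis: joint beta/gamma sampling of all
# parameters, Monte-Carlo model evaluation, cost-saving probability, and
# cost-effectiveness acceptability curves.

# Deterministic per-draw seed below 2^31, mixing the run seed and draw index.
draw_seed <- function(seed, draw_index) {
  (as.numeric(seed) * 48271 + as.numeric(draw_index) * 16807) %% 2147483563 + 1
}

#' Sample one parameter set for PSA
#'
#' Draws every sampled parameter independently from its fitted distribution
#' (beta for clinical probabilities, gamma for costs and device longevity;
#' fixed parameters and health-state utilities are left unchanged — the
#' probabilistic analysis varies clinical probabilities, costs and device
#' longevity, while utility CIs feed the one-way analyses). The two low-frequency
#' arms share one draw for each pooled clinical parameter (`lf.*`) and draw
#' device cost/longevity separately. Draws are taken in registry order under
#' a seed derived deterministically from `(seed, draw_index)`, so any draw of
#' a run can be reproduced in isolation.
#'
#' @param ps An `scs_params` object with fitted distributions.
#' @param seed Integer run seed.
#' @param draw_index Integer draw number (>= 1).
#' @return A new `scs_params` object with sampled values (distribution fits
#'   are not refitted around the draws).
#' @export
sample_parameter_set <- function(ps, seed, draw_index) {
  sp <- ps$specs
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()), add = TRUE)
  set.seed(draw_seed(seed, draw_index))
  vals <- ps$values
  for (i in seq_len(nrow(sp))) {
    fam <- sp$family[i]
    if (fam == "fixed" || !sp$sampled[i]) next
    x <- switch(fam,
                beta = stats::rbeta(1, sp$par1[i], sp$par2[i]),
                gamma = stats::rgamma(1, shape = sp$par1[i], scale = sp$par2[i]),
                uniform = stats::runif(1, sp$par1[i], sp$par2[i]))
    if (grepl("device_longevity$", sp$name[i])) {
      x <- max(x, ps$values[["cycle_length_years"]])  # at least one cycle
    }
    vals[[sp$name[i]]] <- x
  }
  # the two drug pain-therapy costs (CMM alone, SCS+CMM) are the same cost
  # object measured in two care settings and share one printed uncertainty
  # range (£0-£8412): apply a single uncertainty draw to both by matching
  # percentiles on their fitted gammas
  i_cmm <- match("cost_drug_cmm_6mo", sp$name)
  i_scs <- match("cost_drug_scs_6mo", sp$name)
  if (sp$sampled[i_cmm] && sp$sampled[i_scs]) {
    u <- stats::pgamma(vals[["cost_drug_cmm_6mo"]],
                       shape = sp$par1[i_cmm], scale = sp$par2[i_cmm])
    vals[["cost_drug_scs_6mo"]] <- stats::qgamma(u, shape = sp$par1[i_scs],
                                                 scale = sp$par2[i_scs])
  }
  # the two rechargeable systems (10 kHz and RLF) carry one longevity
  # assumption (10 years, range 8-25): a single uncertain quantity applied to
  # both devices, so their replacement schedules move together in a draw
  vals[["rlf.device_longevity"]] <- vals[["hf10.device_longevity"]]
  # no joint validation here: parameters are sampled independently, so order
  # constraints that hold for the base case (e.g. with-complication utility
  # below without-complication) may be crossed in a draw; supports are
  # guaranteed by the distribution families themselves
  ps$values <- vals
  ps
}

#' Run the probabilistic sensitivity analysis
#'
#' Evaluates the full decision tree + Markov model for all three arms under
#' `n` joint parameter draws. Reports, per comparison (each low-frequency arm
#' versus 10 kHz SCS): the probability that 10 kHz SCS is cost-saving
#' (fraction of draws with positive comparator-minus-reference cost
#' difference), the mean cost difference with a normal-approximation 95% CI
#' (and a percentile interval), and cost-effectiveness acceptability curve
#' points over a willingness-to-pay grid.
#'
#' @param ps An `scs_params` object.
#' @param n Number of draws (default 5000).
#' @param seed Integer seed; identical `(seed, n)` reproduce the result
#'   exactly.
#' @param wtp_grid Willingness-to-pay grid for the CEAC, GBP/QALY.
#' @return A list of class `scs_psa` with `n_draws`, `seed`, `draws` (one row
#'   per draw and comparison), `summary` (per comparison), and `ceac`.
#' @export
run_psa <- function(ps, n = 5000, seed = 1, wtp_grid = seq(0, 50000, by = 1000)) {
  if (n < 1) stop("n must be >= 1")
  arms <- c("HF10", "NRLF", "RLF")
  cost <- matrix(NA_real_, n, 3, dimnames = list(NULL, arms))
  qaly <- matrix(NA_real_, n, 3, dimnames = list(NULL, arms))
  for (d in seq_len(n)) {
    psd <- sample_parameter_set(ps, seed, d)
    for (a in arms) {
      r <- evaluate_arm(psd, a)
      cost[d, a] <- r$total_cost
      qaly[d, a] <- r$total_qalys
    }
  }
  comparisons <- c(NRLF_vs_HF10 = "NRLF", RLF_vs_HF10 = "RLF")
  draws <- do.call(rbind, lapply(names(comparisons), function(cn) {
    a <- comparisons[[cn]]
    data.frame(draw = seq_len(n), comparison = cn,
               delta_cost = cost[, a] - cost[, "HF10"],
               delta_qalys = qaly[, a] - qaly[, "HF10"],
               stringsAsFactors = FALSE)
  }))
  summ <- do.call(rbind, lapply(names(comparisons), function(cn) {
    d <- draws[draws$comparison == cn, ]
    m <- mean(d$delta_cost); sdv <- stats::sd(d$delta_cost)
    half <- 1.96 * sdv / sqrt(n)
    qs <- stats::quantile(d$delta_cost, c(0.025, 0.975), names = FALSE)
    data.frame(comparison = cn,
               prob_cost_saving = mean(d$delta_cost > 0),
               mean_delta_cost = m,
               ci_low = m - half, ci_high = m + half,
               pctl_low = qs[1], pctl_high = qs[2],
               mean_delta_qalys = mean(d$delta_qalys),
               stringsAsFactors = FALSE)
  }))
  res <- structure(list(n_draws = n, seed = seed, draws = draws,
                        arm_costs = cost, arm_qalys = qaly,
                        summary = summ), class = "scs_psa")
  res$ceac <- ceac(res, wtp_grid)
  res
}

#' @export
print.scs_psa <- function(x, ...) {
  cat(sprintf("<scs_psa> %d draws, seed %d\n", x$n_draws, x$seed))
  print(x$summary, row.names = FALSE)
  invisible(x)
}

#' Cost-effectiveness acceptability curve
#'
#' For each willingness-to-pay value, the probability (fraction of draws)
#' that 10 kHz SCS has the higher net monetary benefit than the comparator:
#' `NMB = wtp * QALYs - cost`, so the criterion per draw is
#' `delta_cost - wtp * delta_qalys > 0` with deltas comparator-minus-
#' reference. At `wtp = 0` this reduces to the probability of being
#' cost-saving.
#'
#' @param psa An `scs_psa` object (or any list with a `draws` data.frame).
#' @param wtp_grid Non-negative willingness-to-pay grid, GBP/QALY.
#' @return A data.frame with columns `comparison`, `wtp`, `probability`.
#' @export
ceac <- function(psa, wtp_grid = seq(0, 50000, by = 1000)) {
  draws <- psa$draws
  if (is.null(draws) || nrow(draws) == 0) stop("no PSA draws supplied")
  if (any(wtp_grid < 0)) stop("wtp_grid must be non-negative")
  do.call(rbind, lapply(unique(draws$comparison), function(cn) {
    d <- draws[draws$comparison == cn, ]
    data.frame(comparison = cn, wtp = wtp_grid,
               probability = vapply(wtp_grid, function(w) {
                 mean(d$delta_cost - w * d$delta_qalys > 0)
               }, numeric(1)),
               stringsAsFactors = FALSE)
  }))
}
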