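# Model parameters: registry of base-case values with 95% CIs and PSA sampling
# families, configuration loading/validation, and the rate/discount/distribution
# primitives used by every other module.

#' Parameter registry for the SCS cost-utility model
#'
#' Returns the flat table of model parameters: base-case value, 95% CI (or
#' plausible range) bounds, and the distribution family used when the parameter
#' is sampled in probabilistic sensitivity analysis. Clinical probabilities and
#' utilities use a beta family, costs and device longevity a gamma family;
#' structural settings (discount rate, horizon, cycle length, willingness to
#' pay) are fixed. Reimplantation costs default to `NA`, meaning "track the
#' corresponding implantation cost"; scenario analyses may pin them explicitly.
#'
#' Parameter names are prefixed `hf10.` (10 kHz high-frequency SCS), `lf.`
#' (clinical parameters shared by both low-frequency arms), `nrlf.` / `rlf.`
#' (device-specific cost and longevity of the non-rechargeable and rechargeable
#' low-frequency arms), or unprefixed (shared across all arms).
#'
#' @return A data.frame with columns `name`, `base`, `lo`, `hi`, `family`.
#' @export
parameter_registry <- function() {
  spec <- function(name, base, lo, hi, family) {
    data.frame(name = name, base = base, lo = lo, hi = hi, family = family,
               stringsAsFactors = FALSE)
  }
  rbind(
    # clinical probabilities (beta)
    spec("hf10.trial_success",          0.928, 0.876, 0.979, "beta"),
    spec("lf.trial_success",            0.880, 0.814, 0.947, "beta"),
    spec("hf10.p_optimal_6mo",          0.809, 0.727, 0.891, "beta"),
    spec("lf.p_optimal_6mo",            0.544, 0.435, 0.652, "beta"),
    spec("p_optimal_cmm_6mo",           0.093, 0.084, 0.102, "beta"),
    spec("hf10.p_complication_6mo",     0.337, 0.239, 0.435, "beta"),
    spec("lf.p_complication_6mo",       0.358, 0.254, 0.462, "beta"),
    spec("hf10.p_complication_late",    0.037, 0.006, 0.071, "beta"),
    spec("lf.p_complication_late",      0.128, 0.068, 0.189, "beta"),
    spec("hf10.explant_yr1",            0.044, 0.002, 0.087, "beta"),
    spec("lf.explant_yr1",              0.111, 0.043, 0.180, "beta"),
    spec("hf10.explant_yr2",            0.047, 0.002, 0.091, "beta"),
    spec("lf.explant_yr2",              0.097, 0.029, 0.166, "beta"),
    spec("hf10.explant_yr3plus",        0.032, 0.000, 0.158, "beta"),
    spec("lf.explant_yr3plus",          0.032, 0.000, 0.158, "beta"),
    spec("annual_mortality",            0.0081, 0.007, 0.009, "beta"),
    spec("p_reoperation",               0.050, 0.045, 0.055, "beta"),
    spec("p_optimal_post_reop",         0.190, 0.171, 0.209, "beta"),
    # utilities (beta: bounded on [0,1])
    spec("u_opt_nc",                    0.598, 0.538, 0.658, "beta"),
    spec("u_opt_c",                     0.528, 0.475, 0.581, "beta"),
    spec("u_subopt_nc",                 0.258, 0.232, 0.284, "beta"),
    spec("u_subopt_c",                  0.258, 0.232, 0.284, "beta"),
    spec("u_no_relief",                 0.168, 0.151, 0.185, "beta"),
    # device longevity in years (gamma)
    spec("hf10.device_longevity",       10, 8, 25, "gamma"),
    spec("nrlf.device_longevity",        4, 2,  6, "gamma"),
    spec("rlf.device_longevity",        10, 8, 25, "gamma"),
    # costs, 2016 GBP (gamma)
    spec("cost_trial",                  5281,  3441,  7931, "gamma"),
    spec("cost_failed_trial_removal",   2140,   921,  3593, "gamma"),
    spec("hf10.cost_implant",          16648, 13116, 21421, "gamma"),
    spec("nrlf.cost_implant",          11281,  8888, 14516, "gamma"),
    spec("rlf.cost_implant",           17422, 13726, 22418, "gamma"),
    spec("cost_explant",                2140,     0,  3015, "gamma"),
    spec("cost_complication",            740,   241,  1869, "gamma"),
    spec("cost_drug_cmm_6mo",           3167,     0,  8412, "gamma"),
    spec("cost_nondrug_cmm_6mo",         956,     0,  1157, "gamma"),
    spec("cost_drug_scs_6mo",           2012,     0,  8412, "gamma"),
    spec("cost_nondrug_scs_6mo",          33,     0,    40, "gamma"),
    # fixed structural settings
    spec("cost_reoperation",               0,    NA,    NA, "fixed"),
    spec("hf10.cost_reimplant",           NA,    NA,    NA, "fixed"),
    spec("nrlf.cost_reimplant",           NA,    NA,    NA, "fixed"),
    spec("rlf.cost_reimplant",            NA,    NA,    NA, "fixed"),
    spec("discount_rate",              0.035,    NA,    NA, "fixed"),
    spec("horizon_years",                 15,    NA,    NA, "fixed"),
    spec("cycle_length_years",          0.25,    NA,    NA, "fixed"),
    spec("wtp_per_qaly",               20000,    NA,    NA, "fixed")
  )
}

#' Construct the base-case parameter set
#'
#' Builds a validated parameter set from the registry defaults (the base-case
#' configuration), optionally applying named overrides.
#'
#' @param overrides Named numeric vector or list of parameter replacements.
#' @return An object of class `scs_params`: a list with elements `values`
#'   (named numeric vector), `specs` (the registry with fitted beta/gamma
#'   hyper-parameters), and `schema_version`.
#' @export
#' @examples
#' ps <- default_parameters()
#' unname(ps$values["hf10.trial_success"])
default_parameters <- function(overrides = NULL) {
  reg <- parameter_registry()
  values <- stats::setNames(reg$base, reg$name)
  ps <- new_scs_params(values, reg)
  if (!is.null(overrides)) ps <- set_parameters(ps, overrides)
  ps
}

new_scs_params <- function(values, specs, schema_version = "1.0") {
  ps <- structure(
    list(values = values, specs = specs, schema_version = schema_version),
    class = "scs_params"
  )
  validate_parameters(ps)  # field-level errors before any distribution fitting
  ps$specs <- fit_distributions(values, specs)
  ps
}

# Pre-fit beta/gamma hyper-parameters for every sampled entry so PSA draws are
# a single rbeta/rgamma call. A CI too wide for a beta mean falls back to a
# uniform on [lo, hi], with a warning at load time. Utilities keep a fitted
# beta (their CI bounds drive the one-way analyses) but are not drawn in PSA:
# the probabilistic analysis varies clinical probabilities, costs and device
# longevity.
fit_distributions <- function(values, specs) {
  specs$par1 <- NA_real_
  specs$par2 <- NA_real_
  specs$sampled <- specs$family != "fixed" & !startsWith(specs$name, "u_")
  for (i in seq_len(nrow(specs))) {
    fam <- specs$family[i]
    if (fam == "fixed") next
    m <- values[[specs$name[i]]]
    lo <- specs$lo[i]; hi <- specs$hi[i]
    if (fam == "beta") {
      fit <- tryCatch(fit_beta_ci(m, lo, hi), error = function(e) NULL)
      if (is.null(fit)) {
        warning(sprintf("beta fit failed for '%s'; falling back to uniform on [%g, %g]",
                        specs$name[i], lo, hi))
        specs$family[i] <- "uniform"
        specs$par1[i] <- lo; specs$par2[i] <- hi
      } else {
        specs$par1[i] <- fit[["shape1"]]; specs$par2[i] <- fit[["shape2"]]
      }
    } else if (fam == "gamma") {
      fit <- fit_gamma_ci(m, lo, hi)
      specs$par1[i] <- fit[["shape"]]; specs$par2[i] <- fit[["scale"]]
    }
  }
  specs
}

#' Replace parameter values
#'
#' @param ps An `scs_params` object.
#' @param overrides Named numeric vector or list; every name must exist in the
#'   parameter registry.
#' @param refit Refit PSA distributions around the new values (default `TRUE`).
#'   Sensitivity analyses that probe a single value leave the fitted
#'   distributions untouched.
#' @return A new validated `scs_params` object.
#' @export
set_parameters <- function(ps, overrides, refit = TRUE) {
  overrides <- unlist(overrides)
  unknown <- setdiff(names(overrides), names(ps$values))
  if (length(unknown) > 0) {
    stop("unknown parameter(s): ", paste(unknown, collapse = ", "))
  }
  ps$values[names(overrides)] <- overrides
  if (refit) {
    specs <- ps$specs[, c("name", "base", "lo", "hi", "family")]
    specs$family[specs$family == "uniform"] <- "beta"  # retry the fit
    return(new_scs_params(ps$values, specs, ps$schema_version))
  }
  validate_parameters(ps, check_ordering = FALSE)
  ps
}

#' @export
print.scs_params <- function(x, ...) {
  n_sampled <- sum(x$specs$sampled)
  cat(sprintf("<scs_params> %d parameters (%d sampled in PSA), schema %s\n",
              length(x$values), n_sampled, x$schema_version))
  cat(sprintf("  horizon %g y, cycle %g y, discount %g, WTP %g GBP/QALY\n",
              x$values[["horizon_years"]], x$values[["cycle_length_years"]],
              x$values[["discount_rate"]], x$values[["wtp_per_qaly"]]))
  invisible(x)
}

# Field-level validation; errors name the offending parameter. Ordering
# constraints between utilities are enforced for full configurations but not
# for one-way excursions that move a single utility to a CI bound.
validate_parameters <- function(ps, check_ordering = TRUE) {
  v <- ps$values
  reg <- parameter_registry()
  missing <- setdiff(reg$name, names(v))
  if (length(missing) > 0) {
    stop("configuration is missing parameter(s): ", paste(missing, collapse = ", "))
  }
  prob_names <- grep("^(hf10|lf)\\.(trial_success|p_|explant_)|^p_|^annual_mortality|^u_",
                     names(v), value = TRUE)
  for (nm in prob_names) {
    x <- v[[nm]]
    if (!is.finite(x) || x < 0 || x > 1) {
      stop(sprintf("parameter '%s' must be a probability/utility in [0,1], got %s",
                   nm, format(x)))
    }
  }
  cost_names <- grep("^cost_|\\.cost_implant$", names(v), value = TRUE)
  for (nm in cost_names) {
    if (!is.finite(v[[nm]]) || v[[nm]] < 0) {
      stop(sprintf("parameter '%s' must be a non-negative cost, got %s", nm, format(v[[nm]])))
    }
  }
  for (nm in grep("device_longevity$", names(v), value = TRUE)) {
    if (!is.finite(v[[nm]]) || v[[nm]] <= 0) {
      stop(sprintf("parameter '%s' must be a positive duration, got %s", nm, format(v[[nm]])))
    }
  }
  cyc <- v[["cycle_length_years"]]; hor <- v[["horizon_years"]]
  if (!is.finite(cyc) || cyc <= 0 || cyc > 1) {
    stop("parameter 'cycle_length_years' must lie in (0, 1]")
  }
  if (abs(hor / cyc - round(hor / cyc)) > 1e-9) {
    stop("parameter 'horizon_years' must be an integer multiple of 'cycle_length_years'")
  }
  if (v[["discount_rate"]] < 0) stop("parameter 'discount_rate' must be >= 0")
  if (check_ordering) {
    if (v[["u_opt_c"]] > v[["u_opt_nc"]] + 1e-12) {
      stop("parameter 'u_opt_c' must not exceed 'u_opt_nc'")
    }
    if (v[["u_subopt_c"]] > v[["u_subopt_nc"]] + 1e-12) {
      stop("parameter 'u_subopt_c' must not exceed 'u_subopt_nc'")
    }
  }
  invisible(ps)
}

#' Load a parameter configuration from JSON
#'
#' Reads a configuration document (see `inst/extdata/base_case.json` for the
#' packaged base case) with a `schema_version` field and a `parameters` array
#' of `{name, value, ci_low, ci_high, family}` records. Every registry
#' parameter must be present; values are validated and a violation is reported
#' with the offending field name.
#'
#' @param path Path to a JSON configuration file.
#' @return A validated `scs_params` object.
#' @export
load_parameters <- function(path) {
  if (!file.exists(path)) stop("configuration file not found: ", path)
  doc <- jsonlite::fromJSON(path, simplifyDataFrame = TRUE)
  if (is.null(doc$schema_version)) stop("configuration is missing field 'schema_version'")
  if (is.null(doc$parameters)) stop("configuration is missing field 'parameters'")
  pars <- doc$parameters
  for (fld in c("name", "value")) {
    if (is.null(pars[[fld]])) stop("configuration parameters are missing field '", fld, "'")
  }
  reg <- parameter_registry()
  missing <- setdiff(reg$name, pars$name)
  if (length(missing) > 0) {
    stop("configuration is missing parameter(s): ", paste(missing, collapse = ", "))
  }
  idx <- match(reg$name, pars$name)
  values <- stats::setNames(as.numeric(pars$value[idx]), reg$name)
  if (!is.null(pars$ci_low)) reg$lo <- ifelse(is.na(pars$ci_low[idx]), reg$lo, pars$ci_low[idx])
  if (!is.null(pars$ci_high)) reg$hi <- ifelse(is.na(pars$ci_high[idx]), reg$hi, pars$ci_high[idx])
  if (!is.null(pars$family)) {
    fam <- pars$family[idx]
    bad <- !is.na(fam) & !fam %in% c("beta", "gamma", "fixed")
    if (any(bad)) stop("unknown distribution family for: ",
                       paste(reg$name[bad], collapse = ", "))
    reg$family <- ifelse(is.na(fam), reg$family, fam)
  }
  new_scs_params(values, reg, as.character(doc$schema_version))
}

#' Write a parameter configuration to JSON
#'
#' @param ps An `scs_params` object.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_parameters <- function(ps, path) {
  doc <- list(
    schema_version = ps$schema_version,
    parameters = data.frame(
      name = ps$specs$name,
      value = unname(ps$values[ps$specs$name]),
      ci_low = ps$specs$lo,
      ci_high = ps$specs$hi,
      family = ps$specs$family,
      stringsAsFactors = FALSE
    )
  )
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA, na = "null", pretty = TRUE)
  invisible(path)
}

#' Per-arm parameter view
#'
#' Collects the clinical and device parameters applicable to one comparator
#' arm. The two low-frequency arms share clinical parameters (`lf.*`) and
#' differ only in device cost and longevity. A reimplantation cost left `NA`
#' resolves to the arm's implantation cost (the base-case assumption).
#'
#' @param ps An `scs_params` object.
#' @param arm One of `"HF10"`, `"NRLF"`, `"RLF"`.
#' @return A named list of arm-level parameters.
#' @export
arm_parameters <- function(ps, arm) {
  arm <- match.arg(arm, c("HF10", "NRLF", "RLF"))
  v <- ps$values
  clin <- if (arm == "HF10") "hf10" else "lf"
  dev <- switch(arm, HF10 = "hf10", NRLF = "nrlf", RLF = "rlf")
  g <- function(p, f) v[[paste0(p, ".", f)]]
  reimp <- g(dev, "cost_reimplant")
  if (is.na(reimp)) reimp <- g(dev, "cost_implant")
  list(
    arm = arm,
    trial_success = g(clin, "trial_success"),
    p_optimal_6mo = g(clin, "p_optimal_6mo"),
    p_complication_6mo = g(clin, "p_complication_6mo"),
    explant_yr1 = g(clin, "explant_yr1"),
    explant_yr2 = g(clin, "explant_yr2"),
    explant_yr3plus = g(clin, "explant_yr3plus"),
    p_complication_late_annual = g(clin, "p_complication_late"),
    device_longevity_years = g(dev, "device_longevity"),
    cost_implant = g(dev, "cost_implant"),
    cost_reimplant = reimp
  )
}

#' Convert an annual probability to a per-cycle probability
#'
#' Assumes a constant hazard within the year: the per-cycle probability is
#' `1 - (1 - p_annual)^cycle_length_years`, so that compounding over the
#' year's cycles recovers the annual probability.
#'
#' @param p_annual Annual event probability in \[0, 1\].
#' @param cycle_length_years Cycle length in years (> 0).
#' @return Per-cycle probability.
#' @export
#' @examples
#' annual_to_cycle_prob(0.0081, 0.25)
annual_to_cycle_prob <- function(p_annual, cycle_length_years) {
  if (any(!is.finite(p_annual)) || any(p_annual < 0) || any(p_annual > 1)) {
    stop("p_annual must lie in [0, 1]")
  }
  if (any(cycle_length_years <= 0)) stop("cycle_length_years must be > 0")
  1 - (1 - p_annual)^cycle_length_years
}

#' Discount factor at a point in time
#'
#' @param t_years Time in years (>= 0).
#' @param rate Annual discount rate (default 3.5%, applied to both costs and
#'   outcomes).
#' @return `(1 + rate)^(-t_years)`.
#' @export
discount_factor <- function(t_years, rate = 0.035) {
  if (any(t_years < 0)) stop("t_years must be >= 0")
  (1 + rate)^(-t_years)
}

#' Fit a beta distribution from a mean and 95% CI
#'
#' Method of moments: the CI width is converted to a standard error with the
#' normal-approximation divisor 3.92, then `nu = mean (1 - mean) / SE^2 - 1`,
#' `shape1 = mean * nu`, `shape2 = (1 - mean) * nu`. The fitted mean equals
#' the input mean exactly.
#'
#' @param mean Mean in (0, 1).
#' @param ci_low,ci_high 95% CI bounds (`ci_low < ci_high`).
#' @return Named numeric vector `c(shape1, shape2)`.
#' @export
#' @examples
#' fit_beta_ci(0.928, 0.876, 0.979)
fit_beta_ci <- function(mean, ci_low, ci_high) {
  if (!is.finite(mean) || mean <= 0 || mean >= 1) stop("mean must lie in (0, 1)")
  if (!(ci_low < ci_high)) stop("ci_low must be < ci_high")
  se <- (ci_high - ci_low) / 3.92
  nu <- mean * (1 - mean) / se^2 - 1
  if (nu <= 0) {
    cond <- structure(
      class = c("scscea_fit_error", "error", "condition"),
      list(message = sprintf(
        "CI too wide for a beta with mean %g; fall back to a uniform on [%g, %g]",
        mean, ci_low, ci_high), call = sys.call(-1))
    )
    stop(cond)
  }
  c(shape1 = mean * nu, shape2 = (1 - mean) * nu)
}

#' Fit a gamma distribution from a mean and 95% CI
#'
#' Method of moments with `SE = (ci_high - ci_low) / 3.92`:
#' `shape = mean^2 / SE^2`, `scale = SE^2 / mean`. `shape * scale` reproduces
#' the input mean exactly.
#'
#' @param mean Mean (> 0).
#' @param ci_low,ci_high 95% CI or range bounds (`ci_low < ci_high`).
#' @return Named numeric vector `c(shape, scale)`.
#' @export
#' @examples
#' fit_gamma_ci(5281, 3441, 7931)
fit_gamma_ci <- function(mean, ci_low, ci_high) {
  if (!is.finite(mean) || mean <= 0) stop("mean must be > 0")
  if (!(ci_low < ci_high)) stop("ci_low must be < ci_high")
  se <- (ci_high - ci_low) / 3.92
  c(shape = mean^2 / se^2, scale = se^2 / mean)
}
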