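test_that("default parameter set carries the base-case inputs and validates", {
  ps <- default_parameters()
  expect_s3_class(ps, "scs_params")
  expect_equal(unname(ps$values["hf10.trial_success"]), 0.928)
  expect_equal(unname(ps$values["nrlf.cost_implant"]), 11281)
  expect_equal(unname(ps$values["u_opt_nc"]), 0.598)
  a <- arm_parameters(ps, "NRLF")
  expect_equal(a$trial_success, 0.880)
  expect_equal(a$device_longevity_years, 4)
  # base case: reimplantation priced at the implantation cost
  expect_equal(a$cost_reimplant, a$cost_implant)
  # the two LF arms share clinical parameters
  r <- arm_parameters(ps, "RLF")
  expect_equal(r$explant_yr2, a$explant_yr2)
  expect_false(r$cost_implant == a$cost_implant)
})

test_that("validation names the offending field", {
  ps <- default_parameters()
  expect_error(set_parameters(ps, c(hf10.trial_success = 1.2)), "hf10.trial_success")
  expect_error(set_parameters(ps, c(cost_trial = -5)), "cost_trial")
  expect_error(set_parameters(ps, c(nonexistent_par = 1)), "nonexistent_par")
  expect_error(set_parameters(ps, c(nrlf.device_longevity = 0)), "nrlf.device_longevity")
})

test_that("JSON configuration round-trips and schema errors name fields", {
  ps <- default_parameters()
  path <- withr::local_tempfile(fileext = ".json")
  write_parameters(ps, path)
  ps2 <- load_parameters(path)
  expect_equal(ps2$values, ps$values)
  expect_equal(ps2$specs$family, ps$specs$family)

  doc <- jsonlite::fromJSON(path, simplifyDataFrame = TRUE)
  doc$parameters <- doc$parameters[doc$parameters$name != "cost_trial", ]
  path2 <- withr::local_tempfile(fileext = ".json")
  jsonlite::write_json(doc, path2, auto_unbox = TRUE, digits = NA, na = "null")
  expect_error(load_parameters(path2), "cost_trial")
  expect_error(load_parameters("no/such/file.json"), "not found")

  pkg_cfg <- system.file("extdata", "base_case.json", package = "scscea")
  expect_equal(load_parameters(pkg_cfg)$values, ps$values)
})

test_that("annual-to-cycle conversion follows the constant-hazard closed form", {
  expect_equal(annual_to_cycle_prob(0, 0.25), 0)
  expect_equal(annual_to_cycle_prob(1, 0.25), 1)
  expect_equal(annual_to_cycle_prob(0.0081, 0.25), 0.0020312, tolerance = 1e-4)
  expect_error(annual_to_cycle_prob(1.2, 0.25), "\\[0, 1\\]")
  # compounding four quarterly cycles recovers the annual probability
  for (p in c(0.0081, 0.044, 0.111, 0.32, 0.9)) {
    q <- annual_to_cycle_prob(p, 0.25)
    expect_equal(1 - (1 - q)^4, p, tolerance = 1e-12)
  }
})

test_that("discount factor matches closed forms and is monotone", {
  expect_equal(discount_factor(0, 0.035), 1)
  expect_equal(discount_factor(1, 0.035), 1 / 1.035)
  expect_equal(discount_factor(15, 0.035), 1.035^-15)
  expect_equal(discount_factor(15, 0.035), 0.59689, tolerance = 1e-5)
  t <- seq(0, 20, by = 0.25)
  expect_true(all(diff(discount_factor(t, 0.035)) < 0))
  expect_true(all(discount_factor(t, 0) == 1))
  expect_error(discount_factor(-1), ">= 0")
})

test_that("beta fit from a CI reproduces the requested moments", {
  # symmetric case: mean 0.5 with SE 0.05 gives shape1 = shape2 = 49.5
  f <- fit_beta_ci(0.5, 0.5 - 1.96 * 0.05, 0.5 + 1.96 * 0.05)
  expect_equal(unname(f), c(49.5, 49.5), tolerance = 1e-9)
  # the trial-success row of the input table
  f <- fit_beta_ci(0.928, 0.876, 0.979)
  expect_equal(unname(f), c(88.88, 6.896), tolerance = 1e-3)
  m <- f[1] / (f[1] + f[2])
  expect_equal(unname(m), 0.928, tolerance = 1e-12)
  expect_error(fit_beta_ci(1.1, 0, 1), "\\(0, 1\\)")
  # CI too wide for the mean signals a fit error prescribing a uniform fallback
  expect_error(fit_beta_ci(0.01, 0, 0.9), class = "scscea_fit_error")
})

test_that("gamma fit from a CI reproduces the requested moments", {
  f <- fit_gamma_ci(100, 100 - 1.96 * 10, 100 + 1.96 * 10)
  expect_equal(unname(f), c(100, 1), tolerance = 1e-9)
  f <- fit_gamma_ci(5281, 3441, 7931)
  se <- (7931 - 3441) / 3.92
  expect_equal(unname(f[1]), (5281 / se)^2, tolerance = 1e-12)
  expect_equal(unname(f[1] * f[2]), 5281, tolerance = 1e-9)
  expect_error(fit_gamma_ci(0, 1, 2), "> 0")
})

test_that("fitted distributions round-trip mean and SD for every sampled parameter", {
  ps <- default_parameters()
  sp <- ps$specs[ps$specs$family %in% c("beta", "gamma"), ]
  for (i in seq_len(nrow(sp))) {
    m <- ps$values[[sp$name[i]]]
    se <- (sp$hi[i] - sp$lo[i]) / 3.92
    if (sp$family[i] == "beta") {
      a <- sp$par1[i]; b <- sp$par2[i]
      expect_equal(a / (a + b), m, tolerance = 1e-9, label = sp$name[i])
      expect_equal(sqrt(a * b / ((a + b)^2 * (a + b + 1))), se, tolerance = 1e-9,
                   label = sp$name[i])
    } else {
      expect_equal(sp$par1[i] * sp$par2[i], m, tolerance = 1e-9, label = sp$name[i])
      expect_equal(sqrt(sp$par1[i]) * sp$par2[i], se, tolerance = 1e-9,
                   label = sp$name[i])
    }
  }
})
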