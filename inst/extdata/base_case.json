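{
  "schema_version": "1.0",
  "parameters": [
    {
      "name": "hf10.trial_success",
      "value": 0.928,
      "ci_low": 0.876,
      "ci_high": 0.979,
      "family": "beta"
    },
    {
      "name": "lf.trial_success",
      "value": 0.88,
      "ci_low": 0.814,
      "ci_high": 0.947,
      "family": "beta"
    },
    {
      "name": "hf10.p_optimal_6mo",
      "value": 0.809,
      "ci_low": 0.727,
      "ci_high": 0.891,
      "family": "beta"
    },
    {
      "name": "lf.p_optimal_6mo",
      "value": 0.544,
      "ci_low": 0.435,
      "ci_high": 0.652,
      "family": "beta"
    },
    {
      "name": "p_optimal_cmm_6mo",
      "value": 0.093,
      "ci_low": 0.084,
      "ci_high": 0.102,
      "family": "beta"
    },
    {
      "name": "hf10.p_complication_6mo",
      "value": 0.337,
      "ci_low": 0.239,
      "ci_high": 0.435,
      "family": "beta"
    },
    {
      "name": "lf.p_complication_6mo",
      "value": 0.358,
      "ci_low": 0.254,
      "ci_high": 0.462,
      "family": "beta"
    },
    {
      "name": "hf10.p_complication_late",
      "value": 0.037,
      "ci_low": 0.006,
      "ci_high": 0.071,
      "family": "beta"
    },
    {
      "name": "lf.p_complication_late",
      "value": 0.128,
      "ci_low": 0.068,
      "ci_high": 0.189,
      "family": "beta"
    },
    {
      "name": "hf10.explant_yr1",
      "value": 0.044,
      "ci_low": 0.002,
      "ci_high": 0.087,
      "family": "beta"
    },
    {
      "name": "lf.explant_yr1",
      "value": 0.111,
      "ci_low": 0.043,
      "ci_high": 0.18,
      "family": "beta"
    },
    {
      "name": "hf10.explant_yr2",
      "value": 0.047,
      "ci_low": 0.002,
      "ci_high": 0.091,
      "family": "beta"
    },
    {
      "name": "lf.explant_yr2",
      "value": 0.097,
      "ci_low": 0.029,
      "ci_high": 0.166,
      "family": "beta"
    },
    {
      "name": "hf10.explant_yr3plus",
      "value": 0.032,
      "ci_low": 0,
      "ci_high": 0.158,
      "family": "beta"
    },
    {
      "name": "lf.explant_yr3plus",
      "value": 0.032,
      "ci_low": 0,
      "ci_high": 0.158,
      "family": "beta"
    },
    {
      "name": "annual_mortality",
      "value": 0.0081,
      "ci_low": 0.007,
      "ci_high": 0.009,
      "family": "beta"
    },
    {
      "name": "p_reoperation",
      "value": 0.05,
      "ci_low": 0.045,
      "ci_high": 0.055,
      "family": "beta"
    },
    {
      "name": "p_optimal_post_reop",
      "value": 0.19,
      "ci_low": 0.171,
      "ci_high": 0.209,
      "family": "beta"
    },
    {
      "name": "u_opt_nc",
      "value": 0.598,
      "ci_low": 0.538,
      "ci_high": 0.658,
      "family": "beta"
    },
    {
      "name": "u_opt_c",
      "value": 0.528,
      "ci_low": 0.475,
      "ci_high": 0.581,
      "family": "beta"
    },
    {
      "name": "u_subopt_nc",
      "value": 0.258,
      "ci_low": 0.232,
      "ci_high": 0.284,
      "family": "beta"
    },
    {
      "name": "u_subopt_c",
      "value": 0.258,
      "ci_low": 0.232,
      "ci_high": 0.284,
      "family": "beta"
    },
    {
      "name": "u_no_relief",
      "value": 0.168,
      "ci_low": 0.151,
      "ci_high": 0.185,
      "family": "beta"
    },
    {
      "name": "hf10.device_longevity",
      "value": 10,
      "ci_low": 8,
      "ci_high": 25,
      "family": "gamma"
    },
    {
      "name": "nrlf.device_longevity",
      "value": 4,
      "ci_low": 2,
      "ci_high": 6,
      "family": "gamma"
    },
    {
      "name": "rlf.device_longevity",
      "value": 10,
      "ci_low": 8,
      "ci_high": 25,
      "family": "gamma"
    },
    {
      "name": "cost_trial",
      "value": 5281,
      "ci_low": 3441,
      "ci_high": 7931,
      "family": "gamma"
    },
    {
      "name": "cost_failed_trial_removal",
      "value": 2140,
      "ci_low": 921,
      "ci_high": 3593,
      "family": "gamma"
    },
    {
      "name": "hf10.cost_implant",
      "value": 16648,
      "ci_low": 13116,
      "ci_high": 21421,
      "family": "gamma"
    },
    {
      "name": "nrlf.cost_implant",
      "value": 11281,
      "ci_low": 8888,
      "ci_high": 14516,
      "family": "gamma"
    },
    {
      "name": "rlf.cost_implant",
      "value": 17422,
      "ci_low": 13726,
      "ci_high": 22418,
      "family": "gamma"
    },
    {
      "name": "cost_explant",
      "value": 2140,
      "ci_low": 0,
      "ci_high": 3015,
      "family": "gamma"
    },
    {
      "name": "cost_complication",
      "value": 740,
      "ci_low": 241,
      "ci_high": 1869,
      "family": "gamma"
    },
    {
      "name": "cost_drug_cmm_6mo",
      "value": 3167,
      "ci_low": 0,
      "ci_high": 8412,
      "family": "gamma"
    },
    {
      "name": "cost_nondrug_cmm_6mo",
      "value": 956,
      "ci_low": 0,
      "ci_high": 1157,
      "family": "gamma"
    },
    {
      "name": "cost_drug_scs_6mo",
      "value": 2012,
      "ci_low": 0,
      "ci_high": 8412,
      "family": "gamma"
    },
    {
      "name": "cost_nondrug_scs_6mo",
      "value": 33,
      "ci_low": 0,
      "ci_high": 40,
      "family": "gamma"
    },
    {
      "name": "cost_reoperation",
      "value": 0,
      "ci_low": null,
      "ci_high": null,
      "family": "fixed"
    },
    {
      "name": "hf10.cost_reimplant",
      "value": null,
      "ci_low": null,
      "ci_high": null,
      "family": "fixed"
    },
    {
      "name": "nrlf.cost_reimplant",
      "value": null,
      "ci_low": null,
      "ci_high": null,
      "family": "fixed"
    },
    {
      "name": "rlf.cost_reimplant",
      "value": null,
      "ci_low": null,
      "ci_high": null,
      "family": "fixed"
    },
    {
      "name": "discount_rate",
      "value": 0.035,
      "ci_low": null,
      "ci_high": null,
      "family": "fixed"
    },
    {
      "name": "horizon_years",
      "value": 15,
      "ci_low": null,
      "ci_high": null,
      "family": "fixed"
    },
    {
      "name": "cycle_length_years",
      "value": 0.25,
      "ci_low": null,
      "ci_high": null,
      "family": "fixed"
    },
    {
      "name": "wtp_per_qaly",
      "value": 20000,
      "ci_low": null,
      "ci_high": null,
      "family": "fixed"
    }
  ]
}
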