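#!/usr/bin/env Rscript
# Stage 2 — base-case deterministic cost-consequence and cost-utility
# analysis: 15-year discounted totals per arm, cost breakdowns, incremental
# comparisons and dominance classification. Writes tables and the per-cycle
# Markov traces under results/base_case/.

suppressPackageStartupMessages(library(scscea))

out_dir <- "results/base_case"
ps <- load_parameters(system.file("extdata", "base_case.json", package = "scscea"))
res <- evaluate_all(ps)
tabs <- summary_tables(res)

write_result_csv(tabs$arms, file.path(out_dir, "arm_totals.csv"))
write_result_csv(tabs$comparisons, file.path(out_dir, "comparisons.csv"))
for (a in names(res$arms)) {
  write_trace_csv(res$arms[[a]]$long_term, file.path(out_dir, paste0("trace_", a, ".csv")))
  bs <- res$arms[[a]]$by_state
  write_result_csv(data.frame(state = names(bs), cost = unname(bs)),
                   file.path(out_dir, paste0("cost_by_state_", a, ".csv")))
}
write_manifest(out_dir, ps, "base-case")

message("Base-case 15-year discounted results (3.5% discount):")
for (a in c("HF10", "NRLF", "RLF")) {
  r <- res$arms[[a]]
  message(sprintf("  %-5s total cost £%s, total QALYs %.3f",
                  a, format(round(r$total_cost), big.mark = ","), r$total_qalys))
}
for (cmp in res$comparisons) {
  message(sprintf("  %s vs %s: Δcost £%s, ΔQALYs %.3f — %s",
                  cmp$comparator, cmp$reference,
                  format(round(cmp$delta_cost), big.mark = ","), cmp$delta_qalys,
                  if (cmp$classification == "reference_dominant")
                    paste(cmp$comparator, "dominated (costlier, fewer QALYs)")
                  else paste("ICER", round(cmp$icer))))
}
message(sprintf("  Device-related complication costs: HF10 £%.0f, NRLF £%.0f, RLF £%.0f",
                res$arms$HF10$breakdown[["complications"]],
                res$arms$NRLF$breakdown[["complications"]],
                res$arms$RLF$breakdown[["complications"]]))
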