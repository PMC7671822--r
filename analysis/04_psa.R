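#!/usr/bin/env Rscript
# Stage 4 — probabilistic sensitivity analysis: 5000 joint draws (beta for
# clinical probabilities, gamma for costs and device longevity), cost-saving
# probability and mean saving per comparison, CE-plane samples and
# cost-effectiveness acceptability curves. Writes CSV/JSON summaries (and
# plots, when ggplot2 is available) under results/psa/.

suppressPackageStartupMessages(library(scscea))

out_dir <- "results/psa"
seed <- 2026
n <- 5000
ps <- default_parameters()

message(sprintf("Running PSA: %d draws, seed %d ...", n, seed))
psa <- run_psa(ps, n = n, seed = seed)

write_result_csv(psa$draws, file.path(out_dir, "ce_plane_draws.csv"))
write_result_csv(psa$summary, file.path(out_dir, "summary.csv"))
write_result_csv(psa$ceac, file.path(out_dir, "ceac.csv"))
jsonlite::write_json(psa$summary, file.path(out_dir, "summary.json"),
                     auto_unbox = TRUE, digits = NA, dataframe = "rows")

for (i in seq_len(nrow(psa$summary))) {
  s <- psa$summary[i, ]
  message(sprintf("  %s: P(cost-saving) = %.1f%%, mean saving £%s (95%% CI £%s-£%s)",
                  s$comparison, 100 * s$prob_cost_saving,
                  format(round(s$mean_delta_cost), big.mark = ","),
                  format(round(s$ci_low), big.mark = ","),
                  format(round(s$ci_high), big.mark = ",")))
}
at20k <- ceac(psa, 20000)
message(sprintf("  CEAC at £20,000/QALY: %s",
                paste(sprintf("%s %.1f%%", at20k$comparison, 100 * at20k$probability),
                      collapse = ", ")))

if (requireNamespace("ggplot2", quietly = TRUE)) {
  library(ggplot2)
  p1 <- ggplot(psa$draws, aes(delta_qalys, delta_cost)) +
    geom_point(alpha = 0.15, size = 0.4) +
    geom_hline(yintercept = 0, linetype = 2) +
    geom_vline(xintercept = 0, linetype = 2) +
    facet_wrap(~comparison) +
    labs(x = "Incremental QALYs (comparator - 10 kHz)",
         y = "Incremental cost, GBP (comparator - 10 kHz)",
         title = "Cost-effectiveness plane, 5000 PSA draws") +
    theme_bw()
  ggsave(file.path(out_dir, "ce_plane.png"), p1, width = 9, height = 4.5, dpi = 150)
  p2 <- ggplot(psa$ceac, aes(wtp, probability, colour = comparison)) +
    geom_line() +
    geom_vline(xintercept = 20000, linetype = 3) +
    coord_cartesian(ylim = c(0, 1)) +
    labs(x = "Willingness to pay, GBP per QALY",
         y = "P(10 kHz SCS cost-effective)",
         title = "Cost-effectiveness acceptability curves") +
    theme_bw()
  ggsave(file.path(out_dir, "ceac.png"), p2, width = 7, height = 4.5, dpi = 150)
}
write_manifest(out_dir, ps, "psa", seed)
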