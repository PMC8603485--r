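#!/usr/bin/env Rscript
# Stage-2 sequential design: solves the two-stage error-spending boundaries
# (HSD gamma -4 efficacy / -2 binding futility, two-sided alpha 0.05, power
# 0.8, interim at half the information) and tabulates the design, the
# t-scale boundary conversion, the expected sample sizes, and the pilot
# margin-of-error planning numbers.

library(adherepilot)
out_dir <- "results/design"
dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

spec <- design_spec(info_fractions = c(0.5, 1), alpha_total = 0.05,
                    beta = 0.2, gamma_upper = -4, gamma_lower = -2,
                    n_fix = 62)
bounds <- solve_boundaries(spec)
print(bounds)

es <- fixed_sample_theta(spec$n_fix, spec$alpha_total, spec$beta)
cat(sprintf("\nFixed-design effect size: theta = %.4f, Hedges g = %.2f\n",
            es$theta, es$hedges_g))
cat(sprintf("Expected N: %.1f under the design alternative, %.1f under the null\n",
            expected_sample_size(bounds, bounds$theta),
            expected_sample_size(bounds, 0)))
cat(sprintf("Pilot margins of error (95%%): %.2f sd (n=10), %.2f sd (10+10), %.2f sd (8+8)\n",
            margin_of_error(10), margin_of_error(10, 10),
            margin_of_error(8, 8)))

write_design_json(bounds, file.path(out_dir, "design.json"))
write.csv(design_report_table(bounds),
          file.path(out_dir, "design_report.csv"), row.names = FALSE)
cat("\nwrote", file.path(out_dir, c("design.json", "design_report.csv")), "\n")
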