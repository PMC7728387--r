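#!/usr/bin/env Rscript
# Closed-form assay statistics: growth-curve doubling times over the 3-7.5 h
# window, delta delta Ct relative expression against a TDH3-like reference,
# total-protein and WT normalizations, and an ANOVA + Tukey comparison.

library(phenoscope)
dir.create("results", showWarnings = FALSE)

# growth: a WT-like and a slow-growing strain, 3 replicates each
curves <- do.call(rbind, lapply(1:3, function(r) {
  rbind(generate_growth_curve(0.1, 1.6, interval_min = 15, duration_h = 24,
                              noise_sd = 0.004, seed = 10 + r,
                              strain = "WT", replicate = r),
        generate_growth_curve(0.1, 2.1, interval_min = 15, duration_h = 24,
                              noise_sd = 0.004, seed = 20 + r,
                              strain = "slow", replicate = r))
}))
write.csv(curves, "results/growth_curves.csv", row.names = FALSE)
dt <- aggregate(od600 ~ strain + replicate, curves, function(x) NA)
dt$doubling_h <- mapply(function(s, r) {
  cc <- curves[curves$strain == s & curves$replicate == r, ]
  doubling_time(cc$time_h, cc$od600)
}, dt$strain, dt$replicate)
dt$od600 <- NULL
write.csv(dt, "results/doubling_times.csv", row.names = FALSE)
cat("Doubling times (h):\n")
print(aggregate(doubling_h ~ strain, dt, mean))

# qPCR: mutant with one extra cycle of target enrichment => 2-fold
ct <- data.frame(strain = rep(c("WT", "mutant"), each = 4),
                 replicate = rep(1:4, 2),
                 ct_target = c(20.1, 19.9, 20.0, 20.0, 19.1, 18.9, 19.0, 19.0),
                 ct_reference = 15)
dd <- delta_delta_ct(ct)
write.csv(dd$per_replicate, "results/qpcr_relative_expression.csv",
          row.names = FALSE)
cat("Relative expression (ddCt):\n")
print(dd$per_strain)

# western-style normalization and WT-relative glycogen-like readout
band <- c(WT = 12, mutant = 180)
total <- c(WT = 100, mutant = 100)
norm <- normalize_to_total(band, total)
fold <- normalize_to_wt(norm, names(norm))
cat(sprintf("Mutant band signal: %.1f-fold over WT after total-protein normalization.\n",
            fold["mutant"]))

# three-group comparison of the doubling times plus a rescued strain
set.seed(3)
groups <- list(WT = rnorm(6, 1.6, 0.05), slow = rnorm(6, 2.1, 0.05),
               rescued = rnorm(6, 1.65, 0.05))
res <- anova_tukey(groups)
write.table(res$tukey, "results/doubling_anova_tukey.tsv", sep = "\t",
            row.names = FALSE, quote = FALSE)
cat(sprintf("ANOVA F = %.1f (p = %.2g); Tukey pairs:\n", res$F, res$p_value))
print(res$tukey)
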