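#!/usr/bin/env Rscript
# Stage 3 — ROI-mean 23Na relaxometry for one subject.
#
# Fits the saturation-recovery T1 model to the five protocol-1 TRs and
# the constrained biexponential T2* model to the twelve protocol-2 TEs,
# per tendon region, on sensitivity-corrected ROI means. Writes a
# relaxometry table shaped like the study's first summary table.

library(sodiumAT)

seed <- 1L
dir_in <- file.path("results", sprintf("study_seed%d", seed))
if (!dir.exists(dir_in)) stop("run analysis/01_simulate.R first")
study <- load_study(dir_in)

smap <- estimate_sensitivity_map(study$volumes$sensitivity)
p1 <- lapply(study$volumes$p1, apply_sensitivity_correction, map = smap)
p2 <- lapply(study$volumes$p2, apply_sensitivity_correction, map = smap)

regions <- list(INS = "INS", MID = "MID", MTJ = "MTJ",
                Total = c("INS", "MID", "MTJ"))
rows <- lapply(names(regions), function(rg) {
  s1 <- roi_mean_series(p1, study$coarse_mask, regions[[rg]])
  f1 <- fit_t1_saturation_recovery(s1$times_ms, s1$signals)
  s2 <- roi_mean_series(p2, study$coarse_mask, regions[[rg]])
  f2 <- fit_t2star_biexponential(s2$times_ms, s2$signals)
  data.frame(roi = rg, t1_ms = f1$params$t1_ms, r2_t1 = f1$r_squared,
             t2s_ms = f2$params$t2s_ms, t2l_ms = f2$params$t2l_ms,
             ps_pct = 100 * f2$params$ps, r2_t2 = f2$r_squared)
})
tab <- do.call(rbind, rows)
write_table(tab, "results/table1_relaxometry.csv")
print(tab, digits = 3)
cat("\nGenerating values: T1 18.4/19.2/23.3 ms, T2s* 1.4-1.5 ms,\n")
cat("T2l* 14.2-14.6 ms, ps 30-33% for INS/MID/MTJ.\n")
cat("-> results/table1_relaxometry.csv\n")
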