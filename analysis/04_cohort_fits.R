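#!/usr/bin/env Rscript
# Synthetic 24-patient cohort (18 at 35 mg/day, 6 at 20 mg/day, sparse
# noisy VAF series) fitted under the three drug-effect hypotheses.
# Findings: allowing ruxolitinib to act on both the malignant stem-cell
# cytokine response (s_y0) and the malignant progenitor death rate (d_y1)
# fits far better than either effect alone; patients simulated without a
# stem-cell effect and observed long enough to relapse are recovered at
# the rho_sy0 = 0 boundary.

library(mpnrux)
dir.create("results", showWarnings = FALSE)

params <- mpn_params()
cohort <- generate_cohort(cohort_spec(seed = 1), params,
                          dir = "results/cohort")

fits <- suppressWarnings(
  lapply(cohort$series, fit_patient_all_modes, params = params))

tab <- do.call(rbind, lapply(names(fits), function(id) {
  do.call(rbind, lapply(fits[[id]], function(f) {
    data.frame(patient_id = id, mode = f$mode, dose_mg_per_day = f$dose,
               rho_sy0_per_mg_day = f$rho_sy0,
               rho_dy1_per_mg_day = f$rho_dy1,
               s_y0_eff = f$s_y0_eff, fold_sy0 = f$fold_sy0,
               d_y1_eff_per_day = f$d_y1_eff, fold_dy1 = f$fold_dy1,
               rmse_vaf = f$rmse)
  }))
}))
write.csv(tab, "results/cohort_fits.csv", row.names = FALSE)

for (md in c("both", "dy1_only", "sy0_only")) {
  cat(sprintf("mean RMSE (%s): %.4f\n", md,
              mean(tab$rmse_vaf[tab$mode == md])))
}

both_fits <- lapply(fits, `[[`, "both")
cs <- cohort_summary(both_fits)
summary_tab <- data.frame(
  mean_fold_sy0 = cs$fold_sy0$mean, sd_fold_sy0 = cs$fold_sy0$sd,
  n_excluded_sy0 = cs$n - cs$fold_sy0$n,
  mean_fold_dy1 = cs$fold_dy1$mean, sd_fold_dy1 = cs$fold_dy1$sd,
  n_excluded_dy1 = cs$n - cs$fold_dy1$n,
  mean_rmse_vaf = cs$rmse_mean,
  n_rmse_le_002 = cs$n_rmse_le_002, n_rmse_le_004 = cs$n_rmse_le_004)
write.csv(summary_tab, "results/cohort_summary.csv", row.names = FALSE)
cat(sprintf("\njoint-fit folds: s_y0 %.1fx (sd %.1f, %d outliers excluded), d_y1 %.1fx (sd %.1f)\n",
            cs$fold_sy0$mean, cs$fold_sy0$sd, cs$n - cs$fold_sy0$n,
            cs$fold_dy1$mean, cs$fold_dy1$sd))
cat(sprintf("RMSE <= 0.02 for %d/24 patients, <= 0.04 for %d/24\n",
            cs$n_rmse_le_002, cs$n_rmse_le_004))

# recovery against the generator's ground truth
err <- abs(vapply(both_fits, `[[`, numeric(1), "rho_dy1") -
             cohort$truth$rho_dy1) / cohort$truth$rho_dy1
cat(sprintf("median relative error of recovered rho_dy1: %.1f%%\n",
            100 * median(err)))
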