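#!/usr/bin/env Rscript
# Stage 4: simulate batch fractionation for three feed size distributions.
#
# Three native-fructan batches spanning the observed composition range
# (FOS:Fc = 0.23, 0.35, 0.39) are ultrafiltered in silico at the validated
# flux parameters, 100 kg/m3 total feed and a 100 L tank, with rejections
# taken from the calibrated correlation of stage 3.  Retentate and permeate
# concentration profiles are written as tidy CSVs.

suppressPackageStartupMessages(library(fructanUF))
out <- "results"
dir.create(out, showWarnings = FALSE)

params <- flux_params(k = 6.31e-6, c_lim = 337.61)
corr <- fit_rejection_correlation(ratio = c(0.23, 0.39),
                                  ro_fos = c(0.55, 0.185),
                                  ro_fc = c(0.76, 0.83))

# batch compositions (% of total carbohydrate) at 100 kg/m3 total feed
batches <- data.frame(
  ratio = c(0.23, 0.35, 0.39),
  pct_fos = c(17.10, 23.68, 24.90),
  pct_fc = c(71.60, 67.33, 63.67)
)
feed_conc <- 100   # kg/m3
v0 <- 0.1          # m3 (100 L working volume of the 150 L pilot tank)
t_end <- 4 * 3600  # s

summary_rows <- list()
for (i in seq_len(nrow(batches))) {
  b <- batches[i, ]
  ro <- predict_rejection(corr, b$ratio)
  sys <- uf_system(area = 0.5, v0 = v0,
                   c0_fc = feed_conc * b$pct_fc / 100,
                   c0_fos = feed_conc * b$pct_fos / 100,
                   ro_fc = ro$ro_fc, ro_fos = ro$ro_fos, params = params)
  traj <- simulate_uf(sys, t_end = t_end, v_min_frac = 0.05)
  fname <- sprintf("uf_profile_ratio_%0.2f.csv", b$ratio)
  write_trajectory_csv(traj, file.path(out, fname))
  last <- traj[nrow(traj), ]
  sf_end <- separation_factor(last$cp_fos / last$cp_fc, b$ratio)
  summary_rows[[i]] <- data.frame(
    ratio = b$ratio, ro_fc = ro$ro_fc, ro_fos = ro$ro_fos,
    t_end_s = last$time, termination = attr(traj, "termination"),
    v_final_m3 = last$v, c_fc_ret = last$c_fc, c_fos_ret = last$c_fos,
    cp_fc = last$cp_fc, cp_fos = last$cp_fos, sf_permeate = sf_end
  )
  cat(sprintf(
    "FOS:Fc %.2f -> Ro(Fc) %.3f, Ro(FOS) %.3f; after %.1f h: retentate Fc %.1f, permeate FOS:Fc %.3f (SF %.2f)\n",
    b$ratio, ro$ro_fc, ro$ro_fos, last$time / 3600, last$c_fc,
    last$cp_fos / last$cp_fc, sf_end))
}
smry <- do.call(rbind, summary_rows)
write.csv(smry, file.path(out, "uf_simulation_summary.csv"), row.names = FALSE)

cat("\nHigher feed FOS:Fc favours fractionation: FOS rejection falls with\n")
cat("the ratio, so relatively more short chains cross into the permeate\n")
cat("while the long chains stay retained and concentrate in the tank.\n")

writeLines(c("stage: 04_simulate_fractionation",
             paste("package: fructanUF", packageVersion("fructanUF")),
             paste("timestamp:", format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")),
             sprintf("scenario: A=0.5 m2, V0=%.3f m3, feed %.0f kg/m3, t_end %.0f s",
                     v0, feed_conc, t_end)),
           file.path(out, "manifest_04.txt"))
cat("\nWrote per-batch trajectories and summary to", out, "\n")
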