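#!/usr/bin/env Rscript
# Stage 1: fit the response surfaces to the 16-run Box-Behnken design.
#
# The separation factor (SF) follows a reduced quadratic model (the
# temperature-TMP and TMP-concentration interactions are dropped as
# insignificant); the solute flux (Ji) is linear in the three factors.
# Writes coefficient tables (coded and actual units), both ANOVA tables and
# the validation-run predictions to results/.

suppressPackageStartupMessages(library(fructanUF))
out <- "results"
dir.create(out, showWarnings = FALSE)

design <- agave_design()
cat("Design:", nrow(design), "runs,",
    sum(design$x1 == 0 & design$x2 == 0 & design$x3 == 0), "centre points\n\n")

sf_fit <- fit_rsm(design, "sf", form = "quadratic_reduced")
ji_fit <- fit_rsm(design, "ji", form = "linear")
print(sf_fit)
cat("\nSF model re-expanded to actual units:\n")
print(signif(actual_coefficients(sf_fit), 6))
cat("\n")
print(ji_fit)

an_sf <- anova_rsm(design, "sf", form = "quadratic")
an_ji <- anova_rsm(design, "ji", form = "linear")
cat("\n"); print(an_sf)
cat("\n"); print(an_ji)

v <- validation_runs()
v$sf_model <- predict(sf_fit, stats::setNames(
  v[c("t_c", "tmp_bar", "conc_kgm3")], c("temperature", "tmp", "conc")))
cat("\nValidation-run predictions (model vs experiment):\n")
print(v[c("experiment", "fos_fc_feed", "sf_model", "sf_experimental")])

write.csv(data.frame(term = names(coef(sf_fit)), coded = coef(sf_fit)),
          file.path(out, "sf_coefficients_coded.csv"), row.names = FALSE)
write.csv(data.frame(term = names(actual_coefficients(sf_fit)),
                     actual = actual_coefficients(sf_fit)),
          file.path(out, "sf_coefficients_actual.csv"), row.names = FALSE)
write.csv(data.frame(term = names(coef(ji_fit)), coded = coef(ji_fit)),
          file.path(out, "ji_coefficients_coded.csv"), row.names = FALSE)
write.csv(as.data.frame(an_sf), file.path(out, "anova_sf.csv"), row.names = FALSE)
write.csv(as.data.frame(an_ji), file.path(out, "anova_ji.csv"), row.names = FALSE)
write.csv(v, file.path(out, "validation_predictions.csv"), row.names = FALSE)

writeLines(c("stage: 01_fit_response_surfaces",
             paste("package: fructanUF", packageVersion("fructanUF")),
             paste("timestamp:", format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")),
             "inputs: packaged design (bbd_design_agave.csv), validation_runs.csv"),
           file.path(out, "manifest_01.txt"))
cat("\nWrote coefficient, ANOVA and validation tables to", out, "\n")
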