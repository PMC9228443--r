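# CSV dialect: UTF-8, comma-separated, dot decimal; units in column names
design_col_map <- c(t_c = "temperature", tmp_bar = "tmp", conc_kgm3 = "conc",
                    run_id = "run")

#' Read a design table from CSV
#'
#' Reads a design in the package's CSV dialect (columns `run_id`, `t_c`,
#' `tmp_bar`, `conc_kgm3`, optionally `x1`--`x3`, `sf`, `ji`).  Coded
#' columns absent from the file are derived from the actual ones through the
#' coding map.  The Box-Behnken structure is checked and deviations produce
#' warnings, not errors, so arbitrary (e.g. validation) condition tables can
#' be read too.
#'
#' @param path CSV file path.
#' @param levels A [design_levels()] object used for coding.
#' @param check If `TRUE` (default) warn when the table is not a standard
#'   3-factor Box-Behnken design.
#' @return A data frame of class `"bbd_design"`.
#' @export
load_design_csv <- function(path, levels = agave_levels(), check = TRUE) {
  raw <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (nrow(raw) == 0L) {
    stop(sprintf("empty design table: '%s' has headers but no runs", path),
         call. = FALSE)
  }
  if (any(grepl("brix", names(raw), ignore.case = TRUE))) {
    warning("a 'brix' column was detected: concentrations must be supplied in kg/m3; no conversion is applied",
            call. = FALSE)
  }
  for (from in names(design_col_map)) {
    if (from %in% names(raw)) {
      names(raw)[names(raw) == from] <- design_col_map[[from]]
    }
  }
  missing <- setdiff(factor_names, names(raw))
  if (length(missing)) {
    stop("design CSV is missing columns: ",
         paste(names(design_col_map)[match(missing, design_col_map)],
               collapse = ", "), call. = FALSE)
  }
  num_cols <- intersect(c(factor_names, coded_names, "sf", "ji"), names(raw))
  for (cl in num_cols) {
    v <- suppressWarnings(as.numeric(raw[[cl]]))
    if (anyNA(v) && !anyNA(raw[[cl]])) {
      stop(sprintf("non-numeric values in column '%s'", cl), call. = FALSE)
    }
    raw[[cl]] <- v
  }
  if (!all(coded_names %in% names(raw))) {
    raw <- cbind(raw, code_conditions(raw[factor_names], levels)[coded_names])
  }
  if (!"run" %in% names(raw)) raw$run <- seq_len(nrow(raw))
  if (!"sf" %in% names(raw)) raw$sf <- NA_real_
  if (!"ji" %in% names(raw)) raw$ji <- NA_real_
  out <- raw[c("run", factor_names, coded_names, "sf", "ji")]
  class(out) <- c("bbd_design", "data.frame")
  attr(out, "levels") <- levels
  if (check) is_bbd(out, levels, warn = TRUE)
  out
}

#' Write a design table to CSV
#'
#' @param design A design data frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_design_csv <- function(design, path) {
  out <- as.data.frame(design)
  inv <- stats::setNames(names(design_col_map), design_col_map)
  for (from in names(inv)) {
    if (from %in% names(out)) names(out)[names(out) == from] <- inv[[from]]
  }
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write a trajectory as tidy CSV
#'
#' One row per time point per stream per solute, with the tank volume
#' repeated on retentate rows.
#'
#' @param traj A [simulate_uf()] trajectory.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_trajectory_csv <- function(traj, path) {
  long <- data.frame(
    time_s = rep(traj$time, 4),
    stream = rep(c("retentate", "retentate", "permeate", "permeate"),
                 each = nrow(traj)),
    solute = rep(c("fc", "fos", "fc", "fos"), each = nrow(traj)),
    conc_kgm3 = c(traj$c_fc, traj$c_fos, traj$cp_fc, traj$cp_fos),
    v_m3 = rep(traj$v, 4),
    jlim_ms = rep(traj$jlim, 4)
  )
  utils::write.csv(long, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' The agave-fructan Box-Behnken study design
#'
#' The packaged 16-run design (12 edge midpoints + 4 centre replicates) with
#' measured separation factor and solute flux for the agave-fructan
#' ultrafiltration study: temperature 30--60 degC, TMP 1--5 bar, feed
#' concentration 50--150 kg m^-3.
#'
#' @return A `"bbd_design"` data frame with 16 runs.
#' @examples
#' agave_design()
#' @export
agave_design <- function() {
  load_design_csv(system.file("extdata", "bbd_design_agave.csv",
                              package = "fructanUF"))
}

#' Validation runs on independent fructan batches
#'
#' The packaged table of four validation experiments run on commercial
#' batches of differing composition: average DP, feed FOS:Fc ratio,
#' operating conditions and the measured separation factor.
#'
#' @return A data frame with one row per validation experiment.
#' @export
validation_runs <- function() {
  utils::read.csv(system.file("extdata", "validation_runs.csv",
                              package = "fructanUF"))
}

#' Re-run the design analysis and compare against its reference values
#'
#' Runs the full design-of-experiments analysis on the packaged study
#' design -- the reduced quadratic separation-factor fit, the linear
#' solute-flux fit, both ANOVA tables and the single- and multi-response
#' desirability optimizations -- and writes the fitted tables plus a
#' comparison report against the packaged reference values, with a
#' pass/fail flag per quantity.
#'
#' @param out_dir Output directory (created if needed).
#' @param skip Character vector of stages to skip; currently `"optimize"`.
#' @return The comparison report data frame, invisibly.
#' @export
reproduce_study <- function(out_dir, skip = character()) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  design <- agave_design()
  sf_fit <- fit_rsm(design, "sf", "quadratic_reduced")
  ji_fit <- fit_rsm(design, "ji", "linear")
  an_sf <- anova_rsm(design, "sf", "quadratic")
  an_ji <- anova_rsm(design, "ji", "linear")
  utils::write.csv(as.data.frame(an_sf), file.path(out_dir, "anova_sf.csv"),
                   row.names = FALSE)
  utils::write.csv(as.data.frame(an_ji), file.path(out_dir, "anova_ji.csv"),
                   row.names = FALSE)
  coefs <- data.frame(
    term = c(names(stats::coef(sf_fit)), names(stats::coef(ji_fit))),
    response = c(rep("sf", length(stats::coef(sf_fit))),
                 rep("ji", length(stats::coef(ji_fit)))),
    coef_coded = c(stats::coef(sf_fit), stats::coef(ji_fit))
  )
  utils::write.csv(coefs, file.path(out_dir, "coefficients.csv"),
                   row.names = FALSE)

  vruns <- validation_runs()
  pred <- predict(sf_fit, vruns[, c("t_c", "tmp_bar", "conc_kgm3")] |>
                    stats::setNames(factor_names))
  utils::write.csv(cbind(vruns, sf_model = pred),
                   file.path(out_dir, "validation_predictions.csv"),
                   row.names = FALSE)

  got <- list(
    pure_error_ss_sf = an_sf$ss[an_sf$term == "Pure error"],
    ss_x2sq_sf = an_sf$ss[an_sf$term == "x2^2"],
    r2_sf_pct = 100 * attr(an_sf, "r2"),
    r2_adj_sf_pct = 100 * attr(an_sf, "r2_adj"),
    r2_ji_pct = 100 * attr(an_ji, "r2"),
    ji_coef_x1 = stats::coef(ji_fit)[["x1"]],
    ji_coef_x2 = stats::coef(ji_fit)[["x2"]],
    ji_coef_x3 = stats::coef(ji_fit)[["x3"]],
    sf_pred_45_3_100 = pred[1],
    sf_pred_30_5_50 = pred[2],
    sf_pred_54_4_120 = pred[4]
  )
  if (!"optimize" %in% skip) {
    opt1 <- optimize_desirability(sf_fit)
    opt2 <- optimize_desirability(list(sf = sf_fit, ji = ji_fit))
    got$desirability_single <- opt1$overall
    got$opt_temperature_c <- opt1$conditions$temperature
    got$desirability_multi <- opt2$overall
    utils::write.csv(data.frame(
      optimization = c("sf_only", "sf_and_ji"),
      temperature_c = c(opt1$conditions$temperature, opt2$conditions$temperature),
      tmp_bar = c(opt1$conditions$tmp, opt2$conditions$tmp),
      conc_kgm3 = c(opt1$conditions$conc, opt2$conditions$conc),
      overall_desirability = c(opt1$overall, opt2$overall)
    ), file.path(out_dir, "optimization.csv"), row.names = FALSE)
  }

  expected <- utils::read.csv(system.file("extdata", "reference_values.csv",
                                          package = "fructanUF"))
  expected <- expected[expected$quantity %in% names(got), ]
  report <- data.frame(
    quantity = expected$quantity,
    reference = expected$value,
    computed = vapply(expected$quantity, function(q) got[[q]], numeric(1)),
    tolerance = expected$tolerance
  )
  report$pass <- abs(report$computed - report$reference) <= report$tolerance
  utils::write.csv(report, file.path(out_dir, "report.csv"), row.names = FALSE)

  manifest <- c(
    sprintf("command: reproduce_study"),
    sprintf("package: fructanUF %s",
            as.character(utils::packageVersion("fructanUF"))),
    sprintf("timestamp: %s", format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")),
    sprintf("skip: %s", if (length(skip)) paste(skip, collapse = ",") else "none"),
    sprintf("out_dir: %s", normalizePath(out_dir))
  )
  writeLines(manifest, file.path(out_dir, "run_manifest.txt"))
  invisible(report)
}
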