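#' Factor levels for a three-factor design
#'
#' Defines low/centre/high actual values for temperature (degC),
#' transmembrane pressure (bar) and feed concentration (kg m^-3).  The
#' coded value of a factor is `(actual - centre) / half_range`, so the
#' low/centre/high levels map to -1/0/+1.
#'
#' @param temperature,tmp,conc Length-3 numeric vectors `(low, centre, high)`,
#'   strictly increasing.
#' @return An object of class `"bbd_levels"`.
#' @examples
#' agave_levels()
#' @export
design_levels <- function(temperature = c(30, 45, 60),
                          tmp = c(1, 3, 5),
                          conc = c(50, 100, 150)) {
  lv <- list(temperature = temperature, tmp = tmp, conc = conc)
  for (nm in names(lv)) {
    v <- lv[[nm]]
    if (length(v) != 3L || any(!is.finite(v)) || v[1] >= v[2] || v[2] >= v[3]) {
      stop(sprintf("levels for '%s' must be three increasing values (low, centre, high)", nm),
           call. = FALSE)
    }
  }
  centre <- vapply(lv, `[`, numeric(1), 2L)
  half <- vapply(lv, function(v) (v[3] - v[1]) / 2, numeric(1))
  structure(list(levels = lv, centre = centre, half_range = half),
            class = "bbd_levels")
}

#' Default factor levels of the agave-fructan ultrafiltration study
#'
#' Temperature 30--60 degC, TMP 1--5 bar, feed concentration 50--150
#' kg m^-3, centred at (45, 3, 100).
#'
#' @return A [design_levels()] object.
#' @export
agave_levels <- function() design_levels()

#' @export
print.bbd_levels <- function(x, ...) {
  cat("3-factor levels (low / centre / high):\n")
  for (nm in names(x$levels)) {
    cat(sprintf("  %-12s %g / %g / %g\n", nm,
                x$levels[[nm]][1], x$levels[[nm]][2], x$levels[[nm]][3]))
  }
  invisible(x)
}

factor_names <- c("temperature", "tmp", "conc")
coded_names <- c("x1", "x2", "x3")

as_conditions_df <- function(x, cols) {
  if (is.data.frame(x)) {
    missing <- setdiff(cols, names(x))
    if (length(missing)) {
      stop("missing columns: ", paste(missing, collapse = ", "), call. = FALSE)
    }
    x[cols]
  } else if (is.numeric(x) && length(x) == 3L) {
    out <- as.data.frame(as.list(as.numeric(x)))
    names(out) <- cols
    out
  } else {
    stop("conditions must be a data frame or a numeric triple", call. = FALSE)
  }
}

#' Convert actual operating conditions to coded units (and back)
#'
#' `code_conditions()` maps actual `(temperature, tmp, conc)` triples to
#' coded `(x1, x2, x3)`; `decode_conditions()` is its exact inverse.
#' Points outside the design box are allowed but flagged with an
#' `extrapolated` column (|coded| > 1).
#'
#' @param x A data frame with columns `temperature`, `tmp`, `conc`
#'   (or `x1`, `x2`, `x3` for decoding), or a numeric triple.
#' @param levels A [design_levels()] object; defaults to [agave_levels()].
#' @return A data frame of coded (resp. actual) conditions with a logical
#'   `extrapolated` column.
#' @examples
#' code_conditions(c(60, 5, 150))    # (1, 1, 1)
#' decode_conditions(c(0, 0, 0))     # centre point
#' @export
code_conditions <- function(x, levels = agave_levels()) {
  a <- as_conditions_df(x, factor_names)
  out <- as.data.frame(mapply(function(v, ctr, hr) (v - ctr) / hr,
                              a, levels$centre, levels$half_range,
                              SIMPLIFY = FALSE))
  names(out) <- coded_names
  out$extrapolated <- apply(abs(out[coded_names]) > 1 + 1e-12, 1L, any)
  out
}

#' @rdname code_conditions
#' @export
decode_conditions <- function(x, levels = agave_levels()) {
  cc <- as_conditions_df(x, coded_names)
  out <- as.data.frame(mapply(function(v, ctr, hr) ctr + hr * v,
                              cc, levels$centre, levels$half_range,
                              SIMPLIFY = FALSE))
  names(out) <- factor_names
  out$extrapolated <- apply(abs(cc) > 1 + 1e-12, 1L, any)
  out
}

# canonical 12 edge-midpoint rows of the 3-factor Box-Behnken design
bbd_edge_rows <- function() {
  pm <- c(-1, -1, 1, 1)
  pm2 <- c(-1, 1, -1, 1)
  rbind(
    cbind(x1 = pm, x2 = pm2, x3 = 0),
    cbind(x1 = pm, x2 = 0, x3 = pm2),
    cbind(x1 = 0, x2 = pm, x3 = pm2)
  )
}

#' Three-factor Box-Behnken design
#'
#' Builds the standard 3-factor Box-Behnken design: the 12 midpoints of the
#' edges of the factor cube plus `n_center` replicated centre points
#' (12 + `n_center` runs).  Response columns `sf` and `ji` are created empty,
#' to be filled with measured (or simulated, see [gen_bbd_responses()])
#' values.
#'
#' @param levels A [design_levels()] object.
#' @param n_center Number of centre-point replicates (>= 1).
#' @return A data frame of class `"bbd_design"` with columns `run`,
#'   `temperature`, `tmp`, `conc` (actual units), `x1`, `x2`, `x3` (coded)
#'   and empty responses `sf`, `ji`.
#' @examples
#' box_behnken(n_center = 4)
#' @export
box_behnken <- function(levels = agave_levels(), n_center = 4L) {
  n_center <- as.integer(n_center)
  if (is.na(n_center) || n_center < 1L) {
    stop("n_center must be a positive integer", call. = FALSE)
  }
  coded <- rbind(bbd_edge_rows(),
                 matrix(0, nrow = n_center, ncol = 3,
                        dimnames = list(NULL, coded_names)))
  coded <- as.data.frame(coded)
  actual <- decode_conditions(coded, levels)
  out <- data.frame(run = seq_len(nrow(coded)),
                    actual[factor_names], coded,
                    sf = NA_real_, ji = NA_real_)
  class(out) <- c("bbd_design", "data.frame")
  attr(out, "levels") <- levels
  out
}

#' Validate the Box-Behnken structure of a design table
#'
#' Checks that a design has the 12 + c run structure of a 3-factor
#' Box-Behnken (each non-centre run has exactly one factor at coded 0, every
#' coded entry in {-1, 0, 1}) and that coded and actual columns agree under
#' the coding map.
#'
#' @param design A design data frame with coded and actual columns.
#' @param levels A [design_levels()] object.
#' @param warn If `TRUE` (default) emit warnings instead of failing.
#' @return Logical: `TRUE` if the table is a standard 3-factor BBD.
#' @export
is_bbd <- function(design, levels = attr(design, "levels") %||% agave_levels(),
                   warn = TRUE) {
  msg <- function(...) if (warn) warning(sprintf(...), call. = FALSE)
  cc <- as.matrix(design[coded_names])
  ok <- TRUE
  if (!all(abs(cc - round(cc)) < 1e-9) || !all(round(cc) %in% c(-1, 0, 1))) {
    msg("coded entries are not all in {-1, 0, 1}")
    ok <- FALSE
  } else {
    centre <- rowSums(cc == 0) == 3L
    if (!all(rowSums(cc[!centre, , drop = FALSE] == 0) == 1L)) {
      msg("non-centre runs must have exactly one factor at coded 0")
      ok <- FALSE
    }
    if (sum(!centre) != 12L) {
      msg("expected 12 edge-midpoint runs, found %d", sum(!centre))
      ok <- FALSE
    }
    if (sum(centre) < 1L) {
      msg("design has no centre points")
      ok <- FALSE
    }
    edge <- cc[!centre, , drop = FALSE]
    want <- bbd_edge_rows()
    key <- function(m) sort(apply(m, 1L, paste, collapse = ","))
    if (ok && !identical(key(edge), key(want))) {
      msg("edge runs do not match the standard 3-factor Box-Behnken pattern")
      ok <- FALSE
    }
  }
  rec <- code_conditions(design[factor_names], levels)
  if (max(abs(as.matrix(rec[coded_names]) - cc)) > 1e-6) {
    msg("coded and actual columns are inconsistent under the coding map")
    ok <- FALSE
  }
  ok
}

`%||%` <- function(a, b) if (is.null(a)) b else a
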