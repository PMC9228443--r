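# model terms as exponent triples over (x1, x2, x3)
rsm_term_table <- function() {
  list(
    "x1"    = c(1, 0, 0), "x2"    = c(0, 1, 0), "x3"    = c(0, 0, 1),
    "x1:x2" = c(1, 1, 0), "x1:x3" = c(1, 0, 1), "x2:x3" = c(0, 1, 1),
    "x1^2"  = c(2, 0, 0), "x2^2"  = c(0, 2, 0), "x3^2"  = c(0, 0, 2)
  )
}

rsm_form_terms <- function(form = c("linear", "quadratic", "quadratic_reduced"),
                           drop_terms = NULL) {
  form <- match.arg(form)
  all_terms <- names(rsm_term_table())
  terms <- switch(form,
    linear = all_terms[1:3],
    quadratic = all_terms,
    quadratic_reduced = {
      if (is.null(drop_terms)) drop_terms <- c("x1:x2", "x2:x3")
      setdiff(all_terms, drop_terms)
    }
  )
  if (!is.null(drop_terms)) {
    bad <- setdiff(drop_terms, all_terms)
    if (length(bad)) {
      stop("unknown terms in drop_terms: ", paste(bad, collapse = ", "),
           call. = FALSE)
    }
    terms <- setdiff(terms, drop_terms)
  }
  terms
}

rsm_basis <- function(coded, terms) {
  x <- as.matrix(coded[, c("x1", "x2", "x3")])
  tt <- rsm_term_table()
  cols <- vapply(terms, function(tm) {
    e <- tt[[tm]]
    x[, 1]^e[1] * x[, 2]^e[2] * x[, 3]^e[3]
  }, numeric(nrow(x)))
  cbind("(Intercept)" = 1, matrix(cols, nrow = nrow(x),
                                  dimnames = list(NULL, terms)))
}

#' Fit a response-surface model to a Box-Behnken design
#'
#' Ordinary least squares on the coded-unit polynomial basis.  Forms:
#' `"linear"` (main effects only), `"quadratic"` (full second-order model:
#' main effects, all two-factor interactions, all squares) and
#' `"quadratic_reduced"` (full quadratic minus `drop_terms`; by default the
#' temperature-TMP and TMP-concentration interactions, the terms found
#' insignificant for the separation factor).  Dropping terms refits the
#' reduced basis rather than zeroing coefficients.
#'
#' @param design A design data frame (see [box_behnken()], [agave_design()])
#'   with coded columns `x1`--`x3` and the response filled in.
#' @param response Column name of the response, `"sf"` or `"ji"` (any numeric
#'   column is accepted).
#' @param form Model form, see Details.
#' @param drop_terms Character vector of coded term labels (e.g. `"x1:x2"`,
#'   `"x2^2"`) to exclude.
#' @return An object of class `"rsm_fit"` with elements `coefficients`
#'   (coded units), `r2`, `r2_adj`, `df_residual`, `terms`, `form`,
#'   `response`, plus the data needed for prediction and ANOVA.
#' @examples
#' d <- agave_design()
#' fit <- fit_rsm(d, "sf", form = "quadratic_reduced")
#' coef(fit)
#' predict(fit, c(45, 3, 100))
#' @export
fit_rsm <- function(design, response = c("sf", "ji"),
                    form = c("linear", "quadratic", "quadratic_reduced"),
                    drop_terms = NULL) {
  response <- if (is.character(response)) response[1] else stop("response must be a column name")
  form <- match.arg(form)
  y <- design[[response]]
  if (is.null(y) || anyNA(y)) {
    stop(sprintf("design has no complete '%s' response column", response),
         call. = FALSE)
  }
  terms <- rsm_form_terms(form, drop_terms)
  X <- rsm_basis(design, terms)
  if (nrow(X) <= ncol(X)) {
    stop("more parameters than runs: reduce the model form", call. = FALSE)
  }
  qrx <- qr(X)
  if (qrx$rank < ncol(X)) {
    stop("rank-deficient design for the requested model form", call. = FALSE)
  }
  beta <- qr.coef(qrx, y)
  fitted <- drop(X %*% beta)
  res <- y - fitted
  rss <- sum(res^2)
  tss <- sum((y - mean(y))^2)
  n <- length(y)
  p <- ncol(X)
  r2 <- if (tss > 0) 1 - rss / tss else NA_real_
  r2_adj <- if (tss > 0) 1 - (rss / (n - p)) / (tss / (n - 1)) else NA_real_
  structure(list(
    coefficients = beta, terms = terms, form = form, response = response,
    y = y, coded = as.data.frame(design[, c("x1", "x2", "x3")]),
    levels = attr(design, "levels") %||% agave_levels(),
    fitted = fitted, residuals = res, rss = rss, tss = tss,
    n = n, df_residual = n - p, sigma2 = rss / (n - p),
    r2 = r2, r2_adj = r2_adj
  ), class = "rsm_fit")
}

#' @export
coef.rsm_fit <- function(object, ...) object$coefficients

#' @export
print.rsm_fit <- function(x, digits = 4, ...) {
  cat(sprintf("Response-surface fit: %s ~ %s model (coded units)\n",
              x$response, x$form))
  print(round(x$coefficients, digits))
  if (is.na(x$r2)) {
    cat("R2 undefined (constant response)\n")
  } else {
    cat(sprintf("R2 = %.2f%%, adjusted R2 = %.2f%% (residual df %d)\n",
                100 * x$r2, 100 * x$r2_adj, x$df_residual))
  }
  invisible(x)
}

#' Re-express a coded-unit fit in actual units
#'
#' Exact polynomial re-expansion of the coded-unit coefficients through the
#' affine coding map `x_i = (X_i - centre_i) / half_range_i`; no refit is
#' performed, so predictions are identical in either unit system.
#'
#' @param fit An [fit_rsm()] object.
#' @return Named numeric vector of coefficients over actual-unit monomials
#'   (`temperature`, `tmp`, `conc` and their products/squares).
#' @examples
#' round(actual_coefficients(fit_rsm(agave_design(), "sf", "quadratic_reduced")), 6)
#' @export
actual_coefficients <- function(fit) {
  tt <- c(list("(Intercept)" = c(0, 0, 0)), rsm_term_table())
  ctr <- fit$levels$centre
  hr <- fit$levels$half_range
  acc <- array(0, dim = c(3, 3, 3))  # index = exponent + 1 per factor
  for (tm in c("(Intercept)", fit$terms)) {
    beta <- fit$coefficients[[tm]]
    e <- tt[[tm]]
    scale <- prod(hr^e)
    for (j1 in 0:e[1]) for (j2 in 0:e[2]) for (j3 in 0:e[3]) {
      w <- choose(e[1], j1) * choose(e[2], j2) * choose(e[3], j3) *
        (-ctr[1])^(e[1] - j1) * (-ctr[2])^(e[2] - j2) * (-ctr[3])^(e[3] - j3)
      acc[j1 + 1, j2 + 1, j3 + 1] <- acc[j1 + 1, j2 + 1, j3 + 1] +
        beta * w / scale
    }
  }
  lab <- function(e) {
    if (sum(e) == 0) return("(Intercept)")
    parts <- character(0)
    for (i in 1:3) {
      if (e[i] == 1) parts <- c(parts, factor_names[i])
      if (e[i] == 2) parts <- c(parts, paste0(factor_names[i], "^2"))
    }
    paste(parts, collapse = ":")
  }
  keep <- c(list(c(0, 0, 0)), rsm_term_table())
  out <- vapply(keep, function(e) acc[e[1] + 1, e[2] + 1, e[3] + 1], numeric(1))
  names(out) <- vapply(keep, lab, character(1))
  out[c(TRUE, names(rsm_term_table()) %in% fit$terms)]
}

#' Predict from a response-surface fit
#'
#' @param object An [fit_rsm()] object.
#' @param newdata Conditions: a data frame with actual columns
#'   (`temperature`, `tmp`, `conc`) or coded columns (`x1`, `x2`, `x3`),
#'   or a numeric triple (interpreted per `units`).
#' @param units `"actual"` (default) or `"coded"` -- how `newdata` is
#'   expressed.
#' @param method `"coded"` evaluates the coded-unit polynomial after coding
#'   the conditions; `"actual"` evaluates the re-expanded actual-unit
#'   polynomial directly.  Both give the same value to numerical precision.
#' @param ... Unused.
#' @return Numeric vector of predicted responses.
#' @export
predict.rsm_fit <- function(object, newdata,
                            units = c("actual", "coded"),
                            method = c("coded", "actual"), ...) {
  units <- match.arg(units)
  method <- match.arg(method)
  if (is.data.frame(newdata) && all(coded_names %in% names(newdata))) {
    units <- "coded"
  }
  coded <- if (units == "coded") {
    as_conditions_df(newdata, coded_names)
  } else {
    code_conditions(as_conditions_df(newdata, factor_names), object$levels)
  }
  if (method == "coded") {
    X <- rsm_basis(coded, object$terms)
    drop(X %*% object$coefficients)
  } else {
    ac <- actual_coefficients(object)
    actual <- decode_conditions(coded, object$levels)
    tt <- c(list("(Intercept)" = c(0, 0, 0)), rsm_term_table())
    keep <- tt[c("(Intercept)", object$terms)]
    Xa <- vapply(keep, function(e) {
      actual$temperature^e[1] * actual$tmp^e[2] * actual$conc^e[3]
    }, numeric(nrow(actual)))
    drop(matrix(Xa, nrow = nrow(actual)) %*% ac)
  }
}

#' ANOVA for a response-surface fit
#'
#' Partial (Type-III) sums of squares per model term, with the residual
#' partitioned into lack-of-fit and pure error.  Pure error is computed from
#' replicated design points (the centre-point replicates in a Box-Behnken
#' design); each term's F statistic uses the residual mean square, while the
#' lack-of-fit F uses the pure-error mean square.
#'
#' @inheritParams fit_rsm
#' @return A data frame of class `"rsm_anova"` with columns `term`, `ss`,
#'   `df`, `ms`, `f`, `p` and rows for every model term plus `Residual`,
#'   `Lack of fit`, `Pure error` and `Total`.  Attributes `r2` and `r2_adj`
#'   carry the fit diagnostics.
#' @examples
#' anova_rsm(agave_design(), "sf", form = "quadratic")
#' @export
anova_rsm <- function(design, response = c("sf", "ji"),
                      form = c("linear", "quadratic", "quadratic_reduced"),
                      drop_terms = NULL) {
  fit <- fit_rsm(design, response, form, drop_terms)
  y <- fit$y
  X <- rsm_basis(fit$coded, fit$terms)
  rss <- fit$rss
  ms_res <- fit$sigma2
  rows <- lapply(fit$terms, function(tm) {
    Xr <- X[, colnames(X) != tm, drop = FALSE]
    rss_r <- sum(qr.resid(qr(Xr), y)^2)
    ss <- rss_r - rss
    f <- ss / ms_res
    data.frame(term = tm, ss = ss, df = 1, ms = ss, f = f,
               p = stats::pf(f, 1, fit$df_residual, lower.tail = FALSE))
  })
  tab <- do.call(rbind, rows)

  # pure error from replicated coded points
  key <- apply(round(as.matrix(fit$coded), 9), 1L, paste, collapse = ",")
  grp <- split(y, key)
  reps <- grp[lengths(grp) > 1L]
  has_pe <- length(reps) > 0L
  tab <- rbind(tab, data.frame(term = "Residual", ss = rss,
                               df = fit$df_residual, ms = ms_res,
                               f = NA_real_, p = NA_real_))
  if (has_pe) {
    ss_pe <- sum(vapply(reps, function(v) sum((v - mean(v))^2), numeric(1)))
    df_pe <- sum(vapply(reps, length, integer(1)) - 1L)
    ss_lof <- rss - ss_pe
    df_lof <- fit$df_residual - df_pe
    ms_pe <- ss_pe / df_pe
    ms_lof <- if (df_lof > 0) ss_lof / df_lof else NA_real_
    f_lof <- if (df_lof > 0) ms_lof / ms_pe else NA_real_
    p_lof <- if (df_lof > 0) {
      stats::pf(f_lof, df_lof, df_pe, lower.tail = FALSE)
    } else NA_real_
    tab <- rbind(tab,
      data.frame(term = "Lack of fit", ss = ss_lof, df = df_lof,
                 ms = ms_lof, f = f_lof, p = p_lof),
      data.frame(term = "Pure error", ss = ss_pe, df = df_pe, ms = ms_pe,
                 f = NA_real_, p = NA_real_))
  } else {
    warning("no replicated design points: pure-error and lack-of-fit rows omitted",
            call. = FALSE)
  }
  tab <- rbind(tab, data.frame(term = "Total", ss = fit$tss,
                               df = fit$n - 1L, ms = NA_real_,
                               f = NA_real_, p = NA_real_))
  rownames(tab) <- NULL
  structure(tab, class = c("rsm_anova", "data.frame"),
            r2 = fit$r2, r2_adj = fit$r2_adj,
            response = fit$response, form = fit$form)
}

#' @export
print.rsm_anova <- function(x, digits = 4, ...) {
  cat(sprintf("ANOVA (%s, %s model; partial SS)\n",
              attr(x, "response"), attr(x, "form")))
  df <- as.data.frame(x)
  df$ss <- signif(df$ss, digits)
  df$ms <- signif(df$ms, digits)
  df$f <- signif(df$f, digits)
  df$p <- signif(df$p, 3)
  print(df, row.names = FALSE)
  cat(sprintf("R2 = %.2f%%, adjusted R2 = %.2f%%\n",
              100 * attr(x, "r2"), 100 * attr(x, "r2_adj")))
  invisible(x)
}
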