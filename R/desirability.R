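#' Desirability transform specification for a maximized response
#'
#' Linear "larger-is-better" desirability: a response value `Y` maps to
#' `d = clip((Y - low) / (high - low), 0, 1)`, so `d = 0` at or below the
#' lower anchor and `d = 1` at or above the upper anchor.  When anchors are
#' omitted they default, at optimization time, to the observed minimum and
#' maximum of the response in the design the model was fitted to.
#'
#' @param low,high Response-unit anchors, `high > low`; `NULL` to default
#'   to the observed response range.
#' @param weight Positive importance weight (default 1).
#' @return An object of class `"desirability_spec"`.
#' @export
desirability_spec <- function(low = NULL, high = NULL, weight = 1) {
  if (!is.null(low) && !is.null(high) && high <= low) {
    stop("desirability anchors require high > low", call. = FALSE)
  }
  if (!is.finite(weight) || weight <= 0) {
    stop("weight must be a positive number", call. = FALSE)
  }
  structure(list(low = low, high = high, weight = weight),
            class = "desirability_spec")
}

d_linear <- function(y, low, high) pmin(pmax((y - low) / (high - low), 0), 1)

#' Maximize overall desirability over the design region
#'
#' Combines one or more fitted response surfaces into the overall
#' desirability `D(x) = (prod_k d_k(Yhat_k(x))^w_k)^(1/sum w_k)` (weighted
#' geometric mean of the individual desirabilities) and maximizes it over a
#' box in coded units.  The search is deterministic: L-BFGS-B from a fixed
#' 27-point start grid, followed by a pattern-search polish on a 0.01-step
#' coded lattice so that the returned point is grid-stationary.
#'
#' @param fits A single [fit_rsm()] object or a named list of them (one per
#'   response to maximize simultaneously).
#' @param specs Optional [desirability_spec()] (or named list matching
#'   `fits`).  Missing anchors default to the observed response range in the
#'   design data.
#' @param coded_box Two-row matrix (or list of length-2 vectors) of lower
#'   and upper coded bounds per factor; default the design cube `[-1, 1]^3`.
#' @param step Polish step in coded units (default 0.01).
#' @return An object of class `"uf_optimum"`: a list with the optimal
#'   `coded` point, the decoded `conditions` (actual units), `predicted`
#'   responses, individual `desirability` scores and the `overall`
#'   desirability.
#' @examples
#' d <- agave_design()
#' sf_fit <- fit_rsm(d, "sf", "quadratic_reduced")
#' optimize_desirability(sf_fit)
#' @export
optimize_desirability <- function(fits, specs = NULL,
                                  coded_box = rbind(lower = c(-1, -1, -1),
                                                    upper = c(1, 1, 1)),
                                  step = 0.01) {
  if (inherits(fits, "rsm_fit")) fits <- stats::setNames(list(fits), fits$response)
  if (!length(fits)) stop("at least one fitted response is required", call. = FALSE)
  if (is.null(names(fits)) || any(!nzchar(names(fits)))) {
    names(fits) <- vapply(fits, function(f) f$response, character(1))
  }
  if (inherits(specs, "desirability_spec")) specs <- list(specs)
  specs <- lapply(seq_along(fits), function(i) {
    sp <- if (is.null(specs)) NULL
          else if (!is.null(names(specs)) && names(fits)[i] %in% names(specs)) {
            specs[[names(fits)[i]]]
          } else if (i <= length(specs)) specs[[i]] else NULL
    if (is.null(sp)) sp <- desirability_spec()
    if (is.null(sp$low)) sp$low <- min(fits[[i]]$y)
    if (is.null(sp$high)) sp$high <- max(fits[[i]]$y)
    if (sp$high <= sp$low) {
      stop("degenerate anchors: observed response range is empty", call. = FALSE)
    }
    sp
  })
  names(specs) <- names(fits)
  w <- vapply(specs, `[[`, numeric(1), "weight")

  lower <- as.numeric(coded_box[1, ])
  upper <- as.numeric(coded_box[2, ])
  if (any(upper <= lower)) stop("invalid coded box", call. = FALSE)

  pred_at <- function(x) {
    nd <- data.frame(x1 = x[1], x2 = x[2], x3 = x[3])
    vapply(fits, function(f) predict(f, nd, units = "coded"), numeric(1))
  }
  overall <- function(x) {
    yhat <- pred_at(x)
    d <- mapply(function(y, sp) d_linear(y, sp$low, sp$high), yhat, specs)
    prod(d^w)^(1 / sum(w))
  }

  starts <- as.matrix(expand.grid(
    x1 = c(lower[1] + 0.1 * (upper[1] - lower[1]), mean(c(lower[1], upper[1])),
           upper[1] - 0.1 * (upper[1] - lower[1])),
    x2 = c(lower[2] + 0.1 * (upper[2] - lower[2]), mean(c(lower[2], upper[2])),
           upper[2] - 0.1 * (upper[2] - lower[2])),
    x3 = c(lower[3] + 0.1 * (upper[3] - lower[3]), mean(c(lower[3], upper[3])),
           upper[3] - 0.1 * (upper[3] - lower[3]))
  ))
  best <- NULL
  for (s in seq_len(nrow(starts))) {
    o <- stats::optim(starts[s, ], function(x) -overall(x),
                      method = "L-BFGS-B", lower = lower, upper = upper,
                      control = list(factr = 1e4))
    if (is.null(best) || -o$value > best$value) {
      best <- list(par = o$par, value = -o$value)
    }
  }

  # pattern-search polish: returned point must be stationary on the lattice
  x <- best$par
  fx <- overall(x)
  repeat {
    improved <- FALSE
    for (i in 1:3) for (s in c(-step, step)) {
      cand <- x
      cand[i] <- min(max(cand[i] + s, lower[i]), upper[i])
      fc <- overall(cand)
      if (fc > fx + 1e-12) {
        x <- cand; fx <- fc; improved <- TRUE
      }
    }
    if (!improved) break
  }

  yhat <- pred_at(x)
  d_ind <- mapply(function(y, sp) d_linear(y, sp$low, sp$high), yhat, specs)
  conditions <- decode_conditions(x, fits[[1]]$levels)
  structure(list(
    coded = stats::setNames(as.numeric(x), c("x1", "x2", "x3")),
    conditions = conditions[, factor_names],
    predicted = yhat,
    desirability = d_ind,
    overall = fx,
    anchors = lapply(specs, function(sp) c(low = sp$low, high = sp$high)),
    weights = w
  ), class = "uf_optimum")
}

#' @export
print.uf_optimum <- function(x, ...) {
  cat("Desirability optimum\n")
  cat(sprintf("  conditions: %.2f degC, %.2f bar, %.2f kg/m3\n",
              x$conditions$temperature, x$conditions$tmp, x$conditions$conc))
  for (nm in names(x$predicted)) {
    cat(sprintf("  predicted %-4s = %.4f  (d = %.4f, anchors %.3f--%.3f)\n",
                nm, x$predicted[[nm]], x$desirability[[nm]],
                x$anchors[[nm]]["low"], x$anchors[[nm]]["high"]))
  }
  cat(sprintf("  overall desirability D = %.4f\n", x$overall))
  invisible(x)
}
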