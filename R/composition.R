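#' Carbohydrate composition of a fructan stream
#'
#' A composition describes the relative abundance of the three size classes
#' found in native agave fructans: long-chain fructans (`fc`, degree of
#' polymerization DP > 10), fructooligosaccharides (`fos`, DP 3--10) and
#' mono-/disaccharides (`md`, DP 1--2).  Fractions must be non-negative and
#' sum to one; inputs may be given as percentages with `unit = "percent"`.
#' Violations of the closure constraint are an error -- use
#' [normalize_composition()] when a measured composition needs explicit
#' renormalization.
#'
#' @param fc Mass fraction (or percentage) of long-chain fructans.
#' @param fos Mass fraction (or percentage) of fructooligosaccharides.
#' @param md Mass fraction (or percentage) of mono-/disaccharides.
#' @param unit `"fraction"` (default) or `"percent"`.
#' @param tol Closure tolerance on `fc + fos + md - 1` (fraction scale).
#' @return An object of class `"composition"`: a named numeric vector with
#'   elements `fc`, `fos`, `md` stored as fractions.
#' @examples
#' feed <- composition(fc = 64.90, fos = 23.77, md = 11.33, unit = "percent")
#' fos_fc_ratio(feed)
#' @seealso [fos_fc_ratio()], [separation_factor()]
#' @export
composition <- function(fc, fos, md, unit = c("fraction", "percent"),
                        tol = 1e-9) {
  unit <- match.arg(unit)
  x <- c(fc = as.numeric(fc), fos = as.numeric(fos), md = as.numeric(md))
  if (unit == "percent") {
    x <- x / 100
    tol <- max(tol, 1e-9)
  }
  if (anyNA(x) || any(!is.finite(x))) {
    stop("composition fractions must be finite numbers", call. = FALSE)
  }
  if (any(x < 0) || any(x > 1)) {
    stop("composition fractions must lie in [0, 1]", call. = FALSE)
  }
  if (abs(sum(x) - 1) > tol) {
    stop(sprintf(
      "composition does not close: fc + fos + md = %.10f (tolerance %.1e); use normalize_composition() if renormalization is intended",
      sum(x), tol
    ), call. = FALSE)
  }
  structure(x, class = "composition")
}

#' Renormalize a near-closing composition
#'
#' Divides the three fractions by their sum.  This is the only place the
#' package silently rescales a composition; [composition()] itself rejects
#' inputs that do not close.
#'
#' @param fc,fos,md Non-negative abundances in arbitrary common units.
#' @return A [composition()].
#' @export
normalize_composition <- function(fc, fos, md) {
  s <- fc + fos + md
  if (!is.finite(s) || s <= 0) {
    stop("cannot normalize: total abundance must be positive", call. = FALSE)
  }
  composition(fc / s, fos / s, md / s)
}

#' @export
print.composition <- function(x, ...) {
  cat(sprintf(
    "composition: Fc %.2f%%  FOS %.2f%%  MD %.2f%%  (FOS:Fc = %.4f)\n",
    100 * x[["fc"]], 100 * x[["fos"]], 100 * x[["md"]],
    x[["fos"]] / x[["fc"]]
  ))
  invisible(x)
}

#' FOS:Fc ratio of a composition
#'
#' The ratio of short-chain (FOS) to long-chain (Fc) fructan content.  This
#' is the quantity whose permeate-to-feed quotient defines the separation
#' factor; mono-/disaccharides never enter it.
#'
#' @param x A [composition()], or a numeric vector with named elements
#'   `fc` and `fos`.
#' @return The dimensionless ratio `fos / fc`.
#' @examples
#' fos_fc_ratio(composition(0.6490, 0.2377, 0.1133))
#' @export
fos_fc_ratio <- function(x) {
  fc <- x[["fc"]]
  fos <- x[["fos"]]
  if (!is.finite(fc) || fc <= 0) {
    stop("FOS:Fc ratio undefined: Fc fraction must be strictly positive",
         call. = FALSE)
  }
  as.numeric(fos / fc)
}

#' Separation factor of an ultrafiltration run
#'
#' The separation factor SF is the FOS:Fc ratio in the permeate divided by
#' the FOS:Fc ratio in the feed.  SF > 1 means the permeate is enriched in
#' short chains relative to the feed, i.e. the membrane fractionates.
#'
#' Arguments may be [composition()] objects or bare numeric FOS:Fc ratios
#' (useful when only the ratios are reported).
#'
#' @param permeate Permeate composition or FOS:Fc ratio.
#' @param feed Feed composition or FOS:Fc ratio.
#' @return The dimensionless separation factor.
#' @examples
#' separation_factor(permeate = 1.225, feed = 0.35)
#' @export
separation_factor <- function(permeate, feed) {
  rp <- if (is.numeric(permeate) && is.null(names(permeate)) &&
            length(permeate) == 1L) as.numeric(permeate) else fos_fc_ratio(permeate)
  rf <- if (is.numeric(feed) && is.null(names(feed)) &&
            length(feed) == 1L) as.numeric(feed) else fos_fc_ratio(feed)
  if (!is.finite(rf) || rf <= 0) {
    stop("separation factor undefined: feed FOS:Fc ratio must be positive",
         call. = FALSE)
  }
  if (!is.finite(rp) || rp < 0) {
    stop("permeate FOS:Fc ratio must be non-negative and finite", call. = FALSE)
  }
  rp / rf
}
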