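# run code under a temporary RNG state so generators are pure in (seed)
with_seed <- function(seed, code) {
  if (is.null(seed) || !is.finite(seed)) stop("a seed is required", call. = FALSE)
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

#' Generate synthetic batches of native agave fructans
#'
#' Emulates the composition structure of commercial native-fructan batches:
#' the long-chain fraction varies between batches (Fc% uniform on 60--75),
#' mono-/disaccharides sit near 10% (normal, sd 1, truncated to 7--13) and
#' FOS takes the remainder -- producing the linear FOS-versus-Fc trade-off
#' seen across real batches and FOS:Fc ratios spanning roughly 0.16--0.55.
#'
#' @param n Number of batches.
#' @param seed RNG seed (mandatory; generators are pure functions of it).
#' @return Data frame with columns `batch_id`, `pct_fc`, `pct_fos`,
#'   `pct_md`; every row closes to 100%.
#' @examples
#' gen_batches(5, seed = 42)
#' @export
gen_batches <- function(n, seed) {
  if (n < 1L) stop("n must be at least 1", call. = FALSE)
  with_seed(seed, {
    pct_fc <- stats::runif(n, 60, 75)
    pct_md <- vapply(seq_len(n), function(i) {
      repeat {
        x <- stats::rnorm(1, 10, 1)
        if (x >= 7 && x <= 13) return(x)
      }
    }, numeric(1))
    pct_fos <- 100 - pct_fc - pct_md
    data.frame(batch_id = seq_len(n), pct_fc = pct_fc,
               pct_fos = pct_fos, pct_md = pct_md)
  })
}

#' Fill a design table with noisy polynomial responses
#'
#' Evaluates a known coded-unit polynomial ("truth") on the design and adds
#' independent Gaussian noise, producing a response column whose refit should
#' recover the truth (exactly at `sigma = 0`).
#'
#' @param design A design table with coded columns (see [box_behnken()]).
#' @param truth Named coefficient vector in coded units; names from
#'   `"(Intercept)"`, `"x1"`, ..., `"x1:x2"`, `"x1^2"`, ...
#' @param sigma Gaussian noise standard deviation (response units).
#' @param seed RNG seed.
#' @param response Name of the response column to fill (default `"sf"`).
#' @return The design with the response column filled.
#' @examples
#' d <- box_behnken()
#' truth <- c("(Intercept)" = 2.71, x1 = 0.1125, "x1^2" = -0.345)
#' d <- gen_bbd_responses(d, truth, sigma = 0.05, seed = 7)
#' @export
gen_bbd_responses <- function(design, truth, sigma = 0, seed = 1,
                              response = "sf") {
  terms <- setdiff(names(truth), "(Intercept)")
  bad <- setdiff(terms, names(rsm_term_table()))
  if (length(bad)) {
    stop("unknown coefficient names: ", paste(bad, collapse = ", "), call. = FALSE)
  }
  X <- rsm_basis(design, terms)
  beta <- c(truth[["(Intercept)"]] %||% 0, truth[terms])
  y <- drop(X %*% beta)
  if (sigma > 0) {
    y <- y + with_seed(seed, stats::rnorm(nrow(design), 0, sigma))
  }
  design[[response]] <- y
  design
}

#' Generate a synthetic flux-versus-concentration curve
#'
#' Evaluates the limiting-flux law on a concentration grid and applies
#' multiplicative Gaussian noise, `J * (1 + N(0, cv))`.  With `cv = 0` and
#' `ro = 1` the curve is exactly log-linear, and [fit_flux_params()]
#' recovers `(k, Clim)` to numerical precision.
#'
#' @param params A [flux_params()] object (the truth).
#' @param conc Concentration grid, strictly inside `(0, c_lim)`.
#' @param cv Multiplicative coefficient of variation (>= 0).
#' @param seed RNG seed.
#' @param ro Rejection used in the flux law (default 1, the pure
#'   gel-polarization form matched by the estimator).
#' @return A [flux_curve()].
#' @export
gen_flux_curve <- function(params, conc = seq(50, 250, by = 50), cv = 0,
                           seed = 1, ro = 1) {
  if (any(conc <= 0) || any(conc >= params$c_lim)) {
    stop("concentration grid must lie strictly inside (0, c_lim)", call. = FALSE)
  }
  j <- limiting_flux(conc, ro, params)
  if (cv > 0) {
    j <- j * (1 + with_seed(seed, stats::rnorm(length(conc), 0, cv)))
    if (any(j < 0)) {
      warning("noisy flux fell below zero; clipped at 0", call. = FALSE)
      j <- pmax(j, 0)
    }
  }
  flux_curve(conc, j)
}

#' Generate a noisy observed ultrafiltration time series
#'
#' Simulates a batch run ([simulate_uf()]), samples retentate and permeate
#' concentrations at the requested times and adds independent additive
#' Gaussian noise, yielding an "observed" table in the layout accepted by
#' [validate_profiles()].
#'
#' @param spec A [uf_system()] object.
#' @param sample_times Observation times, s.
#' @param sigma Additive noise standard deviation, kg m^-3.
#' @param seed RNG seed.
#' @param t_end Simulation horizon; defaults to `max(sample_times)`.
#' @param ... Passed to [simulate_uf()].
#' @return Data frame with columns `time`, `stream`, `solute`, `conc`.
#' @export
gen_uf_timeseries <- function(spec, sample_times, sigma = 0, seed = 1,
                              t_end = max(sample_times), ...) {
  traj <- simulate_uf(spec, t_end = t_end, ...)
  prof <- concentration_profiles(traj, sample_times)
  long <- data.frame(
    time = rep(prof$time, 4),
    stream = rep(c("retentate", "retentate", "permeate", "permeate"),
                 each = nrow(prof)),
    solute = rep(c("fc", "fos", "fc", "fos"), each = nrow(prof)),
    conc = c(prof$c_fc_ret, prof$c_fos_ret, prof$c_fc_perm, prof$c_fos_perm)
  )
  if (sigma > 0) {
    long$conc <- long$conc +
      with_seed(seed, stats::rnorm(nrow(long), 0, sigma))
  }
  long
}
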