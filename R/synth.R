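#' Define a synthetic mixture-measurement scenario
#'
#' Describes repeated noisy readings of a gas mixture whose true spectrum is
#' a linear combination of basis spectra -- the forward model of the
#' deconvolution. Each repeat r (at time `(r-1) * dt` seconds) produces one
#' PEAK reading per grid m/z with current
#' `sum_i a_i(t) * x_i(mz) * (1 + e)`, `e ~ Normal(0, noise_rel_sd)`, plus a
#' matching ZERO reading at zero current; when `noise_rel_sd > 0` an additive
#' detector noise floor (`noise_floor`, default 1e-16 A) is added to every
#' reading so that ZERO readings scatter realistically. With
#' `noise_rel_sd = 0` the readings are exactly noise-free.
#'
#' An optional drift species relaxes exponentially,
#' `a(t) = a_inf + (a_start - a_inf) * exp(-t / tau)`, emulating species such
#' as water vapour that adsorb to the vacuum system and stabilise only slowly
#' after a gas-inlet switch; all other coefficients are constant in time.
#'
#' @param basis list of [basis_spectrum()] objects.
#' @param true_coefficients named numeric vector of non-negative amplitudes
#'   in amperes, one per basis species (`a_inf` for the drift species).
#' @param mz_grid integer m/z values to read; defaults to every m/z where
#'   some basis spectrum is non-zero.
#' @param noise_rel_sd relative (multiplicative) 1-sigma noise per reading.
#' @param n_repeats number of repeated readings per m/z.
#' @param seed integer RNG seed; the same scenario always yields the same
#'   readings.
#' @param drift optional `list(species =, tau =, a_start =)` (seconds,
#'   amperes).
#' @param noise_floor additive 1-sigma detector noise in amperes (only
#'   applied when `noise_rel_sd > 0`).
#' @param dt seconds between repeats.
#' @param detector `"F"` or `"M"`; must match the basis spectra.
#' @return an object of class `mixture_scenario`.
#' @export
mixture_scenario <- function(basis, true_coefficients, mz_grid = NULL,
                             noise_rel_sd = 0.01, n_repeats = 10L, seed = 1L,
                             drift = NULL, noise_floor = 1e-16, dt = 1,
                             detector = NULL) {
  basis <- basis_set(basis)
  if (is.null(detector)) detector <- basis[[1L]]$detector
  if (is.null(names(true_coefficients)) ||
      !setequal(names(true_coefficients), names(basis)))
    stop("true_coefficients must be named by the basis species",
         call. = FALSE)
  true_coefficients <- true_coefficients[names(basis)]
  if (any(true_coefficients < 0))
    stop("true coefficients must be >= 0", call. = FALSE)
  if (noise_rel_sd < 0) stop("noise_rel_sd must be >= 0", call. = FALSE)
  if (n_repeats < 1L) stop("n_repeats must be >= 1", call. = FALSE)
  if (is.null(mz_grid)) mz_grid <- basis_support(basis)
  if (!is.null(drift)) {
    stopifnot(all(c("species", "tau", "a_start") %in% names(drift)))
    if (!drift$species %in% names(basis))
      stop("drift species '", drift$species, "' not in basis", call. = FALSE)
    if (drift$tau <= 0) stop("drift tau must be > 0", call. = FALSE)
  }
  structure(list(basis = basis, true_coefficients = true_coefficients,
                 mz_grid = as.integer(mz_grid),
                 noise_rel_sd = noise_rel_sd,
                 n_repeats = as.integer(n_repeats), seed = as.integer(seed),
                 drift = drift, noise_floor = noise_floor, dt = dt,
                 detector = detector),
            class = "mixture_scenario")
}

# evaluate the (possibly drifting) coefficient vector at time t
.coeff_at <- function(s, t) {
  a <- s$true_coefficients
  if (!is.null(s$drift)) {
    d <- s$drift
    a[d$species] <- a[d$species] +
      (d$a_start - a[d$species]) * exp(-t / d$tau)
  }
  a
}

#' Simulate raw readings for a mixture scenario
#'
#' @param s a [mixture_scenario()].
#' @return a raw-readings data frame (columns `time`, `kind`, `mz`,
#'   `detector`, `current`) suitable for [aggregate_peak_heights()] or
#'   [write_readings()]. Deterministic for a fixed scenario seed.
#' @examples
#' bs <- read_basis_table(msdeconv_example("basis_spectra_ne_45eV.csv"))
#' s <- mixture_scenario(bs, c(H2O = 146e-9, NE20 = 0.55e-9, AR = 1530e-9),
#'                       mz_grid = c(17, 20, 36), noise_rel_sd = 0.01,
#'                       n_repeats = 5, seed = 42)
#' head(simulate_readings(s))
#' @export
simulate_readings <- function(s) {
  stopifnot(inherits(s, "mixture_scenario"))
  X <- vapply(s$basis, basis_value, numeric(length(s$mz_grid)),
              mz = s$mz_grid)
  X <- matrix(X, nrow = length(s$mz_grid))
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old,
                                    envir = globalenv()))
  set.seed(s$seed)
  rows <- vector("list", s$n_repeats)
  nm <- length(s$mz_grid)
  for (r in seq_len(s$n_repeats)) {
    t <- (r - 1L) * s$dt
    ytrue <- drop(X %*% .coeff_at(s, t))
    if (s$noise_rel_sd > 0) {
      peak <- ytrue * (1 + rnorm(nm, 0, s$noise_rel_sd)) +
        rnorm(nm, 0, s$noise_floor)
      zero <- rnorm(nm, 0, s$noise_floor)
    } else {
      peak <- ytrue
      zero <- rep(0, nm)
    }
    rows[[r]] <- data.frame(
      time = t + c(rep(0, nm), rep(s$dt / 2, nm)),
      kind = rep(c("PEAK", "ZERO"), each = nm),
      mz = rep(s$mz_grid, 2L),
      detector = s$detector,
      current = c(peak, zero))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Simulate, aggregate and fit a scenario, and check error coverage
#'
#' Runs the full pipeline on one synthetic scenario -- simulate readings,
#' aggregate to peak heights, deconvolve -- and compares the estimated
#' coefficients to the scenario's true values. A species is "covered" when
#' the true value lies within 2 estimated standard errors of the estimate;
#' across many scenario replicates the 2-sigma coverage rate gauges whether
#' the error model is calibrated.
#'
#' @param s a [mixture_scenario()] without drift.
#' @param method aggregation method (see [aggregate_peak_heights()]).
#' @param error_floor relative error floor applied during aggregation.
#' @return a data frame with one row per species: `a_true`, `a_est`, `da`,
#'   `bias`, `covered`; the underlying `deconv_fit` is attached as attribute
#'   `fit`.
#' @export
recovery_experiment <- function(s, method = "mean", error_floor = 0.01) {
  stopifnot(inherits(s, "mixture_scenario"))
  if (!is.null(s$drift))
    stop("recovery_experiment requires a drift-free scenario", call. = FALSE)
  if (length(s$mz_grid) < length(s$basis))
    stop("underdetermined scenario: fewer grid m/z than basis spectra",
         call. = FALSE)
  readings <- simulate_readings(s)
  peaks <- aggregate_peak_heights(readings, method = method,
                                  error_floor = error_floor)
  fit <- fit_coefficients(peaks, s$basis)
  a_true <- s$true_coefficients[names(fit$coefficients)]
  out <- data.frame(species = names(fit$coefficients),
                    a_true = unname(a_true),
                    a_est = unname(fit$coefficients),
                    da = unname(fit$da),
                    bias = unname(fit$coefficients - a_true),
                    covered = unname(abs(fit$coefficients - a_true) <=
                                       2 * fit$da))
  attr(out, "fit") <- fit
  out
}
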