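#' Compensate a measured peak height for overlap interferences
#'
#' Multiplies the measured ion current at the target m/z by the deconvolved
#' fraction contributed by the target species, removing the interfering
#' species' share. Only this compensated current may be used in the
#' peak-height comparison. Relative errors of the fraction and of the peak
#' height are combined in quadrature, so a compensated peak always carries at
#' least the raw peak's relative error -- the deconvolution adds uncertainty,
#' it never hides it.
#'
#' A negative model fraction (possible with an unconstrained fit when the
#' target contributes essentially nothing) is clipped to 0 with a warning and
#' the result flagged below detection.
#'
#' @param peak one-row `peak_table` at the target m/z.
#' @param fractions a [ion_current_fractions()] table evaluated at
#'   `peak$mz`, or `NULL` for no interference (fraction 1, exactly).
#' @param target_species species whose contribution is kept; required unless
#'   `fractions` is `NULL`.
#' @param digits optionally round the fraction and its error to this many
#'   decimals before use, mirroring hand calculations done from printed
#'   two-decimal fractions.
#' @return an object of class `compensated_peak`: `mz`, `detector`,
#'   `species`, `y`, `dy` (raw), `fraction`, `dfraction`, `y_comp`,
#'   `dy_comp`, `below_detection`.
#' @examples
#' pk <- peak_heights(15, 0.629e-12, 0.008e-12)
#' ft <- data.frame(species = "CH4", contribution = NA,
#'                  fraction = 0.70, dfraction = 0.03)
#' attr(ft, "mz") <- 15L
#' class(ft) <- c("fraction_table", "data.frame")
#' compensate(pk, ft, "CH4")
#' @export
compensate <- function(peak, fractions, target_species = NULL,
                       digits = NULL) {
  stopifnot(is.data.frame(peak), nrow(peak) == 1L)
  if (is.null(fractions)) {
    f <- 1; df <- 0
    species <- if (is.null(target_species)) NA_character_ else target_species
  } else {
    stopifnot(inherits(fractions, "fraction_table"))
    if (!is.null(attr(fractions, "mz")) &&
        attr(fractions, "mz") != peak$mz)
      stop("fractions were evaluated at m/z=", attr(fractions, "mz"),
           " but the peak is at m/z=", peak$mz, call. = FALSE)
    i <- match(target_species, fractions$species)
    if (is.na(i))
      stop("species '", target_species, "' not in the fraction table",
           call. = FALSE)
    f <- fractions$fraction[i]
    df <- fractions$dfraction[i]
    species <- target_species
  }
  if (!is.null(digits)) {
    f <- round(f, digits)
    df <- round(df, digits)
  }
  below <- FALSE
  if (f < 0) {
    warning("negative model fraction (", signif(f, 3), ") for '", species,
            "' clipped to 0", call. = FALSE)
    f <- 0
  }
  if (f > 1) f <- 1
  if (f == 0) {
    below <- TRUE
    y_comp <- 0
    dy_comp <- df * abs(peak$y)   # all that remains is the fraction error
  } else {
    y_comp <- f * peak$y
    dy_comp <- abs(y_comp) * sqrt((df / f)^2 + (peak$dy / peak$y)^2)
  }
  structure(list(mz = peak$mz, detector = peak$detector, species = species,
                 y = peak$y, dy = peak$dy, fraction = f, dfraction = df,
                 y_comp = y_comp, dy_comp = dy_comp,
                 below_detection = below),
            class = "compensated_peak")
}

#' @export
print.compensated_peak <- function(x, ...) {
  cat(sprintf(
    "Compensated peak %s at m/z=%d (detector %s):\n  raw %s +- %s; fraction %.4g +- %.2g; compensated %s +- %s%s\n",
    x$species, x$mz, x$detector, format_current(x$y), format_current(x$dy),
    x$fraction, x$dfraction, format_current(x$y_comp),
    format_current(x$dy_comp),
    if (x$below_detection) " [below detection]" else ""))
  invisible(x)
}

#' Calibrate a concentration or partial pressure by peak-height comparison
#'
#' The amount of the target species in the sample equals the known amount in
#' the reference gas times the ratio of the (interference-compensated) ion
#' currents, because detector sensitivity cancels in the ratio. Relative
#' errors of both compensated peaks -- and of the reference amount, if one is
#' given -- combine in quadrature.
#'
#' @param sample,reference [compensate()] results for the same species, m/z
#'   and detector (apply `compensate(peak, NULL)` to use raw, uncompensated
#'   peaks).
#' @param reference_amount known amount of the species in the reference gas
#'   (any unit: ppm-vol, %-vol, partial pressure; the result inherits it).
#' @param reference_damount 1-sigma error of `reference_amount` (default 0:
#'   certified standards are usually taken as exact).
#' @param units unit label carried into the result.
#' @param reference_label name of the reference gas, for the report.
#' @return an object of class `calibrated_amount`: `species`, `value`,
#'   `dvalue`, `units`, `reference`.
#' @export
calibrate <- function(sample, reference, reference_amount,
                      reference_damount = 0, units = "",
                      reference_label = "reference") {
  stopifnot(inherits(sample, "compensated_peak"),
            inherits(reference, "compensated_peak"))
  if (!identical(sample$mz, reference$mz) ||
      !identical(sample$detector, reference$detector))
    stop("calibration error: sample and reference must share m/z and ",
         "detector (sample m/z=", sample$mz, "/", sample$detector,
         ", reference m/z=", reference$mz, "/", reference$detector, ")",
         call. = FALSE)
  if (!is.na(sample$species) && !is.na(reference$species) &&
      sample$species != reference$species)
    stop("calibration error: sample species '", sample$species,
         "' differs from reference species '", reference$species, "'",
         call. = FALSE)
  if (reference$y_comp <= 0)
    stop("invalid reference: compensated reference peak is not positive",
         call. = FALSE)
  if (reference_amount <= 0)
    stop("invalid reference: reference_amount must be positive",
         call. = FALSE)
  value <- sample$y_comp / reference$y_comp * reference_amount
  rel2 <- (reference$dy_comp / reference$y_comp)^2 +
    (reference_damount / reference_amount)^2
  if (sample$y_comp > 0) rel2 <- rel2 + (sample$dy_comp / sample$y_comp)^2
  dvalue <- if (sample$y_comp > 0) abs(value) * sqrt(rel2)
            else sample$dy_comp / reference$y_comp * reference_amount
  structure(list(species = sample$species, value = value, dvalue = dvalue,
                 units = units, reference = reference_label,
                 below_detection = isTRUE(sample$below_detection)),
            class = "calibrated_amount")
}

#' @export
print.calibrated_amount <- function(x, ...) {
  cat(sprintf("%s: %s +- %s %s (vs %s)%s\n", x$species,
              signif(x$value, 6), signif(x$dvalue, 3), x$units, x$reference,
              if (x$below_detection) " [below detection]" else ""))
  invisible(x)
}

#' Subtract a blank analysis from a peak table
#'
#' When a blank step is measured, its peak heights are subtracted from the
#' corresponding sample/standard peaks (matched by m/z, detector and role)
#' before deconvolution; errors add in quadrature and the relative error
#' floor is re-applied.
#'
#' @param peaks a `peak_table`.
#' @param blank a `peak_table` of blank peak heights; peaks without a
#'   matching blank entry are left unchanged.
#' @param error_floor minimum relative uncertainty re-applied after
#'   subtraction.
#' @return the corrected `peak_table`.
#' @export
subtract_blank <- function(peaks, blank, error_floor = 0.01) {
  key <- function(p) paste(p$mz, p$detector, p$role)
  i <- match(key(peaks), key(blank))
  hit <- !is.na(i)
  y <- peaks$y
  dy <- peaks$dy
  y[hit] <- y[hit] - blank$y[i[hit]]
  dy[hit] <- sqrt(dy[hit]^2 + blank$dy[i[hit]]^2)
  peak_heights(peaks$mz, y, dy, detector = peaks$detector, role = peaks$role,
               n_peak = peaks$n_peak, n_zero = peaks$n_zero,
               error_floor = error_floor)
}
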