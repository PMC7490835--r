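#' Construct a table of peak heights with uncertainties
#'
#' A peak table holds ion-current peak heights `y` (amperes) with 1-sigma
#' uncertainties `dy` at integer m/z values on one or more detectors. The
#' relative uncertainty is floored at `error_floor` (default 1 %): errors of
#' the mean from repeated readings capture only random noise within one
#' measurement and underestimate drift and non-linearity of the instrument,
#' for which 1 % is the typical attainable peak-height accuracy.
#'
#' `role` separates `"main"` peaks (used for calibration and, where needed,
#' deconvolution) from `"helper"` peaks recorded at extra m/z values solely
#' to constrain the deconvolution; helper peaks never enter the peak-height
#' comparison.
#'
#' @param mz positive integer m/z values.
#' @param y peak heights in amperes.
#' @param dy 1-sigma uncertainties in amperes (before flooring).
#' @param detector `"F"` or `"M"`, recycled.
#' @param role `"main"` or `"helper"`, recycled.
#' @param n_peak,n_zero numbers of raw PEAK/ZERO readings behind each value
#'   (bookkeeping only).
#' @param error_floor minimum relative uncertainty applied as
#'   `dy = max(dy, error_floor * |y|)`.
#' @return a `peak_table` data frame with columns `mz`, `detector`, `y`,
#'   `dy`, `n_peak`, `n_zero`, `role`.
#' @examples
#' peak_heights(c(14, 15), c(127e-12, 394e-12), c(2e-12, 6e-12))
#' @export
peak_heights <- function(mz, y, dy = 0, detector = "F", role = "main",
                         n_peak = 1L, n_zero = 0L, error_floor = 0.01) {
  n <- length(mz)
  if (any(mz <= 0) || any(mz != round(mz)))
    stop("m/z must be positive integers", call. = FALSE)
  if (!all(detector %in% c("F", "M")))
    stop("detector must be F or M", call. = FALSE)
  if (!all(role %in% c("main", "helper")))
    stop("role must be 'main' or 'helper'", call. = FALSE)
  if (any(dy < 0)) stop("dy must be >= 0", call. = FALSE)
  dy <- pmax(rep_len(dy, n), error_floor * abs(y))
  if (any(dy <= 0))
    stop("peak with y = 0 and dy = 0: uncertainty cannot be estimated",
         call. = FALSE)
  structure(
    data.frame(mz = as.integer(mz),
               detector = rep_len(detector, n),
               y = as.numeric(y), dy = dy,
               n_peak = rep_len(as.integer(n_peak), n),
               n_zero = rep_len(as.integer(n_zero), n),
               role = rep_len(role, n)),
    class = c("peak_table", "data.frame"))
}

#' Validate a peak table as a single-detector measured spectrum
#'
#' A measured spectrum is the input to [fit_coefficients()]: peak heights at
#' unique m/z values, all from one detector and all with strictly positive
#' uncertainties. Mixing the electron multiplier and the Faraday cup in one
#' deconvolution is rejected because their sensitivity ratio drifts between
#' analysis steps.
#'
#' @param peaks a `peak_table` (main and helper peaks both allowed).
#' @return `peaks`, with class `measured_spectrum` prepended.
#' @export
as_measured_spectrum <- function(peaks) {
  stopifnot(is.data.frame(peaks))
  need <- c("mz", "detector", "y", "dy")
  if (!all(need %in% names(peaks)))
    stop("peak table needs columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  if (nrow(peaks) == 0L) stop("empty spectrum", call. = FALSE)
  if (length(unique(peaks$detector)) != 1L)
    stop("mixed-detector spectrum: all peaks must come from one detector",
         call. = FALSE)
  if (anyDuplicated(peaks$mz))
    stop("duplicated m/z in measured spectrum", call. = FALSE)
  if (any(peaks$dy <= 0))
    stop("all peak uncertainties dy must be > 0", call. = FALSE)
  if (!inherits(peaks, "measured_spectrum"))
    class(peaks) <- c("measured_spectrum", class(peaks))
  peaks
}

#' Read a peak-height table from a delimited text file
#'
#' Columns: `mz`, `y`, `dy`, and optionally `gas` (sample label), `detector`,
#' `role`, `unit` (one of A, mA, uA, nA, pA, fA; default A). Currents are
#' converted to amperes and the 1 % relative error floor is applied.
#'
#' @param path CSV file path.
#' @param error_floor minimum relative uncertainty (see [peak_heights()]).
#' @return a `peak_table`; if the file has a `gas` column it is kept, and
#'   [gas_peaks()] extracts one gas.
#' @examples
#' pt <- read_peak_table(msdeconv_example("peaks_ne_gases.csv"))
#' gas_peaks(pt, "GAS-III")
#' @export
read_peak_table <- function(path, error_floor = 0.01) {
  d <- read.csv(path, stringsAsFactors = FALSE)
  if (is.logical(d$detector))  # a column of bare "F" parses as logical
    d$detector <- ifelse(d$detector, "T", "F")
  need <- c("mz", "y", "dy")
  if (!all(need %in% names(d)))
    stop("peak table needs columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  scale <- if ("unit" %in% names(d)) {
    if (!all(d$unit %in% names(.current_units)))
      stop("unknown current unit: ",
           paste(setdiff(d$unit, names(.current_units)), collapse = ", "),
           call. = FALSE)
    .current_units[d$unit]
  } else 1
  pt <- peak_heights(
    d$mz, d$y * scale, d$dy * scale,
    detector = if ("detector" %in% names(d)) d$detector else "F",
    role = if ("role" %in% names(d)) d$role else "main",
    error_floor = error_floor)
  if ("gas" %in% names(d)) pt <- cbind(gas = d$gas, pt)
  class(pt) <- c("peak_table", "data.frame")
  pt
}

#' Extract the peaks of one gas from a multi-gas peak table
#'
#' @param peaks a `peak_table` with a `gas` column.
#' @param gas label to extract.
#' @return a `peak_table` without the `gas` column.
#' @export
gas_peaks <- function(peaks, gas) {
  if (!"gas" %in% names(peaks))
    stop("peak table has no 'gas' column", call. = FALSE)
  out <- peaks[peaks$gas == gas, setdiff(names(peaks), "gas"), drop = FALSE]
  if (nrow(out) == 0L)
    stop("no peaks for gas '", gas, "'", call. = FALSE)
  rownames(out) <- NULL
  class(out) <- c("peak_table", "data.frame")
  out
}

#' @export
print.peak_table <- function(x, ...) {
  y <- as.data.frame(x)
  y$y <- format_current(x$y)
  y$dy <- format_current(x$dy)
  print(y, ...)
  invisible(x)
}
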