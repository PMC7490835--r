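#' Read raw ion-current readings from a plain-text file
#'
#' The raw-readings dialect is one reading per line:
#'
#' ```
#' <ISO-8601 timestamp> <kind> mz=<int> detector=<F|M> I=<value><unit>
#' ```
#'
#' with `kind` one of `PEAK`, `ZERO`, `PEAK_DECONV`, `ZERO_DECONV` and
#' `<unit>` one of A, mA, uA, nA, pA, fA. `PEAK`/`ZERO` readings feed the
#' main peaks used in calibration; the `*_DECONV` kinds mark helper readings
#' recorded at extra m/z values that only constrain the deconvolution and are
#' never used in the peak-height comparison. Lines that are empty, start with
#' `#`, or start with `DECONVOLUTION:` (see
#' [read_deconvolution_blocks()]) are skipped.
#'
#' @param path file path, or a character vector of lines via `text =`.
#' @param text optional character vector of lines instead of a file.
#' @return data frame with columns `time` (seconds, POSIX epoch), `kind`,
#'   `mz`, `detector`, `current` (amperes).
#' @seealso [aggregate_peak_heights()], [write_readings()]
#' @export
read_readings <- function(path, text = NULL) {
  lines <- if (is.null(text)) readLines(path, warn = FALSE) else text
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#") &
                 !startsWith(lines, "DECONVOLUTION:")]
  if (length(lines) == 0L)
    return(data.frame(time = numeric(), kind = character(), mz = integer(),
                      detector = character(), current = numeric()))
  pat <- paste0("^(\\S+)\\s+(PEAK_DECONV|ZERO_DECONV|PEAK|ZERO)\\s+",
                "mz=(\\d+)\\s+detector=([FM])\\s+",
                "I=([-+0-9.eE]+)(A|mA|uA|nA|pA|fA)$")
  bad <- !grepl(pat, lines)
  if (any(bad))
    stop("unparseable reading line(s): ",
         paste(utils::head(lines[bad], 3), collapse = " | "), call. = FALSE)
  m <- regmatches(lines, regexec(pat, lines))
  f <- function(i) vapply(m, `[[`, character(1), i + 1L)
  tm <- as.POSIXct(sub("Z$", "", f(1)), format = "%Y-%m-%dT%H:%M:%OS",
                   tz = "UTC")
  if (anyNA(tm)) stop("unparseable timestamp in readings file", call. = FALSE)
  data.frame(time = as.numeric(tm),
             kind = f(2),
             mz = as.integer(f(3)),
             detector = f(4),
             current = as.numeric(f(5)) * .current_units[f(6)],
             row.names = NULL)
}

#' Write raw readings in the plain-text dialect
#'
#' @param readings data frame as returned by [read_readings()] or
#'   [simulate_readings()].
#' @param path output file; omit to get the lines back as a character vector.
#' @param unit current unit used on output, or `"auto"` to pick a readable
#'   unit per line.
#' @return the lines, invisibly if written to a file.
#' @export
write_readings <- function(readings, path = NULL, unit = "auto") {
  pick <- function(xi) {
    if (!is.finite(xi) || xi == 0) return("A")
    fits <- abs(xi) >= .current_units * 0.9999
    if (any(fits)) names(.current_units)[which.max(fits)] else "fA"
  }
  units <- if (identical(unit, "auto"))
    vapply(readings$current, pick, character(1))
  else rep_len(match.arg(unit, names(.current_units)), nrow(readings))
  lines <- sprintf("%s %s mz=%d detector=%s I=%s%s",
    format(as.POSIXct(readings$time, origin = "1970-01-01", tz = "UTC"),
           "%Y-%m-%dT%H:%M:%OS3Z"),
    readings$kind, readings$mz, readings$detector,
    sprintf("%.12g", readings$current / .current_units[units]),
    units)
  if (is.null(path)) return(lines)
  writeLines(lines, path)
  invisible(lines)
}

#' Aggregate repeated raw readings into peak heights
#'
#' Readings are grouped by (m/z, detector, role), where the role is
#' `"helper"` for the `PEAK_DECONV`/`ZERO_DECONV` kinds and `"main"`
#' otherwise. Within each group the PEAK-type readings and the ZERO-type
#' readings are aggregated separately (mean or median) and the peak height is
#' their difference; a group without ZERO readings gets a zero offset of 0.
#' The uncertainty is the quadrature sum of the two standard errors of the
#' mean (0 for single readings), floored at `error_floor` times the peak
#' height -- so a group of identical readings still carries the 1 % relative
#' error that reflects instrument drift and non-linearity.
#'
#' @param readings data frame of raw readings (see [read_readings()]).
#' @param method `"mean"` or `"median"` for the central value; the
#'   uncertainty always uses the standard error of the mean.
#' @param error_floor minimum relative uncertainty.
#' @return a `peak_table` (see [peak_heights()]).
#' @examples
#' r <- data.frame(time = 1:3, kind = "PEAK", mz = 15, detector = "F",
#'                 current = c(9e-12, 10e-12, 11e-12))
#' aggregate_peak_heights(r)   # y = 10 pA, dy = sem = 0.577 pA
#' @export
aggregate_peak_heights <- function(readings, method = c("mean", "median"),
                                   error_floor = 0.01) {
  method <- match.arg(method)
  stopifnot(is.data.frame(readings))
  if (!all(readings$kind %in% c("PEAK", "ZERO", "PEAK_DECONV", "ZERO_DECONV")))
    stop("unknown reading kind", call. = FALSE)
  role <- ifelse(readings$kind %in% c("PEAK_DECONV", "ZERO_DECONV"),
                 "helper", "main")
  key <- interaction(readings$mz, readings$detector, role, drop = TRUE)
  agg <- if (method == "mean") mean else median
  sem <- function(x) if (length(x) > 1L) sd(x) / sqrt(length(x)) else 0
  rows <- lapply(split(seq_len(nrow(readings)), key), function(idx) {
    g <- readings[idx, ]
    is_peak <- g$kind %in% c("PEAK", "PEAK_DECONV")
    pk <- g$current[is_peak]
    zr <- g$current[!is_peak]
    if (length(pk) == 0L)
      stop("missing data: no PEAK readings for m/z ", g$mz[1L],
           " detector ", g$detector[1L], call. = FALSE)
    y <- agg(pk) - (if (length(zr)) agg(zr) else 0)
    dy <- sqrt(sem(pk)^2 + sem(zr)^2)
    peak_heights(g$mz[1L], y, dy, detector = g$detector[1L],
                 role = if (all(g$kind %in% c("PEAK_DECONV", "ZERO_DECONV")))
                   "helper" else "main",
                 n_peak = length(pk), n_zero = length(zr),
                 error_floor = error_floor)
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$detector, out$role, out$mz), ]
  rownames(out) <- NULL
  class(out) <- c("peak_table", "data.frame")
  out
}
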