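#' Define one analysis step (sample, standard or blank)
#'
#' An analysis step bundles the peak heights of one measurement run with the
#' DECONVOLUTION blocks that apply to it. It can be built directly from
#' objects, or read from a raw data file that contains both the readings and
#' the blocks (see [read_analysis_step()]).
#'
#' @param peaks a `peak_table` (main and helper peaks).
#' @param blocks list of [deconvolution_block()] objects (may be empty: then
#'   no interference compensation is applied).
#' @param label `"sample"`, `"standard"` or `"blank"`.
#' @return an object of class `analysis_step`.
#' @export
analysis_step <- function(peaks, blocks = list(),
                          label = c("sample", "standard", "blank")) {
  label <- match.arg(label)
  stopifnot(is.data.frame(peaks))
  if (inherits(blocks, "deconvolution_block")) blocks <- list(blocks)
  ok <- vapply(blocks, inherits, logical(1), "deconvolution_block")
  if (!all(ok)) stop("blocks must be deconvolution_block objects",
                     call. = FALSE)
  structure(list(label = label, peaks = peaks, blocks = blocks),
            class = "analysis_step")
}

#' Read an analysis step from a raw data file
#'
#' The file holds raw readings in the plain-text dialect of
#' [read_readings()], plus any number of `DECONVOLUTION:` lines. Readings are
#' aggregated into peak heights and the blocks are parsed.
#'
#' @param path file path.
#' @param label step label (`"sample"`, `"standard"`, `"blank"`).
#' @param method,error_floor passed to [aggregate_peak_heights()].
#' @return an [analysis_step()].
#' @export
read_analysis_step <- function(path, label = "sample", method = "mean",
                               error_floor = 0.01) {
  readings <- read_readings(path)
  if (nrow(readings) == 0L)
    stop("no readings in '", path, "'", call. = FALSE)
  analysis_step(
    aggregate_peak_heights(readings, method = method,
                           error_floor = error_floor),
    read_deconvolution_blocks(path),
    label = label)
}

#' Process one analysis step: deconvolve and compensate every target
#'
#' For each DECONVOLUTION block of the step, the peaks recorded with the
#' block's detector (main peaks and deconvolution helper peaks alike) at m/z
#' values covered by the block's basis spectra are deconvolved with
#' [fit_coefficients()]; the ion-current fractions at the block's target m/z
#' are computed and the main peak there is compensated with [compensate()].
#' Steps without blocks simply pass their main peaks through uncompensated
#' (fraction 1). Helper peaks are used only inside the fits and never appear
#' among the compensated results.
#'
#' @param step an [analysis_step()].
#' @param blank optionally, a processed blank step or `peak_table` whose peak
#'   heights are subtracted first (see [subtract_blank()]).
#' @param nonneg passed to [fit_coefficients()].
#' @return an object of class `analysis_result`: the (blank-corrected)
#'   `peaks` and a list `targets`, one element per block with `block`, `fit`,
#'   `fractions`, `raw_peak` and `compensated`.
#' @examples
#' bs <- read_basis_table(msdeconv_example("basis_spectra_ne_45eV.csv"))
#' pk <- gas_peaks(read_peak_table(msdeconv_example("peaks_ne_gases.csv")),
#'                 "GAS-IV")
#' blk <- deconvolution_block(20, "NE20", bs, detector = "M", ms_ee = 45)
#' run_step(analysis_step(pk, list(blk)))
#' @export
run_step <- function(step, blank = NULL, nonneg = FALSE) {
  stopifnot(inherits(step, "analysis_step"))
  peaks <- step$peaks
  if (!is.null(blank)) {
    bpk <- if (inherits(blank, "analysis_result")) blank$peaks
           else if (inherits(blank, "analysis_step")) blank$peaks
           else blank
    peaks <- subtract_blank(peaks, bpk)
  }
  targets <- lapply(step$blocks, function(block) {
    sel <- peaks$detector == block$detector &
      peaks$mz %in% basis_support(block$basis)
    sub <- peaks[sel, , drop = FALSE]
    if (nrow(sub) == 0L)
      stop("deconvolution '", block$target_species, "' at m/z=",
           block$target_mz, ": no peaks recorded with detector ",
           block$detector, call. = FALSE)
    main <- sub[sub$role == "main" & sub$mz == block$target_mz, ,
                drop = FALSE]
    if (nrow(main) != 1L)
      stop("deconvolution '", block$target_species, "' at m/z=",
           block$target_mz, ": no main peak at the target m/z on detector ",
           block$detector, call. = FALSE)
    fit <- tryCatch(
      fit_coefficients(sub, block$basis, nonneg = nonneg),
      error = function(e)
        stop("deconvolution '", block$target_species, "' at m/z=",
             block$target_mz, ": ", conditionMessage(e), call. = FALSE))
    fractions <- ion_current_fractions(fit, block$target_mz,
                                       observed = main)
    list(block = block, fit = fit, fractions = fractions, raw_peak = main,
         compensated = compensate(main, fractions, block$target_species))
  })
  names(targets) <- vapply(step$blocks, function(b)
    sprintf("%s@%d", b$target_species, b$target_mz), character(1))
  structure(list(label = step$label, peaks = peaks, targets = targets),
            class = "analysis_result")
}

#' @export
print.analysis_result <- function(x, ...) {
  cat(sprintf("Analysis step '%s': %d peaks, %d deconvolution target(s)\n",
              x$label, nrow(x$peaks), length(x$targets)))
  for (tg in x$targets) print(tg$compensated)
  invisible(x)
}

#' Calibrate every deconvolution target of a sample against a standard
#'
#' Matches each compensated target of the processed sample step with the same
#' species/m-z target of the processed standard step and applies
#' [calibrate()] with the standard's known amount. Targets that the standard
#' step measured without a DECONVOLUTION block are compared against its raw
#' main peak (fraction 1).
#'
#' @param sample,standard [run_step()] results.
#' @param standard_amounts named numeric vector: known amount of each target
#'   species in the standard gas.
#' @param standard_damounts named numeric vector of 1-sigma errors on the
#'   amounts (default 0).
#' @param units unit label of the amounts.
#' @param standard_label reference-gas name for the report.
#' @return a data frame with one row per target: `species`, `mz`, `detector`,
#'   raw and compensated currents with errors, fraction with error, and the
#'   calibrated `value`/`dvalue`.
#' @export
run_calibration <- function(sample, standard, standard_amounts,
                            standard_damounts = NULL, units = "",
                            standard_label = "standard") {
  stopifnot(inherits(sample, "analysis_result"),
            inherits(standard, "analysis_result"))
  if (length(sample$targets) == 0L)
    stop("sample step has no deconvolution targets to calibrate",
         call. = FALSE)
  rows <- lapply(sample$targets, function(tg) {
    sp <- tg$block$target_species
    if (!sp %in% names(standard_amounts))
      stop("missing standard amount for species '", sp, "'", call. = FALSE)
    ref <- standard$targets[[sprintf("%s@%d", sp, tg$block$target_mz)]]
    ref_comp <- if (!is.null(ref)) ref$compensated else {
      m <- standard$peaks[standard$peaks$role == "main" &
                            standard$peaks$mz == tg$block$target_mz &
                            standard$peaks$detector == tg$block$detector, ,
                          drop = FALSE]
      if (nrow(m) != 1L)
        stop("standard step has no peak for '", sp, "' at m/z=",
             tg$block$target_mz, call. = FALSE)
      compensate(m, NULL, sp)
    }
    dam <- if (!is.null(standard_damounts) && sp %in% names(standard_damounts))
      standard_damounts[[sp]] else 0
    cal <- calibrate(tg$compensated, ref_comp, standard_amounts[[sp]],
                     reference_damount = dam, units = units,
                     reference_label = standard_label)
    data.frame(species = sp, mz = tg$block$target_mz,
               detector = tg$block$detector,
               y = tg$compensated$y, dy = tg$compensated$dy,
               fraction = tg$compensated$fraction,
               dfraction = tg$compensated$dfraction,
               y_comp = tg$compensated$y_comp,
               dy_comp = tg$compensated$dy_comp,
               value = cal$value, dvalue = cal$dvalue, units = units,
               reference = standard_label)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
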