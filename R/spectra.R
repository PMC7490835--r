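#' Create a max-normalised basis spectrum
#'
#' A basis spectrum is the characteristic ion-current pattern of a single gas
#' species (or a fixed mixture, e.g. clean air) over integer m/z values, as
#' measured on the same instrument and with the same ion-source settings as
#' the gas analyses it will be used to deconvolve. Intensities are
#' dimensionless and normalised so that the largest stored intensity equals
#' 1; any m/z not stored evaluates to exactly 0 (see [basis_value()]).
#'
#' Raw (un-normalised) intensities are accepted and divided by their maximum,
#' so constructing a basis spectrum is idempotent and invariant under
#' positive rescaling of the input.
#'
#' @param species character label, e.g. `"CH4"`.
#' @param intensities named numeric vector of non-negative intensities; names
#'   are positive integer m/z values. Fractional m/z values are rejected (the
#'   instrument class targeted here resolves no better than 0.5 amu and all
#'   basis data are tabulated on integers); rounding silently would hide
#'   configuration mistakes.
#' @param detector `"F"` (Faraday cup) or `"M"` (electron multiplier).
#'   Deconvolution refuses to mix basis spectra and measurements from
#'   different detectors, because the multiplier/Faraday sensitivity ratio
#'   drifts between analysis steps.
#' @param electron_energy ion-source electron energy in eV. Documentation
#'   only; it is never used in the numerics.
#' @return an object of class `basis_spectrum`.
#' @examples
#' ch4 <- basis_spectrum("CH4", c(`14` = 0.206, `15` = 1.612, `16` = 2.0))
#' basis_value(ch4, 15)   # 0.806
#' basis_value(ch4, 28)   # 0: absent m/z values are zero
#' @seealso [basis_value()], [read_basis_table()]
#' @export
basis_spectrum <- function(species, intensities, detector = c("F", "M"),
                           electron_energy = NA_real_) {
  detector <- match.arg(detector)
  if (!is.character(species) || length(species) != 1L || !nzchar(species))
    stop("invalid basis: 'species' must be a non-empty string", call. = FALSE)
  if (length(intensities) == 0L)
    stop("invalid basis '", species, "': no intensities given", call. = FALSE)
  mz <- suppressWarnings(as.numeric(names(intensities)))
  if (anyNA(mz))
    stop("invalid basis '", species, "': intensities must be named by m/z",
         call. = FALSE)
  if (any(mz <= 0) || any(mz != round(mz)))
    stop("invalid basis '", species,
         "': m/z values must be positive integers (got ",
         paste(mz[mz <= 0 | mz != round(mz)], collapse = ", "), ")",
         call. = FALSE)
  if (anyDuplicated(mz))
    stop("invalid basis '", species, "': duplicated m/z values", call. = FALSE)
  intensities <- as.numeric(intensities)
  if (anyNA(intensities) || any(intensities < 0))
    stop("invalid basis '", species, "': intensities must be >= 0",
         call. = FALSE)
  mx <- max(intensities)
  if (mx <= 0)
    stop("invalid basis '", species, "': all intensities are zero",
         call. = FALSE)
  intensities <- intensities / mx
  o <- order(mz)
  structure(
    list(species = species,
         intensities = setNames(intensities[o], as.integer(mz[o])),
         detector = detector,
         electron_energy = as.numeric(electron_energy)),
    class = "basis_spectrum")
}

#' Look up a basis-spectrum intensity at an m/z value
#'
#' @param b a [basis_spectrum()].
#' @param mz positive integer m/z value(s).
#' @return numeric vector of intensities; m/z values not stored in the
#'   spectrum return exactly 0 (empty table cells are treated as zero).
#' @export
basis_value <- function(b, mz) {
  stopifnot(inherits(b, "basis_spectrum"))
  if (any(mz <= 0) || any(mz != round(mz)))
    stop("m/z must be a positive integer", call. = FALSE)
  v <- b$intensities[as.character(as.integer(mz))]
  v[is.na(v)] <- 0
  unname(v)
}

#' @export
print.basis_spectrum <- function(x, ...) {
  cat(sprintf("Basis spectrum '%s' (detector %s%s)\n", x$species, x$detector,
              if (is.finite(x$electron_energy))
                sprintf(", %g eV", x$electron_energy) else ""))
  print(x$intensities)
  invisible(x)
}

#' Assemble and validate a set of basis spectra
#'
#' @param ... [basis_spectrum()] objects, or a single list of them.
#' @return a named list of basis spectra (names are the species labels).
#' @export
basis_set <- function(...) {
  bs <- list(...)
  if (length(bs) == 1L && !inherits(bs[[1L]], "basis_spectrum"))
    bs <- bs[[1L]]
  if (length(bs) == 0L) stop("empty basis set", call. = FALSE)
  ok <- vapply(bs, inherits, logical(1), "basis_spectrum")
  if (!all(ok)) stop("all elements must be basis spectra", call. = FALSE)
  nm <- vapply(bs, `[[`, character(1), "species")
  if (anyDuplicated(nm))
    stop("duplicated species in basis set: ",
         paste(unique(nm[duplicated(nm)]), collapse = ", "), call. = FALSE)
  setNames(bs, nm)
}

#' All m/z values where at least one basis spectrum is non-zero
#' @param basis a list of basis spectra.
#' @return sorted integer vector.
#' @export
basis_support <- function(basis) {
  sort(unique(unlist(lapply(basis, function(b)
    as.integer(names(b$intensities)[b$intensities > 0])))))
}

#' Read basis spectra from a delimited text table
#'
#' The table must have columns `species`, `mz`, `intensity` and may have
#' `detector` and `electron_energy` columns (constant per species). Each
#' species' rows are collected into one [basis_spectrum()]; intensities are
#' max-normalised on the way in.
#'
#' @param path file path (CSV).
#' @return named list of basis spectra.
#' @examples
#' bs <- read_basis_table(msdeconv_example("basis_spectra_ch4_70eV.csv"))
#' names(bs)
#' @export
read_basis_table <- function(path) {
  d <- read.csv(path, stringsAsFactors = FALSE)
  if (is.logical(d$detector))  # a column of bare "F" parses as logical
    d$detector <- ifelse(d$detector, "T", "F")
  need <- c("species", "mz", "intensity")
  if (!all(need %in% names(d)))
    stop("basis table needs columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  basis_set(lapply(split(d, factor(d$species, levels = unique(d$species))),
    function(g) {
      basis_spectrum(
        g$species[1L],
        setNames(g$intensity, g$mz),
        detector = if ("detector" %in% names(g)) g$detector[1L] else "F",
        electron_energy = if ("electron_energy" %in% names(g))
          g$electron_energy[1L] else NA_real_)
    }))
}

#' Write basis spectra to a delimited text table
#'
#' @param basis list of basis spectra.
#' @param path output file path (CSV). Readable back with
#'   [read_basis_table()].
#' @return `path`, invisibly.
#' @export
write_basis_table <- function(basis, path) {
  rows <- do.call(rbind, lapply(basis, function(b)
    data.frame(species = b$species,
               mz = as.integer(names(b$intensities)),
               intensity = unname(b$intensities),
               detector = b$detector,
               electron_energy = b$electron_energy)))
  write.csv(rows, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
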