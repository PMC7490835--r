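#' Create a DECONVOLUTION configuration block
#'
#' A DECONVOLUTION block describes one interference-compensation task: at
#' which m/z the ion current must be corrected, for which target species, on
#' which detector, and against which basis spectra. Blocks are stored in the
#' raw data files as single-line plain-text records (see
#' [parse_deconvolution_block()]) so that they can be added or edited with a
#' text editor.
#'
#' @param target_mz positive integer m/z whose ion current is compensated.
#' @param target_species label of the species quantified at `target_mz`;
#'   must name exactly one member of `basis`, with a strictly positive
#'   intensity at `target_mz`.
#' @param basis list of [basis_spectrum()] objects (see [basis_set()]).
#' @param detector `"F"` or `"M"`.
#' @param ms_ee ion-source electron energy in eV; recorded for documentation
#'   only and never used in the numerics.
#' @return an object of class `deconvolution_block`.
#' @export
deconvolution_block <- function(target_mz, target_species, basis,
                                detector = c("F", "M"), ms_ee = NA_real_) {
  detector <- match.arg(detector)
  basis <- basis_set(basis)
  if (length(target_mz) != 1L || target_mz <= 0 || target_mz != round(target_mz))
    stop("target_mz must be a positive integer", call. = FALSE)
  if (sum(names(basis) == target_species) != 1L)
    stop("target_species '", target_species,
         "' must name exactly one basis spectrum (available: ",
         paste(names(basis), collapse = ", "), ")", call. = FALSE)
  if (basis_value(basis[[target_species]], target_mz) <= 0)
    stop("target species '", target_species,
         "' has no intensity at target_mz=", target_mz, call. = FALSE)
  structure(list(target_mz = as.integer(target_mz),
                 target_species = target_species,
                 detector = detector,
                 ms_ee = as.numeric(ms_ee),
                 basis = basis),
            class = "deconvolution_block")
}

#' @export
print.deconvolution_block <- function(x, ...) {
  cat(sprintf(
    "DECONVOLUTION block: %s at m/z=%d (detector %s%s); basis: %s\n",
    x$target_species, x$target_mz, x$detector,
    if (is.finite(x$ms_ee)) sprintf(", %g eV", x$ms_ee) else "",
    paste(names(x$basis), collapse = ", ")))
  invisible(x)
}

# split "a, (b, c), d" at top-level commas (depth 0)
.split_top_level <- function(s) {
  depth <- 0L
  cuts <- integer(0)
  chars <- strsplit(s, "")[[1L]]
  for (i in seq_along(chars)) {
    if (chars[i] == "(") depth <- depth + 1L
    else if (chars[i] == ")") {
      depth <- depth - 1L
      if (depth < 0L) stop("unbalanced ')' at offset ", i, call. = FALSE)
    } else if (chars[i] == "," && depth == 0L) cuts <- c(cuts, i)
  }
  if (depth != 0L) stop("unbalanced '(' in basis array", call. = FALSE)
  trimws(substring(s, c(1L, cuts + 1L), c(cuts - 1L, nchar(s))))
}

#' Parse a DECONVOLUTION block from its plain-text record
#'
#' The record format (normally written on a single data line, but multi-line
#' input is accepted) is:
#'
#' ```
#' DECONVOLUTION: target_mz=15 ; target_species=CH4 ; detector=F ;
#'   MS_EE=70 eV ;
#'   basis=(('CH4', 14,0.103, 15,0.806, 16,1.0), ('N2', ...), ...)
#' ```
#'
#' Each basis entry is a parenthesised tuple: a quoted species name followed
#' by `mz,intensity` pairs. Both typographic and ASCII quotes are accepted.
#' Basis intensities whose maximum deviates from 1 are re-normalised with a
#' warning.
#'
#' @param text the record, as one string or a vector of lines.
#' @return a [deconvolution_block()].
#' @seealso [write_deconvolution_block()], [read_deconvolution_blocks()]
#' @export
parse_deconvolution_block <- function(text) {
  s <- paste(text, collapse = " ")
  s <- gsub("[\u2018\u2019`]", "'", s)
  if (!grepl("DECONVOLUTION:", s, fixed = TRUE))
    stop("not a DECONVOLUTION record", call. = FALSE)
  s <- trimws(sub(".*DECONVOLUTION:", "", s))

  # cut out basis=( ... ) by balancing parentheses
  bpos <- regexpr("basis\\s*=\\s*\\(", s)
  if (bpos == -1L) stop("parse error: missing field 'basis'", call. = FALSE)
  open <- bpos + attr(bpos, "match.length") - 1L
  depth <- 0L; close <- -1L
  chars <- strsplit(s, "")[[1L]]
  for (i in open:length(chars)) {
    if (chars[i] == "(") depth <- depth + 1L
    if (chars[i] == ")") { depth <- depth - 1L
      if (depth == 0L) { close <- i; break } }
  }
  if (close == -1L)
    stop("parse error in basis array: unbalanced '(' at offset ", open,
         call. = FALSE)
  basis_str <- substring(s, open + 1L, close - 1L)
  rest <- paste(substring(s, 1L, bpos - 1L), substring(s, close + 1L))

  fields <- list()
  for (tok in strsplit(rest, ";", fixed = TRUE)[[1L]]) {
    tok <- trimws(tok)
    if (!nzchar(tok)) next
    kv <- regmatches(tok, regexec("^([A-Za-z_]+)\\s*=\\s*(.*)$", tok))[[1L]]
    if (length(kv) != 3L)
      stop("parse error: cannot read field '", tok, "'", call. = FALSE)
    fields[[kv[2L]]] <- trimws(kv[3L])
  }
  for (f in c("target_mz", "target_species", "detector"))
    if (is.null(fields[[f]]))
      stop("parse error: missing field '", f, "'", call. = FALSE)
  if (!fields$detector %in% c("F", "M"))
    stop("detector must be F or M (got '", fields$detector, "')",
         call. = FALSE)
  ms_ee <- if (is.null(fields$MS_EE)) NA_real_ else
    suppressWarnings(as.numeric(sub("\\s*eV\\s*$", "", fields$MS_EE)))

  tuples <- .split_top_level(basis_str)
  basis <- lapply(tuples, function(tp) {
    if (!grepl("^\\(.*\\)$", tp))
      stop("parse error: malformed basis tuple '", tp, "'", call. = FALSE)
    parts <- trimws(strsplit(substring(tp, 2L, nchar(tp) - 1L), ",")[[1L]])
    if (length(parts) < 3L || length(parts) %% 2L == 0L)
      stop("parse error: basis tuple '", tp,
           "' needs a name and mz,intensity pairs", call. = FALSE)
    name <- sub("^'(.*)'$", "\\1", parts[1L])
    if (identical(name, parts[1L]))
      stop("parse error: basis tuple name must be quoted in '", tp, "'",
           call. = FALSE)
    mz <- suppressWarnings(as.numeric(parts[seq(2L, length(parts), 2L)]))
    val <- suppressWarnings(as.numeric(parts[seq(3L, length(parts), 2L)]))
    if (anyNA(mz) || anyNA(val))
      stop("parse error: non-numeric mz or intensity in tuple '", tp, "'",
           call. = FALSE)
    if (max(val) > 0 && abs(max(val) - 1) > 1e-6)
      warning("basis '", name, "': maximum intensity ", max(val),
              " differs from 1; re-normalising", call. = FALSE)
    basis_spectrum(name, setNames(val, mz), detector = fields$detector,
                   electron_energy = ms_ee)
  })

  deconvolution_block(
    target_mz = as.integer(fields$target_mz),
    target_species = fields$target_species,
    basis = basis, detector = fields$detector, ms_ee = ms_ee)
}

# render an intensity so that it round-trips: integers get one decimal
# ("1.0", as in hand-written blocks), everything else full precision
.fmt_intensity <- function(x) {
  ifelse(x == round(x), sprintf("%.1f", x), sprintf("%.15g", x))
}

#' Write a DECONVOLUTION block as a single-line record
#'
#' The inverse of [parse_deconvolution_block()]: field order `target_mz`,
#' `target_species`, `detector`, `MS_EE`, `basis`; numbers carry enough
#' digits to round-trip exactly.
#'
#' @param block a [deconvolution_block()].
#' @return a single string (one data line).
#' @export
write_deconvolution_block <- function(block) {
  stopifnot(inherits(block, "deconvolution_block"))
  tuples <- vapply(block$basis, function(b) {
    mz <- names(b$intensities)
    sprintf("(\u2019%s\u2019, %s)", b$species,
            paste(sprintf("%s,%s", mz, .fmt_intensity(b$intensities)),
                  collapse = ", "))
  }, character(1))
  sprintf(
    "DECONVOLUTION: target_mz=%d ; target_species=%s ; detector=%s ; MS_EE=%s eV ; basis=(%s)",
    block$target_mz, block$target_species, block$detector,
    sprintf("%.15g", block$ms_ee),
    paste(tuples, collapse = ", "))
}

#' Read all DECONVOLUTION blocks from a raw data file
#'
#' Scans a raw-readings file for lines starting with `DECONVOLUTION:` and
#' parses each (see [parse_deconvolution_block()]).
#'
#' @param path file path.
#' @return list of [deconvolution_block()] objects (possibly empty).
#' @export
read_deconvolution_blocks <- function(path) {
  lines <- trimws(readLines(path, warn = FALSE))
  lapply(lines[startsWith(lines, "DECONVOLUTION:")],
         parse_deconvolution_block)
}
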