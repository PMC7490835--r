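#' Build the design matrix of a spectral deconvolution
#'
#' Element (j, i) is the intensity of basis spectrum i at grid m/z j, so the
#' modelled spectrum is `X %*% a` for coefficients `a`. The columns must be
#' linearly independent: the deconvolution can only separate species whose
#' patterns differ on the measured m/z grid.
#'
#' @param basis list of [basis_spectrum()] objects.
#' @param mz_grid integer m/z values (unique, non-empty).
#' @return an M x N numeric matrix with species column names and m/z row
#'   names.
#' @export
build_design_matrix <- function(basis, mz_grid) {
  basis <- basis_set(basis)
  if (length(mz_grid) == 0L) stop("empty m/z grid", call. = FALSE)
  if (anyDuplicated(mz_grid)) stop("duplicated m/z in grid", call. = FALSE)
  X <- vapply(basis, basis_value, numeric(length(mz_grid)), mz = mz_grid)
  X <- matrix(X, nrow = length(mz_grid), ncol = length(basis),
              dimnames = list(as.integer(mz_grid), names(basis)))
  qx <- qr(X)
  if (qx$rank < ncol(X)) {
    dep <- colnames(X)[qx$pivot[seq(qx$rank + 1L, ncol(X))]]
    stop("collinear basis spectra on this m/z grid; dependent: ",
         paste(dep, collapse = ", "), call. = FALSE)
  }
  X
}

#' Deconvolve a measured spectrum into basis-spectrum contributions
#'
#' Estimates the amplitudes `a` of the linear model
#' `y(mz) = sum_i a_i * x_i(mz)` by minimising the chi-square sum of squared
#' error-weighted residuals `((X a - y)/dy)^2` (error-weighted least
#' squares). The number of measured peaks M must be at least the number of
#' basis spectra N, and the measurement detector must match every basis
#' spectrum's detector.
#'
#' Coefficient errors are first propagated from the measurement errors
#' (`covariance = (X' W X)^-1`, `W = diag(1/dy^2)`). The chi-square value at
#' the minimum then measures whether the stated `dy` explain the residual
#' misfit: if `chi2` exceeds the 1-sigma quantile (68.2689 %) of the
#' chi-square distribution with `M - N` degrees of freedom, the `dy` were too
#' small and all coefficient errors are inflated by
#' `sqrt(chi2 / chi2_sigma)`. An exactly determined system (`M == N`) has
#' `chi2 = 0` by construction and is never rescaled.
#'
#' Coefficients are unconstrained by default; a coefficient more negative
#' than 3 of its standard errors triggers a model-mismatch warning (some
#' contribution in the data is missing from the basis set). `nonneg = TRUE`
#' instead solves the non-negative least-squares problem (reported errors
#' then ignore the constraint and are propagated as in the unconstrained
#' fit).
#'
#' @param spectrum a `peak_table` (see [peak_heights()],
#'   [aggregate_peak_heights()]); validated with [as_measured_spectrum()].
#'   Main and helper peaks are both used here.
#' @param basis list of [basis_spectrum()] objects.
#' @param nonneg constrain coefficients to be non-negative.
#' @return an object of class `deconv_fit` with elements `coefficients`
#'   (named, amperes), `da` (rescaled 1-sigma errors), `covariance`
#'   (unrescaled), `chi2`, `dof`, `chi2_sigma`, `rescale_factor`, `mz_grid`,
#'   `detector`, `basis`, `spectrum`.
#' @examples
#' bs <- read_basis_table(msdeconv_example("basis_spectra_ne_45eV.csv"))
#' pk <- gas_peaks(read_peak_table(msdeconv_example("peaks_ne_gases.csv")),
#'                 "GAS-III")
#' fit_coefficients(pk, bs)
#' @seealso [ion_current_fractions()]
#' @export
fit_coefficients <- function(spectrum, basis, nonneg = FALSE) {
  spectrum <- as_measured_spectrum(spectrum)
  basis <- basis_set(basis)
  det <- spectrum$detector[1L]
  bdet <- vapply(basis, `[[`, character(1), "detector")
  if (any(bdet != det))
    stop("mixed-detector fit: spectrum is detector ", det,
         " but basis spectra ",
         paste(names(basis)[bdet != det], collapse = ", "),
         " are detector ", paste(unique(bdet[bdet != det]), collapse = "/"),
         call. = FALSE)
  M <- nrow(spectrum)
  N <- length(basis)
  if (M < N)
    stop("underdetermined system: ", M, " peaks for ", N,
         " basis spectra (need M >= N)", call. = FALSE)
  X <- build_design_matrix(basis, spectrum$mz)
  w <- 1 / spectrum$dy
  Xw <- X * w
  yw <- spectrum$y * w
  if (kappa(Xw, exact = TRUE) > 1e10)
    stop("collinear basis spectra: weighted design matrix is ",
         "numerically singular (condition number > 1e10)", call. = FALSE)
  qx <- qr(Xw)
  a <- qr.coef(qx, yw)
  if (nonneg) {
    nn <- pracma::lsqnonneg(Xw, yw)
    a <- setNames(nn$x, colnames(X))
  }
  R <- qr.R(qx)
  covariance <- chol2inv(R)
  # undo the column pivoting qr() may have applied
  piv <- qx$pivot
  covariance[piv, piv] <- covariance
  dimnames(covariance) <- list(colnames(X), colnames(X))
  chi2 <- sum((drop(Xw %*% a) - yw)^2)
  dof <- M - N
  chi2_sigma <- if (dof > 0) qchisq(0.682689, df = dof) else NA_real_
  rescale <- if (dof > 0 && chi2 > chi2_sigma) sqrt(chi2 / chi2_sigma) else 1
  da <- sqrt(diag(covariance)) * rescale
  if (!nonneg && any(a < -3 * da))
    warning("model mismatch: coefficient(s) ",
            paste(names(a)[a < -3 * da], collapse = ", "),
            " more than 3 sigma below zero; the basis set may be incomplete",
            call. = FALSE)
  structure(list(coefficients = a, da = da, covariance = covariance,
                 chi2 = chi2, dof = dof, chi2_sigma = chi2_sigma,
                 rescale_factor = rescale,
                 mz_grid = spectrum$mz, detector = det,
                 basis = basis, spectrum = spectrum, nonneg = nonneg),
            class = "deconv_fit")
}

#' @export
print.deconv_fit <- function(x, ...) {
  cat(sprintf("Spectral deconvolution (detector %s, %d peaks, %d bases)\n",
              x$detector, length(x$mz_grid), length(x$coefficients)))
  cat(sprintf("  chi2 = %.4g on %d dof%s; error rescale factor %.4g\n",
              x$chi2, x$dof,
              if (x$dof > 0) sprintf(" (1-sigma quantile %.4g)", x$chi2_sigma)
              else "",
              x$rescale_factor))
  out <- data.frame(a = format_current(x$coefficients),
                    da = format_current(x$da))
  rownames(out) <- names(x$coefficients)
  print(out)
  invisible(x)
}

#' Per-species fractions of the ion current at one m/z
#'
#' From a deconvolution fit, computes each species' modelled contribution
#' `c_i = a_i * x_i(mz)` at the requested m/z, and its fraction
#' `f_i = c_i / sum(c)` of the modelled total ion current. Fraction errors
#' are propagated from the full (rescaled) coefficient covariance by the
#' delta method, which correctly accounts for correlations between the
#' fitted amplitudes. A species with no intensity at `mz` has fraction
#' exactly 0.
#'
#' The denominator is the modelled total, not the observed peak height: the
#' fractions describe the fitted linear model, and for an acceptable fit the
#' two totals agree within the measurement error. With an unconstrained fit
#' a fraction can fall slightly outside [0, 1]; clipping happens only at
#' compensation time (see [compensate()]).
#'
#' @param fit a [fit_coefficients()] result.
#' @param mz the m/z at which fractions are evaluated; at least one basis
#'   spectrum must be non-zero there.
#' @param observed optionally, the observed peak height at `mz` (one-row
#'   `peak_table`), attached for reporting.
#' @return a `fraction_table` data frame with columns `species`,
#'   `contribution` (amperes), `fraction`, `dfraction`; attributes `mz`,
#'   `total` (modelled, amperes) and `observed`.
#' @export
ion_current_fractions <- function(fit, mz, observed = NULL) {
  stopifnot(inherits(fit, "deconv_fit"))
  if (length(mz) != 1L || mz <= 0 || mz != round(mz))
    stop("mz must be one positive integer", call. = FALSE)
  x <- vapply(fit$basis, basis_value, numeric(1), mz = mz)
  a <- fit$coefficients
  cc <- a * x
  total <- sum(cc)
  if (all(cc == 0))
    stop("undefined fraction: no basis spectrum contributes at m/z=", mz,
         call. = FALSE)
  f <- cc / total
  # delta method: G[i,k] = df_i/da_k = (x_i 1{i==k} S - c_i x_k) / S^2
  N <- length(a)
  G <- (diag(x, N) * total - outer(cc, x)) / total^2
  V <- fit$covariance * fit$rescale_factor^2
  df <- sqrt(pmax(rowSums((G %*% V) * G), 0))
  out <- data.frame(species = names(a), contribution = unname(cc),
                    fraction = unname(f), dfraction = unname(df))
  structure(out, mz = as.integer(mz), total = total, observed = observed,
            class = c("fraction_table", "data.frame"))
}

#' @export
print.fraction_table <- function(x, ...) {
  cat(sprintf("Ion-current fractions at m/z=%d (modelled total %s)\n",
              attr(x, "mz"), format_current(attr(x, "total"))))
  y <- as.data.frame(x)
  y$contribution <- format_current(y$contribution)
  y$fraction <- sprintf("%.4g%%", 100 * x$fraction)
  y$dfraction <- sprintf("%.2g%%", 100 * x$dfraction)
  print(y, row.names = FALSE)
  invisible(x)
}

#' Serialise a deconvolution fit as a flat key-value report
#'
#' @param fit a [fit_coefficients()] result.
#' @return character vector of `key = value` lines (species coefficients
#'   with errors, chi-square, degrees of freedom, rescale factor).
#' @export
fit_report <- function(fit) {
  stopifnot(inherits(fit, "deconv_fit"))
  num <- function(v) sprintf("%.9g", v)
  c(sprintf("detector = %s", fit$detector),
    sprintf("mz_grid = %s", paste(fit$mz_grid, collapse = " ")),
    sprintf("a[%s] = %s A", names(fit$coefficients), num(fit$coefficients)),
    sprintf("da[%s] = %s A", names(fit$da), num(fit$da)),
    sprintf("chi2 = %s", num(fit$chi2)),
    sprintf("dof = %d", fit$dof),
    sprintf("chi2_sigma = %s", num(fit$chi2_sigma)),
    sprintf("rescale_factor = %s", num(fit$rescale_factor)))
}
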