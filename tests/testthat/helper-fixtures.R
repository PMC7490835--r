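# Example data built in code: the two bundled measurement campaigns.
# (The CSV fixtures under inst/extdata hold the same numbers; building them
# here keeps unit tests independent of the readers under test.)

ch4_bases <- function() {
  basis_set(
    basis_spectrum("CH4", c(`14` = 0.103, `15` = 0.806, `16` = 1.0),
                   detector = "F", electron_energy = 70),
    basis_spectrum("N2", c(`14` = 0.059, `15` = 0.00012, `28` = 1.0),
                   detector = "F", electron_energy = 70),
    basis_spectrum("AIR", c(`14` = 0.059, `15` = 0.00014, `16` = 0.0158,
                            `28` = 1.0, `32` = 0.208),
                   detector = "F", electron_energy = 70))
}

ne_bases <- function() {
  basis_set(
    basis_spectrum("H2O", c(`17` = 0.164, `18` = 1.0, `20` = 1.34e-3),
                   detector = "M", electron_energy = 45),
    basis_spectrum("NE20", c(`20` = 1.0), detector = "M",
                   electron_energy = 45),
    basis_spectrum("AR", c(`20` = 1.06e-9, `36` = 3.00e-3, `40` = 1.0),
                   detector = "M", electron_energy = 45))
}

# peak heights in pA (Faraday cup) for the CH4 example gases
ch4_gas_peaks <- function(gas) {
  pA <- 1e-12
  switch(gas,
    "GAS-I" = peak_heights(c(14, 15, 16, 28, 32),
                           c(127, 394, 491, 1123, 2.6) * pA,
                           c(2, 6, 5, 8, 0.9) * pA, detector = "F"),
    "GAS-II" = peak_heights(c(14, 15, 16, 28, 32),
                            c(77.6, 0.629, 22.7, 1327, 271) * pA,
                            c(0.9, 0.008, 0.1, 6, 5) * pA, detector = "F"),
    stop("unknown gas"))
}

# peak heights in nA (electron multiplier) for the Ne example gases
ne_gas_peaks <- function(gas) {
  nA <- 1e-9
  switch(gas,
    "GAS-III" = peak_heights(c(17, 20, 36), c(24.0, 0.748, 4.59) * nA,
                             c(0.1, 0.008, 0.02) * nA, detector = "M"),
    "GAS-IV" = peak_heights(c(17, 20, 36), c(96.4, 1.37, 4.91) * nA,
                            c(0.4, 0.02, 0.02) * nA, detector = "M"),
    "GAS-V" = peak_heights(c(17, 20, 36), c(20.6, 0.197, 2.29) * nA,
                           c(0.1, 0.002, 0.01) * nA, detector = "M"),
    stop("unknown gas"))
}

# independent chi-square minimiser: BFGS with analytic gradient on the
# weighted-residual objective, started away from the solution. The problem
# is solved in units of max|y| so that optim sees O(1) parameters.
oracle_wls <- function(X, y, dy, start = NULL) {
  s <- max(abs(y))
  ys <- y / s
  dys <- dy / s
  fn <- function(a) sum(((X %*% a - ys) / dys)^2)
  gr <- function(a) drop(2 * t(X / dys) %*% ((X %*% a - ys) / dys))
  if (is.null(start)) start <- rep(1, ncol(X))
  opt <- stats::optim(start / s, fn, gr, method = "BFGS",
                      control = list(reltol = 1e-16, maxit = 5000))
  opt$par * s
}

# random full-rank basis set on a small m/z pool
random_basis_set <- function(n_species, mz_pool = 10:20, detector = "F") {
  repeat {
    bs <- lapply(seq_len(n_species), function(i) {
      k <- sample(2:4, 1)
      mz <- sort(sample(mz_pool, k))
      basis_spectrum(paste0("S", i),
                     setNames(stats::runif(k, 0.05, 1), mz),
                     detector = detector)
    })
    X <- try(build_design_matrix(bs, sort(unique(unlist(lapply(bs, function(b)
      as.integer(names(b$intensities))))))), silent = TRUE)
    if (!inherits(X, "try-error") && kappa(X) < 1e6) return(basis_set(bs))
  }
}

expect_rel_equal <- function(object, expected, tol) {
  expect_lt(max(abs(object - expected) / pmax(abs(expected), 1e-300)), tol)
}
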