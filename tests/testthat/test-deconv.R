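test_that("the design matrix holds basis intensities on the m/z grid", {
  X <- build_design_matrix(ne_bases(), c(17, 20, 36))
  expect_equal(unname(X),
               rbind(c(0.164, 0, 0),
                     c(1.34e-3, 1.0, 1.06e-9),
                     c(0, 0, 3.00e-3)))
  expect_equal(colnames(X), c("H2O", "NE20", "AR"))

  b <- basis_spectrum("A", c(`10` = 0.5, `11` = 1))
  expect_equal(unname(build_design_matrix(list(b), c(10, 11))[, 1]),
               c(0.5, 1))

  expect_error(
    build_design_matrix(list(b, basis_spectrum("B", c(`10` = 1, `11` = 2))),
                        c(10, 11)),
    "collinear")
})

test_that("an exactly determined noble-gas system matches a triangular solve", {
  pk <- ne_gas_peaks("GAS-III")
  fit <- fit_coefficients(pk, ne_bases())

  # independent oracle: the 3x3 system on m/z (17, 20, 36) is triangular
  a_h2o <- 24.0e-9 / 0.164
  a_ar <- 4.59e-9 / 3.00e-3
  a_ne <- 0.748e-9 - a_h2o * 1.34e-3 - a_ar * 1.06e-9
  expect_rel_equal(fit$coefficients[["H2O"]], a_h2o, 1e-9)
  expect_rel_equal(fit$coefficients[["NE20"]], a_ne, 1e-9)
  expect_rel_equal(fit$coefficients[["AR"]], a_ar, 1e-9)

  # M == N: exact representation, no rescaling
  expect_equal(fit$chi2, 0, tolerance = 1e-18)
  expect_equal(fit$dof, 0L)
  expect_equal(fit$rescale_factor, 1)
  expect_true(all(fit$da > 0))
})

test_that("a spectrum equal to one scaled basis is recovered exactly", {
  b <- basis_spectrum("A", c(`10` = 0.5, `11` = 1, `14` = 0.25))
  pk <- peak_heights(c(10, 11, 14), 7e-12 * c(0.5, 1, 0.25), 1e-14)
  fit <- fit_coefficients(pk, list(b))
  expect_equal(unname(fit$coefficients), 7e-12, tolerance = 1e-12)
  expect_equal(fit$chi2, 0, tolerance = 1e-12)
  ft <- ion_current_fractions(fit, 11)
  expect_identical(ft$fraction, 1)
})

test_that("ill-posed or mismatched fits are rejected", {
  bs <- ne_bases()
  pk2 <- ne_gas_peaks("GAS-III")[1:2, ]
  expect_error(fit_coefficients(pk2, bs), "underdetermined")

  pkF <- peak_heights(c(17, 20, 36), c(1, 1, 1) * 1e-12, 1e-14,
                      detector = "F")
  expect_error(fit_coefficients(pkF, bs), "mixed-detector")

  dup <- list(basis_spectrum("A", c(`10` = 1, `11` = 0.5), detector = "M"),
              basis_spectrum("B", c(`10` = 1, `11` = 0.5), detector = "M"))
  pk <- peak_heights(c(10, 11), c(1, 0.5) * 1e-12, 1e-14, detector = "M")
  expect_error(fit_coefficients(pk, dup), "collinear")
})

test_that("the WLS minimiser agrees with an independent chi-square oracle", {
  set.seed(101)
  for (i in 1:20) {
    N <- sample(1:3, 1)
    bs <- random_basis_set(N)
    grid <- basis_support(bs)
    grid <- sort(sample(grid, min(length(grid), sample(N:6, 1))))
    if (length(grid) < N) next
    X <- try(build_design_matrix(bs, grid), silent = TRUE)
    if (inherits(X, "try-error")) next
    a_true <- runif(N, 0.1, 5) * 1e-12
    y <- drop(X %*% a_true) * (1 + rnorm(length(grid), 0, 0.05))
    pk <- peak_heights(grid, y, abs(y) * 0.02)
    fit <- suppressWarnings(fit_coefficients(pk, bs))
    a_oracle <- oracle_wls(X, pk$y, pk$dy, start = a_true * 1.5)
    expect_rel_equal(unname(fit$coefficients), a_oracle, 1e-8)
  }
})

test_that("noise-free mixtures are recovered to machine precision", {
  set.seed(202)
  for (i in 1:10) {
    N <- sample(1:3, 1)
    bs <- random_basis_set(N)
    grid <- basis_support(bs)
    X <- build_design_matrix(bs, grid)
    a_true <- runif(N, 0.1, 5) * 1e-12
    y <- drop(X %*% a_true)
    keep <- y > 0
    if (sum(keep) < N) next
    pk <- peak_heights(grid[keep], y[keep], 0)  # dy from the 1 % floor
    fit <- fit_coefficients(pk, bs)
    expect_rel_equal(unname(fit$coefficients), a_true, 1e-10)
    expect_lt(fit$chi2, 1e-18)
    expect_equal(fit$rescale_factor, 1)
  }
})

test_that("fits are equivariant under a common rescaling of y and dy", {
  pk <- ch4_gas_peaks("GAS-II")
  bs <- ch4_bases()
  f1 <- suppressWarnings(fit_coefficients(pk, bs))
  s <- 1e3
  pk2 <- peak_heights(pk$mz, pk$y * s, pk$dy * s, detector = "F")
  f2 <- suppressWarnings(fit_coefficients(pk2, bs))
  expect_equal(unname(f2$coefficients), unname(f1$coefficients * s),
               tolerance = 1e-10)
  expect_equal(unname(f2$da), unname(f1$da * s), tolerance = 1e-10)
  expect_equal(f2$chi2, f1$chi2, tolerance = 1e-10)
  for (mz in c(14, 15, 16)) {
    ft1 <- ion_current_fractions(f1, mz)
    ft2 <- ion_current_fractions(f2, mz)
    expect_equal(ft2$fraction, ft1$fraction, tolerance = 1e-10)
    expect_equal(ft2$dfraction, ft1$dfraction, tolerance = 1e-10)
  }
})

test_that("fractions sum to one and vanish where the basis does", {
  for (gas in c("GAS-III", "GAS-IV", "GAS-V")) {
    fit <- fit_coefficients(ne_gas_peaks(gas), ne_bases())
    for (mz in c(17, 20, 36)) {
      ft <- ion_current_fractions(fit, mz)
      expect_equal(sum(ft$fraction), 1, tolerance = 1e-9)
      zero_basis <- ft$contribution == 0
      expect_identical(ft$fraction[zero_basis],
                       rep(0, sum(zero_basis)))
    }
  }
  fit <- fit_coefficients(ne_gas_peaks("GAS-III"), ne_bases())
  expect_error(ion_current_fractions(fit, 99), "undefined fraction")
})

test_that("coefficient errors grow when chi-square shows underestimated dy", {
  b <- list(basis_spectrum("A", c(`10` = 1, `11` = 0.5, `12` = 0.25)))
  y0 <- c(1, 0.5, 0.25) * 1e-12
  deltas <- c(0, 1e-15, 1e-14, 5e-14, 1e-13)
  das <- vapply(deltas, function(d) {
    pk <- peak_heights(c(10, 11, 12), y0 + c(d, 0, 0), 1e-15)
    fit <- fit_coefficients(pk, b)
    fit$da
  }, numeric(1))
  expect_true(all(diff(das) >= -1e-30))
  # and the rescale factor is sqrt(chi2/chi2_sigma) once chi2 exceeds it
  pk <- peak_heights(c(10, 11, 12), y0 + c(1e-13, 0, 0), 1e-15)
  fit <- fit_coefficients(pk, b)
  expect_gt(fit$chi2, fit$chi2_sigma)
  expect_equal(fit$rescale_factor, sqrt(fit$chi2 / fit$chi2_sigma))
  expect_equal(fit$chi2_sigma, qchisq(0.682689, 2))
})

test_that("a strongly negative coefficient triggers a model-mismatch warning", {
  # a spectrum that truly contains MINUS half of basis B: the free fit finds
  # a significantly negative amplitude and must flag the model as incomplete
  bA <- basis_spectrum("A", c(`10` = 1, `11` = 0.2))
  bB <- basis_spectrum("B", c(`11` = 1, `12` = 0.5))
  y <- c(1, 0.2, 0) * 1e-12 - 0.5 * c(0, 1, 0.5) * 1e-12
  pk <- peak_heights(c(10, 11, 12), y, abs(y) * 0.02 + 1e-16)
  expect_warning(fit_coefficients(pk, list(bA, bB)), "model mismatch")
})

test_that("the non-negative mode clips what the free fit makes negative", {
  fit <- suppressWarnings(
    fit_coefficients(ch4_gas_peaks("GAS-II"), ch4_bases(), nonneg = TRUE))
  expect_true(all(fit$coefficients >= 0))
  expect_equal(unname(fit$coefficients["N2"]), 0)
})

test_that("fit reports serialise the key quantities", {
  rep <- fit_report(fit_coefficients(ne_gas_peaks("GAS-III"), ne_bases()))
  expect_true(any(grepl("^chi2 = ", rep)))
  expect_true(any(grepl("^a\\[NE20\\]", rep)))
  expect_true(any(grepl("^rescale_factor = 1", rep)))
})
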