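pA <- 1e-12

manual_fractions <- function(species, mz, f, df) {
  structure(data.frame(species = species, contribution = NA_real_,
                       fraction = f, dfraction = df),
            mz = as.integer(mz),
            class = c("fraction_table", "data.frame"))
}

test_that("compensation multiplies by the fraction and adds errors in quadrature", {
  pk <- peak_heights(15, 0.629 * pA, 0.008 * pA)
  cp <- compensate(pk, manual_fractions("CH4", 15, 0.70, 0.03), "CH4")
  expect_equal(cp$y_comp, 0.70 * 0.629 * pA)
  expect_equal(cp$dy_comp / cp$y_comp,
               sqrt((0.03 / 0.70)^2 + (0.008 / 0.629)^2), tolerance = 1e-12)

  # no interference: identity
  cp1 <- compensate(pk, NULL, "CH4")
  expect_equal(cp1$y_comp, pk$y)
  expect_equal(cp1$dy_comp, pk$dy)

  # zero fraction: below detection
  cp0 <- compensate(pk, manual_fractions("CH4", 15, 0, 0.01), "CH4")
  expect_equal(cp0$y_comp, 0)
  expect_true(cp0$below_detection)

  # negative model fractions are clipped with a warning
  expect_warning(
    cpn <- compensate(pk, manual_fractions("CH4", 15, -0.02, 0.01), "CH4"),
    "clipped")
  expect_equal(cpn$y_comp, 0)

  # wrong m/z or species are configuration errors
  expect_error(compensate(pk, manual_fractions("CH4", 16, 0.5, 0.1), "CH4"),
               "m/z")
  expect_error(compensate(pk, manual_fractions("CH4", 15, 0.5, 0.1), "O2"),
               "not in the fraction table")
})

test_that("compensation never shrinks the relative error", {
  set.seed(5)
  for (i in 1:20) {
    y <- runif(1, 0.1, 100) * pA
    dy <- y * runif(1, 0.011, 0.2)
    f <- runif(1, 0.05, 1)
    df <- runif(1, 0, 0.2)
    cp <- compensate(peak_heights(15, y, dy),
                     manual_fractions("X", 15, f, df), "X")
    expect_gte(cp$dy_comp / cp$y_comp, dy / y - 1e-12)
  }
})

test_that("peak-height comparison reproduces the worked CH4 calibration", {
  p1 <- ch4_gas_peaks("GAS-I")[2, ]   # m/z 15
  p2 <- ch4_gas_peaks("GAS-II")[2, ]

  raw <- calibrate(compensate(p2, NULL, "CH4"), compensate(p1, NULL, "CH4"),
                   231000, units = "ppm")
  expect_equal(raw$value, 0.629 / 394 * 231000, tolerance = 1e-12)
  expect_equal(signif(raw$value, 3), 369)
  expect_equal(raw$dvalue, raw$value * sqrt((0.008 / 0.629)^2 + (6 / 394)^2),
               tolerance = 1e-12)
  expect_equal(signif(raw$dvalue, 1), 7)

  comp <- calibrate(
    compensate(p2, manual_fractions("CH4", 15, 0.70, 0.03), "CH4"),
    compensate(p1, manual_fractions("CH4", 15, 1.00, 0.02), "CH4"),
    231000, units = "ppm")
  expect_equal(comp$value, (0.70 * 0.629) / (1.00 * 394) * 231000,
               tolerance = 1e-12)
  expect_equal(signif(comp$value, 2), 260)
  expect_equal(
    comp$dvalue,
    comp$value * sqrt((0.03 / 0.70)^2 + (0.008 / 0.629)^2 +
                        (0.02 / 1.00)^2 + (6 / 394)^2),
    tolerance = 1e-12)
  expect_equal(signif(comp$dvalue, 2), 13)
  # compensated value is consistent with the nominal 250 +- 13 ppm
  expect_lt(abs(comp$value - 250), comp$dvalue + 13)
  # compensation always inflates the relative error
  expect_gt(comp$dvalue / comp$value, raw$dvalue / raw$value)
})

test_that("calibration is exact for sample == reference and scale-invariant", {
  p <- ne_gas_peaks("GAS-III")[2, ]
  cp <- compensate(p, manual_fractions("NE20", 20, 0.74, 0.01), "NE20")
  cal <- calibrate(cp, cp, 326, units = "ppm")
  expect_equal(cal$value, 326)

  p2 <- peak_heights(p$mz, p$y * 1e4, p$dy * 1e4, detector = p$detector)
  cp2 <- compensate(p2, manual_fractions("NE20", 20, 0.74, 0.01), "NE20")
  smp <- compensate(ne_gas_peaks("GAS-IV")[2, ],
                    manual_fractions("NE20", 20, 0.42, 0.01), "NE20")
  smp2 <- compensate(peak_heights(20, 1.37e-9 * 1e4, 0.02e-9 * 1e4,
                                  detector = "M"),
                     manual_fractions("NE20", 20, 0.42, 0.01), "NE20")
  c1 <- calibrate(smp, cp, 326)
  c2 <- calibrate(smp2, cp2, 326)
  expect_equal(c2$value, c1$value, tolerance = 1e-12)
  expect_equal(c2$dvalue, c1$dvalue, tolerance = 1e-12)
})

test_that("calibration rejects mismatched or invalid references", {
  p20 <- compensate(ne_gas_peaks("GAS-III")[2, ], NULL, "NE20")
  p17 <- compensate(ne_gas_peaks("GAS-III")[1, ], NULL, "NE20")
  expect_error(calibrate(p17, p20, 326), "share m/z")
  pF <- compensate(peak_heights(20, 1e-12, 1e-14, detector = "F"), NULL,
                   "NE20")
  expect_error(calibrate(pF, p20, 326), "share m/z and detector")
  zero <- compensate(peak_heights(20, 1e-12, 1e-14, detector = "M"),
                     manual_fractions("NE20", 20, 0, 0.01), "NE20")
  expect_error(calibrate(p20, zero, 326), "invalid reference")
  expect_error(calibrate(p20, p20, -1), "must be positive")
  other <- compensate(ne_gas_peaks("GAS-III")[2, ], NULL, "AR")
  expect_error(calibrate(other, p20, 326), "differs from reference species")

  # reference-amount uncertainty, when given, propagates in quadrature
  cal0 <- calibrate(p20, p20, 326)
  cal1 <- calibrate(p20, p20, 326, reference_damount = 10)
  expect_gt(cal1$dvalue, cal0$dvalue)
})

test_that("blank peak heights subtract with error propagation", {
  pk <- peak_heights(c(15, 20), c(10, 5) * pA, c(0.2, 0.2) * pA)
  blank <- peak_heights(15, 1 * pA, 0.1 * pA)
  out <- subtract_blank(pk, blank)
  expect_equal(out$y, c(9, 5) * pA)
  expect_equal(out$dy[1], sqrt(0.2^2 + 0.1^2) * pA, tolerance = 1e-12)
  expect_equal(out$dy[2], 0.2 * pA)
})
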