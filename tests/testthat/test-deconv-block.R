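test_that("the bundled CH4 DECONVOLUTION block parses to its stated fields", {
  blk <- parse_deconvolution_block(
    readLines(msdeconv_example("deconv_block_ch4.txt"), warn = FALSE))
  expect_equal(blk$target_mz, 15L)
  expect_equal(blk$target_species, "CH4")
  expect_equal(blk$detector, "F")
  expect_equal(blk$ms_ee, 70)
  expect_equal(names(blk$basis), c("CH4", "N2", "AIR"))
  expect_equal(blk$basis$CH4$intensities,
               c(`14` = 0.103, `15` = 0.806, `16` = 1.0))
  expect_equal(blk$basis$AIR$intensities,
               c(`14` = 0.059, `15` = 0.00014, `16` = 0.0158, `28` = 1.0,
                 `32` = 0.208))
})

test_that("blocks write as a single line with canonical tokens", {
  blk <- parse_deconvolution_block(
    readLines(msdeconv_example("deconv_block_ch4.txt"), warn = FALSE))
  line <- write_deconvolution_block(blk)
  expect_length(line, 1L)
  expect_false(grepl("\n", line))
  expect_match(line, "target_mz=15 ;", fixed = TRUE)
  expect_match(line, "(’CH4’, 14,0.103, 15,0.806, 16,1.0)",
               fixed = TRUE)
  expect_match(line, "MS_EE=70 eV", fixed = TRUE)

  # a single-peak basis writes one (mz,value) pair
  b1 <- deconvolution_block(20, "NE20",
                            list(basis_spectrum("NE20", c(`20` = 1),
                                                detector = "M")),
                            detector = "M")
  expect_match(write_deconvolution_block(b1), "(’NE20’, 20,1.0)",
               fixed = TRUE)
})

test_that("write/parse round-trips randomized blocks exactly", {
  set.seed(42)
  for (i in 1:15) {
    n <- sample(1:4, 1)
    bs <- random_basis_set(n, mz_pool = 10:40)
    target <- sample(names(bs), 1)
    tmz <- as.integer(sample(names(bs[[target]]$intensities), 1))
    blk <- deconvolution_block(tmz, target, bs,
                               ms_ee = sample(c(45, 70, 102.5), 1))
    blk2 <- parse_deconvolution_block(write_deconvolution_block(blk))
    expect_equal(blk2$target_mz, blk$target_mz)
    expect_equal(blk2$target_species, blk$target_species)
    expect_equal(blk2$ms_ee, blk$ms_ee)
    expect_equal(names(blk2$basis), names(blk$basis))
    for (nm in names(bs))
      expect_equal(blk2$basis[[nm]]$intensities, blk$basis[[nm]]$intensities)
  }
})

test_that("multi-line records and ASCII quotes are accepted", {
  blk <- parse_deconvolution_block(c(
    "DECONVOLUTION:", "target_mz=15 ;", "target_species=CH4 ;",
    "detector=F ;", "MS_EE=70 eV ;",
    "basis=(", "('CH4', 14,0.103, 15,0.806, 16,1.0),",
    "('N2', 14,0.059, 15,0.00012, 28,1.0))"))
  expect_equal(blk$target_species, "CH4")
  expect_equal(names(blk$basis), c("CH4", "N2"))
})

test_that("malformed blocks fail with errors naming the problem", {
  good <- readLines(msdeconv_example("deconv_block_ch4.txt"), warn = FALSE)
  expect_error(parse_deconvolution_block(sub("detector=F", "detector=X", good)),
               "detector must be F or M")
  expect_error(parse_deconvolution_block(sub("target_mz=15 ; ", "", good)),
               "missing field 'target_mz'")
  expect_error(parse_deconvolution_block(sub("target_species=CH4",
                                             "target_species=CO2", good)),
               "target_species 'CO2'")
  expect_error(parse_deconvolution_block("DECONVOLUTION: target_mz=1 ; target_species=A ; detector=F ; basis=((A, 1,1.0))"),
               "must be quoted")
  expect_error(parse_deconvolution_block("DECONVOLUTION: target_mz=1 ; target_species=A ; detector=F ; basis=(('A', 1,1.0)"),
               "unbalanced")
  # un-normalised basis intensities are re-normalised with a warning
  expect_warning(
    blk <- parse_deconvolution_block(
      "DECONVOLUTION: target_mz=15 ; target_species=CH4 ; detector=F ; basis=(('CH4', 14,0.206, 15,1.612, 16,2.0))"),
    "re-normalising")
  expect_equal(blk$basis$CH4$intensities,
               c(`14` = 0.103, `15` = 0.806, `16` = 1.0))
})

test_that("blocks are recovered from a mixed raw data file", {
  path <- withr::local_tempfile(fileext = ".txt")
  writeLines(c(
    "# raw data",
    "2020-08-21T12:00:00Z PEAK mz=15 detector=F I=0.63pA",
    readLines(msdeconv_example("deconv_block_ch4.txt"), warn = FALSE),
    "2020-08-21T12:00:05Z ZERO mz=15 detector=F I=0.001pA"), path)
  blocks <- read_deconvolution_blocks(path)
  expect_length(blocks, 1L)
  expect_equal(blocks[[1L]]$target_species, "CH4")
})
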