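test_that("titration write/load round trip preserves the series", {
  ser <- generateEmissionTitration(quenchTruth(ksv = 6.28e4), seed = 1,
                                   blankLevel = 5)
  path <- withr::local_tempfile(fileext = ".csv")
  writeTitration(ser, path)
  back <- loadTitration(path)
  expect_length(spectra(back), length(spectra(ser)))
  expect_equal(quencherConc(back), quencherConc(ser))
  expect_equal(temperatureK(back), temperatureK(ser))
  expect_equal(pHValue(back), pHValue(ser))
  for (k in seq_along(spectra(ser))) {
    expect_equal(wavelengths(spectra(back)[[k]]),
                 wavelengths(spectra(ser)[[k]]))
    expect_equal(intensities(spectra(back)[[k]]),
                 intensities(spectra(ser)[[k]]), tolerance = 1e-11)
  }
  expect_false(is.null(blankSpectrum(back)))
  expect_equal(intensities(blankSpectrum(back)),
               intensities(blankSpectrum(ser)), tolerance = 1e-11)
})

test_that("loading rejects malformed titration files", {
  ser <- generateEmissionTitration(quenchTruth(ksv = 1e4), seed = 1)
  path <- withr::local_tempfile(fileext = ".csv")
  writeTitration(ser, path)
  lines <- readLines(path)

  # drop the zero-concentration rows -> F0 missing
  noF0 <- lines[!grepl(",0,298,7.4$", lines)]
  p1 <- withr::local_tempfile(); writeLines(noF0, p1)
  expect_error(loadTitration(p1), "F0")

  # duplicate a data row
  p2 <- withr::local_tempfile(); writeLines(c(lines, lines[3]), p2)
  expect_error(loadTitration(p2), "duplicate")

  # mix a second temperature (fresh wavelength so the row is unique)
  mixed <- c(lines, sub(",298,", ",305,", sub("^300,", "299,", lines[3])))
  p3 <- withr::local_tempfile(); writeLines(mixed, p3)
  expect_error(loadTitration(p3), "temperatur")

  # remove a required column
  p4 <- withr::local_tempfile()
  writeLines(c("wavelength_nm,intensity", "300,1"), p4)
  expect_error(loadTitration(p4), "required column")
})

test_that("an empty or too-short series cannot even be constructed", {
  expect_error(new("TitrationSeries", spectra = list()), "at least 3")
})

test_that("blank subtraction is an elementwise shift and is linear", {
  ser <- generateEmissionTitration(quenchTruth(ksv = 1e4), seed = 1,
                                   blankLevel = 5)
  sub <- subtractBlank(ser)
  expect_null(blankSpectrum(sub))
  for (k in seq_along(spectra(ser)))
    expect_equal(intensities(spectra(sub)[[k]]),
                 intensities(spectra(ser)[[k]]) - 5)

  # subtracting the blank twice equals subtracting 2x blank once
  reblank <- TitrationSeries(spectra(sub), blank = blankSpectrum(ser))
  twice <- subtractBlank(reblank)
  double <- TitrationSeries(spectra(ser),
    blank = EmissionSpectrum(wavelengths(blankSpectrum(ser)),
                             2 * intensities(blankSpectrum(ser)),
                             temperatureK(ser), pHValue(ser), 0))
  once2x <- subtractBlank(double)
  for (k in seq_along(spectra(ser)))
    expect_equal(intensities(spectra(twice)[[k]]),
                 intensities(spectra(once2x)[[k]]))

  # no blank: warning, unchanged
  expect_warning(same <- subtractBlank(sub), "no blank")
  expect_equal(intensities(spectra(same)[[1]]),
               intensities(spectra(sub)[[1]]))
})

test_that("peak extraction finds casein-like emission maxima", {
  wl <- seq(300, 450)
  for (ctr in c(337, 334)) {
    s <- EmissionSpectrum(wl, 900 * exp(-(wl - ctr)^2 / (2 * 25^2)),
                          298, 7.4, 0)
    p <- extractPeak(s)
    expect_equal(p@lambdaMax, ctr, tolerance = 1e-6)
    expect_false(p@atBoundary)
  }
  # off-grid centre is recovered by parabolic refinement
  s <- EmissionSpectrum(wl, 900 * exp(-(wl - 336.4)^2 / (2 * 25^2)),
                        298, 7.4, 0)
  expect_equal(extractPeak(s)@lambdaMax, 336.4, tolerance = 0.05)
})

test_that("peak extraction flags boundaries and rejects flat spectra", {
  wl <- seq(300, 450)
  rising <- EmissionSpectrum(wl, seq_along(wl), 298, 7.4, 0)
  p <- extractPeak(rising, window = 0)
  expect_true(p@atBoundary)
  expect_equal(p@lambdaMax, 450)
  flat <- EmissionSpectrum(wl, rep(7, length(wl)), 298, 7.4, 0)
  expect_error(extractPeak(flat), "degenerate")
})

test_that("peak extraction is invariant under intensity scaling", {
  wl <- seq(300, 450)
  y <- 900 * exp(-(wl - 337)^2 / (2 * 25^2)) +
    sin(wl / 3) * 5    # deterministic ripple
  s1 <- EmissionSpectrum(wl, y, 298, 7.4, 0)
  s2 <- EmissionSpectrum(wl, 3.7 * y, 298, 7.4, 0)
  p1 <- extractPeak(s1); p2 <- extractPeak(s2)
  expect_equal(p2@lambdaMax, p1@lambdaMax)
  expect_equal(p2@intensity, 3.7 * p1@intensity, tolerance = 1e-12)
})

test_that("UV absorption peaks are found near expected bands", {
  wl <- seq(190, 450)
  ab <- 0.8 * exp(-(wl - 210)^2 / 50) + 0.5 * exp(-(wl - 280)^2 / 200)
  sp <- EmissionSpectrum(wl, ab, 298, 7.4, 2e-6, kind = "absorbance")
  r <- uvAbsorptionPeaks(sp, c(210, 280))
  expect_length(r$missing, 0)
  expect_equal(r$peaks[["210"]]@lambdaMax, 210, tolerance = 0.5)
  expect_equal(r$peaks[["280"]]@lambdaMax, 280, tolerance = 0.5)

  # more intense than a quencher-free reference -> hyperchromic
  ref <- EmissionSpectrum(wl, 0.9 * ab, 298, 7.4, 0, kind = "absorbance")
  expect_true(uvAbsorptionPeaks(sp, c(210, 280),
                                reference = ref)$hyperchromic)
  expect_false(uvAbsorptionPeaks(ref, c(210, 280),
                                 reference = sp)$hyperchromic)

  # expected band outside the scanned range is reported missing
  short <- EmissionSpectrum(seq(250, 450),
                            0.5 * exp(-(seq(250, 450) - 280)^2 / 200),
                            298, 7.4, 0, kind = "absorbance")
  expect_equal(uvAbsorptionPeaks(short, c(210, 280))$missing, 210)
})

test_that("spectrum and series validity invariants are enforced", {
  expect_error(EmissionSpectrum(c(300, 299), c(1, 2), 298, 7.4, 0),
               "increasing")
  expect_error(EmissionSpectrum(c(300, 301), c(1, NA), 298, 7.4, 0),
               "finite")
  expect_error(EmissionSpectrum(c(300, 301), c(1, 2), 298, 7.4, -1),
               "quencherConc")
  sp <- lapply(c(2e-6, 4e-6, 6e-6), function(q)
    EmissionSpectrum(300:310, rep(1, 11), 298, 7.4, q))
  expect_error(TitrationSeries(sp), "quencherConc = 0")
})
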