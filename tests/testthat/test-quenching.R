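test_that("noiseless Stern-Volmer fits recover the generator exactly", {
  for (ksv in c(6.28e4, 3.67e4)) {
    ser <- generateEmissionTitration(quenchTruth(ksv = ksv), seed = 1)
    fit <- fitSternVolmer(ser)
    expect_equal(fit@ksv, ksv, tolerance = 1e-6)
    expect_equal(fit@intercept, 1, tolerance = 1e-6)
    expect_gt(fit@r2, 1 - 1e-9)
    # Kq/Ksv ratio is identically 1/tau0
    expect_equal(fit@kq / fit@ksv, 1e8)
  }
  # constrained-intercept mode recovers the same slope on clean data
  ser <- generateEmissionTitration(quenchTruth(ksv = 6.28e4), seed = 1)
  cfit <- fitSternVolmer(ser, constrainedIntercept = TRUE)
  expect_equal(cfit@ksv, 6.28e4, tolerance = 1e-6)
  expect_identical(cfit@intercept, 1)
})

test_that("Kq reproduces the diffusion-limit comparison of the study", {
  # Ksv = 3.67e4 L/mol with tau0 = 1e-8 s -> Kq = 3.67e12 L/(mol s)
  ser <- generateEmissionTitration(quenchTruth(ksv = 3.67e4), seed = 1)
  fit <- fitSternVolmer(ser, tau0 = 1e-8)
  expect_equal(fit@kq, 3.67e12, tolerance = 1e-6)
  expect_identical(fit@mechanism, "static")
})

test_that("mechanism classification respects the threshold band", {
  mk <- function(kq, se) QuenchBind:::.QuenchingFit(
    ksv = kq * 1e-8, ksvSE = se * 1e-8, kq = kq, tau0 = 1e-8,
    intercept = 1, r2 = 1, mechanism = "indeterminate")
  expect_identical(classifyMechanism(mk(3.67e12, 1e9)), "static")
  expect_identical(classifyMechanism(mk(1.0e9, 1e7)), "dynamic")
  # exactly on the boundary -> indeterminate even with zero SE
  expect_identical(classifyMechanism(mk(2.0e10, 0)), "indeterminate")
  # within one SE of the boundary -> indeterminate
  expect_identical(classifyMechanism(mk(2.1e10, 2e9)), "indeterminate")
})

test_that("absent quenching is detected", {
  wl <- seq(300, 450)
  y <- 900 * exp(-(wl - 337)^2 / (2 * 25^2))
  sp <- lapply(c(0, 2, 4, 6) * 1e-6, function(q)
    EmissionSpectrum(wl, y, 298, 7.4, q))
  flat <- TitrationSeries(sp)
  expect_error(fitSternVolmer(flat), "no quenching")
  expect_error(fitDoubleLog(flat), "F >= F0")
})

test_that("noiseless double-log fits recover Kb and n exactly", {
  cases <- list(c(6.48e4, 1.13), c(3.98e4, 1.59))
  for (cs in cases) {
    ser <- generateEmissionTitration(quenchTruth(kb = cs[1], n = cs[2]),
                                     seed = 1)
    fit <- fitDoubleLog(ser)
    expect_equal(fit@kb, cs[1], tolerance = 1e-6)
    expect_equal(fit@n, cs[2], tolerance = 1e-6)
    expect_identical(fit@stoichiometry, as.integer(round(cs[2])))
  }
})

test_that("double-log and Stern-Volmer agree when n = 1", {
  ser <- generateEmissionTitration(quenchTruth(kb = 5.1e4, n = 1), seed = 1)
  expect_equal(fitDoubleLog(ser)@kb, fitSternVolmer(ser)@ksv,
               tolerance = 1e-6)
})

test_that("fitted parameters are invariant under intensity scaling", {
  ser <- generateEmissionTitration(quenchTruth(kb = 6.48e4, n = 1.13),
                                   seed = 1)
  for (fac in c(0.01, 3, 1e4)) {
    sc <- scale_series(ser, fac)
    expect_equal(fitDoubleLog(sc)@kb, fitDoubleLog(ser)@kb,
                 tolerance = 1e-9)
    expect_equal(fitDoubleLog(sc)@n, fitDoubleLog(ser)@n,
                 tolerance = 1e-9)
    expect_equal(fitSternVolmer(sc)@ksv, fitSternVolmer(ser)@ksv,
                 tolerance = 1e-9)
  }
})

test_that("fits degrade gracefully under measurement noise", {
  # Stern-Volmer: at noise SD = 1% of the F0 peak the median relative
  # error of Ksv over 200 seeded replicates stays below 5%. The double-log
  # binding constant is far more noise-sensitive by construction: its
  # intercept extrapolates about five decades beyond the sampled
  # concentration range (10^-5.7..10^-5 mol/L), so the same 1% noise
  # inflates Kb errors by well over an order of magnitude. The binding fit
  # is therefore checked for error scaling with noise, and for 5% median
  # recovery at the proportionally tighter noise level.
  errK <- errB_hi <- errB_lo <- numeric(200)
  for (k in 1:200) {
    serS <- generateEmissionTitration(
      quenchTruth(ksv = 6.28e4, f0Peak = 1000, noiseSD = 10), seed = k)
    errK[k] <- abs(fitSternVolmer(serS)@ksv - 6.28e4) / 6.28e4
    bHi <- fitDoubleLog(generateEmissionTitration(
      quenchTruth(kb = 6.48e4, n = 1.13, f0Peak = 1000, noiseSD = 10),
      seed = 1000 + k))
    bLo <- fitDoubleLog(generateEmissionTitration(
      quenchTruth(kb = 6.48e4, n = 1.13, f0Peak = 1000, noiseSD = 0.1),
      seed = 1000 + k))
    errB_hi[k] <- abs(bHi@kb - 6.48e4) / 6.48e4
    errB_lo[k] <- abs(bLo@kb - 6.48e4) / 6.48e4
  }
  expect_lt(median(errK), 0.05)
  expect_lt(median(errB_lo), 0.05)
  expect_lt(median(errB_lo), median(errB_hi))
})

test_that("titration analysis orchestrates blank handling and both fits", {
  ser <- generateEmissionTitration(quenchTruth(kb = 6.48e4, n = 1.13),
                                   temperature = 298, pH = 2.0, seed = 1,
                                   blankLevel = 5)
  res <- analyzeTitration(ser)
  expect_s4_class(res$quenching, "QuenchingFit")
  expect_s4_class(res$binding, "BindingFit")
  expect_equal(res$binding@kb, 6.48e4, tolerance = 1e-6)
  expect_equal(res$binding@n, 1.13, tolerance = 1e-6)

  # pre-subtracted input gives the same answer
  pre <- analyzeTitration(subtractBlank(ser))
  expect_equal(pre$binding@kb, res$binding@kb)
  expect_equal(pre$quenching@ksv, res$quenching@ksv)

  # minimal 4-spectrum series (3 nonzero points) warns about few points
  mini <- generateEmissionTitration(quenchTruth(kb = 6.48e4, n = 1.13),
                                    concs = c(0, 2, 4, 6) * 1e-6, seed = 1)
  expect_warning(analyzeTitration(mini), "concentrations")
})
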