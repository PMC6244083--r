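mkTraj <- function(conc, coef) {
  new("CoefficientTrajectories", concentrations = conc,
      coefficients = coef, residuals = rep(0, length(conc)),
      labels = colnames(coef), flags = rep("", length(conc)))
}

test_that("component efficiencies come from coefficient depletion ratios", {
  conc <- c(0, 1e-6, 2e-6)
  coef <- cbind(t = c(0.50, 0.20, 0.05), w = c(0.30, 0.30, 0.30))
  res <- componentFretEfficiencies(mkTraj(conc, coef))
  expect_equal(unname(coefficients(res)["t"]), 0.90)
  expect_equal(unname(coefficients(res)["w"]), 0)
  expect_equal(unname(res@efficiencyCurves[2, "t"]), 0.6)

  allconst <- cbind(t = rep(0.4, 3), m = rep(0.2, 3))
  expect_equal(unname(coefficients(
    componentFretEfficiencies(mkTraj(conc, allconst)))), c(0, 0))

  expect_error(componentFretEfficiencies(
    mkTraj(c(1e-6, 2e-6), coef[1:2, ])), "baseline")
  expect_error(componentFretEfficiencies(mkTraj(0, coef[1, , drop = FALSE])),
               "at least two")

  # near-zero baseline components are indeterminate, not guessed
  tiny <- cbind(t = c(1, 0.1, 0.05), x = c(0.005, 0.004, 0.001))
  res <- componentFretEfficiencies(mkTraj(conc, tiny))
  expect_identical(unname(res@classification[2]), "indeterminate")
  expect_true(is.na(coefficients(res)["x"]))
})

test_that("classification splits coupled and decoupled at the threshold", {
  conc <- c(0, 1e-6)
  coef <- cbind(t = c(1, 0.1), d = c(1, 0.1), a = c(1, 0.1),
                m = c(1, 0.1), w = c(1, 1))
  res <- classifyComponents(componentFretEfficiencies(mkTraj(conc, coef)))
  expect_identical(unname(res@classification),
                   c(rep("coupled", 4), "decoupled"))
  expect_identical(unname(res@distanceBound),
                   c(rep("r <= R0", 4), "r > R0"))

  half <- cbind(t = c(1, 0.5))
  res <- classifyComponents(componentFretEfficiencies(mkTraj(conc, half)))
  expect_identical(unname(res@classification), "coupled")  # E = 0.5 couples

  none <- cbind(t = c(1, 1), w = c(2, 2))
  res <- classifyComponents(componentFretEfficiencies(mkTraj(conc, none)))
  expect_identical(unname(res@classification), rep("decoupled", 2))

  d <- componentDistances(res, R0 = 29.7)
  expect_identical(unname(d), c(Inf, Inf))
})

test_that("efficiency estimates are invariant to global intensity rescaling", {
  setup <- fretSetup(grid = seq(360, 800, by = 2))
  fret <- simulateStandardFret(setup, noise = 0.01, seed = 12)
  map1 <- fretMap(fret$donor, setup$refsP, setup$refsNR)
  scaled <- newTitrationSeries(
    fret$donor@concentrations,
    lapply(fret$donor@spectra, function(s)
      newSpectrum(wavelengths(s), 3.7 * intensities(s))))
  map2 <- fretMap(scaled, setup$refsP, setup$refsNR)
  expect_equal(coefficients(map1), coefficients(map2), tolerance = 1e-9)
})

test_that("per-component recovery degrades gracefully with spectral noise", {
  setup <- fretSetup()
  # 1% noise: within +-0.02 (checked exhaustively in the acceptance suite);
  # 5% noise: within +-0.07 under these study conditions, the information
  # limit set by the methanol/water band overlap
  errs <- sapply(1:25, function(s) {
    fret <- simulateStandardFret(setup, noise = 0.05, seed = s)
    map <- fretMap(fret$donor, setup$refsP, setup$refsNR)
    coefficients(map) - fret$truth$headlineE
  })
  expect_lt(max(abs(errs)), 0.07)
  # the FRET-silent water component is never classified coupled at 5% noise
  expect_true(all(abs(errs["w", ]) < 0.5))
})

test_that("sensitization profiles detect equal and missing sensitization", {
  setup <- fretSetup(grid = seq(360, 800, by = 2))
  fret <- simulateStandardFret(setup, noise = 0.01, seed = 8)
  prof <- acceptorSensitizationProfile(fret$direct, fret$sensitized,
                                       setup$refsNR, donorRefs = setup$refsP)
  expect_identical(prof$verdict, "equal")
  expect_lt(prof$cv, 0.1)
  expect_length(prof$unsensitized, 0)

  # one acceptor environment receives no energy
  fret2 <- simulateFretTitration(
    setup$sitesP, setup$sitesNR, setup$refsP, setup$refsNR, 5e-6,
    c(0, 0.5, 1, 2, 4, 8, 12) * 1e-6,
    Emax = c(t = 0.9, d = 0.9, a = 0.9, m = 0.9, w = 0),
    sensitization = c(t = 1, d = 1, a = 1, m = 0), noise = 0.01, seed = 8)
  prof2 <- acceptorSensitizationProfile(fret2$direct, fret2$sensitized,
                                        setup$refsNR,
                                        donorRefs = setup$refsP)
  expect_identical(prof2$verdict, "unequal")
  expect_true("m" %in% prof2$unsensitized)

  # identical series compared with themselves: all ratios 1
  prof3 <- acceptorSensitizationProfile(fret$direct, fret$direct,
                                        setup$refsNR)
  fin <- prof3$finalRatios[is.finite(prof3$finalRatios)]
  expect_equal(unname(fin), rep(1, length(fin)), tolerance = 1e-9)

  short <- newTitrationSeries(fret$direct@concentrations[-1],
                              fret$direct@spectra[-1])
  expect_error(acceptorSensitizationProfile(short, fret$sensitized,
                                            setup$refsNR),
               "unmatched")
})

test_that("the end-to-end demo reproduces the expected coupling pattern", {
  demo <- runNanopolarityDemo(seed = 42)
  cls <- setNames(demo$map@classification, solventLabels(demo$map))
  expect_identical(unname(cls[c("t", "d", "a", "m")]), rep("coupled", 4))
  expect_identical(unname(cls["w"]), "decoupled")
  expect_identical(demo$sensitization$verdict, "equal")
  expect_equal(unname(coefficients(demo$map)[c("t", "d", "a", "m")]),
               rep(0.9, 4), tolerance = 0.02)
})
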