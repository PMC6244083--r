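test_that("band generator honours FWHM, amplitude and peak position", {
  g <- seq(360, 650, by = 0.5)
  s <- bandSpectrum(g, lambdaMax = 500, fwhm = 60, skew = 0)
  y <- intensities(s)
  half <- range(g[y >= 0.5])
  expect_equal(half[1], 470, tolerance = 0.5)
  expect_equal(half[2], 530, tolerance = 0.5)

  expect_true(all(intensities(bandSpectrum(g, 500, 60, amplitude = 0)) == 0))

  # argmax self-consistency over random models, including skewed bands
  set.seed(5)
  for (i in 1:50) {
    lm <- runif(1, 420, 600); fw <- runif(1, 30, 90)
    sk <- runif(1, -0.6, 0.6)
    s <- bandSpectrum(g, lm, fw, skew = sk)
    expect_lt(abs(g[which.max(intensities(s))] - lm), 0.5 + 1e-9)
    expect_true(all(intensities(s) >= 0))
  }
  # skewed band keeps its FWHM too
  s <- bandSpectrum(g, 500, 60, skew = 0.4)
  expect_equal(diff(range(g[intensities(s) >= 0.5])), 60, tolerance = 1)
})

test_that("reference libraries follow the tabulated maxima and brightness", {
  refsP <- makeReferenceLibrary("P")
  tabP <- photophysicsTable("P")
  g <- wavelengths(refsP)
  peaks <- apply(intensities(refsP), 2, function(y) g[which.max(y)])
  expect_equal(unname(peaks), tabP$lambda_em_max)

  refsNR <- makeReferenceLibrary("NR")
  ampNR <- apply(intensities(refsNR), 2, max)
  tabNR <- photophysicsTable("NR")
  # amplitude ratio water/toluene = (eps*QY)_w / (eps*QY)_t ~ 0.003
  expect_equal(unname(ampNR["w"] / ampNR["t"]),
               (14400 * 0.005) / (29500 * 0.80), tolerance = 1e-9)
  expect_equal(unname(ampNR / max(ampNR)),
               tabNR$epsilon * tabNR$quantum_yield /
                 max(tabNR$epsilon * tabNR$quantum_yield), tolerance = 1e-9)

  expect_identical(intensities(makeReferenceLibrary("P")),
                   intensities(refsP))  # deterministic
  expect_error(makeReferenceLibrary("P", solvents = c("t", "x")),
               "no photophysics record")
})

test_that("binding mass balance conserves dye and saturates capacity", {
  # high-affinity saturation: 5 sites/NP at 1 uM NP, 25 uM probe
  sat <- siteModel(labels = "t", capacities = 5, affinities = 1e9,
                   npConc = 1e-6, waterPartition = 1)
  eq <- solveBinding(sat, 25e-6)
  expect_equal(unname(eq$bound["t"]), 5e-6, tolerance = 1e-3)

  expect_equal(solveBinding(siteModel(), 0)$free, 0)

  set.seed(9)
  sm <- siteModel()
  for (total in c(1e-8, 2e-7, 5e-6, 2.5e-5)) {
    eq <- solveBinding(sm, total)
    expect_lt(abs(eq$free + sum(eq$bound) - total) / total, 1e-10)
    expect_true(all(eq$bound <= sm$capacities * sm$npConc + 1e-18))
  }
})

test_that("probe-titration generator is seeded, blank-safe and truthful", {
  refs <- pRefs()
  sm <- siteModel()
  s1 <- simulateProbeTitration(sm, refs, c(0, 1, 5) * 1e-6, seed = 4)
  s2 <- simulateProbeTitration(sm, refs, c(0, 1, 5) * 1e-6, seed = 4)
  expect_identical(lapply(s1$series@spectra, intensities),
                   lapply(s2$series@spectra, intensities))
  expect_true(all(intensities(s1$series@spectra[[1]]) == 0))  # blank
  eq <- solveBinding(sm, 5e-6)
  expect_equal(unname(coefficients(s1$truth)[3, sm$labels]),
               unname(eq$bound / sm$refConc))
  expect_equal(unname(coefficients(s1$truth)[3, "w"]),
               eq$free / sm$refConc)
})

test_that("FRET generator conserves quanta and reduces to no-FRET at E = 0", {
  setup <- fretSetup(grid = seq(360, 800, by = 2))
  fret0 <- simulateStandardFret(setup, noise = 0,
                                Emax = c(t = 0, d = 0, a = 0, m = 0, w = 0),
                                seed = 1)
  ints <- lapply(fret0$donor@spectra, intensities)
  for (i in 2:length(ints)) expect_identical(ints[[i]], ints[[1]])
  expect_true(all(fret0$truth$quantaLost == 0))

  fret <- simulateStandardFret(setup, noise = 0, seed = 1)
  expect_equal(fret$truth$quantaLost, fret$truth$quantaGained,
               tolerance = 1e-9)
  expect_gt(fret$truth$quantaLost[7], 0)
  # donor components scaled by 1 - E; water untouched
  cDon7 <- fret$truth$donorBaseline * (1 - fret$truth$efficiencyCurves[7, ])
  expect_equal(unname(cDon7["w"]), unname(fret$truth$donorBaseline["w"]))
  expect_error(
    simulateStandardFret(setup, noise = 0, seed = 1,
                         Emax = c(t = 1.2, d = 0, a = 0, m = 0, w = 0)),
    "Emax|\\[0, 1\\]")
})

test_that("Monte-Carlo quenching matches limits and is monotone in colocalization", {
  geom <- nanoparticleGeometry()
  expect_identical(monteCarloQuenching(geom, "center", "ppo", 0, R0 = 40,
                                       nTrials = 10, seed = 1)$mean, 0)
  # one acceptor pinned at r = R0 from a central donor: E = 1/2
  thin <- nanoparticleGeometry(data.frame(
    label = c("core", "ring"), r_in_nm = c(0, 4), r_out_nm = c(4, 4 + 1e-9)))
  mc <- monteCarloQuenching(thin, "center", "ring", 1, R0 = 40,
                            nTrials = 200, seed = 2)
  expect_equal(mc$mean, 0.5, tolerance = 1e-6)

  # colocalized acceptors (same shell as the donor) transfer two orders of
  # magnitude more efficiently than acceptors dispersed into bulk
  same <- monteCarloQuenching(geom, "ppo", "ppo", 4, R0 = 40,
                              nTrials = 2000, seed = 3)
  far <- nanoparticleGeometry(data.frame(
    label = c("core", "ppo", "bulk"), r_in_nm = c(0, 5.5, 8),
    r_out_nm = c(5.5, 8, 60)))
  disp <- monteCarloQuenching(far, "ppo", "bulk", 4, R0 = 40,
                              nTrials = 2000, seed = 3)
  expect_gt(same$mean, 0.25)
  expect_lt(disp$mean, 0.05)
  expect_gt(same$mean, 10 * disp$mean)

  r1 <- monteCarloQuenching(geom, "center", "peg", 3, R0 = 40,
                            nTrials = 500, seed = 7)
  r2 <- monteCarloQuenching(geom, "center", "peg", 3, R0 = 40,
                            nTrials = 500, seed = 7)
  expect_identical(r1$samples, r2$samples)
  expect_error(monteCarloQuenching(geom, "center", "nope", 1, R0 = 40),
               "no shell")
})
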