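test_that("unmix recovers a pure reference exactly", {
  refs <- pRefs()
  s <- newSpectrum(wavelengths(refs), intensities(refs)[, "t"])
  res <- unmix(s, refs)
  expect_equal(unname(coefficients(res)),
               c(1, 0, 0, 0, 0), tolerance = 1e-10)
  expect_lt(residuals(res), 1e-10)
})

test_that("unmix matches the normal-equations oracle when constraints are inactive", {
  refs <- pRefs()
  S <- intensities(refs)[, c("t", "m")]
  y <- 0.3 * S[, 1] + 0.7 * S[, 2]
  # oracle: direct linear solve, nonnegativity inactive
  oracle <- solve(crossprod(S), crossprod(S, y))[, 1]
  res <- unmix(newSpectrum(wavelengths(refs), y),
               referenceSubset(refs, c("t", "m")))
  expect_equal(unname(coefficients(res)), unname(oracle), tolerance = 1e-6)
  expect_equal(unname(coefficients(res)), c(0.3, 0.7), tolerance = 1e-6)
  expect_lt(residuals(res), 1e-10)
})

test_that("infeasible negative mixtures project onto the constraint boundary", {
  refs <- referenceSubset(pRefs(), c("t", "m"))
  S <- intensities(refs)
  y <- S[, "t"] - 0.2 * S[, "m"]
  res <- unmix(newSpectrum(wavelengths(refs), y), refs)
  # oracle: exhaustive grid search over (c_t, c_m) >= 0 at 1e-3 resolution
  G <- crossprod(S); b <- crossprod(S, y)
  ct <- seq(0, 1.5, by = 1e-3); cm <- seq(0, 0.5, by = 1e-3)
  sse <- outer(ct^2 * G[1, 1], cm^2 * G[2, 2], "+") +
    2 * outer(ct, cm) * G[1, 2] - 2 * outer(ct * b[1], cm * b[2], "+")
  best <- arrayInd(which.min(sse), dim(sse))
  expect_equal(unname(coefficients(res)["m"]), 0)
  expect_equal(unname(coefficients(res)["t"]), ct[best[1]],
               tolerance = 2e-3)
  expect_equal(cm[best[2]], 0)
  expect_gt(residuals(res), 0)
})

test_that("noiseless random nonnegative mixtures are recovered to numerical precision", {
  refs <- pRefs()
  S <- intensities(refs)
  set.seed(11)
  for (i in 1:20) {
    truth <- runif(5, 0, 2) * rbinom(5, 1, 0.8)
    if (all(truth == 0)) truth[1] <- 1
    y <- as.numeric(S %*% truth)
    cc <- coefficients(unmix(newSpectrum(wavelengths(refs), y), refs))
    expect_equal(unname(cc), truth, tolerance = 1e-8)
  }
})

test_that("unmix is scale-equivariant and ignores all-zero references", {
  refs <- pRefs()
  S <- intensities(refs)
  y <- as.numeric(S %*% c(0.5, 0.1, 0.8, 0.2, 0.3)) *
    (1 + 0.02 * sin(seq_len(nrow(S))))
  s1 <- newSpectrum(wavelengths(refs), y)
  s2 <- newSpectrum(wavelengths(refs), 7.5 * y)
  r1 <- unmix(s1, refs); r2 <- unmix(s2, refs)
  expect_equal(coefficients(r2), 7.5 * coefficients(r1), tolerance = 1e-8)
  expect_equal(residuals(r2), residuals(r1), tolerance = 1e-10)

  zrefs <- new("ReferenceSet", wavelength = wavelengths(refs),
               intensities = cbind(S, z = 0),
               labels = c(solventLabels(refs), "z"),
               probe = "P", excitation = 330)
  rz <- unmix(s1, zrefs)
  expect_equal(coefficients(rz)[solventLabels(refs)], coefficients(r1),
               tolerance = 1e-10)
  expect_equal(unname(coefficients(rz)["z"]), 0)
})

test_that("degenerate unmixing inputs are rejected or flagged", {
  refs <- pRefs()
  expect_error(unmix(newSpectrum(wavelengths(refs),
                                 rep(0, length(wavelengths(refs)))), refs),
               "all-zero")
  dup <- new("ReferenceSet", wavelength = wavelengths(refs),
             intensities = intensities(refs)[, c("t", "t")] +
               matrix(c(0, 1e-12), length(wavelengths(refs)), 2),
             labels = c("t1", "t2"), probe = "P", excitation = 330)
  res <- unmix(newSpectrum(wavelengths(refs), intensities(refs)[, "t"]), dup)
  expect_true("collinear-references" %in% res@flags)
})

test_that("brightness correction turns coefficients into occupancy fractions", {
  refs <- pRefs()
  tab <- photophysicsTable("P")
  bright <- setNames(tab$epsilon * tab$quantum_yield, tab$solvent)
  # equal occupancy in t and w: coefficients must be brightness-weighted
  cc <- setNames(c(0.5, 0, 0, 0, 0.5), solventLabels(refs))
  res <- new("UnmixResult", coefficients = cc, residual = 0,
             fitted = newSpectrum(c(400, 500), c(1, 1)),
             labels = names(cc), flags = character())
  occ <- occupancyFractions(res, "P")
  expect_equal(sum(occ), 1)
  expect_equal(unname(occ["t"] / occ["w"]),
               unname(bright["w"] / bright["t"]), tolerance = 1e-12)
})

test_that("reference selection finds minimal subsets and monotone greedy paths", {
  refs <- pRefs()
  S <- intensities(refs)
  pure <- newSpectrum(wavelengths(refs), S[, "a"])
  sel <- selectReferenceSet(pure, refs)
  expect_identical(sel$labels, "a")
  expect_lt(sel$residual, 1e-10)

  mix <- newSpectrum(wavelengths(refs), 0.5 * S[, "t"] + 0.5 * S[, "w"])
  sel <- selectReferenceSet(mix, refs)
  expect_setequal(sel$labels, c("t", "w"))
  expect_true(sel$thresholdMet)

  greedy <- selectReferenceSet(mix, refs, threshold = 1e-12,
                               minGain = 1e-12, method = "greedy")
  expect_true(all(diff(greedy$path$residual) <= 1e-12))

  # unreachable threshold returns the full set, flagged
  noisy <- newSpectrum(wavelengths(refs),
                       abs(sin(wavelengths(refs) / 3)) + 0.2)
  sel <- selectReferenceSet(noisy, refs, threshold = 1e-6)
  expect_false(sel$thresholdMet)
  expect_setequal(sel$labels, solventLabels(refs))
})

test_that("titration fitting recovers generator truth and flags blanks", {
  refs <- pRefs()
  sim <- simulateProbeTitration(siteModel(), refs,
                                probeConcs = c(0, 1, 5, 25) * 1e-6,
                                noise = 0.01, seed = 3)
  traj <- fitTitration(sim$series, refs, weighting = "relative")
  expect_identical(traj@flags[1], "blank")
  expect_equal(unname(coefficients(traj)[1, ]), rep(0, 5))
  truth <- coefficients(sim$truth)
  est <- coefficients(traj)
  # per point, error relative to the dominant coefficient stays within the
  # 1% noise level (x2)
  for (i in 2:nrow(est))
    expect_lt(max(abs(est[i, ] - truth[i, ])) / max(truth[i, ]), 0.02)
  # hydrophilic sites overtake hydrophobic ones at high load
  last <- nrow(est)
  expect_gt(est[last, "a"], est[last, "t"])
  expect_gt(est[last, "m"], est[last, "d"])
  # hydrophobic sites saturate: plateau between 5 and 25 uM
  expect_lt((est[last, "t"] - est[last - 1, "t"]) / est[last, "t"], 0.2)
})
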