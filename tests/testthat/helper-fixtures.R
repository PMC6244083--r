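# Shared fixtures, built in code at test time.

# Coarse 2 nm grid keeps the suite fast; bands are smooth single peaks so
# this still oversamples them.
pRefs <- function(grid = seq(360, 650, by = 2))
  makeReferenceLibrary("P", grid = grid)

# Shared donor/acceptor setup for FRET simulations: Prodan-like donor with a
# large bulk-water fraction, Nile-Red-like acceptor dark in water, both
# libraries on one grid covering the two emission envelopes.
fretSetup <- function(grid = seq(360, 800, by = 1)) {
  refsP <- makeReferenceLibrary("P", grid = grid)
  refsNR <- referenceSubset(makeReferenceLibrary("NR", grid = grid),
                            c("t", "d", "a", "m"))
  list(refsP = refsP, refsNR = refsNR,
       sitesP = siteModel(),
       sitesNR = siteModel(capacities = c(2, 3, 10, 15),
                           affinities = c(5e6, 3e6, 3e5, 1.5e5),
                           waterPartition = 0))
}

simulateStandardFret <- function(setup, noise, seed,
                                 Emax = c(t = 0.9, d = 0.9, a = 0.9,
                                          m = 0.9, w = 0)) {
  simulateFretTitration(setup$sitesP, setup$sitesNR, setup$refsP,
                        setup$refsNR, donorConc = 5e-6,
                        acceptorConcs = c(0, 0.5, 1, 2, 4, 8, 12) * 1e-6,
                        Emax = Emax, noise = noise, seed = seed)
}

# Independent NNLS residual used by selection-oracle tests: calls the solver
# directly on matrices, bypassing the package's Spectrum/ReferenceSet path.
rawRelativeResidual <- function(y, S) {
  cc <- pracma::lsqnonneg(S, y)$x
  sqrt(sum((y - as.numeric(S %*% cc))^2) / sum(y^2))
}
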