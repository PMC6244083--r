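#' End-to-end simulated nanopolarity-mapping workflow
#'
#' Runs the whole two-step method on synthetic data emulating a core-shell
#' nanoparticle suspension: (1) single-probe loading titrations of the donor
#' (Prodan-like) and acceptor (Nile-Red-like) dyes, unmixed into coefficient
#' trajectories; (2) a FRET titration in which the four nanoparticle-bound
#' donor components are quenched (maximal efficiency 0.9) while the
#' bulk-water component is FRET-silent, followed by component-resolved
#' efficiency extraction, coupled/decoupled classification and the acceptor
#' sensitization check. The expected classification pattern is t, d, a, m
#' coupled and w decoupled.
#'
#' @param seed Integer seed driving all synthetic noise.
#' @param noise Multiplicative spectral noise fraction (default 0.01).
#' @return List: \code{map} ([FretMapResult-class]), \code{sensitization}
#'   (from [acceptorSensitizationProfile()]), \code{donorTitration} and
#'   \code{acceptorTitration} (each a list with the fitted and the truth
#'   [CoefficientTrajectories-class]), and \code{truth} of the FRET
#'   simulation.
#' @examples
#' demo <- runNanopolarityDemo(seed = 1)
#' demo$map
#' @export
runNanopolarityDemo <- function(seed = 1, noise = 0.01) {
  grid <- seq(360, 800, by = 1)
  refsP <- makeReferenceLibrary("P", grid = grid)
  refsNR <- makeReferenceLibrary("NR", grid = grid)
  # water reference excluded when fitting the acceptor (dark in water)
  refsNRfit <- referenceSubset(refsNR, c("t", "d", "a", "m"))

  sitesP <- siteModel()
  sitesNR <- siteModel(capacities = c(2, 3, 10, 15),
                       affinities = c(5e6, 3e6, 3e5, 1.5e5),
                       waterPartition = 0)

  # step 1: single-probe loading titrations
  pSim <- simulateProbeTitration(sitesP, refsP,
                                 probeConcs = c(0.2, 0.5, 1, 2, 5, 10, 25) *
                                   1e-6, noise = noise, seed = seed)
  pTraj <- fitTitration(pSim$series, refsP)
  nrSim <- simulateProbeTitration(sitesNR, refsNRfit,
                                  probeConcs = c(0.2, 0.5, 1, 2, 4) * 1e-6,
                                  noise = noise, seed = seed + 1)
  nrTraj <- fitTitration(nrSim$series, refsNRfit)

  # step 2: FRET titration of donor-loaded particles with the acceptor
  fret <- simulateFretTitration(
    sitesP, sitesNR, refsP, refsNRfit, donorConc = 5e-6,
    acceptorConcs = c(0, 0.5, 1, 2, 4, 8, 12) * 1e-6,
    Emax = c(t = 0.9, d = 0.9, a = 0.9, m = 0.9, w = 0),
    noise = noise, seed = seed + 2)
  map <- fretMap(fret$donor, refsP, refsNRfit)
  sensProfile <- acceptorSensitizationProfile(fret$direct, fret$sensitized,
                                              refsNRfit, donorRefs = refsP)
  list(map = map, sensitization = sensProfile,
       donorTitration = list(fitted = pTraj, truth = pSim$truth),
       acceptorTitration = list(fitted = nrTraj, truth = nrSim$truth),
       truth = fret$truth)
}
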