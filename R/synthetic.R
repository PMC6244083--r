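# Synthetic-data generators: parametric solvatochromic bands, site-binding
# titrations, FRET titrations and geometric Monte-Carlo quenching. Every
# generator returns (data, truth) so each pipeline stage can be tested for
# parameter recovery against known ground truth.

# Run code with a private RNG stream derived from `seed`, restoring the
# caller's RNG state afterwards: identical seeds give bit-identical output
# without clobbering the session RNG.
withSeed <- function(seed, code) {
  if (is.null(seed)) return(code)
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  code
}

#' Single solvatochromic emission band (log-normal lineshape)
#'
#' Generates one smooth, unimodal, nonnegative emission band of the kind a
#' solvatochromic dye shows in a pure solvent. The lineshape is a log-normal
#' peak with exact peak position \code{lambdaMax}, exact full width at half
#' maximum \code{fwhm} and dimensionless skew; \code{skew = 0} reduces to a
#' Gaussian. Positive skew gives the red-side tail typical of emission bands.
#'
#' @param grid Wavelength grid (nm), strictly ascending.
#' @param lambdaMax Peak wavelength (nm).
#' @param fwhm Full width at half maximum (nm), > 0.
#' @param skew Asymmetry parameter; 0 = symmetric Gaussian.
#' @param amplitude Peak height (arbitrary units, proportional to the
#'   product of molar extinction at the excitation wavelength and quantum
#'   yield for equimolar reference spectra).
#' @param probe,solvent,excitation,concentration Metadata for the returned
#'   [Spectrum-class].
#' @return A [Spectrum-class] on \code{grid}.
#' @examples
#' s <- bandSpectrum(seq(360, 650), lambdaMax = 500, fwhm = 60)
#' wavelengths(s)[which.max(intensities(s))]  # 500
#' @export
bandSpectrum <- function(grid, lambdaMax, fwhm, skew = 0, amplitude = 1,
                         probe = NA_character_, solvent = NA_character_,
                         excitation = NA_real_, concentration = NA_real_) {
  stopifnot(fwhm > 0, amplitude >= 0)
  grid <- as.numeric(grid)
  x <- grid - lambdaMax
  if (abs(skew) < 1e-8) {
    y <- exp(-log(2) * (2 * x / fwhm)^2)
  } else {
    # width rescaled so the half-maximum crossings are exactly fwhm apart
    w <- fwhm * skew / sinh(skew)
    u <- 1 + 2 * skew * x / w
    y <- ifelse(u > 0, exp(-log(2) * (log(pmax(u, .Machine$double.xmin)) /
                                        skew)^2), 0)
  }
  newSpectrum(grid, amplitude * y, probe = probe, solvent = solvent,
              excitation = excitation, concentration = concentration)
}

#' Synthetic pure-solvent reference library for a probe
#'
#' Builds a five-solvent reference library emulating equimolar pure-solvent
#' emission spectra of Prodan (\code{"P"}) or Nile Red (\code{"NR"}): one
#' log-normal band per solvent with the peak at the tabulated emission
#' maximum and peak amplitude proportional to the tabulated brightness
#' (molar extinction times quantum yield), normalized to 1 for the brightest
#' solvent. The Nile-Red-in-water band is therefore extremely weak
#' (amplitude ratio to toluene about 0.003).
#'
#' @param probe \code{"P"} or \code{"NR"}.
#' @param solvents Solvent labels to include (default all five t/d/a/m/w).
#' @param grid Wavelength grid; defaults to 360-650 nm for P and 530-800 nm
#'   for NR, 1 nm step.
#' @param fwhm Band FWHM in nm, recycled per solvent; defaults: 70 (P),
#'   60 (NR). Band shapes of the real probes are not tabulated, so widths
#'   are free parameters.
#' @param skew Band asymmetry, default 0.25 (mild red tail).
#' @param concentration Nominal equimolar probe concentration (M) recorded in
#'   the metadata, default 1e-6.
#' @return A [ReferenceSet-class].
#' @examples
#' refs <- makeReferenceLibrary("P")
#' solventLabels(refs)
#' @export
makeReferenceLibrary <- function(probe = c("P", "NR"),
                                 solvents = c("t", "d", "a", "m", "w"),
                                 grid = NULL, fwhm = NULL, skew = 0.25,
                                 concentration = 1e-6) {
  probe <- match.arg(probe)
  tab <- photophysicsTable(probe)
  miss <- setdiff(solvents, tab$solvent)
  if (length(miss))
    stop("no photophysics record for solvent(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  tab <- tab[match(solvents, tab$solvent), ]
  if (is.null(grid))
    grid <- if (probe == "P") seq(360, 650, by = 1) else seq(530, 800, by = 1)
  if (is.null(fwhm)) fwhm <- if (probe == "P") 70 else 60
  fwhm <- rep_len(fwhm, length(solvents))
  exc <- if (probe == "P") 330 else 520
  bright <- tab$epsilon * tab$quantum_yield
  amp <- bright / max(bright)
  spectra <- lapply(seq_along(solvents), function(i) {
    bandSpectrum(grid, lambdaMax = tab$lambda_em_max[i], fwhm = fwhm[i],
                 skew = skew, amplitude = amp[i], probe = probe,
                 solvent = solvents[i], excitation = exc,
                 concentration = concentration)
  })
  buildReferenceSet(spectra, grid = grid)
}

#' Site-binding model of a multicompartment nanoparticle
#'
#' Independent-class Langmuir binding: each environment offers
#' \code{capacity} sites per nanoparticle with association constant
#' \code{affinity} against the free-dye concentration; unbound dye resides in
#' bulk water, of which a fraction \code{waterPartition} is emissive (1 for a
#' probe with appreciable water emission, 0 for one that is dark in water).
#' Defaults emulate a core-shell particle probed by a partly
#' water-soluble dye: a few high-affinity hydrophobic sites
#' (toluene/dichloromethane-like, saturable at low probe load), many weaker
#' hydrophilic sites (acetonitrile/methanol-like, not saturated up to tens
#' of micromolar), and a large bulk-water fraction from the very first
#' additions (over half the dye at 5 uM load, so the water coefficient is
#' several-fold larger than any bound-site coefficient and dominates once
#' the particle sites saturate).
#'
#' @param labels Environment labels (must exist in the reference set used
#'   for spectrum synthesis).
#' @param capacities Sites per nanoparticle, one per label, >= 0.
#' @param affinities Association constants (1/M), one per label, > 0.
#' @param npConc Nanoparticle concentration (M).
#' @param waterLabel Label of the bulk-water component (default \code{"w"}).
#' @param waterPartition Emissive fraction of unbound dye, in [0, 1].
#' @param refConc Probe concentration (M) at which the reference spectra are
#'   recorded; coefficients are bound-concentration / \code{refConc}.
#' @return An object of class \code{"SiteModel"} (validated list).
#' @export
siteModel <- function(labels = c("t", "d", "a", "m"),
                      capacities = c(0.8, 1, 4, 6),
                      affinities = c(1.5e6, 8e5, 6e4, 3e4),
                      npConc = 1e-6, waterLabel = "w", waterPartition = 1,
                      refConc = 1e-6) {
  stopifnot(length(labels) == length(capacities),
            length(labels) == length(affinities),
            all(capacities >= 0), all(affinities > 0), npConc > 0,
            waterPartition >= 0, waterPartition <= 1, refConc > 0)
  structure(list(labels = labels, capacities = as.numeric(capacities),
                 affinities = as.numeric(affinities), npConc = npConc,
                 waterLabel = waterLabel, waterPartition = waterPartition,
                 refConc = refConc),
            class = "SiteModel")
}

#' Solve the free-dye mass balance of a site model
#'
#' For total dye concentration \code{total}, finds the free concentration f
#' satisfying \eqn{f + \sum_j n_j C_{NP} K_j f/(1+K_j f) = total} by
#' bisection (monotone left side), to an interval width of 1e-12 relative to
#' the total, and returns free and per-class bound concentrations.
#'
#' @param sites A \code{"SiteModel"}.
#' @param total Total dye concentration (M), >= 0.
#' @return List with \code{free} (M) and named \code{bound} (M) per label.
#' @export
solveBinding <- function(sites, total) {
  stopifnot(inherits(sites, "SiteModel"), total >= 0)
  if (total == 0)
    return(list(free = 0,
                bound = stats::setNames(numeric(length(sites$labels)),
                                        sites$labels)))
  boundAt <- function(f)
    sites$capacities * sites$npConc * sites$affinities * f /
      (1 + sites$affinities * f)
  g <- function(f) f + sum(boundAt(f)) - total
  lo <- 0; hi <- total
  if (g(hi) < -1e-12 * total)
    stop("mass balance not bracketed; non-convergent", call. = FALSE)
  for (i in 1:200) {
    mid <- (lo + hi) / 2
    if (g(mid) > 0) hi <- mid else lo <- mid
    if ((hi - lo) < 1e-12 * total) break
  }
  if ((hi - lo) >= 1e-12 * total)
    stop("mass balance did not converge to tolerance", call. = FALSE)
  f <- (lo + hi) / 2
  list(free = f, bound = stats::setNames(boundAt(f), sites$labels))
}

#' Simulate a probe-into-nanoparticle titration with known truth
#'
#' For each total probe concentration, occupancies follow the site model's
#' self-consistent Langmuir balance; the emission spectrum is the
#' occupancy-weighted sum of the (equimolar) reference spectra,
#' \eqn{y = \sum_i c_i S_i} with \eqn{c_i = bound_i / C_{ref}} (and
#' \eqn{c_w} proportional to free dye), plus multiplicative Gaussian noise.
#'
#' @param sites A \code{"SiteModel"}.
#' @param refs [ReferenceSet-class]; its labels must cover the site labels
#'   (plus the water label when \code{waterPartition > 0}).
#' @param probeConcs Total probe concentrations (M), strictly ascending; a
#'   leading 0 produces a blank.
#' @param noise Multiplicative Gaussian noise fraction (default 0.01).
#' @param seed Integer seed; identical seeds give bit-identical output.
#' @return List with \code{series} ([TitrationSeries-class]) and
#'   \code{truth} ([CoefficientTrajectories-class] of the noiseless
#'   ground-truth coefficients).
#' @examples
#' refs <- makeReferenceLibrary("P")
#' sim <- simulateProbeTitration(siteModel(), refs,
#'                               probeConcs = c(1, 5, 25) * 1e-6, seed = 1)
#' coefficients(sim$truth)
#' @export
simulateProbeTitration <- function(sites, refs, probeConcs, noise = 0.01,
                                   seed = 1) {
  stopifnot(inherits(sites, "SiteModel"), is(refs, "ReferenceSet"))
  need <- sites$labels
  if (sites$waterPartition > 0) need <- c(need, sites$waterLabel)
  miss <- setdiff(need, solventLabels(refs))
  if (length(miss))
    stop("reference set lacks label(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  labs <- solventLabels(refs)
  S <- intensities(refs)
  truth <- matrix(0, length(probeConcs), length(labs),
                  dimnames = list(NULL, labs))
  for (i in seq_along(probeConcs)) {
    eq <- solveBinding(sites, probeConcs[i])
    truth[i, sites$labels] <- eq$bound / sites$refConc
    if (sites$waterPartition > 0)
      truth[i, sites$waterLabel] <-
        sites$waterPartition * eq$free / sites$refConc
  }
  spectra <- withSeed(seed, lapply(seq_along(probeConcs), function(i) {
    y <- as.numeric(S %*% truth[i, ])
    if (noise > 0 && any(y != 0))
      y <- y * (1 + noise * stats::rnorm(length(y)))
    newSpectrum(wavelengths(refs), y, probe = probeId(refs),
                excitation = refs@excitation,
                concentration = probeConcs[i])
  }))
  list(series = newTitrationSeries(probeConcs, spectra),
       truth = new("CoefficientTrajectories", concentrations = probeConcs,
                   coefficients = truth,
                   residuals = rep(0, length(probeConcs)),
                   labels = labs, flags = rep("", length(probeConcs))))
}

#' Per-component FRET efficiency curves for a simulated acceptor titration
#'
#' Saturating efficiency profile \eqn{E_i(A) = E_i^{max}\, g(A)} with
#' \eqn{g(A) = (A/A_{max}) (A_{max}+A_{50})/(A+A_{50})}: g rises steeply,
#' saturates, and reaches exactly 1 at the final acceptor concentration, so
#' the generated headline efficiency equals \code{Emax}.
#'
#' @param Emax Named per-label maximal efficiencies in [0, 1].
#' @param acceptorConcs Acceptor concentrations (M), ascending, max > 0.
#' @param A50 Half-rise concentration (M), default a quarter of the maximum.
#' @return Matrix of E (rows = acceptor points, columns = labels).
#' @export
fretEfficiencyProfile <- function(Emax, acceptorConcs, A50 = NULL) {
  stopifnot(all(Emax >= 0), all(Emax <= 1), max(acceptorConcs) > 0)
  Amax <- max(acceptorConcs)
  if (is.null(A50)) A50 <- Amax / 4
  g <- (acceptorConcs / Amax) * (Amax + A50) / (acceptorConcs + A50)
  E <- outer(g, Emax)
  colnames(E) <- names(Emax)
  E
}

#' Simulate a donor + acceptor FRET titration with known truth
#'
#' Emulates titrating a nanoparticle suspension preloaded with donor dye by
#' increasing amounts of acceptor dye. Donor occupancies (from
#' \code{sitesDonor} at \code{donorConc}) stay fixed; acceptor occupancies
#' follow \code{sitesAcceptor} at each acceptor concentration. At acceptor
#' concentration A the donor coefficients are scaled by \eqn{1 - E_i(A)}; the
#' quanta lost by the donor are conserved and re-emitted as sensitized
#' acceptor emission, distributed over acceptor components in proportion to
#' \code{sensitization} times occupancy (uniform weights = every acceptor
#' environment equally sensitized). The returned donor-excitation series
#' contains quenched donor plus sensitized acceptor emission (one physical
#' measurement serving both the donor-quenching and the sensitization
#' analysis); the direct-excitation series contains acceptor emission only.
#'
#' @param sitesDonor,sitesAcceptor \code{"SiteModel"}s for the two dyes.
#' @param refsDonor,refsAcceptor [ReferenceSet-class]s on one shared grid.
#' @param donorConc Total donor concentration (M).
#' @param acceptorConcs Acceptor concentrations (M), ascending, first = 0
#'   (the zero-acceptor baseline).
#' @param Emax Named per-donor-label maximal efficiencies in [0, 1] (pin the
#'   bulk-water label at 0 for a FRET-silent component), expanded into curves
#'   by [fretEfficiencyProfile()]; or a full matrix from that function.
#' @param sensitization Named nonnegative weights per acceptor-site label;
#'   default uniform.
#' @param noise Multiplicative Gaussian noise fraction.
#' @param seed Integer seed.
#' @return List: \code{donor} and \code{sensitized} (the same
#'   donor-excitation [TitrationSeries-class]), \code{direct}
#'   (acceptor-excitation series) and \code{truth} (donor baseline
#'   coefficients, efficiency curves, headline efficiencies, acceptor
#'   occupancy coefficients, per-point donor quanta lost and acceptor quanta
#'   gained).
#' @export
simulateFretTitration <- function(sitesDonor, sitesAcceptor, refsDonor,
                                  refsAcceptor, donorConc, acceptorConcs,
                                  Emax, sensitization = NULL, noise = 0.01,
                                  seed = 1) {
  stopifnot(is(refsDonor, "ReferenceSet"), is(refsAcceptor, "ReferenceSet"))
  if (!isTRUE(all.equal(wavelengths(refsDonor), wavelengths(refsAcceptor))))
    stop("donor and acceptor reference sets must share one grid",
         call. = FALSE)
  if (acceptorConcs[1] != 0)
    stop("acceptor titration must start at the zero-acceptor baseline",
         call. = FALSE)
  dLabs <- solventLabels(refsDonor)
  aLabs <- solventLabels(refsAcceptor)
  E <- if (is.matrix(Emax)) Emax
       else fretEfficiencyProfile(Emax, acceptorConcs)
  if (!all(dLabs %in% colnames(E)))
    stop("efficiency profile must cover all donor labels", call. = FALSE)
  E <- E[, dLabs, drop = FALSE]
  if (any(E < 0 | E > 1))
    stop("efficiencies must lie in [0, 1]", call. = FALSE)

  # fixed donor occupancies at zero acceptor
  eqD <- solveBinding(sitesDonor, donorConc)
  c0 <- stats::setNames(numeric(length(dLabs)), dLabs)
  c0[sitesDonor$labels] <- eqD$bound / sitesDonor$refConc
  if (sitesDonor$waterPartition > 0)
    c0[sitesDonor$waterLabel] <-
      sitesDonor$waterPartition * eqD$free / sitesDonor$refConc

  # acceptor occupancies per titration point
  dMat <- matrix(0, length(acceptorConcs), length(aLabs),
                 dimnames = list(NULL, aLabs))
  for (i in seq_along(acceptorConcs)) {
    eqA <- solveBinding(sitesAcceptor, acceptorConcs[i])
    dMat[i, sitesAcceptor$labels] <- eqA$bound / sitesAcceptor$refConc
    if (sitesAcceptor$waterPartition > 0)
      dMat[i, sitesAcceptor$waterLabel] <-
        sitesAcceptor$waterPartition * eqA$free / sitesAcceptor$refConc
  }

  if (is.null(sensitization))
    sensitization <- stats::setNames(rep(1, length(aLabs)), aLabs)
  sens <- stats::setNames(numeric(length(aLabs)), aLabs)
  sens[names(sensitization)] <- sensitization

  wl <- wavelengths(refsDonor)
  SD <- intensities(refsDonor)
  SA <- intensities(refsAcceptor)
  areaD <- apply(SD, 2, function(y) pracma::trapz(wl, y))
  areaA <- apply(SA, 2, function(y) pracma::trapz(wl, y))

  n <- length(acceptorConcs)
  cDon <- matrix(0, n, length(dLabs), dimnames = list(NULL, dLabs))
  cSens <- matrix(0, n, length(aLabs), dimnames = list(NULL, aLabs))
  qLost <- qGained <- numeric(n)
  for (i in seq_len(n)) {
    cDon[i, ] <- c0 * (1 - E[i, ])
    qLost[i] <- sum(c0 * E[i, ] * areaD)
    wgt <- sens * dMat[i, ]
    denom <- sum(wgt * areaA)
    if (qLost[i] > 0 && denom > 0) cSens[i, ] <- qLost[i] * wgt / denom
    qGained[i] <- sum(cSens[i, ] * areaA)
  }

  noisy <- function(y) {
    if (noise > 0 && any(y != 0)) y * (1 + noise * stats::rnorm(length(y)))
    else y
  }
  out <- withSeed(seed, {
    s330 <- lapply(seq_len(n), function(i) {
      y <- as.numeric(SD %*% cDon[i, ] + SA %*% cSens[i, ])
      newSpectrum(wl, noisy(y), probe = probeId(refsDonor),
                  excitation = refsDonor@excitation,
                  concentration = acceptorConcs[i])
    })
    s520 <- lapply(seq_len(n), function(i) {
      y <- as.numeric(SA %*% dMat[i, ])
      if (i == 1L && all(y == 0))
        newSpectrum(wl, y, probe = probeId(refsAcceptor),
                    excitation = refsAcceptor@excitation, concentration = 0)
      else
        newSpectrum(wl, noisy(y), probe = probeId(refsAcceptor),
                    excitation = refsAcceptor@excitation,
                    concentration = acceptorConcs[i])
    })
    list(s330 = s330, s520 = s520)
  })
  donorSeries <- newTitrationSeries(acceptorConcs, out$s330)
  directSeries <- newTitrationSeries(acceptorConcs, out$s520)
  list(donor = donorSeries, sensitized = donorSeries, direct = directSeries,
       truth = list(donorBaseline = c0, efficiencyCurves = E,
                    headlineE = E[n, ], acceptorCoefficients = dMat,
                    sensitizedCoefficients = cSens, quantaLost = qLost,
                    quantaGained = qGained))
}

#' Radial compartment geometry of a core-shell nanoparticle
#'
#' @param shells data.frame with columns \code{label}, \code{r_in_nm},
#'   \code{r_out_nm}; contiguous shells from the centre outwards. The default
#'   describes a ~5.5 nm silica core, a thin hydrophobic polymer layer and a
#'   hydrated outer layer out to a 13 nm hydrodynamic radius.
#' @return A [NanoparticleGeometry-class].
#' @export
nanoparticleGeometry <- function(shells = data.frame(
    label = c("core", "ppo", "peg"),
    r_in_nm = c(0, 5.5, 8.0),
    r_out_nm = c(5.5, 8.0, 13.0))) {
  new("NanoparticleGeometry", shells = shells)
}

setMethod("show", "NanoparticleGeometry", function(object) {
  cat("NanoparticleGeometry:\n")
  print(object@shells)
})

# uniform point in the spherical shell [rIn, rOut): n x 3 matrix (nm)
samplePointsInShell <- function(n, rIn, rOut) {
  r <- (rIn^3 + stats::runif(n) * (rOut^3 - rIn^3))^(1 / 3)
  v <- matrix(stats::rnorm(3 * n), ncol = 3)
  v <- v / sqrt(rowSums(v^2))
  v * r
}

#' Monte-Carlo multi-acceptor FRET efficiency in a compartment geometry
#'
#' Per trial, places the donor (at the particle centre or uniformly within a
#' named compartment shell) and \code{nAcceptors} acceptors uniformly within
#' their compartment shell(s), and evaluates the multi-acceptor efficiency
#' via [efficiencyAtDistance()]. Confining donor and acceptors to the same
#' thin compartment with R0 comparable to the compartment size drives E
#' towards 1; dispersing the acceptors far from the donor drives E towards 0
#' — the geometric reading of coupled versus decoupled components.
#'
#' @param geometry A [NanoparticleGeometry-class] (radii in nm).
#' @param donor Either \code{"center"} or the label of the shell in which the
#'   donor is placed uniformly.
#' @param acceptorCompartments Label(s) of the shell(s) from which each
#'   acceptor's shell is drawn uniformly by volume.
#' @param nAcceptors Number of acceptors per particle, >= 0.
#' @param R0 Forster radius in Angstrom (geometry radii are nm; 1 nm = 10 A).
#' @param nTrials Number of Monte-Carlo trials, >= 1.
#' @param seed Integer seed.
#' @return List: \code{mean}, \code{sd} of the efficiency distribution, and
#'   the per-trial \code{samples}.
#' @export
monteCarloQuenching <- function(geometry, donor = "center",
                                acceptorCompartments, nAcceptors, R0,
                                nTrials = 1e4, seed = 1) {
  stopifnot(is(geometry, "NanoparticleGeometry"), nAcceptors >= 0,
            nTrials >= 1, R0 > 0)
  sh <- geometry@shells
  pick <- function(labels) {
    rows <- sh[sh$label %in% labels, , drop = FALSE]
    if (!nrow(rows))
      stop("no shell labelled: ", paste(labels, collapse = ", "),
           call. = FALSE)
    if (any(rows$r_out_nm^3 - rows$r_in_nm^3 <= 0))
      stop("empty compartment volume", call. = FALSE)
    rows
  }
  if (nAcceptors == 0)
    return(list(mean = 0, sd = 0, samples = rep(0, nTrials)))
  accRows <- pick(acceptorCompartments)
  vol <- accRows$r_out_nm^3 - accRows$r_in_nm^3
  donRows <- if (identical(donor, "center")) NULL else pick(donor)
  samples <- withSeed(seed, {
    vapply(seq_len(nTrials), function(i) {
      dpos <- if (is.null(donRows)) c(0, 0, 0)
              else as.numeric(samplePointsInShell(1, donRows$r_in_nm[1],
                                                  donRows$r_out_nm[1]))
      shellIdx <- sample.int(nrow(accRows), nAcceptors, replace = TRUE,
                             prob = vol)
      apos <- do.call(rbind, lapply(seq_len(nAcceptors), function(j)
        samplePointsInShell(1, accRows$r_in_nm[shellIdx[j]],
                            accRows$r_out_nm[shellIdx[j]])))
      dist_nm <- sqrt(rowSums(sweep(apos, 2, dpos)^2))
      efficiencyAtDistance(dist_nm * 10, R0)
    }, numeric(1))
  })
  list(mean = mean(samples), sd = stats::sd(samples), samples = samples)
}
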