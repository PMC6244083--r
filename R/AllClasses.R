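#' @import methods
NULL

#' Spectrum: a single emission or molar-absorption spectrum
#'
#' Container for one spectrum on a strictly ascending wavelength grid, with
#' the metadata the downstream fitting machinery needs: probe identity,
#' solvent label, excitation wavelength and probe concentration.
#'
#' @slot wavelength Numeric vector of wavelengths in nm, strictly ascending,
#'   length >= 2.
#' @slot intensity Numeric vector, same length as \code{wavelength}. Arbitrary
#'   emission units, or molar extinction (1/(M cm)) for
#'   \code{kind = "molar-absorption"}.
#' @slot probe Character scalar, probe identifier (e.g. \code{"P"},
#'   \code{"NR"}); may be \code{NA}.
#' @slot solvent Character scalar, solvent/environment label; may be \code{NA}.
#' @slot excitation Numeric scalar, excitation wavelength in nm; may be
#'   \code{NA} (and is ignored for absorption spectra).
#' @slot concentration Numeric scalar, probe concentration in M; may be
#'   \code{NA}.
#' @slot kind Either \code{"emission"} or \code{"molar-absorption"}.
#'
#' @seealso [readSpectrum()], [resample()], [bandSpectrum()]
#' @export
setClass("Spectrum",
  representation(
    wavelength    = "numeric",
    intensity     = "numeric",
    probe         = "character",
    solvent       = "character",
    excitation    = "numeric",
    concentration = "numeric",
    kind          = "character"
  ),
  prototype(
    probe = NA_character_, solvent = NA_character_,
    excitation = NA_real_, concentration = NA_real_,
    kind = "emission"
  )
)

setValidity("Spectrum", function(object) {
  msg <- character()
  w <- object@wavelength
  y <- object@intensity
  if (length(w) < 2L) msg <- c(msg, "spectrum needs at least 2 points")
  if (length(w) != length(y))
    msg <- c(msg, "wavelength and intensity lengths differ")
  if (anyNA(w) || any(!is.finite(w)))
    msg <- c(msg, "non-finite wavelengths")
  if (anyNA(y) || any(!is.finite(y)))
    msg <- c(msg, "non-finite intensities")
  if (length(w) >= 2L && any(diff(w) <= 0))
    msg <- c(msg, "wavelengths must be strictly increasing")
  if (!object@kind %in% c("emission", "molar-absorption"))
    msg <- c(msg, "kind must be 'emission' or 'molar-absorption'")
  if (identical(object@kind, "molar-absorption") &&
      length(y) && all(is.finite(y)) && any(y < 0))
    msg <- c(msg, "molar-absorption intensities must be >= 0")
  if (length(msg)) msg else TRUE
})

#' ReferenceSet: co-gridded pure-solvent reference spectra
#'
#' A library of reference emission spectra S_i(lambda) of one probe recorded
#' in pure solvents on a single shared wavelength grid. The unmixing model
#' expresses a measured spectrum as a nonnegative linear combination of these
#' columns, so the intensities are stored as a wavelength-by-solvent matrix.
#'
#' @slot wavelength Shared grid, nm, strictly ascending.
#' @slot intensities Matrix, \code{length(wavelength)} rows, one column per
#'   solvent label; nonnegative (baseline noise is clipped on construction).
#' @slot labels Unique solvent labels, one per column.
#' @slot probe Probe identifier common to all members.
#' @slot excitation Excitation wavelength (nm) common to all members.
#'
#' @seealso [buildReferenceSet()], [makeReferenceLibrary()], [unmix()]
#' @export
setClass("ReferenceSet",
  representation(
    wavelength  = "numeric",
    intensities = "matrix",
    labels      = "character",
    probe       = "character",
    excitation  = "numeric"
  ),
  prototype(probe = NA_character_, excitation = NA_real_)
)

setValidity("ReferenceSet", function(object) {
  msg <- character()
  if (!length(object@labels)) msg <- c(msg, "empty reference set")
  if (anyDuplicated(object@labels)) msg <- c(msg, "duplicate solvent labels")
  if (nrow(object@intensities) != length(object@wavelength))
    msg <- c(msg, "intensity rows do not match grid length")
  if (ncol(object@intensities) != length(object@labels))
    msg <- c(msg, "intensity columns do not match labels")
  if (length(object@wavelength) >= 2L && any(diff(object@wavelength) <= 0))
    msg <- c(msg, "grid must be strictly increasing")
  if (length(object@intensities) && any(object@intensities < 0))
    msg <- c(msg, "reference intensities must be nonnegative")
  if (length(msg)) msg else TRUE
})

#' TitrationSeries: spectra ordered by titrant concentration
#'
#' An ordered collection of emission spectra recorded along a titration
#' (probe loading or acceptor loading), with one spectrum per titrant
#' concentration.
#'
#' @slot concentrations Titrant concentrations in M, strictly ascending.
#' @slot spectra List of [Spectrum-class] objects, one per concentration.
#'
#' @seealso [fitTitration()], [simulateProbeTitration()]
#' @export
setClass("TitrationSeries",
  representation(concentrations = "numeric", spectra = "list")
)

setValidity("TitrationSeries", function(object) {
  msg <- character()
  if (length(object@concentrations) != length(object@spectra))
    msg <- c(msg, "one spectrum per concentration required")
  if (length(object@concentrations) >= 2L &&
      any(diff(object@concentrations) <= 0))
    msg <- c(msg, "concentrations must be strictly ascending")
  if (any(object@concentrations < 0))
    msg <- c(msg, "concentrations must be >= 0")
  if (!all(vapply(object@spectra, is, logical(1), "Spectrum")))
    msg <- c(msg, "spectra must all be Spectrum objects")
  if (length(msg)) msg else TRUE
})

#' UnmixResult: nonnegative spectral deconvolution of one spectrum
#'
#' Result of fitting a measured spectrum as \eqn{\sum_i c_i S_i(\lambda)} with
#' \eqn{c_i \ge 0}. Coefficients are dimensionless fractions of the
#' (equimolar) reference intensities; the residual is the relative
#' root-mean-square misfit, \eqn{\sqrt{\sum r^2 / \sum y^2}}.
#'
#' @slot coefficients Named nonnegative numeric vector, one entry per label.
#' @slot residual Relative RMS misfit (fraction, >= 0).
#' @slot fitted The fitted spectrum (same grid as the sample).
#' @slot labels Solvent labels, in reference-set order.
#' @slot flags Character vector of quality flags (e.g.
#'   \code{"collinear-references"}); empty when clean.
#'
#' @seealso [unmix()]
#' @export
setClass("UnmixResult",
  representation(
    coefficients = "numeric",
    residual     = "numeric",
    fitted       = "Spectrum",
    labels       = "character",
    flags        = "character"
  ),
  prototype(flags = character())
)

setValidity("UnmixResult", function(object) {
  msg <- character()
  if (length(object@coefficients) != length(object@labels))
    msg <- c(msg, "one coefficient per label required")
  if (any(object@coefficients < 0)) msg <- c(msg, "coefficients must be >= 0")
  if (length(object@residual) != 1L || object@residual < 0)
    msg <- c(msg, "residual must be a single value >= 0")
  if (length(msg)) msg else TRUE
})

#' CoefficientTrajectories: per-solvent unmixing coefficients along a titration
#'
#' The evolution of each unmixing coefficient c_i across a titration: one
#' coefficient vector (plus residual) per titration point.
#'
#' @slot concentrations Titrant concentrations (M), strictly ascending.
#' @slot coefficients Matrix, one row per titration point, one column per
#'   solvent label.
#' @slot residuals Per-point relative RMS residuals.
#' @slot labels Solvent labels (column names of \code{coefficients}).
#' @slot flags Character vector, one per point: \code{""} when clean,
#'   otherwise e.g. \code{"blank"} or \code{"fit-failed"}.
#'
#' @seealso [fitTitration()], [componentFretEfficiencies()]
#' @export
setClass("CoefficientTrajectories",
  representation(
    concentrations = "numeric",
    coefficients   = "matrix",
    residuals      = "numeric",
    labels         = "character",
    flags          = "character"
  )
)

setValidity("CoefficientTrajectories", function(object) {
  msg <- character()
  n <- length(object@concentrations)
  if (nrow(object@coefficients) != n)
    msg <- c(msg, "one coefficient row per titration point required")
  if (ncol(object@coefficients) != length(object@labels))
    msg <- c(msg, "one coefficient column per label required")
  if (length(object@residuals) != n || length(object@flags) != n)
    msg <- c(msg, "residuals/flags must have one entry per point")
  if (n >= 2L && any(diff(object@concentrations) <= 0))
    msg <- c(msg, "concentrations must be strictly ascending")
  if (length(msg)) msg else TRUE
})

#' FretMapResult: per-polarity-component FRET efficiencies and classification
#'
#' For each polarity component (solvent label) of the donor, the transfer
#' efficiency extracted from the depletion of its unmixing coefficient along
#' an acceptor titration, the full efficiency-versus-acceptor-concentration
#' curve, and the coupled/decoupled classification: a component with
#' \eqn{E \ge} the coupling threshold is colocalized with the acceptors
#' within a Forster radius, a component with lower E is FRET-silent.
#'
#' @slot labels Donor solvent labels.
#' @slot efficiencies Headline per-label efficiency E_i (at the highest
#'   acceptor concentration); \code{NA} where indeterminate.
#' @slot efficiencyCurves Matrix of E_i at every acceptor concentration
#'   (rows = acceptor points, columns = labels).
#' @slot acceptorConcentrations Acceptor concentration axis (M).
#' @slot classification Per-label: \code{"coupled"}, \code{"decoupled"} or
#'   \code{"indeterminate"} (baseline coefficient below the floor).
#' @slot distanceBound Per-label distance bound relative to R0:
#'   \code{"r <= R0"}, \code{"r > R0"} or \code{NA}.
#' @slot coupleThreshold Efficiency threshold used for classification.
#' @slot trajectories The raw donor [CoefficientTrajectories-class].
#'
#' @seealso [componentFretEfficiencies()], [classifyComponents()]
#' @export
setClass("FretMapResult",
  representation(
    labels                 = "character",
    efficiencies           = "numeric",
    efficiencyCurves       = "matrix",
    acceptorConcentrations = "numeric",
    classification         = "character",
    distanceBound          = "character",
    coupleThreshold        = "numeric",
    trajectories           = "CoefficientTrajectories"
  ),
  prototype(coupleThreshold = NA_real_)
)

setValidity("FretMapResult", function(object) {
  msg <- character()
  k <- length(object@labels)
  if (length(object@efficiencies) != k)
    msg <- c(msg, "one efficiency per label required")
  if (length(object@classification) != k)
    msg <- c(msg, "one classification per label required")
  ok <- is.na(object@efficiencies) |
    (object@efficiencies >= 0 & object@efficiencies <= 1)
  if (!all(ok)) msg <- c(msg, "efficiencies must lie in [0, 1]")
  if (anyDuplicated(object@labels)) msg <- c(msg, "duplicate labels")
  if (length(msg)) msg else TRUE
})

#' NanoparticleGeometry: concentric compartment shells of a core-shell particle
#'
#' Radial model of a core-shell nanoparticle as contiguous spherical shells
#' \code{[rIn, rOut)}, each carrying an environment label. Defaults describe a
#' silica-core / triblock-copolymer-shell particle: ~5 nm core radius and
#' ~7 nm polymeric shell split into a hydrophobic inner layer and a hydrated
#' outer layer.
#'
#' @slot shells data.frame with columns \code{label}, \code{r_in_nm},
#'   \code{r_out_nm}; shells contiguous and non-overlapping.
#'
#' @seealso [nanoparticleGeometry()], [monteCarloQuenching()]
#' @export
setClass("NanoparticleGeometry", representation(shells = "data.frame"))

setValidity("NanoparticleGeometry", function(object) {
  s <- object@shells
  msg <- character()
  need <- c("label", "r_in_nm", "r_out_nm")
  if (!all(need %in% names(s)))
    return("shells must have columns label, r_in_nm, r_out_nm")
  if (!nrow(s)) msg <- c(msg, "at least one shell required")
  if (any(s$r_out_nm <= s$r_in_nm)) msg <- c(msg, "shells must have r_out > r_in")
  if (nrow(s) >= 2L && any(abs(s$r_in_nm[-1] - s$r_out_nm[-nrow(s)]) > 1e-9))
    msg <- c(msg, "shells must be contiguous")
  if (any(s$r_in_nm < 0)) msg <- c(msg, "radii must be >= 0")
  if (length(msg)) msg else TRUE
})
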