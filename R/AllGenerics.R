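#' Accessors for spectral objects
#'
#' \code{wavelengths()} returns the wavelength grid (nm); \code{intensities()}
#' the intensity vector or wavelength-by-label matrix; \code{solventLabels()}
#' the ordered solvent labels; \code{probeId()} the probe identifier.
#'
#' @param x A [Spectrum-class], [ReferenceSet-class] or result object.
#' @return Numeric vector/matrix or character vector as described.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("wavelengths", function(x) standardGeneric("wavelengths"))

#' @rdname accessors
#' @export
setGeneric("intensities", function(x) standardGeneric("intensities"))

#' @rdname accessors
#' @export
setGeneric("solventLabels", function(x) standardGeneric("solventLabels"))

#' @rdname accessors
#' @export
setGeneric("probeId", function(x) standardGeneric("probeId"))

#' Resample a spectrum onto a new wavelength grid
#'
#' Linear interpolation onto \code{grid}, which must lie inside the source
#' support (no extrapolation). Metadata are preserved. Resampling onto the
#' spectrum's own grid is the identity.
#'
#' @param x A [Spectrum-class].
#' @param grid Strictly ascending numeric vector of wavelengths (nm) within
#'   \code{range(wavelengths(x))}.
#' @return A [Spectrum-class] on \code{grid}.
#' @examples
#' s <- newSpectrum(c(400, 500, 600), c(0, 1, 0))
#' intensities(resample(s, c(450, 550)))  # 0.5, 0.5 by linear interpolation
#' @export
setGeneric("resample", function(x, grid) standardGeneric("resample"))

#' @rdname accessors
#' @export
setGeneric("concentrations", function(x) standardGeneric("concentrations"))
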