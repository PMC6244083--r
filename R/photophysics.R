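# Standard Forster theory. Unit convention, fixed throughout: J in
# M^-1 cm^-1 nm^4, R0 and distances in Angstrom, with
# R0^6 = 8.79e-5 * kappa^2 * n^-4 * QY_D * J  (Angstrom^6).

#' Spectral overlap integral between donor emission and acceptor absorption
#'
#' \deqn{J = \int \bar F_D(\lambda)\, \varepsilon_A(\lambda)\, \lambda^4\,
#' d\lambda}
#' with the donor emission normalized internally to unit area and the
#' acceptor spectrum in molar-extinction units. Trapezoidal quadrature on the
#' common (intersection) grid; the donor spectrum sets the grid and the
#' acceptor is interpolated onto it.
#'
#' @param donorEmission [Spectrum-class], kind \code{"emission"}.
#' @param acceptorAbsorption [Spectrum-class], kind \code{"molar-absorption"}.
#' @return J in M^-1 cm^-1 nm^4. Disjoint supports return 0 with a warning.
#' @seealso [forsterRadius()]
#' @export
overlapIntegral <- function(donorEmission, acceptorAbsorption) {
  stopifnot(is(donorEmission, "Spectrum"), is(acceptorAbsorption, "Spectrum"))
  lo <- max(min(wavelengths(donorEmission)),
            min(wavelengths(acceptorAbsorption)))
  hi <- min(max(wavelengths(donorEmission)),
            max(wavelengths(acceptorAbsorption)))
  if (lo >= hi) {
    warning("donor emission and acceptor absorption have disjoint supports; ",
            "J = 0", call. = FALSE)
    return(0)
  }
  wl <- wavelengths(donorEmission)
  wl <- wl[wl >= lo & wl <= hi]
  if (length(wl) < 2L) wl <- c(lo, hi)
  fd <- intensities(resample(donorEmission, wl))
  ea <- intensities(resample(acceptorAbsorption, wl))
  areaD <- pracma::trapz(wavelengths(donorEmission),
                         intensities(donorEmission))
  if (areaD <= 0) stop("donor emission has non-positive area", call. = FALSE)
  pracma::trapz(wl, (fd / areaD) * ea * wl^4)
}

#' Forster radius from the overlap integral
#'
#' \deqn{R_0 = \left(8.79\times 10^{-5}\, \kappa^2\, n^{-4}\, \Phi_D\, J
#' \right)^{1/6}} in Angstrom, with J in M^-1 cm^-1 nm^4. \code{kappa2}
#' defaults to 2/3 (isotropic dynamic orientational averaging).
#'
#' @param J Overlap integral, M^-1 cm^-1 nm^4, >= 0.
#' @param qyD Donor fluorescence quantum yield (fraction in (0, 1]).
#' @param kappa2 Orientation factor, in (0, 4].
#' @param n Refractive index of the medium (see [refractiveIndex()]).
#' @return R0 in Angstrom; 0 iff \code{J == 0}.
#' @examples
#' forsterRadius(1e15, qyD = 0.5, n = 1.4)
#' @export
forsterRadius <- function(J, qyD, kappa2 = 2 / 3, n = 1.333) {
  stopifnot(J >= 0, qyD > 0, qyD <= 1, kappa2 > 0, kappa2 <= 4, n > 0)
  (8.79e-5 * kappa2 * n^-4 * qyD * J)^(1 / 6)
}

#' FRET efficiency from donor quenching
#'
#' \eqn{E = 1 - F_{DA}/F_D}: the fractional loss of donor signal (intensity
#' or unmixing coefficient) in the presence of acceptors. Values outside
#' [0, 1] (noise) are clipped with an attribute flag, never silently.
#'
#' @param fDA Donor signal with acceptors present (>= 0).
#' @param fD Donor signal without acceptors (> 0). Same units as \code{fDA}.
#' @return Efficiency in [0, 1]; attribute \code{"clipped"} is \code{TRUE}
#'   when the raw value fell outside the interval.
#' @export
efficiencyFromQuench <- function(fDA, fD) {
  if (any(fD <= 0)) stop("reference donor signal must be > 0", call. = FALSE)
  if (any(fDA < 0)) stop("quenched donor signal must be >= 0", call. = FALSE)
  e <- 1 - fDA / fD
  clipped <- e < 0 | e > 1
  e <- pmin(pmax(e, 0), 1)
  attr(e, "clipped") <- clipped
  e
}

#' Donor-acceptor distance from FRET efficiency
#'
#' \eqn{r = R_0 (1/E - 1)^{1/6}}. Boundary efficiencies return sentinels with
#' a flag: \code{E = 0} gives \code{Inf}, \code{E = 1} gives \code{0}.
#'
#' @param E Efficiency in [0, 1].
#' @param R0 Forster radius (Angstrom), > 0.
#' @return Distance in Angstrom (same units as R0); attribute
#'   \code{"boundary"} marks entries where E was exactly 0 or 1.
#' @examples
#' distanceFromEfficiency(0.5, 29.7)  # r = R0
#' @export
distanceFromEfficiency <- function(E, R0) {
  stopifnot(all(E >= 0), all(E <= 1), R0 > 0)
  r <- ifelse(E == 0, Inf, ifelse(E == 1, 0, R0 * (1 / E - 1)^(1 / 6)))
  attr(r, "boundary") <- E == 0 | E == 1
  r
}

#' FRET efficiency of a donor facing one or more acceptors
#'
#' Rate competition among independent transfer channels: with transfer rates
#' \eqn{k_i \propto (R_0/r_i)^6},
#' \deqn{E = \frac{S}{1 + S}, \qquad S = \sum_i (R_0/r_i)^6.}
#' A single acceptor at \eqn{r = R_0} gives E = 1/2.
#'
#' @param distances Donor-acceptor distances (Angstrom), all > 0; an empty
#'   vector means no acceptors and E = 0.
#' @param R0 Forster radius, same units, > 0.
#' @return Efficiency in [0, 1).
#' @export
efficiencyAtDistance <- function(distances, R0) {
  stopifnot(R0 > 0)
  if (!length(distances)) return(0)
  stopifnot(all(distances > 0))
  S <- sum((R0 / distances)^6)
  S / (1 + S)
}

#' Tabulated refractive indices of the five reference solvents
#'
#' Sodium-D-line refractive indices at 20 C for toluene (t), dichloromethane
#' (d), acetonitrile (a), methanol (m) and water (w), for use as the medium
#' index in [forsterRadius()].
#'
#' @param solvent Optional label(s); default returns the full named vector.
#' @return Named numeric vector.
#' @export
refractiveIndex <- function(solvent = NULL) {
  tab <- c(t = 1.497, d = 1.424, a = 1.344, m = 1.328, w = 1.333)
  if (is.null(solvent)) return(tab)
  miss <- setdiff(solvent, names(tab))
  if (length(miss))
    stop("unknown solvent label(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  tab[solvent]
}
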