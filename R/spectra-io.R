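#' Construct a Spectrum
#'
#' @param wavelength Wavelengths in nm. If supplied unordered they are sorted
#'   (with intensities permuted consistently); duplicated wavelengths are an
#'   error.
#' @param intensity Intensities, same length.
#' @param probe,solvent Optional identifiers.
#' @param excitation Excitation wavelength (nm).
#' @param concentration Probe concentration (M).
#' @param kind \code{"emission"} (default) or \code{"molar-absorption"}.
#' @return A validated [Spectrum-class].
#' @examples
#' s <- newSpectrum(c(400, 500, 600), c(0, 1, 0), probe = "P", solvent = "t")
#' s
#' @export
newSpectrum <- function(wavelength, intensity,
                        probe = NA_character_, solvent = NA_character_,
                        excitation = NA_real_, concentration = NA_real_,
                        kind = "emission") {
  wavelength <- as.numeric(wavelength)
  intensity <- as.numeric(intensity)
  if (length(wavelength) < 2L)
    stop("degenerate input: a spectrum needs at least 2 points", call. = FALSE)
  if (anyDuplicated(wavelength))
    stop("duplicated wavelengths: ",
         paste(unique(wavelength[duplicated(wavelength)]), collapse = ", "),
         " nm", call. = FALSE)
  o <- order(wavelength)
  new("Spectrum",
      wavelength = wavelength[o], intensity = intensity[o],
      probe = as.character(probe), solvent = as.character(solvent),
      excitation = as.numeric(excitation),
      concentration = as.numeric(concentration), kind = kind)
}

#' Read a spectrum from a two-column text file
#'
#' Expects comma-, tab- or whitespace-separated columns
#' \code{wavelength_nm, intensity}; lines starting with \code{#} are comments
#' and a single non-numeric header line is tolerated. Rows are returned sorted
#' by wavelength; duplicate wavelengths are rejected.
#'
#' @param file Path or connection.
#' @param probe,solvent,excitation,concentration,kind Metadata, as in
#'   [newSpectrum()].
#' @return A [Spectrum-class].
#' @seealso [writeSpectrum()]
#' @export
readSpectrum <- function(file, probe = NA_character_, solvent = NA_character_,
                         excitation = NA_real_, concentration = NA_real_,
                         kind = "emission") {
  lines <- readLines(file, warn = FALSE)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  if (!length(lines)) stop("degenerate input: no data rows", call. = FALSE)
  parseRow <- function(l) {
    parts <- strsplit(l, "[,\t ]+")[[1]]
    parts <- parts[nzchar(parts)]
    suppressWarnings(as.numeric(parts))
  }
  first <- parseRow(lines[1])
  if (anyNA(first)) lines <- lines[-1]  # header line
  vals <- lapply(seq_along(lines), function(i) {
    v <- parseRow(lines[i])
    if (length(v) < 2L || anyNA(v[1:2]))
      stop("malformed spectrum row at data line ", i, ": '", lines[i], "'",
           call. = FALSE)
    v[1:2]
  })
  m <- do.call(rbind, vals)
  if (nrow(m) < 2L)
    stop("degenerate input: fewer than 2 data rows", call. = FALSE)
  newSpectrum(m[, 1], m[, 2], probe = probe, solvent = solvent,
              excitation = excitation, concentration = concentration,
              kind = kind)
}

#' Write a spectrum as a two-column CSV
#'
#' Full-precision round-trip companion to [readSpectrum()].
#'
#' @param x A [Spectrum-class].
#' @param file Output path.
#' @param comment Optional character vector written as \code{#} header lines.
#' @return \code{file}, invisibly.
#' @export
writeSpectrum <- function(x, file, comment = NULL) {
  stopifnot(is(x, "Spectrum"))
  con <- file(file, "w")
  on.exit(close(con))
  if (length(comment)) writeLines(paste0("# ", comment), con)
  writeLines("wavelength_nm,intensity", con)
  writeLines(paste(format(x@wavelength, digits = 17, trim = TRUE),
                   format(x@intensity, digits = 17, trim = TRUE), sep = ","),
             con)
  invisible(file)
}

#' @rdname accessors
#' @export
setMethod("wavelengths", "Spectrum", function(x) x@wavelength)

#' @rdname accessors
#' @export
setMethod("intensities", "Spectrum", function(x) x@intensity)

#' @rdname accessors
#' @export
setMethod("probeId", "Spectrum", function(x) x@probe)

#' @rdname accessors
#' @export
setMethod("wavelengths", "ReferenceSet", function(x) x@wavelength)

#' @rdname accessors
#' @export
setMethod("intensities", "ReferenceSet", function(x) x@intensities)

#' @rdname accessors
#' @export
setMethod("solventLabels", "ReferenceSet", function(x) x@labels)

#' @rdname accessors
#' @export
setMethod("probeId", "ReferenceSet", function(x) x@probe)

#' @rdname accessors
#' @export
setMethod("concentrations", "TitrationSeries", function(x) x@concentrations)

setMethod("show", "Spectrum", function(object) {
  rng <- range(object@wavelength)
  cat(sprintf("Spectrum (%s): %d points, %.1f-%.1f nm", object@kind,
              length(object@wavelength), rng[1], rng[2]))
  if (!is.na(object@probe)) cat(", probe", object@probe)
  if (!is.na(object@solvent)) cat(", solvent", object@solvent)
  if (!is.na(object@excitation))
    cat(sprintf(", lexc %.0f nm", object@excitation))
  cat("\n")
})

setMethod("show", "ReferenceSet", function(object) {
  rng <- range(object@wavelength)
  cat(sprintf("ReferenceSet: probe %s, %d solvents [%s], %d points, %.1f-%.1f nm\n",
              object@probe, length(object@labels),
              paste(object@labels, collapse = ","),
              length(object@wavelength), rng[1], rng[2]))
})

setMethod("show", "TitrationSeries", function(object) {
  cat(sprintf("TitrationSeries: %d points, titrant %.3g-%.3g M\n",
              length(object@concentrations),
              min(object@concentrations), max(object@concentrations)))
})

#' @rdname resample
#' @export
setMethod("resample", "Spectrum", function(x, grid) {
  grid <- as.numeric(grid)
  if (length(grid) >= 2L && any(diff(grid) <= 0))
    stop("target grid must be strictly ascending", call. = FALSE)
  rng <- range(x@wavelength)
  if (min(grid) < rng[1] || max(grid) > rng[2])
    stop(sprintf(
      "grid [%g, %g] outside spectrum support [%g, %g]: no extrapolation",
      min(grid), max(grid), rng[1], rng[2]), call. = FALSE)
  y <- stats::approx(x@wavelength, x@intensity, xout = grid,
                     method = "linear", ties = "ordered")$y
  initialize(x, wavelength = grid, intensity = y)
})

#' Build a co-gridded reference set from pure-solvent spectra
#'
#' Assembles reference spectra of one probe, recorded at equimolar probe
#' concentration in the pure solvents, onto a single shared grid. By default
#' the grid is the intersection of the member supports at the coarsest input
#' step; alternatively an explicit grid is used. Negative intensities
#' (baseline noise) are clipped to zero: the references enter a nonnegative
#' mixture model.
#'
#' @param spectra List of [Spectrum-class] objects with unique solvent labels,
#'   the same probe id and the same excitation wavelength.
#' @param grid Optional explicit grid (nm); default: support intersection.
#' @return A [ReferenceSet-class].
#' @details Spectra recorded at visibly non-equimolar concentrations trigger a
#'   warning (coefficients are only comparable across solvents when the
#'   references are equimolar); intensities are never rescaled silently.
#' @examples
#' refs <- buildReferenceSet(list(
#'   newSpectrum(400:600, dnorm(400:600, 480, 20), probe = "P", solvent = "t"),
#'   newSpectrum(400:600, dnorm(400:600, 520, 25), probe = "P", solvent = "m")))
#' refs
#' @export
buildReferenceSet <- function(spectra, grid = NULL) {
  if (!length(spectra)) stop("no spectra supplied", call. = FALSE)
  stopifnot(all(vapply(spectra, is, logical(1), "Spectrum")))
  labels <- vapply(spectra, function(s) s@solvent, character(1))
  if (anyDuplicated(labels))
    stop("duplicate solvent labels: ",
         paste(unique(labels[duplicated(labels)]), collapse = ", "),
         call. = FALSE)
  probes <- unique(stats::na.omit(vapply(spectra, function(s) s@probe,
                                         character(1))))
  if (length(probes) > 1L)
    stop("mixed probes in one reference set: ",
         paste(probes, collapse = ", "), call. = FALSE)
  exc <- unique(stats::na.omit(vapply(spectra, function(s) s@excitation,
                                      numeric(1))))
  if (length(exc) > 1L)
    stop("mixed excitation wavelengths in one reference set", call. = FALSE)
  conc <- stats::na.omit(vapply(spectra, function(s) s@concentration,
                                numeric(1)))
  if (length(conc) > 1L &&
      (max(conc) - min(conc)) > 1e-9 * max(conc))
    warning("reference spectra are not equimolar; coefficients will mix ",
            "occupancy with concentration differences", call. = FALSE)
  if (is.null(grid)) {
    lo <- max(vapply(spectra, function(s) min(s@wavelength), numeric(1)))
    hi <- min(vapply(spectra, function(s) max(s@wavelength), numeric(1)))
    if (lo >= hi)
      stop("reference spectra have no common wavelength support",
           call. = FALSE)
    step <- max(vapply(spectra, function(s) min(diff(s@wavelength)),
                       numeric(1)))
    grid <- seq(lo, hi, by = step)
  } else {
    grid <- as.numeric(grid)
  }
  mat <- vapply(spectra, function(s) intensities(resample(s, grid)),
                numeric(length(grid)))
  mat <- pmax(matrix(mat, nrow = length(grid)), 0)
  colnames(mat) <- labels
  new("ReferenceSet", wavelength = grid, intensities = mat, labels = labels,
      probe = if (length(probes)) probes else NA_character_,
      excitation = if (length(exc)) exc else NA_real_)
}

#' Read a reference library described by a JSON/YAML manifest
#'
#' The manifest maps solvent labels to spectrum files plus shared metadata:
#' \preformatted{
#' probe: P
#' excitation: 330
#' concentration: 1e-6
#' spectra:
#'   t: refs/P_toluene.csv
#'   w: refs/P_water.csv
#' }
#'
#' @param manifest Path to a \code{.json}, \code{.yaml} or \code{.yml} file.
#' @param grid Optional explicit grid forwarded to [buildReferenceSet()].
#' @return A [ReferenceSet-class].
#' @export
readReferenceManifest <- function(manifest, grid = NULL) {
  m <- if (grepl("\\.json$", manifest, ignore.case = TRUE)) {
    jsonlite::read_json(manifest, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(manifest)
  }
  if (is.null(m$spectra) || !length(m$spectra))
    stop("manifest has no 'spectra' mapping", call. = FALSE)
  base <- dirname(manifest)
  spectra <- lapply(names(m$spectra), function(lab) {
    path <- as.character(m$spectra[[lab]])
    if (!file.exists(path) && file.exists(file.path(base, path)))
      path <- file.path(base, path)
    if (!file.exists(path))
      stop("reference file not found: ", path, call. = FALSE)
    readSpectrum(path, probe = m$probe %||% NA_character_, solvent = lab,
                 excitation = m$excitation %||% NA_real_,
                 concentration = m$concentration %||% NA_real_)
  })
  buildReferenceSet(spectra, grid = grid)
}

#' Construct a titration series
#'
#' @param concentrations Titrant concentrations (M), strictly ascending.
#' @param spectra List of [Spectrum-class], one per concentration.
#' @return A [TitrationSeries-class].
#' @export
newTitrationSeries <- function(concentrations, spectra) {
  new("TitrationSeries", concentrations = as.numeric(concentrations),
      spectra = spectra)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
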