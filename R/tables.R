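# Packaged photophysical tables for the Prodan (P) / Nile Red (NR) pair in
# the five reference solvents t/d/a/m/w. Shipped as authoritative data: the
# orientation factor, refractive index and spectra behind the tabulated
# Forster radii are not re-derived here.

#' Photophysical data for the probes in the five reference solvents
#'
#' Quantum yield (fraction), fluorescence lifetime (ns, metadata only),
#' emission and absorption maxima (nm) and molar extinction coefficient
#' (M^-1 cm^-1) for Prodan (\code{"P"}) and Nile Red (\code{"NR"}) in
#' toluene, dichloromethane, acetonitrile, methanol and water.
#'
#' @param probe Optional probe id to filter (\code{"P"} or \code{"NR"}).
#' @return data.frame with columns \code{probe}, \code{solvent},
#'   \code{quantum_yield}, \code{tau_ns}, \code{lambda_em_max},
#'   \code{lambda_abs_max}, \code{epsilon}.
#' @examples
#' photophysicsTable("P")$lambda_em_max  # 414 438 456 501 524
#' @export
photophysicsTable <- function(probe = NULL) {
  path <- system.file("extdata", "photophysics_table1.csv",
                      package = "nanopolarity", mustWork = TRUE)
  tab <- utils::read.csv(path, comment.char = "#",
                         stringsAsFactors = FALSE)
  if (!is.null(probe)) {
    tab <- tab[tab$probe %in% probe, , drop = FALSE]
    if (!nrow(tab)) stop("unknown probe: ", probe, call. = FALSE)
  }
  tab
}

#' Forster radii for the Prodan/Nile Red pair across solvent combinations
#'
#' Tabulated R0 (Angstrom) for every combination of donor (Prodan)
#' environment and acceptor (Nile Red) environment among the five reference
#' solvents. Rows index the acceptor solvent, columns the donor solvent.
#'
#' @return 5x5 numeric matrix with dimnames
#'   \code{list(acceptor = t/d/a/m/w, donor = t/d/a/m/w)}.
#' @seealso [forsterRadius0()] for a single lookup.
#' @export
forsterRadiusTable <- function() {
  path <- system.file("extdata", "forster_radii_table2.csv",
                      package = "nanopolarity", mustWork = TRUE)
  tab <- utils::read.csv(path, comment.char = "#", check.names = FALSE)
  m <- as.matrix(tab[, -1])
  rownames(m) <- tab[[1]]
  names(dimnames(m)) <- c("acceptor", "donor")
  m
}

#' Look up a tabulated Forster radius
#'
#' @param donorSolvent Donor (Prodan) environment label, one of t/d/a/m/w.
#' @param acceptorSolvent Acceptor (Nile Red) environment label, same labels.
#' @return R0 in Angstrom.
#' @examples
#' forsterRadius0("t", "t")  # 29.7
#' @export
forsterRadius0 <- function(donorSolvent, acceptorSolvent) {
  m <- forsterRadiusTable()
  if (!donorSolvent %in% colnames(m))
    stop("unknown donor solvent: ", donorSolvent, call. = FALSE)
  if (!acceptorSolvent %in% rownames(m))
    stop("unknown acceptor solvent: ", acceptorSolvent, call. = FALSE)
  unname(m[acceptorSolvent, donorSolvent])
}
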