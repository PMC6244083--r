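#' Deconvolve a spectrum into nonnegative fractions of reference environments
#'
#' Fits a measured emission spectrum as a nonnegative linear combination of
#' pure-solvent reference spectra,
#' \deqn{y(\lambda) = \sum_i c_i S_i(\lambda), \quad c_i \ge 0,}
#' by non-negative least squares. With references recorded at equimolar probe
#' concentration, each coefficient \eqn{c_i} estimates the fraction of
#' emitting dye probing an environment of polarity/proticity matching solvent
#' \eqn{i}, weighted by that environment's brightness.
#'
#' The residual reported is the relative root-mean-square misfit
#' \eqn{\sqrt{\sum_\lambda (y - \hat y)^2 / \sum_\lambda y^2}}, a scale-free
#' fraction directly comparable to a percent threshold.
#'
#' @param sample A [Spectrum-class]; resampled onto the reference grid if its
#'   grid differs (its support must cover the reference grid).
#' @param refs A [ReferenceSet-class].
#' @param conditionLimit Condition number of the reference matrix above which
#'   a \code{"collinear-references"} flag is attached (default \code{1e8}).
#' @param weighting \code{"none"} (default): ordinary nonnegative least
#'   squares, every wavelength weighted equally. \code{"relative"}:
#'   inverse-variance weighting for multiplicative (signal-proportional)
#'   instrument noise — each wavelength is weighted by
#'   \eqn{1/\max(|y|, f\,\max|y|)^2} with floor fraction \code{weightFloor},
#'   the maximum-likelihood weighting when the noise standard deviation is
#'   proportional to the signal. This greatly improves the recovery of weak
#'   components sitting under bright bands; the reported residual is always
#'   the unweighted relative RMS.
#' @param weightFloor Floor for the relative weights as a fraction of the
#'   peak intensity (default 0.05), preventing near-zero-signal wavelengths
#'   from dominating the weighted fit.
#' @return An [UnmixResult-class]. The problem is convex, so the solution is
#'   deterministic (unique up to reference collinearity, which is flagged).
#' @examples
#' refs <- makeReferenceLibrary("P")
#' truth <- c(t = 0.3, d = 0, a = 0, m = 0.7, w = 0)
#' y <- as.numeric(intensities(refs) %*% truth)
#' s <- newSpectrum(wavelengths(refs), y)
#' coefficients(unmix(s, refs))
#' @seealso [selectReferenceSet()], [fitTitration()]
#' @export
unmix <- function(sample, refs, conditionLimit = 1e8,
                  weighting = c("none", "relative"), weightFloor = 0.05) {
  stopifnot(is(sample, "Spectrum"), is(refs, "ReferenceSet"))
  weighting <- match.arg(weighting)
  if (!isTRUE(all.equal(wavelengths(sample), wavelengths(refs))))
    sample <- resample(sample, wavelengths(refs))
  y <- intensities(sample)
  if (all(y == 0))
    stop("all-zero sample spectrum cannot be unmixed", call. = FALSE)
  S <- intensities(refs)
  flags <- character()
  keep <- colSums(S^2) > 0
  if (sum(keep) == 0) stop("all reference spectra are zero", call. = FALSE)
  if (sum(keep) >= 2L && kappa(S[, keep, drop = FALSE], exact = TRUE) >
      conditionLimit)
    flags <- c(flags, "collinear-references")
  cc <- rep(0, ncol(S))
  if (weighting == "relative") {
    sw <- 1 / pmax(abs(y), weightFloor * max(abs(y)))
    fit <- pracma::lsqnonneg(sw * S[, keep, drop = FALSE], sw * y)
  } else {
    fit <- pracma::lsqnonneg(S[, keep, drop = FALSE], y)
  }
  cc[keep] <- fit$x
  names(cc) <- solventLabels(refs)
  yhat <- as.numeric(S %*% cc)
  residual <- sqrt(sum((y - yhat)^2) / sum(y^2))
  new("UnmixResult", coefficients = cc, residual = residual,
      fitted = initialize(sample, intensity = yhat),
      labels = solventLabels(refs), flags = flags)
}

#' @describeIn unmix Coefficients of an [UnmixResult-class], named by solvent.
#' @param object,... For the \code{coefficients} method.
#' @export
setMethod("coefficients", "UnmixResult", function(object, ...)
  object@coefficients)

#' @describeIn unmix Relative RMS residual of an [UnmixResult-class].
#' @export
setMethod("residuals", "UnmixResult", function(object, ...) object@residual)

setMethod("show", "UnmixResult", function(object) {
  cat("UnmixResult: relative RMS residual",
      sprintf("%.3g%%", 100 * object@residual), "\n")
  print(round(object@coefficients, 6))
  if (length(object@flags)) cat("flags:", paste(object@flags, collapse = ", "),
                                "\n")
})

#' Brightness-corrected occupancies from raw unmixing coefficients
#'
#' Raw coefficients weight dye fractions by each environment's brightness
#' (molar extinction at the excitation wavelength times quantum yield, to
#' which the equimolar reference amplitudes are proportional). Dividing by a
#' per-solvent brightness and renormalizing yields relative occupancies.
#' Correction is opt-in; raw coefficients are the primary output.
#'
#' @param result An [UnmixResult-class].
#' @param probe Probe id used to look up brightness in the packaged
#'   photophysics table (epsilon times quantum yield per solvent).
#' @return Named numeric vector of occupancy fractions summing to 1 over the
#'   labels with nonzero brightness-corrected weight.
#' @export
occupancyFractions <- function(result, probe) {
  stopifnot(is(result, "UnmixResult"))
  tab <- photophysicsTable(probe)
  b <- stats::setNames(tab$epsilon * tab$quantum_yield, tab$solvent)
  miss <- setdiff(result@labels, names(b))
  if (length(miss))
    stop("no photophysics record for solvent(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  occ <- result@coefficients / b[result@labels]
  occ / sum(occ)
}

#' Select the minimal reference subset that fits a spectrum
#'
#' Finds the smallest set of reference environments whose nonnegative linear
#' combination fits the sample with relative RMS residual at or below
#' \code{threshold} — the parsimony rule of neither underfitting nor
#' overfitting: too few solvents leave structured residuals, too many add
#' components the data cannot support.
#'
#' For up to 10 candidates all subsets are searched exhaustively and the
#' smallest subset meeting the threshold is returned (ties broken by lower
#' residual). For larger candidate pools a greedy forward selection is used:
#' start empty, at each step add the candidate that most reduces the
#' residual, and stop when the threshold is met or the best gain drops below
#' \code{minGain}. \code{method} overrides the automatic choice.
#'
#' @param sample A [Spectrum-class].
#' @param candidates A [ReferenceSet-class] of candidate references.
#' @param threshold Residual threshold (fraction), default 0.05.
#' @param minGain Minimum residual reduction (fraction) that justifies adding
#'   a solvent in the greedy path; default 0.005 (0.5 percentage points).
#' @param method \code{"auto"}, \code{"exhaustive"} or \code{"greedy"}.
#' @return A list with \code{labels} (selected subset), \code{residual},
#'   \code{thresholdMet} (logical; \code{FALSE} means even the full set
#'   misses the threshold and the full set is returned), and \code{path}
#'   (data.frame of best residual versus subset size: the residual curve).
#' @examples
#' refs <- makeReferenceLibrary("P")
#' mix <- newSpectrum(wavelengths(refs),
#'   0.5 * intensities(refs)[, "t"] + 0.5 * intensities(refs)[, "w"])
#' selectReferenceSet(mix, refs)$labels  # "t" "w"
#' @export
selectReferenceSet <- function(sample, candidates, threshold = 0.05,
                               minGain = 0.005, method = c("auto",
                                                           "exhaustive",
                                                           "greedy")) {
  stopifnot(is(candidates, "ReferenceSet"),
            threshold > 0, threshold < 1)
  method <- match.arg(method)
  labs <- solventLabels(candidates)
  n <- length(labs)
  if (method == "auto") method <- if (n <= 10L) "exhaustive" else "greedy"
  sample <- if (isTRUE(all.equal(wavelengths(sample),
                                 wavelengths(candidates)))) sample
            else resample(sample, wavelengths(candidates))
  subsetResidual <- function(sel) {
    residuals(unmix(sample, referenceSubset(candidates, sel)))
  }

  if (method == "exhaustive") {
    best <- NULL
    path <- data.frame(size = integer(), residual = numeric())
    for (k in seq_len(n)) {
      combos <- utils::combn(labs, k, simplify = FALSE)
      res <- vapply(combos, subsetResidual, numeric(1))
      i <- which.min(res)
      path <- rbind(path, data.frame(size = k, residual = res[i]))
      if (is.null(best) && res[i] <= threshold)
        best <- list(labels = combos[[i]], residual = res[i])
    }
    if (is.null(best))
      return(list(labels = labs, residual = path$residual[n],
                  thresholdMet = FALSE, path = path))
    return(c(best, list(thresholdMet = TRUE,
                        path = path[path$size <= length(best$labels), ,
                                    drop = FALSE])))
  }

  # greedy forward selection
  sel <- character()
  lastRes <- Inf
  path <- data.frame(size = integer(), residual = numeric())
  repeat {
    remaining <- setdiff(labs, sel)
    if (!length(remaining)) break
    res <- vapply(remaining, function(l) subsetResidual(c(sel, l)),
                  numeric(1))
    i <- which.min(res)
    gain <- lastRes - res[i]
    if (length(sel) && lastRes <= threshold) break
    if (length(sel) && gain < minGain) break
    sel <- c(sel, remaining[i])
    lastRes <- res[i]
    path <- rbind(path, data.frame(size = length(sel), residual = lastRes))
    if (lastRes <= threshold) break
  }
  list(labels = labs[labs %in% sel], residual = lastRes,
       thresholdMet = lastRes <= threshold, path = path)
}

#' Subset a reference set by solvent label
#'
#' @param refs A [ReferenceSet-class].
#' @param labels Labels to keep, in reference order.
#' @return A [ReferenceSet-class] restricted to \code{labels}.
#' @export
referenceSubset <- function(refs, labels) {
  stopifnot(is(refs, "ReferenceSet"))
  miss <- setdiff(labels, refs@labels)
  if (length(miss))
    stop("unknown labels: ", paste(miss, collapse = ", "), call. = FALSE)
  keep <- refs@labels %in% labels
  new("ReferenceSet", wavelength = refs@wavelength,
      intensities = refs@intensities[, keep, drop = FALSE],
      labels = refs@labels[keep], probe = refs@probe,
      excitation = refs@excitation)
}

#' Fit every spectrum of a titration and assemble coefficient trajectories
#'
#' Applies [unmix()] to each (not-normalized) spectrum of a titration series
#' and collects per-solvent coefficient trajectories \eqn{c_i(conc)}. Blank
#' (all-zero) spectra yield all-zero coefficients flagged \code{"blank"};
#' any other per-point failure is flagged \code{"fit-failed"} with
#' \code{NA} coefficients, never silently dropped.
#'
#' @param series A [TitrationSeries-class], ordered by titrant concentration.
#' @param refs A [ReferenceSet-class].
#' @param weighting,weightFloor Passed to [unmix()].
#' @return A [CoefficientTrajectories-class].
#' @seealso [componentFretEfficiencies()]
#' @export
fitTitration <- function(series, refs, weighting = c("none", "relative"),
                         weightFloor = 0.05) {
  stopifnot(is(series, "TitrationSeries"), is(refs, "ReferenceSet"))
  weighting <- match.arg(weighting)
  n <- length(series@concentrations)
  k <- length(refs@labels)
  coef <- matrix(NA_real_, n, k, dimnames = list(NULL, refs@labels))
  res <- rep(NA_real_, n)
  flags <- rep("", n)
  for (i in seq_len(n)) {
    s <- series@spectra[[i]]
    if (all(intensities(s) == 0)) {
      coef[i, ] <- 0
      res[i] <- 0
      flags[i] <- "blank"
      next
    }
    fit <- tryCatch(unmix(s, refs, weighting = weighting,
                          weightFloor = weightFloor),
                    error = function(e) e)
    if (inherits(fit, "error")) {
      flags[i] <- "fit-failed"
      next
    }
    coef[i, ] <- coefficients(fit)
    res[i] <- residuals(fit)
    if (length(fit@flags)) flags[i] <- paste(fit@flags, collapse = ";")
  }
  new("CoefficientTrajectories", concentrations = series@concentrations,
      coefficients = coef, residuals = res, labels = refs@labels,
      flags = flags)
}

#' @rdname accessors
#' @export
setMethod("concentrations", "CoefficientTrajectories",
          function(x) x@concentrations)

#' @rdname accessors
#' @export
setMethod("solventLabels", "CoefficientTrajectories", function(x) x@labels)

#' @describeIn fitTitration Coefficient matrix (points x labels).
#' @param object,... For the \code{coefficients} method.
#' @export
setMethod("coefficients", "CoefficientTrajectories",
          function(object, ...) object@coefficients)

setMethod("show", "CoefficientTrajectories", function(object) {
  cat(sprintf("CoefficientTrajectories: %d points x %d components [%s]\n",
              length(object@concentrations), length(object@labels),
              paste(object@labels, collapse = ",")))
})

#' Convert coefficient trajectories to a data.frame
#'
#' One row per titration point: concentration, one column per label, residual
#' and flag.
#'
#' @param x A [CoefficientTrajectories-class].
#' @param ... Unused.
#' @return A data.frame.
#' @export
setMethod("as.data.frame", "CoefficientTrajectories", function(x, ...) {
  out <- data.frame(concentration_M = x@concentrations,
                    x@coefficients, check.names = FALSE)
  out$residual <- x@residuals
  out$flag <- x@flags
  out
})
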