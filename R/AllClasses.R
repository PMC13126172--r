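#' @import methods
NULL

#' Lipid-titration CD binding curve
#'
#' Holds one circular-dichroism lipid titration of a peptide: per-point total
#' lipid concentration, the dilution-corrected total peptide concentration,
#' the mean residue ellipticity at 222 nm and its normalized value (nMRE,
#' peptide-in-buffer baseline = 1).
#'
#' @slot peptideConc numeric(1), initial total peptide concentration (mol/L).
#' @slot points data.frame with columns \code{lipidConc} (mol/L, strictly
#'   increasing), \code{peptideConc} (mol/L, per-point after dilution),
#'   \code{mre222} (deg cm^2/dmol, may be NA) and \code{nmre}.
#' @slot compositionLabel character(1), lipid composition label.
#' @slot nmreMin numeric(1), the buffer baseline of the normalized MRE;
#'   fixed to 1 by the binding model.
#' @slot flags character vector of quality flags.
#' @slot groundTruth list, planted parameters when the curve is synthetic
#'   (empty for experimental data).
#' @exportClass TitrationCurve
setClass("TitrationCurve",
  representation(
    peptideConc = "numeric",
    points = "data.frame",
    compositionLabel = "character",
    nmreMin = "numeric",
    flags = "character",
    groundTruth = "list"
  ),
  prototype(
    compositionLabel = "unspecified",
    nmreMin = 1,
    flags = character(),
    groundTruth = list()
  )
)

setValidity("TitrationCurve", function(object) {
  p <- object@points
  msg <- character()
  need <- c("lipidConc", "peptideConc", "nmre")
  if (!all(need %in% names(p)))
    msg <- c(msg, paste("points must have columns:", paste(need, collapse = ", ")))
  else {
    if (any(p$lipidConc < 0)) msg <- c(msg, "lipidConc must be >= 0")
    if (nrow(p) > 1 && any(diff(p$lipidConc) <= 0))
      msg <- c(msg, "points must be strictly increasing in lipidConc")
    if (any(p$peptideConc <= 0)) msg <- c(msg, "peptideConc must be > 0")
  }
  if (length(object@peptideConc) != 1 || object@peptideConc <= 0)
    msg <- c(msg, "peptideConc must be a positive scalar")
  if (!isTRUE(all.equal(object@nmreMin, 1)))
    msg <- c(msg, "nmreMin is fixed to 1 by the binding model")
  if (length(msg)) msg else TRUE
})

#' Posterior of the binding-isotherm fit
#'
#' Container for the ensemble-MCMC posterior over the modified-Langmuir
#' binding parameters: dissociation constant \code{kd} (mol/L), lipids per
#' peptide \code{nLipids}, saturation value \code{nmreMax} and the Gaussian
#' noise SD \code{noiseSd} treated as a nuisance parameter.
#'
#' @slot samples numeric matrix of post burn-in draws, one column per
#'   parameter (\code{kd}, \code{nLipids}, \code{nmreMax}, \code{noiseSd}).
#' @slot medians named numeric vector of posterior medians.
#' @slot ci68 numeric matrix (2 x p) of central 68\% interval bounds.
#' @slot diagnostics list: \code{acceptance}, \code{nWalkers}, \code{rhat},
#'   \code{converged}, \code{noBinding}, \code{nGenerations}, \code{burnIn}.
#' @exportClass BindingPosterior
setClass("BindingPosterior",
  representation(
    samples = "matrix",
    medians = "numeric",
    ci68 = "matrix",
    diagnostics = "list"
  )
)

setValidity("BindingPosterior", function(object) {
  msg <- character()
  if (nrow(object@samples) > 0) {
    lo <- object@ci68[1, ]
    hi <- object@ci68[2, ]
    m <- object@medians
    if (any(lo > m + 1e-12) || any(hi < m - 1e-12))
      msg <- c(msg, "ci68 must bracket the medians")
  }
  if (length(msg)) msg else TRUE
})

#' 1-D lamellar diffraction pattern
#'
#' A reduced one-dimensional specular diffraction trace: momentum transfer
#' Q (1/Angstrom, along the membrane normal) versus detector counts.
#' Traces recorded in 2-theta are converted on load using the declared
#' wavelength (theta-2theta geometry).
#'
#' @slot q numeric, strictly increasing momentum transfer (1/Angstrom).
#' @slot counts numeric, nonnegative counts per bin.
#' @slot wavelength numeric(1), probe wavelength (Angstrom).
#' @slot metadata list (relative humidity, temperature, sample label, ...).
#' @slot groundTruth list, planted values when synthetic.
#' @exportClass DiffractionPattern
setClass("DiffractionPattern",
  representation(
    q = "numeric",
    counts = "numeric",
    wavelength = "numeric",
    metadata = "list",
    groundTruth = "list"
  ),
  prototype(metadata = list(), groundTruth = list())
)

setValidity("DiffractionPattern", function(object) {
  msg <- character()
  if (length(object@q) != length(object@counts))
    msg <- c(msg, "q and counts must have equal length")
  if (length(object@q) > 1 && any(diff(object@q) <= 0))
    msg <- c(msg, "q must be strictly increasing")
  if (any(object@counts < 0)) msg <- c(msg, "counts must be >= 0")
  if (length(object@wavelength) != 1 || object@wavelength <= 0)
    msg <- c(msg, "wavelength must be a positive scalar")
  if (length(msg)) msg else TRUE
})

#' Lamellar lattice fit
#'
#' Result of regressing Bragg peak positions Q_h on diffraction order h
#' through the origin: the repeat spacing d = 2*pi/slope with its SD,
#' the orders used and the per-peak residuals (1/Angstrom).
#'
#' @slot d numeric(1), repeat spacing (Angstrom).
#' @slot dSd numeric(1), SD of d (Angstrom).
#' @slot orders integer vector of assigned diffraction orders.
#' @slot residuals numeric, per-peak Q residuals (1/Angstrom).
#' @slot peaks data.frame of the peaks used (center, sd, order, ...).
#' @slot flags character vector ("two.lattice.suspected", "no.split.detected",
#'   "degenerate.split", ...).
#' @exportClass LatticeFit
setClass("LatticeFit",
  representation(
    d = "numeric",
    dSd = "numeric",
    orders = "integer",
    residuals = "numeric",
    peaks = "data.frame",
    flags = "character"
  ),
  prototype(flags = character())
)

setValidity("LatticeFit", function(object) {
  if (length(object@d) != 1 || object@d <= 0) "d must be a positive scalar" else TRUE
})

#' Set of lamellar structure factors
#'
#' Bragg amplitudes F(h) on one lattice, unsigned as measured or signed after
#' phasing, with counting-statistics SDs and isotopic-contrast metadata
#' (D2O mole fraction of the hydration water, d7-lipid mole fraction).
#'
#' @slot d numeric(1), repeat spacing (Angstrom).
#' @slot h integer vector of diffraction orders (unique).
#' @slot f numeric, amplitudes (unsigned magnitudes unless \code{signed}).
#' @slot sd numeric, positive SDs on the amplitudes.
#' @slot d2oFraction numeric(1) in [0, 1].
#' @slot d7Fraction numeric(1) in [0, 1].
#' @slot signed logical(1), whether phases (signs) have been assigned.
#' @slot flags character vector ("phase.ambiguous", ...).
#' @exportClass StructureFactorSet
setClass("StructureFactorSet",
  representation(
    d = "numeric",
    h = "integer",
    f = "numeric",
    sd = "numeric",
    d2oFraction = "numeric",
    d7Fraction = "numeric",
    signed = "logical",
    flags = "character"
  ),
  prototype(d2oFraction = 0, d7Fraction = 0, signed = FALSE, flags = character())
)

setValidity("StructureFactorSet", function(object) {
  msg <- character()
  n <- length(object@h)
  if (length(object@f) != n || length(object@sd) != n)
    msg <- c(msg, "h, f and sd must have equal length")
  if (anyDuplicated(object@h)) msg <- c(msg, "h values must be unique")
  if (any(object@h < 1)) msg <- c(msg, "h must be >= 1")
  if (any(object@sd <= 0)) msg <- c(msg, "sd must be > 0")
  if (!object@signed && any(object@f < 0))
    msg <- c(msg, "unsigned amplitudes must be >= 0")
  if (object@d2oFraction < 0 || object@d2oFraction > 1)
    msg <- c(msg, "d2oFraction must lie in [0, 1]")
  if (object@d7Fraction < 0 || object@d7Fraction > 1)
    msg <- c(msg, "d7Fraction must lie in [0, 1]")
  if (length(object@d) != 1 || object@d <= 0) msg <- c(msg, "d must be positive")
  if (length(msg)) msg else TRUE
})

#' Isotopic contrast series of structure-factor sets
#'
#' A list of \linkS4class{StructureFactorSet} objects measured on the same
#' lattice (shared d and order coverage) at different D2O mole fractions
#' and/or d7-lipid label fractions, plus sample-composition metadata.
#'
#' @slot sets list of StructureFactorSet.
#' @slot composition list, e.g. \code{peptidePerLipid}, lipid species.
#' @slot groundTruth list, planted values when synthetic.
#' @exportClass ContrastSeries
setClass("ContrastSeries",
  representation(
    sets = "list",
    composition = "list",
    groundTruth = "list"
  ),
  prototype(composition = list(), groundTruth = list())
)

setValidity("ContrastSeries", function(object) {
  msg <- character()
  if (!length(object@sets)) return("series must contain at least one set")
  if (!all(vapply(object@sets, is, logical(1), "StructureFactorSet")))
    return("all sets must be StructureFactorSet objects")
  ds <- vapply(object@sets, function(s) s@d, numeric(1))
  if (max(ds) - min(ds) > 1e-6 * ds[1])
    msg <- c(msg, "all sets must share the same repeat spacing d")
  hs <- lapply(object@sets, function(s) sort(s@h))
  if (length(unique(lapply(hs, paste, collapse = ","))) != 1)
    msg <- c(msg, "all sets must share identical h coverage")
  if (length(msg)) msg else TRUE
})

#' 1-D scattering-length-density profile
#'
#' A scattering-length density profile rho(z) across one lamellar repeat,
#' z in [-d/2, d/2] centered at the bilayer midplane, built by cosine Fourier
#' synthesis from signed structure factors (mean term omitted, so profiles
#' are relative unless amplitude-calibrated).
#'
#' @slot z numeric grid (Angstrom) on [-d/2, d/2].
#' @slot rho numeric, SLD per length at each z (relative or calibrated units).
#' @slot sdBand numeric, per-z 1-SD uncertainty band.
#' @slot d numeric(1), repeat spacing (Angstrom).
#' @slot hmax integer(1), truncation order of the synthesis.
#' @slot scale character(1), \code{"relative"} or \code{"absolute"}.
#' @slot flags character vector.
#' @exportClass SLDProfile
setClass("SLDProfile",
  representation(
    z = "numeric",
    rho = "numeric",
    sdBand = "numeric",
    d = "numeric",
    hmax = "integer",
    scale = "character",
    flags = "character"
  ),
  prototype(scale = "relative", flags = character())
)

setValidity("SLDProfile", function(object) {
  msg <- character()
  if (length(object@rho) != length(object@z))
    msg <- c(msg, "rho must match z in length")
  if (length(object@sdBand) &&
      length(object@sdBand) != length(object@z))
    msg <- c(msg, "sdBand must match z in length (or be empty)")
  if (!object@scale %in% c("relative", "absolute"))
    msg <- c(msg, "scale must be 'relative' or 'absolute'")
  if (length(object@d) != 1 || object@d <= 0) msg <- c(msg, "d must be positive")
  if (length(msg)) msg else TRUE
})

#' Water-per-peptide accounting result
#'
#' Bound-water bookkeeping from a calibrated deuterium-difference profile:
#' total exchanged scattering length per lipid is converted to exchanged
#' protons, corrected for the peptide's exchangeable protons and the baseline
#' headgroup hydration, and expressed as excess waters per peptide.
#'
#' @slot watersPerPeptide numeric(1).
#' @slot sd numeric(1), propagated SD.
#' @slot inputs list echoing every input (B, x, wL, nExchangeable, r, deltaB).
#' @slot flags character vector ("negative.water", ...).
#' @exportClass WaterQuantification
setClass("WaterQuantification",
  representation(
    watersPerPeptide = "numeric",
    sd = "numeric",
    inputs = "list",
    flags = "character"
  ),
  prototype(flags = character())
)

#' Gaussian-component bilayer model (forward simulator)
#'
#' A lamellar unit cell described by Gaussian components of the SLD profile:
#' mirrored headgroup maxima, a terminal-methyl trough at the center, an
#' inter-bilayer water envelope at the cell boundary (amplitude linear in the
#' D2O fraction x), peptide envelopes and an optional d7-label distribution.
#' Component areas are per lipid; \code{area0} is the x-independent part and
#' \code{areaX} the coefficient of x.
#'
#' @slot d numeric(1), repeat spacing (Angstrom).
#' @slot components data.frame with columns \code{name}, \code{center}
#'   (Angstrom, >= 0; mirrored at -center when \code{pair}), \code{sigma}
#'   (Angstrom), \code{area0}, \code{areaX} (total area of the component,
#'   both mirror halves included), \code{pair} (logical).
#' @slot groundTruth list of the planted quantities.
#' @exportClass BilayerModel
setClass("BilayerModel",
  representation(
    d = "numeric",
    components = "data.frame",
    groundTruth = "list"
  ),
  prototype(groundTruth = list())
)

setValidity("BilayerModel", function(object) {
  msg <- character()
  cp <- object@components
  need <- c("name", "center", "sigma", "area0", "areaX", "pair")
  if (!all(need %in% names(cp)))
    msg <- c(msg, paste("components must have columns:", paste(need, collapse = ", ")))
  else {
    if (any(cp$sigma <= 0)) msg <- c(msg, "component sigma must be > 0")
    if (any(cp$center < 0)) msg <- c(msg, "component center must be >= 0 (pairs are mirrored)")
  }
  if (length(object@d) != 1 || object@d <= 0) msg <- c(msg, "d must be positive")
  if (length(msg)) msg else TRUE
})
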