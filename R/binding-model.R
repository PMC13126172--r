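#' Binding-model parameter set
#'
#' Validated parameter triple of the modified Langmuir lipid-binding model:
#' dissociation constant K_D (mol/L), lipids bound per peptide n, and the
#' saturation value of the normalized mean residue ellipticity, nMRE_max.
#'
#' @param kd numeric(1), dissociation constant (mol/L), >= 0.
#' @param nLipids numeric(1), lipids per bound peptide, > 0.
#' @param nmreMax numeric(1), saturation nMRE, > 1 (the buffer baseline is 1).
#' @return named list of class \code{"bindingParameters"}.
#' @examples
#' bindingParameters(kd = 1.9e-6, nLipids = 25, nmreMax = 13)
#' @export
bindingParameters <- function(kd, nLipids, nmreMax) {
  checkScalar(kd, "kd", 0)
  checkScalar(nLipids, "nLipids", 0, strict = TRUE)
  checkScalar(nmreMax, "nmreMax", 1, strict = TRUE)
  structure(list(kd = kd, nLipids = nLipids, nmreMax = nmreMax),
            class = "bindingParameters")
}

#' Fraction of peptide bound at a given total lipid concentration
#'
#' Inverts the implicit mass-action relation of the modified Langmuir model,
#' C_Lt = n f_b [1 + K_D / (C_pt (1 - f_b))] C_pt,
#' for the bound fraction f_b. Clearing the denominator gives the quadratic
#'   n C_pt f^2 - (n C_pt + n K_D + C_Lt) f + C_Lt = 0,
#' whose smaller root is the physical solution: the product of the roots is
#' C_Lt / (n C_pt) > 0 and their sum exceeds 1 + C_Lt/(n C_pt), so the larger
#' root always exceeds 1 while the smaller lies in [0, 1]. Evaluated in the
#' numerically stable form 2c / (b + sqrt(b^2 - 4ac)).
#'
#' @param cLt numeric, total lipid concentration (mol/L, free + bound),
#'   vectorized.
#' @param cPt numeric(1), total peptide concentration (mol/L), > 0; or a
#'   vector matching \code{cLt} when the peptide is diluted during titration.
#' @param params a \code{\link{bindingParameters}} object.
#' @return numeric, bound fraction(s) in [0, 1].
#' @examples
#' p <- bindingParameters(kd = 2e-6, nLipids = 25, nmreMax = 13)
#' fractionBound(500e-6, 20e-6, p)
#' @export
fractionBound <- function(cLt, cPt, params) {
  if (any(!is.finite(cLt)) || any(cLt < 0))
    stop("'cLt' must be finite and >= 0", call. = FALSE)
  if (any(!is.finite(cPt)) || any(cPt <= 0))
    stop("'cPt' must be finite and > 0", call. = FALSE)
  n <- params$nLipids
  kd <- params$kd
  a <- n * cPt
  b <- n * cPt + n * kd + cLt
  disc <- pmax(0, b * b - 4 * a * cLt)
  f <- 2 * cLt / (b + sqrt(disc))
  pmin(1, pmax(0, f))
}

#' Normalized MRE predicted from the bound fraction
#'
#' The bound fraction is linearly related to the normalized mean residue
#' ellipticity: f_b = (nMRE - nMRE_min) / (nMRE_max - nMRE_min) with
#' nMRE_min = 1; this is that relation inverted.
#'
#' @param fb numeric, bound fraction(s) in [0, 1].
#' @param params a \code{\link{bindingParameters}} object.
#' @return numeric, predicted nMRE = 1 + fb * (nmreMax - 1).
#' @export
predictNMRE <- function(fb, params) {
  if (any(!is.finite(fb)) || any(fb < 0) || any(fb > 1))
    stop("'fb' must lie in [0, 1]", call. = FALSE)
  1 + fb * (params$nmreMax - 1)
}

#' Mean residue ellipticity from raw ellipticity in millidegrees
#'
#' Standard CD conversion: MRE = theta / (10 * l * c * N) with the path
#' length l in cm, molar concentration c in mol/L and N residues.
#'
#' @param thetaMdeg numeric, ellipticity (millidegrees), vectorized.
#' @param pathLength numeric(1), cuvette path length (cm), > 0.
#' @param conc numeric(1) or vector, peptide concentration (mol/L), > 0.
#' @param nResidues numeric(1), number of residues, > 0.
#' @return numeric, MRE (deg cm^2/dmol).
#' @examples
#' mreFromMillidegrees(-100, 0.1, 20e-6, 25)  # -2e5 deg cm^2/dmol
#' @export
mreFromMillidegrees <- function(thetaMdeg, pathLength, conc, nResidues) {
  checkScalar(pathLength, "pathLength", 0, strict = TRUE)
  if (any(conc <= 0)) stop("'conc' must be > 0", call. = FALSE)
  checkScalar(nResidues, "nResidues", 0, strict = TRUE)
  thetaMdeg / (10 * pathLength * conc * nResidues)
}

#' Percent alpha-helicity from the 222 nm MRE
#'
#' Two-state estimate between a random-coil baseline and a chain-length
#' corrected full-helix limit, clipped to [0, 100]. Default baselines are
#' mre_helix = -40000 (1 - 2.5/N) + 100 T and mre_coil = 640 - 45 T with T
#' in degrees Celsius; both can be overridden.
#'
#' @param mre222 numeric, MRE at 222 nm (deg cm^2/dmol), vectorized.
#' @param nResidues numeric(1), residues in the peptide.
#' @param temperature numeric(1), degrees Celsius (default 25).
#' @param mreHelix,mreCoil numeric(1) overrides of the baselines.
#' @return numeric, percent helicity in [0, 100].
#' @export
percentHelicity <- function(mre222, nResidues, temperature = 25,
                            mreHelix = NULL, mreCoil = NULL) {
  checkScalar(nResidues, "nResidues", 1)
  mreHelix <- mreHelix %||% (-40000 * (1 - 2.5 / nResidues) + 100 * temperature)
  mreCoil <- mreCoil %||% (640 - 45 * temperature)
  if (isTRUE(all.equal(mreHelix, mreCoil)))
    stop("degenerate baselines: mreHelix equals mreCoil", call. = FALSE)
  pmin(100, pmax(0, 100 * (mre222 - mreCoil) / (mreHelix - mreCoil)))
}

#' Dilution schedule of a stepwise titration
#'
#' Cumulative-volume bookkeeping for an automatic titrator: starting from
#' \code{initialVolume} of peptide solution, successive additions of titrant
#' dilute the peptide by V0 / (V0 + v_cum) and set the total lipid
#' concentration to C_titrant * v_cum / (V0 + v_cum).
#'
#' @param initialVolume numeric(1), starting sample volume (any volume unit).
#' @param stepVolumes numeric, titrant volume added at each step (same unit);
#'   the pre-addition point (zero lipid) is prepended automatically.
#' @return data.frame with columns \code{addedVolume}, \code{dilutionFactor}
#'   (peptide), \code{lipidFactor} (multiply by the titrant lipid
#'   concentration to get C_Lt).
#' @examples
#' sch <- dilutionSchedule(300, rep(10, 20))
#' tail(sch, 1)  # final peptide dilution factor 300/500 = 0.6
#' @export
dilutionSchedule <- function(initialVolume, stepVolumes) {
  checkScalar(initialVolume, "initialVolume", 0, strict = TRUE)
  if (any(stepVolumes < 0)) stop("'stepVolumes' must be >= 0", call. = FALSE)
  vcum <- c(0, cumsum(stepVolumes))
  data.frame(
    addedVolume = vcum,
    dilutionFactor = initialVolume / (initialVolume + vcum),
    lipidFactor = vcum / (initialVolume + vcum)
  )
}

#' Normalize a raw titration to a TitrationCurve
#'
#' Applies cumulative dilution correction to the peptide and lipid
#' concentrations, converts raw millidegree readings to MRE when requested,
#' and normalizes the 222 nm signal to the peptide-in-buffer reference so
#' that the zero-lipid point sits at nMRE = 1 within noise.
#'
#' @param raw numeric vector of per-step 222 nm readings, one per schedule
#'   row (first = zero lipid). Interpreted as MRE (deg cm^2/dmol) unless
#'   \code{millidegrees = TRUE}.
#' @param bufferMre222 numeric(1), MRE of the peptide in buffer (nonzero).
#' @param peptideConc numeric(1), initial peptide concentration (mol/L).
#' @param titrantLipidConc numeric(1), lipid concentration of the titrant
#'   (mol/L).
#' @param schedule data.frame from \code{\link{dilutionSchedule}} with
#'   \code{nrow(schedule) == length(raw)}.
#' @param millidegrees logical(1); if TRUE, \code{raw} is in millidegrees and
#'   is converted per point with the dilution-corrected concentration.
#' @param pathLength,nResidues conversion inputs used when
#'   \code{millidegrees = TRUE}.
#' @param compositionLabel character(1) label for the lipid composition.
#' @return a \linkS4class{TitrationCurve}. An opposite-sign buffer reference
#'   sets the flag \code{"buffer.sign.mismatch"}; a zero-lipid point far from
#'   nMRE = 1 sets \code{"baseline.offset"}.
#' @export
normalizeCurve <- function(raw, bufferMre222, peptideConc, titrantLipidConc,
                           schedule, millidegrees = FALSE, pathLength = 0.1,
                           nResidues = 25, compositionLabel = "unspecified") {
  checkScalar(bufferMre222, "bufferMre222")
  if (bufferMre222 == 0) stop("'bufferMre222' must be nonzero", call. = FALSE)
  checkScalar(peptideConc, "peptideConc", 0, strict = TRUE)
  checkScalar(titrantLipidConc, "titrantLipidConc", 0, strict = TRUE)
  if (nrow(schedule) != length(raw))
    stop("schedule must have one row per raw reading", call. = FALSE)

  pepConc <- peptideConc * schedule$dilutionFactor
  lipConc <- titrantLipidConc * schedule$lipidFactor
  mre <- if (millidegrees)
    mreFromMillidegrees(raw, pathLength, pepConc, nResidues) else raw
  nmre <- mre / bufferMre222

  fl <- character()
  if (sign(bufferMre222) != sign(stats::median(mre[mre != 0])))
    fl <- c(fl, "buffer.sign.mismatch")
  if (abs(nmre[1] - 1) > 0.2) fl <- c(fl, "baseline.offset")

  ## drop the zero-lipid reference point from the fit table only if lipid
  ## concentrations fail strict monotonicity; otherwise keep all points
  ord <- order(lipConc)
  keep <- ord[c(TRUE, diff(lipConc[ord]) > 0)]
  new("TitrationCurve",
      peptideConc = peptideConc,
      points = data.frame(lipidConc = lipConc[keep],
                          peptideConc = pepConc[keep],
                          mre222 = mre[keep], nmre = nmre[keep]),
      compositionLabel = compositionLabel,
      nmreMin = 1, flags = fl, groundTruth = list())
}

#' Read titration CD spectra from CSV
#'
#' Expects a header row \code{wavelength_nm} followed by one column per
#' titration step, values in millidegrees.
#'
#' @param path CSV file path.
#' @return list with \code{wavelength} (numeric) and \code{steps} (matrix,
#'   wavelengths x steps, millidegrees).
#' @export
readTitrationSpectra <- function(path) {
  x <- utils::read.csv(path, check.names = FALSE)
  if (names(x)[1] != "wavelength_nm")
    stop("first column must be 'wavelength_nm'", call. = FALSE)
  list(wavelength = x[[1]],
       steps = as.matrix(x[, -1, drop = FALSE]))
}

#' Extract a single wavelength channel from titration spectra
#'
#' @param spectra list from \code{\link{readTitrationSpectra}}.
#' @param wavelength numeric(1), target wavelength (nm); the nearest measured
#'   wavelength is used. Default 222 nm.
#' @param smoothSd numeric(1), optional Gaussian smoothing SD in nm applied
#'   along wavelength before extraction; 0 (default) disables smoothing.
#'   Smoothing is cosmetic and is never applied before fitting by the
#'   pipeline.
#' @return numeric vector, one value per titration step (millidegrees).
#' @export
extractChannel <- function(spectra, wavelength = 222, smoothSd = 0) {
  w <- spectra$wavelength
  m <- spectra$steps
  if (smoothSd > 0) {
    kern <- function(center) {
      k <- stats::dnorm(w, center, smoothSd)
      k / sum(k)
    }
    m <- apply(m, 2, function(col)
      vapply(seq_along(w), function(i) sum(kern(w[i]) * col), numeric(1)))
  }
  i <- which.min(abs(w - wavelength))
  as.numeric(m[i, ])
}
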