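## Forward simulators: every input the analysis modules consume can be
## generated from planted ground truth, and every generator records the
## planted values in the object's groundTruth audit list.

#' Build a Gaussian-component bilayer model
#'
#' Constructs a lamellar unit cell from mirrored Gaussian components, loosely
#' shaped on a fluid phosphatidylcholine bilayer: headgroup maxima near
#' +/-20 Angstrom, a terminal-methyl trough at the center, an inter-bilayer
#' water envelope wrapped at the cell boundary whose amplitude is linear in
#' the D2O fraction, a peptide envelope, the peptide's exchangeable-proton
#' envelope (co-located with the water envelope by default - the accounting
#' uses only its total area), and an optional d7 acyl-label distribution.
#' The shapes are simulation fixtures for closed-loop validation, not claims
#' about any particular peptide. Component areas are scattering length per
#' lipid (Angstrom).
#'
#' @param d numeric(1), repeat spacing (Angstrom, default 54.9).
#' @param peptidePerLipid numeric(1), peptides per lipid r (default 1/25).
#' @param watersPerLipid numeric(1), baseline headgroup hydration
#'   (default 9.4).
#' @param watersPerPeptide numeric(1), planted excess waters per peptide
#'   (default 114).
#' @param nExchangeable numeric(1), exchangeable protons per peptide
#'   (default 57).
#' @param d7Fraction numeric(1) in [0, 1], mole fraction of d7-labeled lipid
#'   (7 deuterons each; default 0).
#' @param deltaB numeric(1), b_2H - b_H per proton (Angstrom,
#'   default 1.041e-4).
#' @param bWater numeric(1), x-independent scattering length of one water
#'   (Angstrom, default -1.68e-5: one O and two H).
#' @param headgroupCenter,headgroupSigma,headgroupArea headgroup pair shape.
#' @param methylSigma,methylArea central methyl-trough shape.
#' @param waterSigma numeric(1), water envelope SD (Angstrom, default 4.5).
#' @param peptideCenter,peptideSigma,peptideArea fixed (non-exchangeable)
#'   peptide envelope shape; area is per peptide and scaled by r.
#' @param labelCenter,labelFwhm d7 label distribution (mirrored pair;
#'   defaults 1.87 and 15 Angstrom).
#' @param components optional data.frame overriding the assembled component
#'   table entirely (columns name, center, sigma, area0, areaX, pair).
#' @return a \linkS4class{BilayerModel} with a full ground-truth audit list.
#' @export
bilayerModel <- function(d = 54.9, peptidePerLipid = 1 / 25,
                         watersPerLipid = 9.4, watersPerPeptide = 114,
                         nExchangeable = 57, d7Fraction = 0,
                         deltaB = 1.041e-4, bWater = -1.68e-5,
                         headgroupCenter = 20, headgroupSigma = 3,
                         headgroupArea = 6e-4,
                         methylSigma = 3, methylArea = -3e-4,
                         waterSigma = 4.5,
                         peptideCenter = 10, peptideSigma = 6,
                         peptideArea = 1.5e-2,
                         labelCenter = 1.87, labelFwhm = 15,
                         components = NULL) {
  r <- peptidePerLipid
  if (is.null(components)) {
    wTot <- watersPerLipid + watersPerPeptide * r
    components <- data.frame(
      name = c("headgroup", "methyl", "peptide", "water", "peptideExchange",
               "d7label"),
      center = c(headgroupCenter, 0, peptideCenter, d / 2, d / 2, labelCenter),
      sigma = c(headgroupSigma, methylSigma, peptideSigma, waterSigma,
                waterSigma, labelFwhm / 2.3548),
      area0 = c(headgroupArea, methylArea, peptideArea * r,
                wTot * bWater, 0, d7Fraction * 7 * deltaB),
      areaX = c(0, 0, 0, wTot * 2 * deltaB, nExchangeable * r * deltaB, 0),
      pair = c(TRUE, FALSE, TRUE, TRUE, TRUE, TRUE))
    components <- components[components$area0 != 0 | components$areaX != 0, ]
  }
  new("BilayerModel", d = d, components = components,
      groundTruth = list(d = d, peptidePerLipid = r,
                         watersPerLipid = watersPerLipid,
                         watersPerPeptide = watersPerPeptide,
                         nExchangeable = nExchangeable,
                         d7Fraction = d7Fraction, deltaB = deltaB,
                         labelCenter = labelCenter, labelFwhm = labelFwhm))
}

#' Closed-form signed structure factors of a bilayer model
#'
#' F(h) = sum over components a_c(x) cos(2 pi h z_c / d)
#' exp(-2 pi^2 h^2 sigma_c^2 / d^2) with a_c(x) = area0 + x * areaX - the
#' exact cosine transform of the symmetric Gaussian components. These exact
#' values anchor the Fourier-synthesis oracle.
#'
#' @param model a \linkS4class{BilayerModel}.
#' @param hmax integer, highest order (default 5).
#' @param x numeric(1), D2O fraction (default 0).
#' @return a signed \linkS4class{StructureFactorSet} with (near-)zero SDs.
#' @export
forwardStructureFactors <- function(model, hmax = 5, x = 0) {
  stopifnot(is(model, "BilayerModel"))
  cp <- model@components
  hs <- seq_len(hmax)
  area <- cp$area0 + x * cp$areaX
  fh <- componentStructureFactors(cp$center, cp$sigma, area, model@d, hs)
  d7 <- model@groundTruth$d7Fraction %||% 0
  new("StructureFactorSet", d = model@d, h = hs, f = fh,
      sd = rep(1e-12, hmax), d2oFraction = x, d7Fraction = d7,
      signed = TRUE)
}

#' Generate a synthetic CD titration curve
#'
#' Forward-simulates an nMRE-vs-lipid titration under the modified Langmuir
#' model with the stepwise-dilution schedule of an automatic titrator
#' (default: 300 uL of 20 umol/L peptide titrated with 20 additions of 10 uL
#' of 3 mmol/L vesicles, spanning peptide-to-lipid ratios 1:5 to 1:100), and
#' adds Gaussian noise to the nMRE values.
#'
#' @param truth a \code{\link{bindingParameters}} object (planted K_D, n,
#'   nMRE_max).
#' @param peptideConc numeric(1), initial peptide concentration (mol/L,
#'   default 20e-6).
#' @param titrantLipidConc numeric(1), titrant lipid concentration (mol/L,
#'   default 3e-3).
#' @param initialVolume,stepVolumes titration schedule (defaults 300 and
#'   rep(10, 20); arbitrary volume units).
#' @param noiseSd numeric(1), Gaussian noise SD in nMRE units (default 0.3).
#' @param seed integer seed; the curve is bit-reproducible given a seed.
#' @param compositionLabel character label.
#' @return a \linkS4class{TitrationCurve} whose groundTruth records every
#'   planted value.
#' @export
generateTitration <- function(truth, peptideConc = 20e-6,
                              titrantLipidConc = 3e-3, initialVolume = 300,
                              stepVolumes = rep(10, 20), noiseSd = 0.3,
                              seed = 1, compositionLabel = "synthetic") {
  stopifnot(inherits(truth, "bindingParameters"))
  if (length(stepVolumes) < 6)
    stop("schedule must cover >= 6 points", call. = FALSE)
  sch <- dilutionSchedule(initialVolume, stepVolumes)
  cPt <- peptideConc * sch$dilutionFactor
  cLt <- titrantLipidConc * sch$lipidFactor
  fb <- fractionBound(cLt, cPt, truth)
  nmreTrue <- predictNMRE(fb, truth)
  set.seed(seed)
  nmre <- nmreTrue + stats::rnorm(length(nmreTrue), 0, noiseSd)
  new("TitrationCurve",
      peptideConc = peptideConc,
      points = data.frame(lipidConc = cLt, peptideConc = cPt,
                          mre222 = NA_real_, nmre = nmre),
      compositionLabel = compositionLabel, nmreMin = 1,
      flags = character(),
      groundTruth = list(kd = truth$kd, nLipids = truth$nLipids,
                         nmreMax = truth$nmreMax, noiseSd = noiseSd,
                         seed = seed, nmreTrue = nmreTrue))
}

#' Render a 1-D diffraction pattern from signed structure factors
#'
#' intensity(Q) proportional to a flat background plus
#' sum_h |F(h)|^2 Gaussian(Q; 2 pi h / d, fwhm), scaled to the requested
#' total counts and Poisson-sampled per bin.
#'
#' @param set a \linkS4class{StructureFactorSet}.
#' @param wavelength numeric(1), probe wavelength (Angstrom, default 5).
#' @param peakFwhmQ numeric(1), instrumental peak FWHM in 1/Angstrom
#'   (default 0.005).
#' @param backgroundFraction numeric(1) in [0, 1), fraction of total counts
#'   in a flat background (default 0.1).
#' @param totalCounts numeric(1), expected total counts (default 1e6).
#' @param nBins integer, bins (default 2000).
#' @param qRange numeric(2), abscissa range; default 0.3 x first order to
#'   1.15 x last order.
#' @param seed integer seed, or NULL for the infinite-counts limit (expected
#'   counts, no Poisson sampling).
#' @return a \linkS4class{DiffractionPattern} with groundTruth recording the
#'   planted d and |F(h)|.
#' @export
renderPattern <- function(set, wavelength = 5, peakFwhmQ = 0.005,
                          backgroundFraction = 0.1, totalCounts = 1e6,
                          nBins = 2000, qRange = NULL, seed = 1) {
  stopifnot(is(set, "StructureFactorSet"))
  checkScalar(peakFwhmQ, "peakFwhmQ", 0, strict = TRUE)
  checkScalar(totalCounts, "totalCounts", 0, strict = TRUE)
  d <- set@d
  qh <- 2 * pi * set@h / d
  if (is.null(qRange)) qRange <- c(0.3 * min(qh), 1.15 * max(qh))
  q <- seq(qRange[1], qRange[2], length.out = nBins)
  sig <- peakFwhmQ / 2.3548
  peakPart <- numeric(nBins)
  for (i in seq_along(qh))
    peakPart <- peakPart + set@f[i]^2 * exp(-(q - qh[i])^2 / (2 * sig^2))
  tot <- sum(peakPart)
  if (tot <= 0) {
    intensity <- rep(totalCounts / nBins, nBins)
  } else {
    intensity <- totalCounts * ((1 - backgroundFraction) * peakPart / tot +
                                  backgroundFraction / nBins)
  }
  counts <- if (is.null(seed)) intensity else {
    set.seed(seed)
    stats::rpois(nBins, intensity)
  }
  new("DiffractionPattern", q = q, counts = as.numeric(counts),
      wavelength = wavelength,
      metadata = list(peakFwhmQ = peakFwhmQ),
      groundTruth = list(d = d, h = set@h, absF = abs(set@f),
                         peakFwhmQ = peakFwhmQ, seed = seed,
                         backgroundFraction = backgroundFraction,
                         totalCounts = totalCounts))
}

#' Generate an isotopic contrast series with planted ground truth
#'
#' Computes exact signed structure factors of the model at each D2O
#' fraction, applies an arbitrary instrument scale, adds relative Gaussian
#' noise with a floor, and strips the signs (the pipeline must recover them
#' by contrast phasing). True signs are logged to the ground-truth audit.
#'
#' @param model a \linkS4class{BilayerModel}.
#' @param xList numeric vector of D2O fractions (default c(0, 0.5, 1)).
#' @param hmax integer, orders 1..hmax (default 5).
#' @param relSd numeric(1), relative noise SD on |F| (default 0.05).
#' @param sdFloorFraction numeric(1), SD floor as a fraction of the largest
#'   |F| in each set (default 0.005).
#' @param instrumentScale numeric(1), arbitrary amplitude scale (default 1).
#' @param seed integer seed.
#' @param composition list of composition metadata.
#' @return a \linkS4class{ContrastSeries} of unsigned sets.
#' @export
generateContrastSeries <- function(model, xList = c(0, 0.5, 1), hmax = 5,
                                   relSd = 0.05, sdFloorFraction = 0.005,
                                   instrumentScale = 1, seed = 1,
                                   composition = list()) {
  set.seed(seed)
  trueSigns <- matrix(NA_real_, hmax, length(xList))
  sets <- vector("list", length(xList))
  for (j in seq_along(xList)) {
    sf <- forwardStructureFactors(model, hmax = hmax, x = xList[j])
    fTrue <- sf@f * instrumentScale
    trueSigns[, j] <- sign(fTrue)
    sdv <- pmax(relSd * abs(fTrue), sdFloorFraction * max(abs(fTrue)))
    fObs <- abs(fTrue + stats::rnorm(hmax, 0, sdv))
    sets[[j]] <- new("StructureFactorSet", d = model@d,
                     h = seq_len(hmax), f = fObs, sd = sdv,
                     d2oFraction = xList[j],
                     d7Fraction = model@groundTruth$d7Fraction %||% 0,
                     signed = FALSE)
  }
  new("ContrastSeries", sets = sets,
      composition = utils::modifyList(
        list(peptidePerLipid = model@groundTruth$peptidePerLipid), composition),
      groundTruth = list(model = model, instrumentScale = instrumentScale,
                         trueSigns = trueSigns, xList = xList,
                         relSd = relSd, seed = seed))
}

#' Generate a superposition of two lamellar lattices
#'
#' Renders two lattices from the default bilayer model at repeat spacings d1
#' and d2, mixes their intensities with the given weight for the second
#' lattice, and Poisson-samples the sum. Planted spacings are logged.
#'
#' @param d1,d2 numeric(1), repeat spacings (Angstrom).
#' @param weight numeric(1) in [0, 1], intensity weight of the d2 lattice
#'   (0.5 = equal weights; 0 reduces to a single lattice).
#' @param hmax integer, orders per lattice (default 5).
#' @param wavelength,peakFwhmQ,backgroundFraction,totalCounts,nBins,seed
#'   rendering settings as in \code{\link{renderPattern}}.
#' @return a \linkS4class{DiffractionPattern}.
#' @export
generateTwoPhasePattern <- function(d1, d2, weight = 0.5, hmax = 5,
                                    wavelength = 5, peakFwhmQ = 0.005,
                                    backgroundFraction = 0.1,
                                    totalCounts = 2e6, nBins = 2500,
                                    seed = 1) {
  if (weight < 0 || weight > 1) stop("'weight' must lie in [0, 1]", call. = FALSE)
  m1 <- bilayerModel(d = d1)
  m2 <- bilayerModel(d = d2)
  s1 <- forwardStructureFactors(m1, hmax = hmax)
  s2 <- forwardStructureFactors(m2, hmax = hmax)
  qmax <- 1.15 * max(2 * pi * hmax / d1, 2 * pi * hmax / d2)
  qmin <- 0.3 * min(2 * pi / d1, 2 * pi / d2)
  q <- seq(qmin, qmax, length.out = nBins)
  sig <- peakFwhmQ / 2.3548
  part <- function(s, d) {
    out <- numeric(nBins)
    for (i in seq_along(s@h))
      out <- out + s@f[i]^2 * exp(-(q - 2 * pi * s@h[i] / d)^2 / (2 * sig^2))
    out / max(sum(out), .Machine$double.xmin)
  }
  mix <- (1 - weight) * part(s1, d1) + weight * part(s2, d2)
  intensity <- totalCounts * ((1 - backgroundFraction) * mix / sum(mix) +
                                backgroundFraction / nBins)
  set.seed(seed)
  counts <- stats::rpois(nBins, intensity)
  new("DiffractionPattern", q = q, counts = as.numeric(counts),
      wavelength = wavelength, metadata = list(peakFwhmQ = peakFwhmQ),
      groundTruth = list(d1 = d1, d2 = d2, weight = weight, seed = seed))
}

#' Generate synthetic hydration-shell coordinate frames
#'
#' Places "water" points on spherical shells at planted radii around a
#' solute point set (a single point at the origin by default), with uniform
#' angular coverage and Gaussian radial jitter. Counts per shell are logged
#' to the ground-truth audit.
#'
#' @param shellRadii numeric, increasing shell radii (Angstrom).
#' @param shellCounts integer, waters per shell (same length).
#' @param jitter numeric(1), radial Gaussian SD (Angstrom, default 0.1).
#' @param nFrames integer, number of frames (default 5).
#' @param nBulk integer, additional uniformly distributed waters within
#'   \code{bulkRadius} (default 0).
#' @param bulkRadius numeric(1), radius of the bulk region (default
#'   3 x the largest shell radius).
#' @param solute numeric matrix (n x 3) of solute coordinates; default a
#'   single point at the origin.
#' @param seed integer seed.
#' @return list with \code{frames} (list of lists with \code{solute} and
#'   \code{water} coordinate matrices) and \code{groundTruth}.
#' @export
generateHydrationFrames <- function(shellRadii, shellCounts, jitter = 0.1,
                                    nFrames = 5, nBulk = 0,
                                    bulkRadius = NULL, solute = NULL,
                                    seed = 1) {
  if (length(shellRadii) != length(shellCounts))
    stop("shellRadii and shellCounts must have equal length", call. = FALSE)
  if (any(diff(shellRadii) <= 0))
    stop("shellRadii must be strictly increasing", call. = FALSE)
  if (is.null(solute)) solute <- matrix(0, 1, 3)
  if (is.null(bulkRadius)) bulkRadius <- 3 * max(shellRadii)
  set.seed(seed)
  randomDirections <- function(n) {
    u <- stats::runif(n, -1, 1)
    phi <- stats::runif(n, 0, 2 * pi)
    s <- sqrt(1 - u^2)
    cbind(s * cos(phi), s * sin(phi), u)
  }
  frames <- lapply(seq_len(nFrames), function(f) {
    pts <- do.call(rbind, lapply(seq_along(shellRadii), function(k) {
      r <- shellRadii[k] + stats::rnorm(shellCounts[k], 0, jitter)
      randomDirections(shellCounts[k]) * abs(r)
    }))
    if (nBulk > 0) {
      rb <- bulkRadius * stats::runif(nBulk)^(1 / 3)
      pts <- rbind(pts, randomDirections(nBulk) * rb)
    }
    list(solute = solute, water = pts, frameId = f)
  })
  list(frames = frames,
       groundTruth = list(shellRadii = shellRadii, shellCounts = shellCounts,
                          jitter = jitter, nFrames = nFrames, nBulk = nBulk,
                          bulkRadius = bulkRadius, seed = seed))
}
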