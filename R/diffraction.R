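#' Momentum transfer from the scattering half-angle
#'
#' Specular (theta-2theta) geometry: Q = 4 pi sin(theta) / lambda.
#'
#' @param theta numeric, incidence angle theta in degrees (0 <= theta < 90);
#'   note this is half the detector angle 2-theta.
#' @param wavelength numeric(1), probe wavelength (Angstrom).
#' @return numeric, Q in 1/Angstrom.
#' @examples
#' qFromTheta(0.804, 1.54)  # ~ 2*pi/54.9
#' @export
qFromTheta <- function(theta, wavelength) {
  if (any(theta < 0) || any(theta >= 90))
    stop("'theta' must lie in [0, 90) degrees", call. = FALSE)
  checkScalar(wavelength, "wavelength", 0, strict = TRUE)
  4 * pi * sin(theta * pi / 180) / wavelength
}

#' @rdname qFromTheta
#' @param q numeric, momentum transfer (1/Angstrom).
#' @return \code{thetaFromQ}: theta in degrees.
#' @export
thetaFromQ <- function(q, wavelength) {
  s <- q * wavelength / (4 * pi)
  if (any(s < 0) || any(s > 1)) stop("q out of range for this wavelength", call. = FALSE)
  asin(s) * 180 / pi
}

#' Construct a DiffractionPattern
#'
#' @param abscissa numeric, strictly increasing Q (1/Angstrom) or 2-theta
#'   (degrees) values.
#' @param counts numeric, nonnegative counts per bin.
#' @param wavelength numeric(1), wavelength in Angstrom (1.54 for a Cu X-ray
#'   tube, 5.0 for cold neutrons; any positive value accepted).
#' @param units character(1), \code{"q"} or \code{"twotheta"}; 2-theta input
#'   is converted to Q on construction (theta = 2theta / 2).
#' @param metadata list of free-form metadata.
#' @return a \linkS4class{DiffractionPattern}.
#' @export
diffractionPattern <- function(abscissa, counts, wavelength,
                               units = c("q", "twotheta"), metadata = list()) {
  units <- match.arg(units)
  q <- if (units == "twotheta") qFromTheta(abscissa / 2, wavelength) else abscissa
  new("DiffractionPattern", q = q, counts = counts,
      wavelength = wavelength, metadata = metadata)
}

## prominence of local maximum i among counts y (standard topographic def.)
peakProminence <- function(y, i) {
  h <- y[i]
  left <- if (i > 1) y[seq_len(i - 1)] else numeric(0)
  right <- if (i < length(y)) y[(i + 1):length(y)] else numeric(0)
  minSide <- function(v) {
    ## walk outward until a higher point; the key col is the min before it
    higher <- which(v > h)
    if (length(higher)) min(v[seq_len(max(higher))]) else min(c(v, h))
  }
  lm <- if (length(left)) minSide(rev(left)) else h
  rm <- if (length(right)) minSide(right) else h
  h - max(lm, rm)
}

## residual function for a sum-of-Gaussians + linear background model
gaussLinResiduals <- function(par, q, y, w, k) {
  mu <- par[seq_len(k)]
  sig <- exp(par[k + seq_len(k)])
  amp <- exp(par[2 * k + seq_len(k)])
  b0 <- par[3 * k + 1]; b1 <- par[3 * k + 2]
  model <- b0 + b1 * (q - mean(q))
  for (j in seq_len(k)) model <- model + amp[j] * exp(-(q - mu[j])^2 / (2 * sig[j]^2))
  (model - y) * w
}

#' Detect and refine Bragg peaks in a 1-D pattern
#'
#' Selects local maxima by topographic prominence above the counting-noise
#' floor, groups nearby maxima, and refines each group by a Levenberg-
#' Marquardt least-squares fit of a sum of Gaussians plus a linear background
#' (residuals weighted by Poisson counting SDs). Peaks closer than one fitted
#' FWHM are merged (the stronger is kept).
#'
#' @param pattern a \linkS4class{DiffractionPattern} with >= 50 bins.
#' @param minProminence numeric(1), minimum prominence in counts; default
#'   8x the noise scale (MAD-based, with the Poisson sqrt(floor) as a lower
#'   bound). In addition, when clear peaks exist, candidates below 2\% of
#'   the largest prominence are dropped, and refined peaks must rise at
#'   least 4 counting SDs above their local background.
#' @param maxPeaks integer, keep at most this many most-prominent maxima
#'   before refinement (default 20).
#' @param windowFactor numeric(1), half-width of each fit window in units of
#'   the rough FWHM (default 3).
#' @return data.frame of refined peaks sorted by center: columns
#'   \code{center}, \code{centerSd}, \code{height}, \code{fwhm},
#'   \code{fwhmSd}, \code{area}, \code{areaSd} (area in counts, summed bin
#'   counts equivalent). Zero rows when nothing rises above the noise floor.
#' @export
detectPeaks <- function(pattern, minProminence = NULL, maxPeaks = 20,
                        windowFactor = 3) {
  stopifnot(is(pattern, "DiffractionPattern"))
  q <- pattern@q; y <- pattern@counts
  n <- length(q)
  if (n < 50) stop("pattern must have >= 50 bins", call. = FALSE)
  floorLevel <- stats::median(y)
  noiseScale <- max(stats::mad(y), sqrt(max(floorLevel, 1)), 1)
  if (is.null(minProminence)) minProminence <- 10 * noiseScale

  ## candidate local maxima
  cand <- which(diff(sign(diff(y))) < 0) + 1L
  cand <- cand[y[cand] > floorLevel + 5 * noiseScale]
  if (!length(cand)) return(emptyPeakTable())
  prom <- vapply(cand, function(i) peakProminence(y, i), numeric(1))
  keep <- prom > max(minProminence, 0.02 * max(prom))
  cand <- cand[keep]; prom <- prom[keep]
  if (!length(cand)) return(emptyPeakTable())
  if (length(cand) > maxPeaks) {
    ord <- order(prom, decreasing = TRUE)[seq_len(maxPeaks)]
    cand <- sort(cand[ord]); prom <- prom[match(cand, cand)]
    prom <- vapply(cand, function(i) peakProminence(y, i), numeric(1))
  }

  ## rough FWHM from half-prominence crossings
  dq <- stats::median(diff(q))
  roughFwhm <- vapply(seq_along(cand), function(j) {
    i <- cand[j]; half <- y[i] - prom[j] / 2
    l <- i; while (l > 1 && y[l] > half) l <- l - 1
    r <- i; while (r < n && y[r] > half) r <- r + 1
    max(q[r] - q[l], 2 * dq)
  }, numeric(1))

  ## suppress duplicate candidates on one peak top: within one rough FWHM
  ## only the most prominent maximum survives (closer peaks are
  ## unresolvable at this width anyway)
  keep <- rep(TRUE, length(cand))
  for (j in order(prom, decreasing = TRUE)) {
    if (!keep[j]) next
    clash <- keep & abs(q[cand] - q[cand[j]]) < roughFwhm[j] &
      seq_along(cand) != j
    keep[clash & prom <= prom[j]] <- FALSE
  }
  cand <- cand[keep]; prom <- prom[keep]; roughFwhm <- roughFwhm[keep]

  ## group candidates whose windows overlap, then joint-fit each group
  win <- windowFactor * roughFwhm
  grp <- cumsum(c(1, diff(q[cand]) > (win[-length(win)] + win[-1]) / 1.5))
  out <- list()
  for (g in unique(grp)) {
    jj <- which(grp == g)
    k <- length(jj)
    lo <- max(min(q[cand[jj]]) - win[jj[1]], q[1])
    hi <- min(max(q[cand[jj]]) + win[jj[k]], q[n])
    sel <- q >= lo & q <= hi
    if (sum(sel) < 3 * k + 3) next
    qs <- q[sel]; ys <- y[sel]
    wts <- 1 / sqrt(pmax(ys, 1))
    sig0 <- roughFwhm[jj] / 2.3548
    amp0 <- pmax(prom[jj], 1)
    par0 <- c(q[cand[jj]], log(sig0), log(amp0),
              stats::median(ys[c(1, length(ys))]), 0)
    fit <- try(minpack.lm::nls.lm(
      par = par0, fn = gaussLinResiduals, q = qs, y = ys, w = wts, k = k,
      control = minpack.lm::nls.lm.control(maxiter = 200)), silent = TRUE)
    if (inherits(fit, "try-error")) next
    pp <- fit$par
    covm <- try(solve(fit$hessian) * 2 * fit$deviance / max(1, length(qs) - length(pp)),
                silent = TRUE)
    sdp <- if (inherits(covm, "try-error")) rep(NA_real_, length(pp)) else
      sqrt(pmax(diag(covm), 0))
    bg0 <- pp[3 * k + 1]
    for (j in seq_len(k)) {
      mu <- pp[j]; sig <- exp(pp[k + j]); amp <- exp(pp[2 * k + j])
      if (mu < lo || mu > hi || !is.finite(sig)) next
      if (amp < 4 * sqrt(max(bg0, 1))) next
      ## area in counts: Gaussian integral divided by the bin width
      area <- amp * sig * sqrt(2 * pi) / dq
      sdMu <- sdp[j]
      sdLsig <- sdp[k + j]; sdLamp <- sdp[2 * k + j]
      out[[length(out) + 1]] <- data.frame(
        center = mu, centerSd = sdMu, height = amp,
        fwhm = 2.3548 * sig, fwhmSd = 2.3548 * sig * sdLsig,
        area = area, areaSd = area * sqrt(sdLamp^2 + sdLsig^2))
    }
  }
  if (!length(out)) return(emptyPeakTable())
  pk <- do.call(rbind, out)
  pk <- pk[order(pk$center), , drop = FALSE]
  ## merge peaks closer than one FWHM: keep the taller
  repeat {
    if (nrow(pk) < 2) break
    gap <- diff(pk$center)
    lim <- pmax(pk$fwhm[-nrow(pk)], pk$fwhm[-1])
    i <- which(gap < lim)[1]
    if (is.na(i)) break
    drop <- if (pk$height[i] >= pk$height[i + 1]) i + 1 else i
    pk <- pk[-drop, , drop = FALSE]
  }
  rownames(pk) <- NULL
  pk
}

emptyPeakTable <- function() {
  data.frame(center = numeric(0), centerSd = numeric(0), height = numeric(0),
             fwhm = numeric(0), fwhmSd = numeric(0), area = numeric(0),
             areaSd = numeric(0))
}

## 1/sd^2 weights for peak centers; non-finite sds fall back to the median
## finite sd, or to fwhm/5 when no sds are available at all
peakWeights <- function(peaks) {
  n <- nrow(peaks)
  sdv <- peaks$centerSd %||% rep(NA_real_, n)
  bad <- !is.finite(sdv) | sdv <= 0
  if (all(bad)) {
    fw <- peaks$fwhm %||% rep(NA_real_, n)
    sdv <- if (all(is.finite(fw))) fw / 5 else rep(1, n)
  } else if (any(bad)) {
    sdv[bad] <- stats::median(sdv[!bad])
  }
  1 / sdv^2
}

## weighted regression of Q on h through the origin for a fixed order vector
latticeRegression <- function(qv, hv, w) {
  slope <- sum(w * qv * hv) / sum(w * hv^2)
  res <- qv - slope * hv
  n <- length(qv)
  varSlope <- if (n > 1) (sum(w * res^2) / (n - 1)) / sum(w * hv^2)
  else 1 / sum(w * hv^2)
  list(slope = slope, slopeSd = sqrt(varSlope), residuals = res,
       chi2 = sum(w * res^2))
}

assignOrders <- function(qv, maxBase = 3, maxOrder = 12L) {
  ## nearest-integer ratio to the lowest peak. A base order m > 1 for the
  ## lowest peak (needed when h = 1 is extinct) is accepted only on a clear
  ## residual improvement - otherwise any peak set can be "indexed" by a
  ## fine enough lattice - and assigned orders are capped at maxOrder.
  tryBase <- function(m) {
    hv <- pmax(1L, as.integer(round(m * qv / qv[1])))
    if (max(hv) > maxOrder) return(NULL)
    fit <- latticeRegression(qv, hv, rep(1, length(qv)))
    list(h = hv, chi2 = fit$chi2,
         maxRel = max(abs(fit$residuals) / qv), m = m)
  }
  best <- tryBase(1)
  if (is.null(best) || best$maxRel > 5e-3) {
    ## base 1 inconsistent: consider extinct-first-order assignments
    for (m in 2:maxBase) {
      cand <- tryBase(m)
      if (!is.null(cand) &&
          (is.null(best) || cand$chi2 < 0.5 * best$chi2)) best <- cand
    }
  }
  if (is.null(best)) return(pmax(1L, as.integer(round(qv / qv[1]))))
  best$h
}

#' Index Bragg peaks and fit the lamellar repeat spacing
#'
#' Assigns diffraction orders by nearest-integer ratio to the lowest peak
#' (trying base orders 1-3 for the lowest peak and keeping the assignment
#' with least residual), then fits Q_h = (2 pi / d) h by weighted least
#' squares through the origin. The repeat spacing is d = 2 pi / slope with
#' its SD propagated from the regression.
#'
#' @param peaks data.frame from \code{\link{detectPeaks}} (needs
#'   \code{center}; \code{centerSd} used as weights when available), or a
#'   numeric vector of peak positions (1/Angstrom).
#' @param residualTolerance numeric(1), relative residual |dQ|/Q above which
#'   the peak set is flagged as inconsistent with a single lattice
#'   (\code{"two.lattice.suspected"}); default 0.005.
#' @return a \linkS4class{LatticeFit}.
#' @examples
#' indexAndFitLattice(2 * pi * (1:5) / 53.2)  # d = 53.2 exactly
#' @export
indexAndFitLattice <- function(peaks, residualTolerance = 0.005) {
  if (is.numeric(peaks)) peaks <- data.frame(center = peaks, centerSd = NA_real_)
  if (!nrow(peaks)) stop("need at least one peak", call. = FALSE)
  qv <- peaks$center
  w <- peakWeights(peaks)
  ord <- order(qv)
  qv <- qv[ord]; w <- w[ord]
  peaks <- peaks[ord, , drop = FALSE]

  hv <- assignOrders(qv)
  fit <- latticeRegression(qv, hv, w)
  d <- 2 * pi / fit$slope
  dSd <- 2 * pi * fit$slopeSd / fit$slope^2
  fl <- character()
  if (any(abs(fit$residuals) > residualTolerance * qv))
    fl <- c(fl, "two.lattice.suspected")
  peaks$order <- hv
  new("LatticeFit", d = d, dSd = dSd, orders = as.integer(hv),
      residuals = fit$residuals, peaks = peaks, flags = fl)
}

#' Deconvolve a superposition of two lamellar lattices
#'
#' Exhaustively assigns each peak to lattice A or B (each subset indexed and
#' fitted as in \code{\link{indexAndFitLattice}}) and keeps the assignment
#' minimizing the total weighted squared residual; the search is exact for
#' up to 12 peaks. The split is accepted only if the two-lattice fit beats
#' the single-lattice fit by a Bayesian-information-criterion margin,
#' otherwise the single fit is returned with the \code{"no.split.detected"}
#' flag.
#'
#' @param peaks data.frame from \code{\link{detectPeaks}} (>= 4 peaks) or a
#'   numeric vector of positions.
#' @param bicMargin numeric(1), required BIC advantage of the two-lattice
#'   model (default 10).
#' @param degenerateTolerance numeric(1), |dA - dB| (Angstrom) below which
#'   the split is flagged \code{"degenerate.split"} (default 0.5).
#' @return list with elements \code{lattices} (list of
#'   \linkS4class{LatticeFit}, sorted by decreasing d; length 1 when no split
#'   is detected), \code{membership} (integer vector, 1 or 2 per peak in
#'   center order), and \code{split} (logical).
#' @export
deconvolveTwoLattices <- function(peaks, bicMargin = 10,
                                  degenerateTolerance = 0.5) {
  if (is.numeric(peaks)) peaks <- data.frame(center = peaks, centerSd = NA_real_)
  n <- nrow(peaks)
  if (n < 4) stop("need >= 4 peaks for a two-lattice decomposition", call. = FALSE)
  if (n > 12) stop("exact search supports at most 12 peaks", call. = FALSE)
  ord <- order(peaks$center)
  peaks <- peaks[ord, , drop = FALSE]
  qv <- peaks$center
  w <- peakWeights(peaks)

  single <- indexAndFitLattice(peaks)
  chiSingle <- latticeRegression(qv, single@orders, w)$chi2

  best <- NULL
  ## peak 1 fixed to lattice A to halve the search
  for (mask in 0:(2^(n - 1) - 1)) {
    inA <- c(TRUE, as.logical(bitwAnd(mask, 2^(0:(n - 2))) > 0))
    nA <- sum(inA)
    if (nA < 2 || n - nA < 2) next
    hA <- assignOrders(qv[inA]); hB <- assignOrders(qv[!inA])
    fA <- latticeRegression(qv[inA], hA, w[inA])
    fB <- latticeRegression(qv[!inA], hB, w[!inA])
    chi <- fA$chi2 + fB$chi2
    if (is.null(best) || chi < best$chi) {
      best <- list(chi = chi, inA = inA, hA = hA, hB = hB, fA = fA, fB = fB)
    }
  }

  ## scale-free model comparison: normalize the chi-squared difference by
  ## the residual variance of the two-lattice fit, so the rule works both
  ## for counting-statistics weights (variance ~ 1) and for unweighted
  ## peak lists. An extra slope costs log(n) (BIC) plus the margin.
  sigma2 <- best$chi / max(1, n - 4)
  eps <- 1e-18 * mean(qv)^2
  improvement <- if (chiSingle < n * eps) 0 else
    (chiSingle - best$chi) / max(sigma2, eps)
  if (!(improvement > bicMargin + log(n))) {
    single@flags <- unique(c(single@flags, "no.split.detected"))
    return(list(lattices = list(single),
                membership = rep(1L, n), split = FALSE))
  }

  mkFit <- function(sel, hv, fit) {
    pk <- peaks[sel, , drop = FALSE]
    pk$order <- hv
    new("LatticeFit", d = 2 * pi / fit$slope,
        dSd = 2 * pi * fit$slopeSd / fit$slope^2,
        orders = as.integer(hv), residuals = fit$residuals,
        peaks = pk, flags = character())
  }
  fitA <- mkFit(best$inA, best$hA, best$fA)
  fitB <- mkFit(!best$inA, best$hB, best$fB)
  lat <- list(fitA, fitB)
  memb <- ifelse(best$inA, 1L, 2L)
  if (fitB@d > fitA@d) {
    lat <- list(fitB, fitA)
    memb <- 3L - memb
  }
  if (abs(fitA@d - fitB@d) < degenerateTolerance) {
    lat[[1]]@flags <- unique(c(lat[[1]]@flags, "degenerate.split"))
    lat[[2]]@flags <- unique(c(lat[[2]]@flags, "degenerate.split"))
  }
  list(lattices = lat, membership = memb, split = TRUE)
}

#' Integrate Bragg peaks into unsigned structure factors
#'
#' For each diffraction order h the counts in a window around Q_h = 2 pi h/d
#' are summed above a linear background estimated from flanking strips;
#' structure factors are the square roots of the corrected integrated counts,
#' F(h) = sqrt(area * C_abs(h) * C_ext(h)), with SDs propagated from Poisson
#' counting statistics through the square root (delta method:
#' sd_F = sd_area * C / (2 F)).
#'
#' Quantitative absorption/extinction corrections are instrument-specific;
#' they enter as pluggable multiplicative functions of (h, Q) with identity
#' defaults, and must be calibrated per instrument for absolute work.
#'
#' @param pattern a \linkS4class{DiffractionPattern}.
#' @param lattice a \linkS4class{LatticeFit} for the indexed lattice.
#' @param hmax integer, highest order to integrate (default 5).
#' @param corrections list with optional functions \code{absorption(h, q)}
#'   and \code{extinction(h, q)} returning multiplicative area corrections.
#' @param windowHalfWidth numeric(1), integration half-width in 1/Angstrom;
#'   default 1.5x the median fitted FWHM of the lattice peaks.
#' @param d2oFraction,d7Fraction contrast metadata carried onto the result.
#' @return a \linkS4class{StructureFactorSet} (unsigned). Orders whose
#'   corrected area is negative get amplitude 0 with inflated SD and the
#'   flag \code{"negative.area"}.
#' @export
integrateStructureFactors <- function(pattern, lattice, hmax = 5,
                                      corrections = list(),
                                      windowHalfWidth = NULL,
                                      d2oFraction = 0, d7Fraction = 0) {
  stopifnot(is(pattern, "DiffractionPattern"), is(lattice, "LatticeFit"))
  q <- pattern@q; y <- pattern@counts
  d <- lattice@d
  cAbs <- corrections$absorption %||% function(h, q) 1
  cExt <- corrections$extinction %||% function(h, q) 1
  if (is.null(windowHalfWidth)) {
    fw <- lattice@peaks$fwhm
    windowHalfWidth <- if (!is.null(fw) && any(is.finite(fw)))
      1.5 * stats::median(fw[is.finite(fw)]) else 10 * stats::median(diff(q))
  }
  hs <- seq_len(hmax)
  fv <- sdv <- numeric(0)
  hv <- integer(0)
  fl <- character()
  for (h in hs) {
    qh <- 2 * pi * h / d
    if (qh - 2 * windowHalfWidth < min(q) || qh + 2 * windowHalfWidth > max(q)) next
    core <- q >= qh - windowHalfWidth & q <= qh + windowHalfWidth
    flank <- (q >= qh - 2 * windowHalfWidth & q < qh - windowHalfWidth) |
      (q > qh + windowHalfWidth & q <= qh + 2 * windowHalfWidth)
    if (sum(core) < 3 || sum(flank) < 3) next
    bgFit <- stats::lm.fit(cbind(1, q[flank]), y[flank])
    bg <- bgFit$coefficients[1] + bgFit$coefficients[2] * q[core]
    area <- sum(y[core] - bg)
    sdArea <- sqrt(sum(pmax(y[core], 0)) +
                     sum(pmax(bg, 0)) * sum(core) / max(1, sum(flank)))
    corr <- cAbs(h, qh) * cExt(h, qh)
    areaC <- area * corr
    if (areaC < 0) {
      fv <- c(fv, 0)
      sdv <- c(sdv, sqrt(abs(areaC) + (sdArea * corr)))
      fl <- unique(c(fl, "negative.area"))
      warning(sprintf("order %d: negative corrected area set to 0", h))
    } else {
      fh <- sqrt(areaC)
      fv <- c(fv, fh)
      sdv <- c(sdv, if (fh > 0) sdArea * corr / (2 * fh) else sqrt(sdArea * corr))
    }
    hv <- c(hv, h)
  }
  if (!length(hv)) stop("no integrable orders within the pattern range", call. = FALSE)
  new("StructureFactorSet", d = d, h = hv, f = fv, sd = pmax(sdv, 1e-12),
      d2oFraction = d2oFraction, d7Fraction = d7Fraction,
      signed = FALSE, flags = fl)
}

#' Thin-film absorption correction factory
#'
#' Simple specular thin-film absorption correction: the measured area at
#' half-angle theta is attenuated by A(theta) =
#' (1 - exp(-2 mu t / sin theta)) / (2 mu t / sin theta); the returned
#' function gives the multiplicative correction 1/A to apply to areas.
#'
#' @param muT numeric(1), absorption coefficient times film thickness
#'   (dimensionless).
#' @param wavelength numeric(1), probe wavelength (Angstrom).
#' @return function(h, q) suitable for the \code{corrections} argument of
#'   \code{\link{integrateStructureFactors}}.
#' @export
thinFilmAbsorption <- function(muT, wavelength) {
  checkScalar(muT, "muT", 0, strict = TRUE)
  function(h, q) {
    s <- sin(thetaFromQ(q, wavelength) * pi / 180)
    x <- 2 * muT / s
    x / (1 - exp(-x))
  }
}
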