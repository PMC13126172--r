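#' Construct a StructureFactorSet
#'
#' @param d numeric(1), repeat spacing (Angstrom).
#' @param h integer vector of diffraction orders.
#' @param f numeric, amplitudes (unsigned magnitudes unless \code{signed}).
#' @param sd numeric, positive SDs.
#' @param d2oFraction,d7Fraction contrast metadata in [0, 1].
#' @param signed logical(1).
#' @return a \linkS4class{StructureFactorSet}.
#' @export
structureFactorSet <- function(d, h, f, sd, d2oFraction = 0, d7Fraction = 0,
                               signed = FALSE) {
  new("StructureFactorSet", d = d, h = as.integer(h), f = f, sd = sd,
      d2oFraction = d2oFraction, d7Fraction = d7Fraction, signed = signed)
}

#' Construct a ContrastSeries
#'
#' @param sets list of \linkS4class{StructureFactorSet} sharing d and order
#'   coverage.
#' @param composition list of sample-composition metadata (e.g.
#'   \code{peptidePerLipid}).
#' @param groundTruth list of planted values when the series is synthetic.
#' @return a \linkS4class{ContrastSeries}.
#' @export
contrastSeries <- function(sets, composition = list(), groundTruth = list()) {
  new("ContrastSeries", sets = sets, composition = composition,
      groundTruth = groundTruth)
}

## Closed-form cosine structure factors of a symmetric Gaussian-component
## profile: each component of total area a at +/-z0 (or wrapped at the cell
## boundary) contributes a * cos(2 pi h z0 / d) * exp(-2 pi^2 h^2 s^2 / d^2).
componentStructureFactors <- function(center, sigma, area, d, h) {
  vapply(h, function(hh)
    sum(area * cos(2 * pi * hh * center / d) *
          exp(-2 * pi^2 * hh^2 * sigma^2 / d^2)),
    numeric(1))
}

#' Phase structure factors by H2O/2H2O contrast variation
#'
#' For a centrosymmetric bilayer the phases are signs. Exchanging hydration
#' water makes each signed F(h) linear in the D2O mole fraction x, so for
#' every order the sign pattern across contrasts is found by exhaustive
#' search (first contrast fixed positive) minimizing the weighted residual of
#' a straight-line fit of signed F(h) against x. The remaining per-order
#' global sign is fixed by the physical anchor that the water difference
#' density is positive at the unit-cell boundary z = +/- d/2: the slope
#' dF(h)/dx must carry sign (-1)^h.
#'
#' Orders whose best and second-best sign patterns are statistically tied
#' (delta chi-squared < \code{tieDelta}), or whose slope is smaller than its
#' SD (sign anchor unreliable), set the \code{"phase.ambiguous"} flag on the
#' returned sets.
#'
#' @param series a \linkS4class{ContrastSeries} with >= 2 distinct D2O
#'   fractions.
#' @param tieDelta numeric(1), chi-squared tie threshold (default 1).
#' @param method \code{"envelope"} (default) additionally constrains the
#'   per-order slopes dF(h)/dx to the shared water-envelope law
#'   A (-1)^h exp(-beta h^2), A > 0 - the inter-bilayer water layer is one
#'   distribution, so all orders' x-responses share its transform. This
#'   resolves sign patterns robustly even for orders whose F crosses zero
#'   within the measured x range. \code{"linear"} uses only per-order
#'   straight-line fits.
#' @return list of signed \linkS4class{StructureFactorSet} objects (same
#'   order as \code{series@sets}), with a \code{"signMatrix"} attribute
#'   (orders x contrasts).
#' @export
phaseByContrast <- function(series, tieDelta = 1,
                            method = c("envelope", "linear")) {
  stopifnot(is(series, "ContrastSeries"))
  method <- match.arg(method)
  sets <- series@sets
  xs <- vapply(sets, function(s) s@d2oFraction, numeric(1))
  if (length(unique(xs)) < 2)
    stop("phasing needs >= 2 distinct D2O fractions", call. = FALSE)
  hs <- sort(sets[[1]]@h)
  nh <- length(hs)
  nx <- length(sets)
  absF <- matrix(sapply(sets, function(s) abs(s@f[match(hs, s@h)])), nrow = nh)
  sdF <- matrix(sapply(sets, function(s) s@sd[match(hs, s@h)]), nrow = nh)

  patterns <- as.matrix(expand.grid(rep(list(c(1, -1)), nx - 1)))
  patterns <- cbind(1, patterns)  # first contrast fixed positive
  X <- cbind(1, xs)
  want <- ifelse(hs %% 2 == 0, 1, -1)  # water-positivity anchor on slopes

  ## stage 1: per-order free-slope line fits over all sign patterns
  lineFit <- function(i, p) {
    w <- 1 / sdF[i, ]^2
    fv <- p * absF[i, ]
    fit <- stats::lm.wfit(X, fv, w)
    list(chi2 = sum(w * fit$residuals^2), slope = fit$coefficients[2],
         slopeSd = sqrt(solve(crossprod(X / sdF[i, ]))[2, 2]))
  }
  chiFree <- matrix(NA_real_, nh, nrow(patterns))
  slopeFree <- matrix(NA_real_, nh, nrow(patterns))
  for (i in seq_len(nh)) for (j in seq_len(nrow(patterns))) {
    lf <- lineFit(i, patterns[j, ])
    chiFree[i, j] <- lf$chi2
    slopeFree[i, j] <- lf$slope
  }

  ambiguous <- logical(nh)
  signMat <- matrix(1, nh, nx)

  pickFree <- function() {
    for (i in seq_len(nh)) {
      ord <- order(chiFree[i, ])
      if (length(ord) > 1 && chiFree[i, ord[2]] - chiFree[i, ord[1]] < tieDelta)
        ambiguous[i] <<- TRUE
      best <- patterns[ord[1], ]
      sl <- slopeFree[i, ord[1]]
      if (sl != 0 && sign(sl) != want[i]) best <- -best
      lf <- lineFit(i, best)
      if (abs(lf$slope) < lf$slopeSd) ambiguous[i] <<- TRUE
      signMat[i, ] <<- best
    }
  }
  pickFree()

  if (method == "envelope" && nx >= 3) {
    ## stage 2: refit with slopes tied to the water-envelope transform.
    ## For fixed (A, beta) each order's slope is known, only the intercept
    ## is free, so a sign flip of one precise point can no longer be
    ## absorbed by the slope.
    ## the slope sign is anchored, so p and -p are inequivalent: enumerate
    ## the full sign set
    allPat <- rbind(patterns, -patterns)
    chiEnv <- function(par) {
      A <- exp(par[1]); beta <- par[2]
      tot <- 0
      for (i in seq_len(nh)) {
        s <- want[i] * A * exp(-beta * hs[i]^2)
        w <- 1 / sdF[i, ]^2
        chis <- apply(allPat, 1, function(p) {
          fv <- p * absF[i, ]
          c0 <- sum(w * (fv - s * xs)) / sum(w)
          sum(w * (fv - c0 - s * xs)^2)
        })
        tot <- tot + min(chis)
      }
      tot
    }
    ## initialize from the free-fit slopes of the anchored patterns
    sl0 <- vapply(seq_len(nh), function(i) lineFit(i, signMat[i, ])$slope,
                  numeric(1))
    ok <- sign(sl0) == want & abs(sl0) > 0
    if (sum(ok) >= 2) {
      lf0 <- stats::lm.fit(cbind(1, -hs[ok]^2), log(abs(sl0[ok])))
      par0 <- c(lf0$coefficients[1], max(lf0$coefficients[2], 1e-4))
      opt <- stats::optim(par0, chiEnv, method = "Nelder-Mead",
                          control = list(maxit = 400))
      A <- exp(opt$par[1]); beta <- opt$par[2]
      ambiguous[] <- FALSE
      for (i in seq_len(nh)) {
        s <- want[i] * A * exp(-beta * hs[i]^2)
        w <- 1 / sdF[i, ]^2
        allChis <- apply(allPat, 1, function(p) {
          fv <- p * absF[i, ]
          c0 <- sum(w * (fv - s * xs)) / sum(w)
          sum(w * (fv - c0 - s * xs)^2)
        })
        ord <- order(allChis)
        signMat[i, ] <- allPat[ord[1], ]
        if (length(ord) > 1 && allChis[ord[2]] - allChis[ord[1]] < tieDelta)
          ambiguous[i] <- TRUE
      }
    }
  }

  out <- lapply(seq_len(nx), function(j) {
    s <- sets[[j]]
    idx <- match(hs, s@h)
    s@f <- signMat[, j] * abs(s@f[idx])
    s@sd <- s@sd[idx]
    s@h <- as.integer(hs)
    s@signed <- TRUE
    if (any(ambiguous)) s@flags <- unique(c(s@flags, "phase.ambiguous"))
    s
  })
  attr(out, "signMatrix") <- signMat
  attr(out, "ambiguousOrders") <- hs[ambiguous]
  out
}

#' Fourier synthesis of a 1-D SLD profile from signed structure factors
#'
#' rho(z) = (2/d) sum_h F(h) cos(2 pi h z / d) on z in [-d/2, d/2]. The
#' unmeasurable mean (h = 0) term is omitted, so the profile is relative and
#' integrates to zero over one period; even symmetry is exact by
#' construction. The per-z uncertainty band is propagated from the F(h) SDs.
#'
#' @param set a signed \linkS4class{StructureFactorSet}.
#' @param nGrid integer, grid points per period (default 512).
#' @param hmax integer, truncation order (default: all orders in the set).
#' @return an \linkS4class{SLDProfile} on the relative scale.
#' @export
fourierSynthesis <- function(set, nGrid = 512, hmax = NULL) {
  stopifnot(is(set, "StructureFactorSet"))
  if (!set@signed) stop("structure factors must be signed (phased) first", call. = FALSE)
  d <- set@d
  hmax <- as.integer(hmax %||% max(set@h))
  use <- set@h <= hmax
  z <- seq(-d / 2, d / 2, length.out = nGrid)
  rho <- sdsq <- numeric(nGrid)
  for (i in which(use)) {
    cosz <- cos(2 * pi * set@h[i] * z / d)
    rho <- rho + set@f[i] * cosz
    sdsq <- sdsq + (set@sd[i] * cosz)^2
  }
  new("SLDProfile", z = z, rho = 2 * rho / d, sdBand = 2 * sqrt(sdsq) / d,
      d = d, hmax = hmax, scale = "relative", flags = set@flags)
}

#' Deuterium-difference profile
#'
#' Pointwise difference of two SLD profiles on the same lattice and grid,
#' isolating a deuterated label (d7 acyl chains, exchanged hydration water).
#' The Fourier coefficients of the result equal the differences of the input
#' coefficient sets.
#'
#' @param profileA,profileB \linkS4class{SLDProfile} objects with matching
#'   d, grid, truncation order and scale - or two signed
#'   \linkS4class{StructureFactorSet} objects with matching d and orders,
#'   in which case the difference is taken order by order in the measured
#'   domain (SDs add in quadrature) and a difference set is returned.
#' @return an \linkS4class{SLDProfile} (or \linkS4class{StructureFactorSet});
#'   SDs add in quadrature.
#' @export
deuteriumDifference <- function(profileA, profileB) {
  if (is(profileA, "StructureFactorSet") && is(profileB, "StructureFactorSet")) {
    if (!profileA@signed || !profileB@signed)
      stop("structure factors must be signed (phased) first", call. = FALSE)
    if (abs(profileA@d - profileB@d) > 1e-6 * profileA@d)
      stop("sets have different repeat spacings", call. = FALSE)
    if (!identical(sort(profileA@h), sort(profileB@h)))
      stop("sets have different order coverage", call. = FALSE)
    ia <- order(profileA@h); ib <- order(profileB@h)
    return(new("StructureFactorSet", d = profileA@d,
               h = profileA@h[ia],
               f = profileA@f[ia] - profileB@f[ib],
               sd = sqrt(profileA@sd[ia]^2 + profileB@sd[ib]^2),
               d2oFraction = profileA@d2oFraction,
               d7Fraction = profileA@d7Fraction,
               signed = TRUE,
               flags = unique(c(profileA@flags, profileB@flags))))
  }
  stopifnot(is(profileA, "SLDProfile"), is(profileB, "SLDProfile"))
  if (abs(profileA@d - profileB@d) > 1e-6 * profileA@d)
    stop("profiles have different repeat spacings", call. = FALSE)
  if (length(profileA@z) != length(profileB@z) ||
      max(abs(profileA@z - profileB@z)) > 1e-9 * profileA@d)
    stop("profiles are on different grids", call. = FALSE)
  if (profileA@hmax != profileB@hmax)
    stop("profiles have different truncation orders", call. = FALSE)
  if (profileA@scale != profileB@scale)
    stop("profiles are on different scales", call. = FALSE)
  sdA <- if (length(profileA@sdBand)) profileA@sdBand else 0
  sdB <- if (length(profileB@sdBand)) profileB@sdBand else 0
  new("SLDProfile", z = profileA@z, rho = profileA@rho - profileB@rho,
      sdBand = sqrt(sdA^2 + sdB^2), d = profileA@d, hmax = profileA@hmax,
      scale = profileA@scale,
      flags = unique(c(profileA@flags, profileB@flags)))
}

#' Rescale a relative profile to the absolute (calibrated) scale
#'
#' @param profile an \linkS4class{SLDProfile}.
#' @param scaleFactor numeric(1), multiplicative calibration factor from
#'   \code{\link{calibrateAmplitude}}.
#' @return the calibrated \linkS4class{SLDProfile} (scale = "absolute").
#' @export
applyCalibration <- function(profile, scaleFactor) {
  checkScalar(scaleFactor, "scaleFactor")
  profile@rho <- profile@rho * scaleFactor
  profile@sdBand <- profile@sdBand * abs(scaleFactor)
  profile@scale <- "absolute"
  profile
}

#' Fit symmetric Gaussian components to an SLD profile
#'
#' Minimizes the uncertainty-weighted chi-squared between the profile and a
#' model of mirrored Gaussian components by Levenberg-Marquardt least
#' squares. Because measured profiles are mean-free and truncated at hmax,
#' the model profile is computed the same way - through its closed-form
#' cosine coefficients up to the profile's hmax - so truncation and the
#' missing h = 0 term introduce no bias and a noiseless planted component set
#' is recovered exactly.
#'
#' Each component is a mirrored pair at +/-center sharing width and area
#' (a component with center 0 is a single central Gaussian; a component at
#' the cell boundary d/2 is the wrapped inter-bilayer envelope). "area" is
#' the total area of the component (both mirror halves).
#'
#' @param profile an \linkS4class{SLDProfile} (sdBand used as weights when
#'   present), or a signed \linkS4class{StructureFactorSet}. Passing the
#'   structure factors fits in the measured-data domain with per-order
#'   1/sd weights - the statistically faithful weighting, since profile
#'   points are correlated combinations of the few measured amplitudes.
#' @param components data.frame of 1-4 starting components with columns
#'   \code{center} (Angstrom, >= 0), \code{fwhm} (Angstrom), \code{area};
#'   optional logical columns \code{fixCenter} and \code{fixArea} pin a
#'   component's center or area (e.g. an area known from amplitude
#'   calibration).
#' @param maxRestarts integer, random restarts on non-convergence (default 3).
#' @param centerRange numeric(2), box bounds on component centers
#'   (default c(0, d/2)).
#' @param fwhmRange numeric(2), box bounds on component FWHMs (default:
#'   grid resolution to d); physically motivated bounds stabilize
#'   low-signal-to-noise fits.
#' @return data.frame with fitted \code{center}, \code{fwhm}, \code{area}
#'   and their covariance-derived SDs; attributes \code{"converged"}
#'   (logical) and \code{"covariance"}. Widths are bounded below at the grid
#'   resolution.
#' @examples
#' sfs <- forwardStructureFactors(
#'   bilayerModel(components = data.frame(
#'     name = "label", center = 1.87, sigma = 15 / 2.3548,
#'     area0 = 1, areaX = 0, pair = TRUE)), hmax = 5)
#' prof <- fourierSynthesis(sfs)
#' fitGaussianComponents(prof, data.frame(center = 3, fwhm = 10, area = 0.8))
#' @export
fitGaussianComponents <- function(profile, components, maxRestarts = 3,
                                  centerRange = NULL, fwhmRange = NULL) {
  k <- nrow(components)
  if (k < 1 || k > 4) stop("model must specify 1-4 components", call. = FALSE)
  fSpace <- is(profile, "StructureFactorSet")
  if (fSpace && !profile@signed)
    stop("structure factors must be signed (phased) first", call. = FALSE)
  if (!fSpace) stopifnot(is(profile, "SLDProfile"))
  d <- profile@d
  hs <- if (fSpace) profile@h else seq_len(profile@hmax)
  fixC <- components$fixCenter %||% rep(FALSE, k)
  fixA <- components$fixArea %||% rep(FALSE, k)
  if (fSpace) {
    gridRes <- d / 512
    w <- 1 / profile@sd
    target <- profile@f
  } else {
    z <- profile@z
    gridRes <- stats::median(diff(z))
    w <- if (length(profile@sdBand) && all(profile@sdBand > 0))
      1 / profile@sdBand else rep(1, length(z))
    target <- profile@rho
    cosBasis <- sapply(hs, function(h) cos(2 * pi * h * z / d))
  }
  w <- w / mean(w)  # relative weights only; rescaling stabilizes the solver
  nObs <- length(target)

  nC <- sum(!fixC); nA <- sum(!fixA)
  unpack <- function(par) {
    centers <- components$center
    centers[!fixC] <- par[seq_len(nC)]
    sig <- exp(par[nC + seq_len(k)])
    area <- components$area
    area[!fixA] <- par[nC + k + seq_len(nA)]
    list(center = centers, sigma = sig, area = area)
  }
  resFun <- function(par) {
    pp <- unpack(par)
    fh <- componentStructureFactors(pp$center, pp$sigma, pp$area, d, hs)
    model <- if (fSpace) fh else as.numeric(cosBasis %*% fh) * 2 / d
    (model - target) * w
  }

  centerRange <- centerRange %||% c(0, d / 2)
  fwhmRange <- fwhmRange %||% c(2.3548 * gridRes / 2, 2.3548 * d)
  lower <- c(rep(centerRange[1], nC), rep(log(fwhmRange[1] / 2.3548), k),
             rep(-Inf, nA))
  upper <- c(rep(centerRange[2], nC), rep(log(fwhmRange[2] / 2.3548), k),
             rep(Inf, nA))
  ctrl <- minpack.lm::nls.lm.control(maxiter = 1000, ftol = 1e-14,
                                     ptol = 1e-14, gtol = 0)
  start <- c(components$center[!fixC],
             log(pmax(components$fwhm, 2 * gridRes) / 2.3548),
             components$area[!fixA])
  best <- NULL
  set0 <- start
  for (r in 0:maxRestarts) {
    st <- if (r == 0) set0 else {
      s <- set0
      if (nC) s[seq_len(nC)] <- stats::runif(nC, 0, d / 4)
      s[nC + seq_len(k)] <- s[nC + seq_len(k)] + stats::rnorm(k, 0, 0.2)
      s
    }
    st <- pmin(pmax(st, lower + 1e-9), upper - 1e-9)
    fit <- try(minpack.lm::nls.lm(
      par = st, fn = resFun, lower = lower, upper = upper,
      control = ctrl), silent = TRUE)
    if (inherits(fit, "try-error")) next
    if (is.null(best) || fit$deviance < best$deviance) best <- fit
  }
  if (is.null(best)) stop("component fit failed", call. = FALSE)
  pp <- unpack(best$par)
  pp$sigma <- pmax(pp$sigma, gridRes)

  ## hessian ~ 2 J'J in normalized-weight units; scale by the residual
  ## variance. Profile grid points are correlated (only hmax independent
  ## amplitudes), so the profile-space SDs are indicative - Monte-Carlo
  ## resampling gives honest ones.
  npar <- length(best$par)
  sig2 <- best$deviance / max(1, nObs - npar)
  covm <- try(solve(best$hessian) * 2 * sig2, silent = TRUE)
  sds <- if (inherits(covm, "try-error")) rep(NA_real_, npar) else
    sqrt(pmax(diag(covm), 0))
  iS <- nC + seq_len(k)
  centerSd <- rep(0, k); centerSd[!fixC] <- sds[seq_len(nC)]
  areaSd <- rep(0, k); areaSd[!fixA] <- sds[nC + k + seq_len(nA)]
  out <- data.frame(
    center = pp$center, centerSd = centerSd,
    fwhm = 2.3548 * pp$sigma, fwhmSd = 2.3548 * pp$sigma * sds[iS],
    area = pp$area, areaSd = areaSd)
  attr(out, "converged") <- best$info %in% 1:4
  attr(out, "covariance") <- if (inherits(covm, "try-error")) NULL else covm
  if (!attr(out, "converged"))
    warning("component fit did not converge after restarts")
  out
}

#' Amplitude calibration from a d7-label difference profile
#'
#' A deuterium-difference profile between d7-labeled and unlabeled samples
#' carries a known integrated scattering length per lipid:
#' labelFraction * 7 * deltaB (7 deuterons per labeled chain, deltaB =
#' b_2H - b_H per exchanged/substituted proton). The profile's label area is
#' measured by a truncation-consistent Gaussian-component fit (a mean-free
#' profile integrates to zero over the period, so the fitted component area
#' is the finite-order estimate of the h = 0 difference amplitude), and the
#' calibration factor is expected / measured.
#'
#' @param differenceProfile \linkS4class{SLDProfile} (labeled minus
#'   unlabeled) or the corresponding signed difference
#'   \linkS4class{StructureFactorSet}; the latter is fit in the measured
#'   domain with per-order weights.
#' @param labelFraction numeric(1) in (0, 1], mole fraction of d7 lipid.
#' @param deuteronsPerLabel numeric(1), deuterons per labeled lipid
#'   (default 7).
#' @param deltaB numeric(1), scattering-length gain per H->D (Angstrom,
#'   default 1.041e-4).
#' @param components starting component table for the label distribution fit
#'   (default: one mirrored pair near the bilayer center).
#' @return list: \code{scale} (multiply relative profiles by this to get
#'   scattering length per lipid per Angstrom), \code{measuredArea},
#'   \code{expectedArea}, \code{fit} (the component table).
#' @export
calibrateAmplitude <- function(differenceProfile, labelFraction,
                               deuteronsPerLabel = 7, deltaB = 1.041e-4,
                               components = NULL,
                               centerRange = NULL, fwhmRange = c(5, 30)) {
  if (labelFraction <= 0)
    stop("'labelFraction' must be > 0 (zero-label difference carries no calibration)",
         call. = FALSE)
  d <- differenceProfile@d
  ## an acyl-chain label lives in the inner part of the cell; bounding the
  ## component there (and its width to physical values) keeps the
  ## calibration stable when only the low orders carry signal
  centerRange <- centerRange %||% c(0, d / 4)
  if (is.null(components)) {
    prof <- if (is(differenceProfile, "StructureFactorSet"))
      fourierSynthesis(differenceProfile) else differenceProfile
    rho <- prof@rho
    z <- prof@z
    inner <- abs(z) <= d / 4
    zpk <- abs(z[inner][which.max(rho[inner])])
    components <- data.frame(center = min(max(zpk, 1), centerRange[2]),
                             fwhm = 12,
                             area = max(trapint(z, pmax(rho, 0)), 1e-12))
  }
  fit <- fitGaussianComponents(differenceProfile, components,
                               centerRange = centerRange,
                               fwhmRange = fwhmRange)
  measured <- sum(fit$area)
  if (measured <= 0)
    stop("measured label area is <= 0; cannot calibrate", call. = FALSE)
  expected <- labelFraction * deuteronsPerLabel * deltaB
  list(scale = expected / measured, measuredArea = measured,
       expectedArea = expected, fit = fit)
}

#' Monte-Carlo resampling of structure factors through a downstream fit
#'
#' Draws \code{nMock} statistically independent mock structure-factor sets,
#' each value normally distributed around the measured F(h) within 1 SD,
#' runs the supplied deterministic downstream fit on each, and reports the
#' per-parameter mean and SD over the ensemble.
#'
#' @param input a signed \linkS4class{StructureFactorSet} or a
#'   \linkS4class{ContrastSeries}.
#' @param fitFun function taking a perturbed object of the same class and
#'   returning a named numeric vector of fitted parameters.
#' @param nMock integer, ensemble size (default 100).
#' @param seed integer seed; reproducible given a seed.
#' @param maxFailFraction numeric(1); if more than this fraction of mocks
#'   fail the aggregate is flagged (default 0.2).
#' @return list: \code{mean}, \code{sd} (named numeric), \code{draws}
#'   (matrix nMock x p with NA rows for failures), \code{nFailed},
#'   \code{flagged}.
#' @export
mcResample <- function(input, fitFun, nMock = 100, seed = 1,
                       maxFailFraction = 0.2) {
  set.seed(seed)
  perturb <- function(obj) {
    if (is(obj, "StructureFactorSet")) {
      obj@f <- obj@f + stats::rnorm(length(obj@f), 0, obj@sd)
      obj
    } else if (is(obj, "ContrastSeries")) {
      obj@sets <- lapply(obj@sets, function(s) {
        s@f <- s@f + stats::rnorm(length(s@f), 0, s@sd)
        s
      })
      obj
    } else stop("unsupported input class", call. = FALSE)
  }
  draws <- NULL
  nFailed <- 0L
  for (i in seq_len(nMock)) {
    res <- try(fitFun(perturb(input)), silent = TRUE)
    if (inherits(res, "try-error") || any(!is.finite(res))) {
      nFailed <- nFailed + 1L
      res <- NULL
    }
    if (is.null(draws) && !is.null(res))
      draws <- matrix(NA_real_, nMock, length(res),
                      dimnames = list(NULL, names(res)))
    if (!is.null(res)) draws[i, ] <- res
  }
  if (is.null(draws)) stop("all mock fits failed", call. = FALSE)
  list(mean = colMeans(draws, na.rm = TRUE),
       sd = apply(draws, 2, stats::sd, na.rm = TRUE),
       draws = draws, nFailed = nFailed,
       flagged = nFailed > maxFailFraction * nMock)
}

#' Waters bound per peptide from the exchanged scattering length
#'
#' Converts the calibrated, per-lipid exchanged scattering length B measured
#' at D2O fraction x into excess waters per peptide:
#'   w_P = (B / (x deltaB) - N_x r - 2 w_L) / (2 r),
#' counting 2 exchangeable protons per water, N_x exchangeable protons per
#' peptide at peptide-per-lipid ratio r, and a baseline of w_L waters per
#' lipid headgroup. SDs are propagated linearly from B, w_L and N_x.
#'
#' @param B numeric(1), exchanged scattering length per lipid (Angstrom).
#' @param x numeric(1) in (0, 1], D2O fraction (or fraction difference) at
#'   which B was measured.
#' @param peptidePerLipid numeric(1), r > 0 (e.g. 1/25).
#' @param watersPerLipid numeric(1), baseline headgroup hydration
#'   (default 9.4 waters/lipid).
#' @param nExchangeable numeric(1), exchangeable protons per peptide
#'   (default 57).
#' @param deltaB numeric(1), b_2H - b_H (Angstrom, default 1.041e-4).
#' @param bSd,watersPerLipidSd,nExchangeableSd input SDs for propagation
#'   (defaults 0, 0, 2; the baseline hydration is treated as exact unless
#'   overridden).
#' @return a \linkS4class{WaterQuantification}; a negative count is flagged
#'   \code{"negative.water"} but still reported.
#' @examples
#' watersPerPeptide(B = 30.2 * 1.041e-4, x = 1, peptidePerLipid = 1 / 25)
#' @export
watersPerPeptide <- function(B, x, peptidePerLipid, watersPerLipid = 9.4,
                             nExchangeable = 57, deltaB = 1.041e-4,
                             bSd = 0, watersPerLipidSd = 0,
                             nExchangeableSd = 2) {
  checkScalar(B, "B")
  if (x <= 0 || x > 1) stop("'x' must lie in (0, 1]", call. = FALSE)
  checkScalar(peptidePerLipid, "peptidePerLipid", 0, strict = TRUE)
  r <- peptidePerLipid
  protons <- B / (x * deltaB)
  wp <- (protons - nExchangeable * r - 2 * watersPerLipid) / (2 * r)
  sdWp <- sqrt((bSd / (x * deltaB * 2 * r))^2 +
                 (watersPerLipidSd / r)^2 +
                 (nExchangeableSd / 2)^2)
  fl <- if (wp < 0) "negative.water" else character()
  new("WaterQuantification", watersPerPeptide = wp, sd = sdWp,
      inputs = list(B = B, x = x, peptidePerLipid = r,
                    watersPerLipid = watersPerLipid,
                    nExchangeable = nExchangeable, deltaB = deltaB,
                    bSd = bSd, watersPerLipidSd = watersPerLipidSd,
                    nExchangeableSd = nExchangeableSd),
      flags = fl)
}

#' Full deuterium-difference water accounting on a contrast series pair
#'
#' Convenience pipeline: phases the unlabeled and d7-labeled series, builds
#' relative profiles by Fourier synthesis, calibrates the amplitude scale on
#' the d7 difference (labeled minus unlabeled at matching D2O fraction),
#' measures the exchanged scattering length from the H2O/2H2O water
#' difference of the unlabeled series by a boundary-component fit, and runs
#' the waters-per-peptide accounting. Uncertainty on the recovered count is
#' obtained by Monte-Carlo resampling of the unlabeled series' structure
#' factors through the same chain.
#'
#' @param series unlabeled \linkS4class{ContrastSeries} spanning >= 2 D2O
#'   fractions.
#' @param labeledSeries d7-labeled \linkS4class{ContrastSeries} (shares a
#'   D2O fraction with \code{series}).
#' @param peptidePerLipid numeric(1), r.
#' @param watersPerLipid,nExchangeable,deltaB accounting inputs, see
#'   \code{\link{watersPerPeptide}}.
#' @param nGrid grid points per period (default 512).
#' @param nMock MC resampling ensemble size for the SD (default 100; 0
#'   disables resampling).
#' @param seed integer seed for the resampling.
#' @return a \linkS4class{WaterQuantification} whose \code{inputs} echo the
#'   calibration scale and measured areas.
#' @export
quantifyWater <- function(series, labeledSeries, peptidePerLipid,
                          watersPerLipid = 9.4, nExchangeable = 57,
                          deltaB = 1.041e-4, nGrid = 512, nMock = 100,
                          seed = 1) {
  d <- repeatSpacing(series)
  labelFraction <- labeledSeries@sets[[1]]@d7Fraction
  nU <- length(series@sets)

  ## whole measurement chain on one (possibly perturbed) joint series:
  ## phase, difference in the measured domain, calibrate on the d7
  ## difference, measure the exchanged envelope on the water difference
  chain <- function(joint) {
    isLab <- attr(joint, "isLabeled") %||%
      c(rep(FALSE, nU), rep(TRUE, length(joint@sets) - nU))
    serU <- contrastSeries(joint@sets[!isLab])
    serL <- contrastSeries(joint@sets[isLab])
    phU <- phaseByContrast(serU)
    phL <- phaseByContrast(serL)
    xsU <- vapply(phU, function(s) s@d2oFraction, numeric(1))
    xsL <- vapply(phL, function(s) s@d2oFraction, numeric(1))
    shared <- intersect(round(xsU, 6), round(xsL, 6))
    if (!length(shared))
      stop("labeled and unlabeled series share no D2O fraction", call. = FALSE)
    ## the label distribution is x-independent, so the labeled-minus-
    ## unlabeled difference at every shared contrast measures the same
    ## F_label(h): pool them by inverse variance before the calibration fit
    diffs <- lapply(shared, function(x0)
      deuteriumDifference(phL[[which(round(xsL, 6) == x0)[1]]],
                          phU[[which(round(xsU, 6) == x0)[1]]]))
    wts <- lapply(diffs, function(dd) 1 / dd@sd^2)
    wSum <- Reduce(`+`, wts)
    fBar <- Reduce(`+`, Map(function(dd, w) dd@f * w, diffs, wts)) / wSum
    d7diff <- diffs[[1]]
    d7diff@f <- fBar
    d7diff@sd <- 1 / sqrt(wSum)
    calib <- calibrateAmplitude(d7diff, labelFraction, deltaB = deltaB)
    iLo <- which.min(xsU); iHi <- which.max(xsU)
    dx <- xsU[iHi] - xsU[iLo]
    wdiff <- deuteriumDifference(phU[[iHi]], phU[[iLo]])
    ## single wrapped boundary component for the exchanged-proton envelope
    start <- data.frame(center = 0.9 * d / 2, fwhm = 11, area = 1)
    start$area <- {
      p <- fourierSynthesis(wdiff, nGrid = 128)
      max(trapint(p@z, pmax(p@rho, 0)), 1e-12)
    }
    fit <- fitGaussianComponents(wdiff, start)
    c(B = calib$scale * sum(fit$area) / dx, dx = dx,
      scale = calib$scale, labelArea = calib$measuredArea,
      waterArea = sum(fit$area))
  }

  joint <- contrastSeries(c(series@sets, labeledSeries@sets))
  attr(joint, "isLabeled") <- c(rep(FALSE, nU), rep(TRUE, length(labeledSeries@sets)))
  pt <- chain(joint)
  bSd <- 0
  if (nMock > 0) {
    mc <- mcResample(joint, function(j) chain(j)["B"], nMock = nMock,
                     seed = seed)
    bSd <- mc$sd[[1]]
  }
  wq <- watersPerPeptide(B = as.numeric(pt["B"]), x = 1,
                         peptidePerLipid = peptidePerLipid,
                         watersPerLipid = watersPerLipid,
                         nExchangeable = nExchangeable, deltaB = deltaB,
                         bSd = as.numeric(bSd))
  wq@inputs$calibrationScale <- as.numeric(pt["scale"])
  wq@inputs$measuredLabelArea <- as.numeric(pt["labelArea"])
  wq@inputs$waterArea <- as.numeric(pt["waterArea"])
  wq
}
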