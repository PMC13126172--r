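test_that("closed-form structure factors match direct quadrature", {
  m <- bilayerModel(d = 54.9)
  cp <- m@components
  fh <- forwardStructureFactors(m, hmax = 5)@f
  oracle <- quadratureF(cp$center, cp$sigma, cp$area0, 54.9, 1:5)
  expect_equal(fh, oracle, tolerance = 1e-8)
  ## flat model: all F zero
  m0 <- bilayerModel(components = data.frame(
    name = "null", center = 0, sigma = 3, area0 = 0, areaX = 0, pair = FALSE))
  expect_true(all(forwardStructureFactors(m0, 5)@f == 0))
  ## single centered Gaussian: all positive, decaying in h
  m1 <- bilayerModel(components = data.frame(
    name = "c", center = 0, sigma = 4, area0 = 1, areaX = 0, pair = FALSE))
  f1 <- forwardStructureFactors(m1, 5)@f
  expect_true(all(f1 > 0) && all(diff(f1) < 0))
})

test_that("Fourier synthesis is even, mean-free and matches the closed form", {
  ## all-zero amplitudes give a flat zero profile
  z0 <- fourierSynthesis(structureFactorSet(50, 1:5, rep(0, 5), rep(1e-6, 5),
                                            signed = TRUE))
  expect_true(all(z0@rho == 0))

  d <- 54.9
  pair <- data.frame(name = "label", center = 1.87, sigma = 15 / 2.3548,
                     area0 = 1, areaX = 0, pair = TRUE)
  sf <- forwardStructureFactors(bilayerModel(d = d, components = pair), 5)
  prof <- fourierSynthesis(sf, nGrid = 1024)
  ## even symmetry exact by construction
  expect_equal(prof@rho, rev(prof@rho), tolerance = 1e-12)
  ## integrates to zero over one period (mean term omitted)
  expect_lt(abs(lamellar:::trapint(prof@z, prof@rho)), 1e-8)

  ## matches the generating pair within the analytic truncation bound:
  ## the residual is the tail sum (2/d) * sum_{h>5} |F(h)|
  trueRho <- function(z) {
    out <- 0
    for (k in -1:1)
      out <- out + 0.5 * dnorm(z, 1.87 + k * d, 15 / 2.3548) +
        0.5 * dnorm(z, -1.87 + k * d, 15 / 2.3548)
    out
  }
  tailF <- componentStructureFactors(1.87, 15 / 2.3548, 1, d, 6:60)
  bound <- (2 / d) * sum(abs(tailF)) + 1e-12
  resid <- max(abs(prof@rho + 1 / d - trueRho(prof@z)))  # add back the mean
  expect_lte(resid, bound)
})

test_that("contrast phasing recovers forward-planted signs", {
  ## 50 random plantings; compare on orders that carry measurable amplitude
  set.seed(77)
  nbad <- 0; ntot <- 0
  for (i in 1:50) {
    m <- bilayerModel(d = runif(1, 50, 60),
                      watersPerPeptide = runif(1, 50, 150),
                      headgroupCenter = runif(1, 18, 22),
                      waterSigma = runif(1, 3.5, 5.5))
    ser <- generateContrastSeries(m, relSd = 0.02, seed = 3000 + i)
    ph <- phaseByContrast(ser)
    sm <- attr(ph, "signMatrix")
    tr <- ser@groundTruth$trueSigns
    for (j in seq_along(ser@sets)) {
      meaningful <- abs(ser@sets[[j]]@f) > 5 * ser@sets[[j]]@sd
      ntot <- ntot + sum(meaningful)
      nbad <- nbad + sum(sm[meaningful, j] != tr[meaningful, j])
    }
  }
  expect_lt(nbad / ntot, 0.01)
})

test_that("the linear phasing method equals the per-order enumeration oracle", {
  set.seed(5)
  for (i in 1:10) {
    m <- bilayerModel(d = runif(1, 52, 58))
    ser <- generateContrastSeries(m, relSd = 0.01, seed = 500 + i)
    ph <- phaseByContrast(ser, method = "linear")
    sm <- attr(ph, "signMatrix")
    xs <- vapply(ser@sets, function(s) s@d2oFraction, numeric(1))
    for (h in 1:5) {
      absF <- vapply(ser@sets, function(s) abs(s@f[h]), numeric(1))
      sdF <- vapply(ser@sets, function(s) s@sd[h], numeric(1))
      expect_equal(sm[h, ], enumPhaseOracle(absF, sdF, xs, h),
                   ignore_attr = TRUE)
    }
  }
})

test_that("phasing rejects single-contrast series and survives inflated sds", {
  m <- bilayerModel()
  ser1 <- generateContrastSeries(m, xList = 0.5, seed = 1)
  expect_error(phaseByContrast(ser1), "2 distinct")

  ser <- generateContrastSeries(m, relSd = 0.02, seed = 9)
  phRef <- phaseByContrast(ser)
  ## inflate one order's sd 100x: signs of well-measured orders unchanged
  ser@sets <- lapply(ser@sets, function(s) { s@sd[2] <- s@sd[2] * 100; s })
  ph <- phaseByContrast(ser)
  sm <- attr(ph, "signMatrix")
  expect_equal(sm[-2, ], attr(phRef, "signMatrix")[-2, ])
})

test_that("deuterium differences are linear and grid-checked", {
  m <- bilayerModel(d = 54.9)
  mk <- function(x) fourierSynthesis(forwardStructureFactors(m, 5, x))
  a <- mk(0); b <- mk(0.5); c3 <- mk(1)
  z <- deuteriumDifference(a, a)
  expect_true(all(z@rho == 0))
  lhs <- deuteriumDifference(a, b)@rho + deuteriumDifference(b, c3)@rho
  expect_equal(lhs, deuteriumDifference(a, c3)@rho, tolerance = 1e-12)
  other <- fourierSynthesis(forwardStructureFactors(bilayerModel(d = 50), 5))
  expect_error(deuteriumDifference(a, other), "repeat spacing")

  ## labeled minus unlabeled recovers the planted label distribution:
  ## difference coefficients equal the label component's transform
  mL <- bilayerModel(d = 54.9, d7Fraction = 5 / 6)
  dd <- deuteriumDifference(forwardStructureFactors(mL, 5),
                            forwardStructureFactors(m, 5))
  lab <- componentStructureFactors(1.87, 15 / 2.3548, 5 / 6 * 7 * 1.041e-4,
                                   54.9, 1:5)
  expect_equal(dd@f, lab, tolerance = 1e-10)
})

test_that("amplitude calibration recovers a planted instrument scale", {
  mU <- bilayerModel(d = 54.9)
  mL <- bilayerModel(d = 54.9, d7Fraction = 5 / 6)
  ## clean forward series with a known arbitrary scale
  scale <- 37
  fU <- forwardStructureFactors(mU, 5); fL <- forwardStructureFactors(mL, 5)
  fU@f <- fU@f * scale; fL@f <- fL@f * scale
  fU@sd <- pmax(abs(fU@f) * 1e-4, 1e-9); fL@sd <- pmax(abs(fL@f) * 1e-4, 1e-9)
  calib <- calibrateAmplitude(deuteriumDifference(fL, fU), 5 / 6)
  expect_equal(calib$scale, 1 / scale, tolerance = 0.01)
  ## doubling the label fraction doubles the expected integral
  c2 <- calibrateAmplitude(deuteriumDifference(fL, fU), 2 * 5 / 6)
  expect_equal(c2$expectedArea, 2 * calib$expectedArea)
  expect_error(calibrateAmplitude(deuteriumDifference(fL, fU), 0), "labelFraction")
})

test_that("Gaussian component fits recover noiseless plantings exactly", {
  d <- 54.9
  pair <- data.frame(name = "label", center = 1.87, sigma = 15 / 2.3548,
                     area0 = 1, areaX = 0, pair = TRUE)
  sf <- forwardStructureFactors(bilayerModel(d = d, components = pair), 5)
  prof <- fourierSynthesis(sf)
  fit <- fitGaussianComponents(prof, data.frame(center = 3, fwhm = 10, area = 0.7))
  expect_equal(fit$center, 1.87, tolerance = 1e-6)
  expect_equal(fit$fwhm, 15, tolerance = 1e-6)
  expect_equal(fit$area, 1, tolerance = 1e-6)

  ## single centered component
  single <- data.frame(name = "c", center = 0, sigma = 3, area0 = 2,
                       areaX = 0, pair = FALSE)
  sfs <- forwardStructureFactors(bilayerModel(d = d, components = single), 5)
  fit1 <- fitGaussianComponents(fourierSynthesis(sfs),
                                data.frame(center = 0, fwhm = 9, area = 1,
                                           fixCenter = TRUE))
  expect_equal(fit1$fwhm, 2.3548 * 3, tolerance = 1e-6)
  expect_equal(fit1$area, 2, tolerance = 1e-6)

  ## fitting in structure-factor space gives the same solution
  sf5 <- sf; sf5@sd <- rep(0.01, 5)
  fitF <- fitGaussianComponents(sf5, data.frame(center = 3, fwhm = 10, area = 0.7))
  expect_equal(fitF$center, 1.87, tolerance = 1e-6)
})

test_that("overlapped components carry larger uncertainties than separated", {
  d <- 60
  mk <- function(z0) {
    cmp <- data.frame(name = c("a", "b"), center = c(z0, 22),
                      sigma = c(3, 3), area0 = c(1, 1), areaX = 0,
                      pair = TRUE)
    sf <- forwardStructureFactors(bilayerModel(d = d, components = cmp), 8)
    sf@sd <- rep(0.02, 8)
    fitGaussianComponents(sf, data.frame(center = c(z0, 22) + 0.5,
                                         fwhm = c(7, 7), area = c(0.9, 0.9)))
  }
  sep <- mk(5)        # well separated from the 22-Angstrom component
  ovl <- mk(18)       # heavily overlapped
  expect_gt(ovl$centerSd[1], sep$centerSd[1])
})

test_that("MC resampling is reproducible, homogeneous and flags failures", {
  d <- 54.9
  pair <- data.frame(name = "label", center = 1.87, sigma = 15 / 2.3548,
                     area0 = 1, areaX = 0, pair = TRUE)
  sf <- forwardStructureFactors(bilayerModel(d = d, components = pair), 5)
  fitFun <- function(s) {
    f <- fitGaussianComponents(s, data.frame(center = 1.87, fwhm = 15, area = 1),
                               maxRestarts = 0)
    c(center = f$center[1], fwhm = f$fwhm[1])
  }
  ## zero sds: ensemble SD 0, means equal the point estimate
  sf0 <- sf; sf0@sd <- rep(1e-15, 5)
  mc0 <- mcResample(sf0, fitFun, nMock = 20, seed = 2)
  expect_equal(unname(mc0$sd), c(0, 0), tolerance = 1e-6)
  expect_equal(unname(mc0$mean[["center"]]), 1.87, tolerance = 1e-4)

  ## same seed twice: identical draws
  sfN <- sf; sfN@sd <- 0.02 * abs(sf@f)
  m1 <- mcResample(sfN, fitFun, nMock = 30, seed = 5)
  m2 <- mcResample(sfN, fitFun, nMock = 30, seed = 5)
  expect_identical(m1$draws, m2$draws)

  ## homogeneity: doubling input sds roughly doubles ensemble SDs
  sfH <- sf; sfH@sd <- 0.01 * abs(sf@f)
  sfH2 <- sf; sfH2@sd <- 0.02 * abs(sf@f)
  s1 <- mcResample(sfH, fitFun, nMock = 60, seed = 7)$sd[["fwhm"]]
  s2 <- mcResample(sfH2, fitFun, nMock = 60, seed = 7)$sd[["fwhm"]]
  expect_equal(s2 / s1, 2, tolerance = 0.35)

  ## chronic downstream failure is flagged (and total failure is an error)
  k <- 0
  flaky <- function(s) { k <<- k + 1; if (k %% 2 == 0) stop("boom"); c(a = 1) }
  mcF <- mcResample(sfN, flaky, nMock = 10, seed = 1, maxFailFraction = 0.2)
  expect_true(mcF$flagged)
  expect_error(mcResample(sfN, function(s) stop("boom"), nMock = 5, seed = 1),
               "all mock fits failed")
})

test_that("waters-per-peptide accounting matches the closed form", {
  deltaB <- 1.041e-4
  ## no excess water: B accounts exactly for the headgroup baseline
  wq0 <- watersPerPeptide(B = 2 * 9.4 * deltaB, x = 1, peptidePerLipid = 1 / 25,
                          nExchangeable = 0, nExchangeableSd = 0)
  expect_equal(wq0@watersPerPeptide, 0)
  ## closed-form oracle on 20 random tuples
  set.seed(12)
  for (i in 1:20) {
    r <- runif(1, 1 / 100, 1 / 10); x <- runif(1, 0.3, 1)
    wL <- runif(1, 5, 12); Nx <- runif(1, 20, 80); B <- runif(1, 1e-3, 5e-3)
    wq <- watersPerPeptide(B, x, r, wL, Nx)
    expect_equal(wq@watersPerPeptide,
                 (B / (x * deltaB) - Nx * r - 2 * wL) / (2 * r),
                 tolerance = 1e-12)
  }
  ## linear in B; halves when r doubles at fixed excess
  w1 <- watersPerPeptide(3e-3, 1, 1 / 25)@watersPerPeptide
  w2 <- watersPerPeptide(6e-3, 1, 1 / 25)@watersPerPeptide
  w3 <- watersPerPeptide(3e-3, 1, 1 / 25, watersPerLipid = 0,
                         nExchangeable = 0)@watersPerPeptide
  w4 <- watersPerPeptide(3e-3, 1, 2 / 25, watersPerLipid = 0,
                         nExchangeable = 0)@watersPerPeptide
  expect_gt(w2, w1)
  expect_equal(w4, w3 / 2, tolerance = 1e-12)
  ## negative counts are flagged but reported
  wneg <- watersPerPeptide(1e-5, 1, 1 / 25)
  expect_true("negative.water" %in% flags(wneg))
  expect_lt(wneg@watersPerPeptide, 0)
})

test_that("the full forward/inverse loop reproduces the generating profile", {
  m <- bilayerModel(d = 54.9)
  ## forward -> render -> reduce -> (re)sign -> synthesize
  sfTrue <- forwardStructureFactors(m, hmax = 5, x = 0)
  pat <- renderPattern(sfTrue, peakFwhmQ = 0.005, totalCounts = 5e6, seed = 31)
  lat <- indexAndFitLattice(detectPeaks(pat))
  expect_lt(abs(lat@d - 54.9) / 54.9, 0.001)
  red <- suppressWarnings(integrateStructureFactors(pat, lat))
  ## per-order amplitude check against planting (relative scale)
  scale <- red@f[which(red@h == 1)] / abs(sfTrue@f[1])
  ok <- abs(red@f - abs(sfTrue@f[red@h]) * scale) <= 3 * red@sd +
    0.03 * abs(sfTrue@f[red@h]) * scale
  expect_gte(mean(ok), 0.9)
  ## attach the true signs and synthesize: matches the model profile
  red@f <- red@f * sign(sfTrue@f[red@h])
  red@signed <- TRUE
  red@d <- 54.9
  prof <- fourierSynthesis(red)
  ref <- fourierSynthesis(sfTrue)
  expect_gt(cor(prof@rho, ref@rho), 0.999)
})

test_that("structure-factor files round trip with contrast metadata", {
  s <- structureFactorSet(54.9, 1:5, c(1, -0.5, 0.2, -0.1, 0.05),
                          rep(0.01, 5), d2oFraction = 0.5,
                          d7Fraction = 5 / 6, signed = TRUE)
  tmp <- tempfile(fileext = ".csv")
  writeStructureFactorSet(s, tmp)
  b <- readStructureFactorSet(tmp)
  expect_equal(b@f, s@f, tolerance = 1e-7)
  expect_equal(b@d2oFraction, 0.5)
  expect_equal(b@d7Fraction, 5 / 6, tolerance = 1e-6)
  expect_true(b@signed)
  unlink(tmp)
})
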