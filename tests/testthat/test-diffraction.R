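test_that("Q from theta follows the specular Bragg geometry", {
  expect_equal(qFromTheta(0, 1.54), 0)
  ## invert numerically and round trip at the neutron-relevant angle
  th <- thetaFromQ(2 * pi / 54.9, 1.54)
  expect_equal(th, 0.804, tolerance = 1e-3)
  expect_equal(qFromTheta(th, 1.54), 2 * pi / 54.9, tolerance = 1e-12)
  ## doubling the wavelength halves Q at small angle
  expect_equal(qFromTheta(0.3, 3.08), qFromTheta(0.3, 1.54) / 2)
  expect_true(all(diff(qFromTheta(seq(0.1, 10, 0.1), 1.54)) > 0))
  expect_error(qFromTheta(-1, 1.54), "theta")
})

test_that("flat noise yields no peaks; a single peak is found precisely", {
  set.seed(4)
  flat <- diffractionPattern(seq(0.05, 0.6, length.out = 1000),
                             rpois(1000, 100), wavelength = 5)
  expect_equal(nrow(detectPeaks(flat)), 0)

  one <- testLatticeSet(54.9, f = 1)
  pat <- renderPattern(one, peakFwhmQ = 0.005, totalCounts = 5e5, seed = 2)
  pk <- detectPeaks(pat)
  expect_equal(nrow(pk), 1)
  expect_lt(abs(pk$center - 2 * pi / 54.9) / (2 * pi / 54.9), 0.002)
  expect_equal(pk$fwhm, 0.005, tolerance = 0.05)
})

test_that("five rendered orders are recovered with areas within 5 percent", {
  sf <- testLatticeSet(54.9)
  pat <- renderPattern(sf, peakFwhmQ = 0.005, totalCounts = 2e6, seed = 3)
  pk <- detectPeaks(pat)
  expect_equal(nrow(pk), 5)
  gt <- groundTruth(pat)
  ## planted per-peak counts: intensity share of each |F|^2
  I <- gt$absF^2
  planted <- (1 - gt$backgroundFraction) * gt$totalCounts * I / sum(I)
  expect_lt(max(abs(pk$area - planted) / planted), 0.05)
})

test_that("lattice indexing and regression recover repeat spacings", {
  ## one peak: d = 2 pi / Q exactly
  lat1 <- indexAndFitLattice(2 * pi / 53.2)
  expect_equal(lat1@d, 53.2)
  ## exact five orders at 53.2 Angstrom
  lat <- indexAndFitLattice(2 * pi * (1:5) / 53.2)
  expect_equal(lat@d, 53.2, tolerance = 1e-12)
  expect_equal(lat@orders, 1:5)
  ## alternate-order absences index correctly
  lodd <- indexAndFitLattice(2 * pi * c(1, 3, 5) / 53.2)
  expect_equal(lodd@orders, c(1L, 3L, 5L))
  expect_equal(lodd@d, 53.2, tolerance = 1e-12)
  ## extinct first order
  lex <- indexAndFitLattice(2 * pi * (2:5) / 53.2)
  expect_equal(lex@orders, 2:5)
  expect_equal(lex@d, 53.2, tolerance = 1e-12)
})

test_that("d uncertainty shrinks with the number of orders", {
  set.seed(11)
  jitterSd <- 2e-4
  dsd <- vapply(c(3, 10), function(k) {
    reps <- vapply(1:30, function(i) {
      q <- 2 * pi * (1:k) / 54 + rnorm(k, 0, jitterSd)
      indexAndFitLattice(q)@dSd
    }, numeric(1))
    median(reps)
  }, numeric(1))
  expect_gt(dsd[1], dsd[2])
})

test_that("two-lattice deconvolution matches the brute-force oracle", {
  set.seed(21)
  for (i in 1:12) {
    dA <- runif(1, 50, 62)
    dB <- dA + runif(1, 1.5, 6)
    hA <- c(1, sort(sample(2:5, 2)))
    hB <- c(1, sort(sample(2:5, 2)))
    q <- c(2 * pi * hA / dA, 2 * pi * hB / dB) + rnorm(6, 0, 1e-5)
    ours <- deconvolveTwoLattices(q, bicMargin = 0)
    oracle <- bruteTwoLattices(q)
    expect_true(ours$split)
    dOurs <- sort(vapply(ours$lattices, repeatSpacing, numeric(1)))
    dOrac <- sort(c(oracle$dA, oracle$dB))
    expect_equal(dOurs, dOrac, tolerance = 1e-3)
  }
})

test_that("single lattices and degenerate splits are flagged", {
  q <- 2 * pi * (1:5) / 54.9 + c(1e-5, -1e-5, 2e-5, 0, -2e-5)
  dec <- deconvolveTwoLattices(q)
  expect_false(dec$split)
  expect_true("no.split.detected" %in% flags(dec$lattices[[1]]))

  ## two lattices with (near-)identical d: degenerate
  q2 <- c(2 * pi * (1:3) / 55, 2 * pi * (1:3) / 55.05 + 1e-6)
  dec2 <- deconvolveTwoLattices(q2, bicMargin = 0, degenerateTolerance = 0.5)
  if (dec2$split)
    expect_true("degenerate.split" %in% flags(dec2$lattices[[1]]))
})

test_that("superposed rendered lattices are separated to 0.2 Angstrom", {
  pat <- generateTwoPhasePattern(58.6, 55.3, weight = 0.5, seed = 4)
  dec <- deconvolveTwoLattices(detectPeaks(pat))
  expect_true(dec$split)
  ds <- vapply(dec$lattices, repeatSpacing, numeric(1))
  expect_equal(ds[1], 58.6, tolerance = 0.2 / 58.6)
  expect_equal(ds[2], 55.3, tolerance = 0.2 / 55.3)
  ## weight 0 reduces to a single lattice
  pat0 <- generateTwoPhasePattern(58.6, 55.3, weight = 0, seed = 5)
  dec0 <- deconvolveTwoLattices(detectPeaks(pat0))
  expect_false(dec0$split)
  expect_equal(dec0$lattices[[1]]@d, 58.6, tolerance = 0.01 / 58.6)
})

test_that("structure-factor integration follows Poisson propagation", {
  ## clean single peak of known integrated counts on zero background:
  ## amplitude = sqrt(area), sd = sqrt(area)/(2 amplitude) = 0.5 for 400
  q <- seq(0.08, 0.16, length.out = 400)
  sig <- 0.002
  counts <- 400 * dnorm(q, 2 * pi / 54.9, sig) * (q[2] - q[1])
  pat <- diffractionPattern(q, counts, wavelength = 5)
  lat <- indexAndFitLattice(data.frame(center = 2 * pi / 54.9,
                                       centerSd = 1e-5, fwhm = 2.3548 * sig))
  sfs <- integrateStructureFactors(pat, lat, hmax = 1,
                                   windowHalfWidth = 6 * sig)
  expect_equal(sfs@f, 20, tolerance = 0.02)
  expect_equal(sfs@sd, 0.5, tolerance = 0.1)

  ## homogeneity: doubling all areas scales amplitudes by sqrt(2)
  pat2 <- diffractionPattern(q, 2 * counts, wavelength = 5)
  sfs2 <- integrateStructureFactors(pat2, lat, hmax = 1,
                                    windowHalfWidth = 6 * sig)
  expect_equal(sfs2@f / sfs@f, sqrt(2), tolerance = 0.01)

  ## zero area -> amplitude 0
  pat0 <- diffractionPattern(q, rep(0, length(q)), wavelength = 5)
  sfs0 <- integrateStructureFactors(pat0, lat, hmax = 1,
                                    windowHalfWidth = 6 * sig)
  expect_equal(sfs0@f, 0)
})

test_that("reduction round trip recovers d and relative amplitudes", {
  sf <- testLatticeSet(57)
  pat <- renderPattern(sf, peakFwhmQ = 0.005, totalCounts = 2e6, seed = 9)
  pk <- detectPeaks(pat)
  lat <- indexAndFitLattice(pk)
  expect_lt(abs(lat@d - 57) / 57, 0.001)
  red <- integrateStructureFactors(pat, lat)
  ## relative |F| within noise-propagated error bars on >= 90% of orders
  scale <- red@f[1] / sf@f[1]
  ok <- abs(red@f - sf@f * scale) <= 3 * red@sd + 0.02 * sf@f * scale
  expect_gte(mean(ok), 0.9)
})

test_that("pattern text files round trip with metadata", {
  sf <- testLatticeSet(54.9)
  pat <- renderPattern(sf, totalCounts = 1e5, seed = 1)
  tmp <- tempfile(fileext = ".dat")
  writeDiffractionPattern(pat, tmp)
  back <- readDiffractionPattern(tmp)
  expect_equal(back@q, pat@q, tolerance = 1e-6)
  expect_equal(back@counts, pat@counts, tolerance = 1e-6)
  expect_equal(back@wavelength, 5)
  ## 2-theta convention converts through the declared wavelength
  th2 <- 2 * thetaFromQ(pat@q, 1.54)
  writeLines(c("# units = twotheta", "# wavelength = 1.54",
               sprintf("%.8g %.8g", th2, pat@counts)), tmp)
  back2 <- readDiffractionPattern(tmp)
  expect_equal(back2@q, pat@q, tolerance = 1e-6)
  unlink(tmp)
})
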