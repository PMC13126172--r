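test_that("generators are bit-reproducible under a fixed seed", {
  tr <- bindingParameters(1.9e-6, 25, 13)
  c1 <- generateTitration(tr, seed = 7)
  c2 <- generateTitration(tr, seed = 7)
  expect_identical(titrationPoints(c1), titrationPoints(c2))

  m <- bilayerModel()
  p1 <- renderPattern(forwardStructureFactors(m, 5), seed = 3)
  p2 <- renderPattern(forwardStructureFactors(m, 5), seed = 3)
  expect_identical(p1@counts, p2@counts)

  s1 <- generateContrastSeries(m, seed = 4)
  s2 <- generateContrastSeries(m, seed = 4)
  expect_identical(structureFactors(s1), structureFactors(s2))

  f1 <- generateHydrationFrames(3, 20, seed = 5)
  f2 <- generateHydrationFrames(3, 20, seed = 5)
  expect_identical(f1$frames[[1]]$water, f2$frames[[1]]$water)
})

test_that("noise-free titrations lie exactly on the forward model", {
  tr <- bindingParameters(11.2e-6, 19, 14.7)
  cur <- generateTitration(tr, noiseSd = 0, seed = 1)
  pts <- titrationPoints(cur)
  fb <- fractionBound(pts$lipidConc, pts$peptideConc, tr)
  expect_equal(pts$nmre, predictNMRE(fb, tr), tolerance = 1e-12)
  ## saturating toward the planted nMRE_max
  expect_gt(max(pts$nmre), 0.8 * 14.7)
  expect_lt(max(pts$nmre), 14.7)
})

test_that("every generator records a ground-truth audit", {
  tr <- bindingParameters(1.9e-6, 25, 13)
  expect_equal(groundTruth(generateTitration(tr, seed = 1))$nLipids, 25)
  m <- bilayerModel(watersPerPeptide = 114)
  expect_equal(groundTruth(m)$watersPerPeptide, 114)
  ser <- generateContrastSeries(m, seed = 2)
  expect_true(is.matrix(groundTruth(ser)$trueSigns))
  pat <- generateTwoPhasePattern(58.6, 55.3, seed = 3)
  expect_equal(groundTruth(pat)$d1, 58.6)
  fr <- generateHydrationFrames(c(3, 4), c(10, 20), seed = 4)
  expect_equal(fr$groundTruth$shellCounts, c(10, 20))
})

test_that("rendered patterns behave in limiting cases", {
  ## zero structure factors: pure background
  s0 <- structureFactorSet(54.9, 1:5, rep(0, 5), rep(1e-9, 5), signed = TRUE)
  pat0 <- renderPattern(s0, totalCounts = 1e5, qRange = c(0.05, 0.6), seed = 2)
  expect_lt(diff(range(tapply(pat0@counts, cut(pat0@q, 10), mean))), 30)
  ## infinite-counts limit: smooth analytic curve, no sampling
  s <- testLatticeSet(54.9)
  smooth <- renderPattern(s, totalCounts = 1e6, seed = NULL)
  expect_equal(smooth@counts, renderPattern(s, totalCounts = 1e6, seed = NULL)@counts)
  expect_false(all(smooth@counts == round(smooth@counts)))
})

test_that("contrast series strip signs but log them as truth", {
  m <- bilayerModel()
  ser <- generateContrastSeries(m, seed = 11)
  for (s in ser@sets) {
    expect_false(s@signed)
    expect_true(all(s@f >= 0))
  }
  tr <- groundTruth(ser)$trueSigns
  fTrue <- forwardStructureFactors(m, 5, x = 0)@f
  expect_equal(tr[, 1], sign(fTrue))
})

test_that("zero-jitter hydration frames recover exact planted counts", {
  fr <- generateHydrationFrames(shellRadii = c(3, 4.3), shellCounts = c(31, 75),
                                jitter = 0, nFrames = 1, seed = 6)
  d <- sqrt(rowSums(fr$frames[[1]]$water^2))
  expect_equal(sum(abs(d - 3) < 1e-9), 31)
  expect_equal(sum(abs(d - 4.3) < 1e-9), 75)
})
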