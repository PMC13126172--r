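test_that("g(r) approaches 1 for ideal-gas waters around a point solute", {
  set.seed(3)
  rmax <- 10
  frames <- lapply(1:4, function(f) {
    ## uniform points in the analysis sphere
    n <- 4000
    r <- rmax * runif(n)^(1 / 3)
    u <- runif(n, -1, 1); phi <- runif(n, 0, 2 * pi)
    s <- sqrt(1 - u^2)
    list(solute = matrix(0, 1, 3),
         water = cbind(r * s * cos(phi), r * s * sin(phi), r * u),
         frameId = f)
  })
  g <- radialDistribution(frames, rMax = rmax, binWidth = 0.5)
  outer <- g$g[g$r > 3]
  expect_lt(max(abs(outer - 1)), 0.15)
})

test_that("planted shells appear as g(r) maxima at the planted radii", {
  fr <- generateHydrationFrames(shellRadii = 3.0, shellCounts = 200,
                                jitter = 0.05, nFrames = 3, seed = 2)
  g <- radialDistribution(fr$frames, rMax = 6, binWidth = 0.25)
  expect_equal(g$r[which.max(g$g)], 3.0, tolerance = 0.25)
})

test_that("binned counts conserve direct distance counts", {
  fr <- generateHydrationFrames(shellRadii = c(3, 4.5), shellCounts = c(40, 80),
                                jitter = 0.2, nFrames = 2, nBulk = 100, seed = 4)
  for (bw in c(0.2, 0.4)) {
    g <- radialDistribution(fr$frames, rMax = 8, binWidth = bw)
    direct <- mean(vapply(fr$frames, function(f)
      sum(sqrt(rowSums(f$water^2)) <= 8), numeric(1)))
    expect_equal(sum(g$count), direct, tolerance = 1e-9)
  }
})

test_that("shell boundaries bracket planted shells and stay increasing", {
  fr <- generateHydrationFrames(shellRadii = c(3, 5), shellCounts = c(150, 250),
                                jitter = 0.15, nFrames = 4, seed = 6)
  g <- radialDistribution(fr$frames, rMax = 8, binWidth = 0.2)
  b <- shellBoundaries(g, nShells = 2)
  expect_gte(nrow(b), 1)
  expect_true(all(diff(b$radius) > 0))
  expect_true(b$radius[1] > 3 && b$radius[1] < 5)

  ## monotone g: no boundaries, flagged short
  gm <- data.frame(r = seq(0.1, 5, 0.1), g = seq(0.1, 5, 0.1))
  bm <- shellBoundaries(gm, nShells = 2)
  expect_equal(nrow(bm), 0)
  expect_true(attr(bm, "short"))
})

test_that("cumulative shell counts are exact on noise-free frames", {
  fr <- generateHydrationFrames(shellRadii = c(2.5, 3.7), shellCounts = c(31, 75),
                                jitter = 0, nFrames = 3, seed = 8)
  cw <- countWatersInShells(fr$frames, c(3.0, 4.3))
  expect_equal(cw$waterCount, c(31, 106))
  ## identical frames: zero SD over frames
  expect_equal(cw$waterCountSd, c(0, 0))
  ## counts monotone nondecreasing across shells; nothing inside tiny radius
  expect_true(all(diff(cw$waterCount) >= 0))
  expect_equal(countWatersInShells(fr$frames, 1.0)$waterCount, 0)
})

test_that("distance conventions and periodic boxes are honoured", {
  sol <- rbind(c(0, 0, 0), c(10, 0, 0))
  wat <- rbind(c(3, 0, 0), c(13, 0, 0))
  fr <- list(list(solute = sol, water = wat, frameId = 1))
  ## nearest-atom: both waters at distance 3; center-of-mass (5,0,0): 2 and 8
  cn <- countWatersInShells(fr, c(4))
  expect_equal(cn$waterCount, 2)
  cc <- countWatersInShells(fr, c(4), convention = "com")
  expect_equal(cc$waterCount, 1)
  ## minimum image: water at 19 is 1 away from origin under a 20-box
  fr2 <- list(list(solute = matrix(0, 1, 3),
                   water = matrix(c(19, 0, 0), 1, 3), frameId = 1))
  expect_equal(countWatersInShells(fr2, 2, box = c(20, 20, 20))$waterCount, 1)
})

test_that("XYZ frames round trip through files", {
  fr <- generateHydrationFrames(shellRadii = 3, shellCounts = 12,
                                nFrames = 2, seed = 9)
  tmp <- tempfile(fileext = ".xyz")
  writeXYZFrames(fr$frames, tmp)
  back <- readXYZFrames(tmp, soluteLabels = "P")
  expect_length(back, 2)
  expect_lt(max(abs(back[[1]]$water - fr$frames[[1]]$water)), 1e-3)
  expect_equal(nrow(back[[2]]$solute), 1)
  unlink(tmp)
})
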