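test_that("fractionBound solves the implicit binding relation", {
  p <- bindingParameters(kd = 2e-6, nLipids = 25, nmreMax = 13)
  ## no lipid, nothing bound; stoichiometric limit at K_D = 0
  expect_equal(fractionBound(0, 20e-6, p), 0)
  p0 <- bindingParameters(kd = 0, nLipids = 25, nmreMax = 13)
  expect_equal(fractionBound(500e-6, 20e-6, p0), 1)
  expect_equal(fractionBound(250e-6, 20e-6, p0), 0.5)

  ## bisection oracle on the printed relation
  fb <- fractionBound(500e-6, 20e-6, p)
  expect_equal(fb, bisectFractionBound(500e-6, 20e-6, 2e-6, 25),
               tolerance = 1e-9)
  expect_equal(round(fb, 3), 0.730)

  ## substituting back reproduces C_Lt to 1e-10 relative
  grid <- seq(1e-6, 2e-3, length.out = 40)
  f <- fractionBound(grid, 20e-6, p)
  back <- p$nLipids * f * (1 + p$kd / (20e-6 * (1 - f))) * 20e-6
  expect_lt(max(abs(back - grid) / grid), 1e-10)
})

test_that("fractionBound agrees with bisection on 1000 random draws", {
  set.seed(42)
  for (i in 1:1000) {
    kd <- 10^runif(1, -8, -3)
    n <- runif(1, 2, 100)
    cPt <- 10^runif(1, -6, -4)
    cLt <- 10^runif(1, -6, -2)
    p <- bindingParameters(kd, n, 10)
    expect_equal(fractionBound(cLt, cPt, p),
                 bisectFractionBound(cLt, cPt, kd, n),
                 tolerance = 1e-7)
  }
})

test_that("fractionBound is monotone in lipid and in K_D", {
  cPt <- 20e-6
  grid <- seq(0, 2e-3, length.out = 60)
  p <- bindingParameters(5e-6, 20, 10)
  f <- fractionBound(grid, cPt, p)
  expect_true(all(diff(f) >= -1e-12))
  kds <- 10^seq(-8, -3, length.out = 30)
  fk <- vapply(kds, function(k)
    fractionBound(5e-4, cPt, bindingParameters(k, 20, 10)), numeric(1))
  expect_true(all(diff(fk) <= 1e-12))
})

test_that("inputs are validated with a named message", {
  p <- bindingParameters(2e-6, 25, 13)
  expect_error(fractionBound(-1e-6, 20e-6, p), "cLt")
  expect_error(fractionBound(1e-6, 0, p), "cPt")
  expect_error(bindingParameters(-1, 25, 13), "kd")
  expect_error(bindingParameters(1e-6, 0, 13), "nLipids")
  expect_error(bindingParameters(1e-6, 25, 1), "nmreMax")
})

test_that("predictNMRE is the inverted linear bound-fraction relation", {
  p <- bindingParameters(2e-6, 25, 13)
  expect_equal(predictNMRE(0, p), 1)
  expect_equal(predictNMRE(1, p), 13)
  expect_equal(predictNMRE(0.5, bindingParameters(2e-6, 25, 3)), 2)
  fb <- seq(0, 1, 0.05)
  expect_true(all(diff(predictNMRE(fb, p)) > 0))
  expect_error(predictNMRE(1.2, p), "0, 1")
})

test_that("millidegree-to-MRE conversion is the standard formula", {
  expect_equal(mreFromMillidegrees(-100, 0.1, 20e-6, 25), -2e5)
  expect_equal(mreFromMillidegrees(0, 0.1, 20e-6, 25), 0)
  ## doubling concentration halves MRE
  expect_equal(mreFromMillidegrees(-100, 0.1, 40e-6, 25),
               mreFromMillidegrees(-100, 0.1, 20e-6, 25) / 2)
  expect_error(mreFromMillidegrees(-100, 0, 20e-6, 25), "pathLength")
})

test_that("dilution schedule and normalization follow cumulative volumes", {
  sch <- dilutionSchedule(300, rep(10, 20))
  expect_equal(nrow(sch), 21)
  expect_equal(sch$dilutionFactor[21], 0.6)  # 300/500
  expect_equal(sch$dilutionFactor[1], 1)
  ## no titrant: factors all 1
  sch0 <- dilutionSchedule(300, rep(0, 6))
  expect_true(all(sch0$dilutionFactor == 1))
  expect_true(all(sch0$lipidFactor == 0))

  ## raw signal equal to buffer at every step -> nmre identically 1
  cur <- normalizeCurve(rep(-8000, 21), bufferMre222 = -8000,
                        peptideConc = 20e-6, titrantLipidConc = 3e-3,
                        schedule = sch)
  expect_true(all(abs(titrationPoints(cur)$nmre - 1) < 1e-12))
  ## peptide-to-lipid molar range of the default schedule: 1:5 to 1:100
  pts <- titrationPoints(cur)
  pl <- pts$lipidConc[-1] / pts$peptideConc[-1]
  expect_equal(pl[1], 5, tolerance = 1e-6)
  expect_equal(pl[length(pl)], 100, tolerance = 1e-6)

  ## opposite-sign buffer reference is flagged
  cur2 <- normalizeCurve(rep(8000, 21), bufferMre222 = -8000,
                         peptideConc = 20e-6, titrantLipidConc = 3e-3,
                         schedule = sch)
  expect_true("buffer.sign.mismatch" %in% flags(cur2))
})

test_that("percent helicity interpolates between baselines and clips", {
  expect_equal(percentHelicity(640 - 45 * 25, 25), 0)
  h100 <- -40000 * (1 - 2.5 / 25) + 100 * 25
  expect_equal(percentHelicity(h100, 25), 100)
  mid <- (h100 + 640 - 45 * 25) / 2
  expect_equal(percentHelicity(mid, 25), 50)
  expect_equal(percentHelicity(-1e6, 25), 100)  # clipped
  expect_error(percentHelicity(0, 25, mreHelix = 1, mreCoil = 1), "degenerate")
})

test_that("noise-free synthetic curves are recovered within 1 percent", {
  truth <- bindingParameters(1.9e-6, 25, 13.0)
  cur <- generateTitration(truth, noiseSd = 0, seed = 1)
  fit <- fitBinding(cur, nGenerations = 1500, seed = 3)
  m <- posteriorMedians(fit)
  expect_lt(abs(m[["kd"]] - truth$kd) / truth$kd, 0.01)
  expect_lt(abs(m[["nLipids"]] - truth$nLipids) / truth$nLipids, 0.01)
  expect_lt(abs(m[["nmreMax"]] - truth$nmreMax) / truth$nmreMax, 0.01)
})

test_that("flat titrations are flagged as no binding, not fitted", {
  sch <- dilutionSchedule(300, rep(10, 20))
  set.seed(8)
  cur <- normalizeCurve(rnorm(21, -8000, 30), bufferMre222 = -8000,
                        peptideConc = 20e-6, titrantLipidConc = 3e-3,
                        schedule = sch)
  fit <- fitBinding(cur, seed = 1)
  expect_true("no.binding.detected" %in% flags(fit))
  expect_equal(nrow(posteriorSamples(fit)), 0)
})

test_that("fits are deterministic given a seed", {
  truth <- bindingParameters(1.9e-6, 25, 13.0)
  cur <- generateTitration(truth, noiseSd = 0.3, seed = 5)
  f1 <- fitBinding(cur, nGenerations = 800, seed = 11)
  f2 <- fitBinding(cur, nGenerations = 800, seed = 11)
  expect_identical(posteriorSamples(f1), posteriorSamples(f2))
})

test_that("68 percent intervals cover the planted K_D in at least half of runs", {
  ## desk-scale coverage sanity: 12 noisy curves per planted truth
  for (tr in list(c(kd = 11.2e-6, n = 19, mx = 14.7),
                  c(kd = 1.9e-6, n = 25, mx = 13.0))) {
    truth <- bindingParameters(tr[["kd"]], tr[["n"]], tr[["mx"]])
    hits <- vapply(1:12, function(s) {
      cur <- generateTitration(truth, noiseSd = 0.3, seed = 1000 + s)
      f <- fitBinding(cur, nGenerations = 3000, seed = 2000 + s)
      ci <- credibleInterval(f)
      ci["lower", "kd"] <= truth$kd && truth$kd <= ci["upper", "kd"]
    }, logical(1))
    expect_gte(mean(hits), 0.5)
  }
})

test_that("titration spectra read/extract round trip", {
  tmp <- tempfile(fileext = ".csv")
  w <- seq(200, 260, 2)
  m <- outer(-dnorm(w, 222, 8) * 1e4, seq(1, 3, length.out = 4))
  df <- data.frame(wavelength_nm = w, m)
  names(df) <- c("wavelength_nm", paste0("step", 1:4))
  write.csv(df, tmp, row.names = FALSE)
  sp <- readTitrationSpectra(tmp)
  expect_equal(dim(sp$steps), c(length(w), 4))
  ch <- extractChannel(sp, 222)
  expect_equal(ch, m[w == 222, ], ignore_attr = TRUE)
  ## smoothing preserves the broad channel value approximately
  chS <- extractChannel(sp, 222, smoothSd = 2)
  expect_equal(chS, ch, tolerance = 0.05)
  unlink(tmp)
})
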