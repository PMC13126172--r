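## Independent oracles used by the recovery tests. These deliberately avoid
## the package's own code paths: bisection instead of the closed-form root,
## plain enumeration instead of the package's search, direct quadrature
## instead of the closed-form transform.

## Bisection on the printed implicit relation
## C_Lt = n f (1 + K_D / (C_pt (1 - f))) C_pt over f in (0, 1).
bisectFractionBound <- function(cLt, cPt, kd, n, tol = 1e-14) {
  if (cLt == 0) return(0)
  g <- function(f) n * f * (1 + kd / (cPt * (1 - f))) * cPt - cLt
  lo <- 0; hi <- 1 - 1e-15
  if (g(hi) < 0) return(1)  # stoichiometric limit: root at/above 1
  for (i in 1:200) {
    mid <- (lo + hi) / 2
    if (g(mid) < 0) lo <- mid else hi <- mid
    if (hi - lo < tol) break
  }
  (lo + hi) / 2
}

## Exhaustive two-lattice assignment oracle: every subset split, every base
## order 1..3 per subset, unweighted residual, no shortcuts.
bruteTwoLattices <- function(qv) {
  n <- length(qv)
  qv <- sort(qv)
  ## plain base-1 indexing: the enumeration under test is the subset
  ## assignment, so oracle instances must contain each lattice's h = 1
  indexChi <- function(qs) {
    hv <- pmax(1, round(qs / qs[1]))
    slope <- sum(qs * hv) / sum(hv^2)
    list(chi = sum((qs - slope * hv)^2), d = 2 * pi / slope)
  }
  best <- NULL
  for (mask in 0:(2^(n - 1) - 1)) {
    inA <- c(TRUE, as.logical(bitwAnd(mask, 2^(0:(n - 2))) > 0))
    if (sum(inA) < 2 || n - sum(inA) < 2) next
    fA <- indexChi(qv[inA]); fB <- indexChi(qv[!inA])
    chi <- fA$chi + fB$chi
    if (is.null(best) || chi < best$chi)
      best <- list(chi = chi, inA = inA, dA = fA$d, dB = fB$d)
  }
  best
}

## Per-order sign-pattern enumeration oracle for contrast phasing
## ("linear" method semantics): weighted straight-line residual over all
## 2^(nx-1) patterns, slope sign anchored to (-1)^h.
enumPhaseOracle <- function(absF, sdF, xs, h) {
  nx <- length(xs)
  pats <- as.matrix(expand.grid(rep(list(c(1, -1)), nx - 1)))
  X <- cbind(1, xs)
  bestChi <- Inf; bestSigns <- NULL
  for (r in seq_len(nrow(pats))) {
    p <- c(1, pats[r, ])
    fv <- p * absF
    w <- 1 / sdF^2
    fit <- lm.wfit(X, fv, w)
    chi <- sum(w * fit$residuals^2)
    if (chi < bestChi) {
      bestChi <- chi
      sl <- fit$coefficients[2]
      want <- if (h %% 2 == 0) 1 else -1
      bestSigns <- if (sl != 0 && sign(sl) != want) -p else p
    }
  }
  bestSigns
}

## Direct quadrature of the cosine transform of a symmetric Gaussian
## component profile (with periodic images for boundary components).
quadratureF <- function(center, sigma, area, d, h) {
  rho <- function(z) {
    out <- 0
    for (i in seq_along(center)) {
      for (k in -2:2) {
        ## mirrored pair: half the area at +center, half at -center
        out <- out +
          area[i] / 2 * dnorm(z, center[i] + k * d, sigma[i]) +
          area[i] / 2 * dnorm(z, -center[i] + k * d, sigma[i])
      }
    }
    out
  }
  vapply(h, function(hh)
    pracma::integral(function(z) rho(z) * cos(2 * pi * hh * z / d),
                     -d / 2, d / 2, reltol = 1e-12),
    numeric(1))
}

## Shorthand for a clean five-order test lattice
testLatticeSet <- function(d, f = c(1, 0.8, 0.6, 0.5, 0.4)) {
  structureFactorSet(d = d, h = seq_along(f), f = f,
                     sd = rep(0.01, length(f)), signed = TRUE)
}
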