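## Differential-evolution ensemble MCMC (ter Braak style) for the
## modified-Langmuir binding model. Parameters are sampled in the
## transformed space (log10 K_D, n, nMRE_max, log sigma).

#' Default priors for the binding fit
#'
#' Log-uniform on K_D over [1e-9, 1e-2] mol/L, uniform on n over [1, 200],
#' uniform on nMRE_max over (1, 50], half-normal on the noise SD.
#'
#' @param kdRange numeric(2), K_D support in mol/L.
#' @param nRange numeric(2), lipids-per-peptide support.
#' @param nmreMaxRange numeric(2), saturation-nMRE support (lower bound 1).
#' @param noiseScale numeric(1), scale of the half-normal prior on the
#'   Gaussian noise SD (nMRE units).
#' @return list of prior settings consumed by \code{\link{fitBinding}}.
#' @export
bindingPriors <- function(kdRange = c(1e-9, 1e-2), nRange = c(1, 200),
                          nmreMaxRange = c(1, 50), noiseScale = 1) {
  list(log10kd = log10(kdRange), n = nRange, nmreMax = nmreMaxRange,
       noiseScale = noiseScale)
}

logPosteriorBinding <- function(theta, cLt, cPt, nmre, priors) {
  logPosteriorBindingMatrix(matrix(theta, 1), cLt, cPt, nmre, priors)[1]
}

## vectorized over rows of theta (one walker per row); columns are
## (log10 K_D, n, nMRE_max, log sigma)
logPosteriorBindingMatrix <- function(theta, cLt, cPt, nmre, priors) {
  l10kd <- theta[, 1]; n <- theta[, 2]; nmx <- theta[, 3]; lsig <- theta[, 4]
  sig <- exp(lsig)
  ok <- l10kd >= priors$log10kd[1] & l10kd <= priors$log10kd[2] &
    n >= priors$n[1] & n <= priors$n[2] &
    nmx > priors$nmreMax[1] & nmx <= priors$nmreMax[2] &
    is.finite(sig) & sig > 0 & sig <= 50
  out <- rep(-Inf, nrow(theta))
  if (!any(ok)) return(out)
  kd <- 10^l10kd[ok]; nOk <- n[ok]; nmxOk <- nmx[ok]; sigOk <- sig[ok]
  ## quadratic root of the implicit binding relation, all walkers at once
  A <- outer(nOk, cPt)                    # n C_pt
  C <- matrix(cLt, sum(ok), length(cLt), byrow = TRUE)
  B <- A + nOk * kd + C
  fb <- 2 * C / (B + sqrt(pmax(B * B - 4 * A * C, 0)))
  fb <- pmin(1, pmax(0, fb))
  mu <- 1 + fb * (nmxOk - 1)
  resid2 <- rowSums((matrix(nmre, sum(ok), length(nmre), byrow = TRUE) - mu)^2)
  npt <- length(nmre)
  ll <- -npt * log(sigOk) - 0.5 * npt * log(2 * pi) - resid2 / (2 * sigOk^2)
  ## half-normal prior on sigma with log-space Jacobian
  out[ok] <- ll - 0.5 * (sigOk / priors$noiseScale)^2 + lsig[ok]
  out
}

#' Fit the binding isotherm by differential-evolution ensemble MCMC
#'
#' Samples the posterior of (K_D, n, nMRE_max, noise SD) under a Gaussian
#' likelihood on the nMRE residuals of the forward model
#' (\code{\link{fractionBound}} then \code{\link{predictNMRE}}), using an
#' adaptive differential-evolution ensemble: each walker proposes jumps along
#' the difference of two randomly chosen other walkers (gamma =
#' 2.38/sqrt(2p), with unit-gamma mode-jumping generations), which adapts the
#' proposal scale and orientation to the posterior. Burn-in is discarded by
#' an integrated-autocorrelation-time heuristic and convergence is monitored
#' by the split-walker potential scale reduction (R-hat).
#'
#' Curves that never depart from the buffer baseline (nMRE approximately 1)
#' are not fit: the returned posterior carries the \code{no.binding.detected}
#' flag, mirroring compositions for which the isotherm is uninformative.
#'
#' @param curve a \linkS4class{TitrationCurve} with >= 6 points spanning at
#'   least a 4-fold range of lipid concentration.
#' @param priors list from \code{\link{bindingPriors}}.
#' @param nWalkers integer, ensemble size (>= 3x the 4 parameters; default 20).
#' @param nGenerations integer, generations per walker (default 6000). The
#'   posterior ridge between K_D and nMRE_max (titrations that stop short of
#'   full saturation) mixes slowly; the proposal scale gamma is adapted
#'   toward ~25\% acceptance during burn-in and frozen afterwards.
#' @param seed integer seed; the fit is deterministic given a seed.
#' @param rhatThreshold numeric(1), convergence threshold on R-hat
#'   (default 1.1).
#' @return a \linkS4class{BindingPosterior}.
#' @examples
#' tr <- bindingParameters(1.9e-6, 25, 13)
#' cur <- generateTitration(tr, noiseSd = 0, seed = 1)
#' fit <- fitBinding(cur, nGenerations = 600, seed = 1)
#' posteriorMedians(fit)
#' @export
fitBinding <- function(curve, priors = bindingPriors(), nWalkers = 20,
                       nGenerations = 6000, seed = 1, rhatThreshold = 1.1) {
  stopifnot(is(curve, "TitrationCurve"))
  p <- curve@points
  pos <- p$lipidConc > 0
  if (nrow(p) < 6) stop("curve must have >= 6 points", call. = FALSE)
  if (max(p$lipidConc[pos]) / min(p$lipidConc[pos]) < 4)
    stop("lipid concentrations must span at least a 4-fold range", call. = FALSE)

  nmre <- p$nmre
  ## flat-curve guard: compare the departure from baseline with the
  ## point-to-point noise level
  run3 <- stats::runmed(nmre, 3)
  signal <- max(run3) - 1
  noise <- stats::mad(diff(nmre)) / sqrt(2)
  if (signal < max(4 * noise, 0.15)) {
    return(new("BindingPosterior",
               samples = matrix(numeric(0), 0, 4,
                                dimnames = list(NULL, c("kd", "nLipids", "nmreMax", "noiseSd"))),
               medians = numeric(0),
               ci68 = matrix(numeric(0), 2, 0),
               diagnostics = list(noBinding = TRUE, converged = FALSE,
                                  acceptance = NA_real_, rhat = NA_real_,
                                  nWalkers = nWalkers, nGenerations = 0L,
                                  burnIn = 0L)))
  }

  set.seed(seed)
  np <- 4L
  gamma0 <- 2.38 / sqrt(2 * np)
  jitterSd <- c(0.05, 1, 0.25, 0.02) * 1e-2

  ## over-dispersed but data-informed initialization (priors stay full-range)
  halfLevel <- 1 + signal / 2
  iHalf <- which(run3 >= halfLevel)[1]
  lipHalf <- if (is.na(iHalf)) stats::median(p$lipidConc[pos]) else
    max(p$lipidConc[iHalf], min(p$lipidConc[pos]))
  nGuess <- max(1.5, min(150, lipHalf / stats::median(p$peptideConc)))
  init <- cbind(
    stats::runif(nWalkers, -7.5, -4.0),
    pmin(priors$n[2], pmax(priors$n[1], nGuess * exp(stats::runif(nWalkers, -0.8, 0.8)))),
    pmin(priors$nmreMax[2],
         pmax(priors$nmreMax[1] + 0.1,
              (1 + signal) * stats::runif(nWalkers, 0.85, 1.35))),
    log(pmax(noise, 0.02) * exp(stats::runif(nWalkers, -1, 1)))
  )

  lpFun <- function(th) logPosteriorBindingMatrix(th, p$lipidConc,
                                                  p$peptideConc, nmre, priors)
  lp <- lpFun(init)
  ## replace any -Inf starts
  bad <- !is.finite(lp)
  while (any(bad)) {
    init[bad, 1] <- stats::runif(sum(bad), -7, -5)
    init[bad, 4] <- log(0.3)
    lp[bad] <- lpFun(init[bad, , drop = FALSE])
    bad <- !is.finite(lp)
  }

  chain <- array(NA_real_, c(nGenerations, nWalkers, np))
  cur <- init
  nAccept <- 0L
  adaptUntil <- floor(nGenerations / 2)
  gamScale <- 1
  winAccept <- 0L
  half <- nWalkers %/% 2
  blocks <- list(seq_len(half), (half + 1):nWalkers)
  for (g in seq_len(nGenerations)) {
    gam <- if (g %% 10 == 0) 1 else gamma0 * gamScale
    ## update each half-ensemble using difference vectors drawn from the
    ## other half (keeps the synchronous vectorized update a valid MCMC)
    for (b in 1:2) {
      tgt <- blocks[[b]]; oth <- blocks[[3 - b]]
      nb <- length(tgt)
      r1 <- oth[sample.int(length(oth), nb, replace = TRUE)]
      r2 <- oth[sample.int(length(oth), nb, replace = TRUE)]
      while (any(eq <- r1 == r2))
        r2[eq] <- oth[sample.int(length(oth), sum(eq), replace = TRUE)]
      prop <- cur[tgt, , drop = FALSE] +
        gam * (cur[r1, , drop = FALSE] - cur[r2, , drop = FALSE]) +
        matrix(stats::rnorm(nb * np, 0, rep(jitterSd, each = nb)), nb, np)
      lpProp <- lpFun(prop)
      acc <- is.finite(lpProp) & log(stats::runif(nb)) < lpProp - lp[tgt]
      if (any(acc)) {
        cur[tgt[acc], ] <- prop[acc, , drop = FALSE]
        lp[tgt[acc]] <- lpProp[acc]
        nAccept <- nAccept + sum(acc)
        winAccept <- winAccept + sum(acc)
      }
    }
    chain[g, , ] <- cur
    ## adapt the proposal scale toward ~25% acceptance during burn-in only
    if (g <= adaptUntil && g %% 50 == 0) {
      rate <- winAccept / (50 * nWalkers)
      gamScale <- gamScale * exp(0.5 * (rate - 0.25))
      gamScale <- min(max(gamScale, 0.2), 3)
      winAccept <- 0L
    }
  }

  ## burn-in from the integrated autocorrelation time of the walker-mean
  ## traces, capped at half the run
  tau <- max(vapply(seq_len(np), function(j)
    autocorrTime(rowMeans(chain[, , j])), numeric(1)))
  burn <- min(ceiling(nGenerations / 2),
              max(ceiling(nGenerations / 5), ceiling(10 * tau)))
  kept <- (burn + 1L):nGenerations

  rhat <- vapply(seq_len(np), function(j) rhatWalkers(chain[kept, , j]), numeric(1))
  names(rhat) <- c("log10kd", "nLipids", "nmreMax", "logSigma")

  flat <- do.call(rbind, lapply(seq_len(nWalkers), function(w) chain[kept, w, ]))
  samples <- cbind(kd = 10^flat[, 1], nLipids = flat[, 2],
                   nmreMax = flat[, 3], noiseSd = exp(flat[, 4]))
  med <- apply(samples, 2, stats::median)
  ci <- apply(samples, 2, stats::quantile, probs = c(0.16, 0.84))
  rownames(ci) <- c("lower", "upper")

  new("BindingPosterior",
      samples = samples, medians = med, ci68 = ci,
      diagnostics = list(
        acceptance = nAccept / (nGenerations * nWalkers),
        rhat = rhat,
        converged = all(is.finite(rhat)) && max(rhat) < rhatThreshold,
        noBinding = FALSE,
        nWalkers = nWalkers,
        nGenerations = as.integer(nGenerations),
        burnIn = as.integer(burn),
        tau = tau,
        seed = seed))
}
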