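## Hydration-shell analysis of water positions around a solute point set.
## Distances use the nearest-solute-atom convention: each water's distance is
## the minimum over solute points, a surface-proximity measure appropriate
## for per-molecule hydration shells (a center-of-mass option is provided
## since published shell tables rarely state their convention).

nearestSoluteDistances <- function(frame, box = NULL,
                                   convention = c("nearest", "com")) {
  convention <- match.arg(convention)
  sol <- frame$solute
  wat <- frame$water
  if (!nrow(sol) || !nrow(wat)) stop("frame has empty coordinates", call. = FALSE)
  if (convention == "com") sol <- matrix(colMeans(sol), 1, 3)
  mindist <- rep(Inf, nrow(wat))
  for (i in seq_len(nrow(sol))) {
    dv <- sweep(wat, 2, sol[i, ])
    if (!is.null(box)) {
      for (k in 1:3) dv[, k] <- dv[, k] - box[k] * round(dv[, k] / box[k])
    }
    mindist <- pmin(mindist, sqrt(rowSums(dv^2)))
  }
  mindist
}

#' Radial distribution function of waters around a solute
#'
#' g(r) of water positions as a function of nearest-solute-atom distance,
#' averaged over frames and normalized by the ideal-gas density of water
#' points in the analysis volume (the periodic box when supplied, otherwise
#' a sphere of radius \code{rMax} around the solute).
#'
#' @param frames list of frames, each a list with numeric matrices
#'   \code{solute} and \code{water} (n x 3, Angstrom), as produced by
#'   \code{\link{generateHydrationFrames}} or \code{\link{readXYZFrames}}.
#' @param rMax numeric(1), largest distance binned (Angstrom).
#' @param binWidth numeric(1), bin width (Angstrom); \code{rMax} must exceed
#'   3 bins.
#' @param box optional numeric(3), periodic box lengths; minimum-image
#'   distances are used when given.
#' @param convention \code{"nearest"} (default) or \code{"com"} distance
#'   convention.
#' @return data.frame with columns \code{r} (bin centers), \code{g}, and
#'   \code{count} (mean waters per bin per frame).
#' @export
radialDistribution <- function(frames, rMax, binWidth, box = NULL,
                               convention = c("nearest", "com")) {
  convention <- match.arg(convention)
  checkScalar(binWidth, "binWidth", 0, strict = TRUE)
  if (rMax <= 3 * binWidth) stop("'rMax' must exceed 3 bin widths", call. = FALSE)
  if (!length(frames)) stop("no frames supplied", call. = FALSE)
  edges <- seq(0, rMax, by = binWidth)
  if (edges[length(edges)] < rMax) edges <- c(edges, rMax)
  mids <- (edges[-1] + edges[-length(edges)]) / 2
  counts <- matrix(0, length(frames), length(mids))
  dens <- numeric(length(frames))
  for (f in seq_along(frames)) {
    dd <- nearestSoluteDistances(frames[[f]], box, convention)
    counts[f, ] <- graphics::hist(dd[dd <= rMax], breaks = edges,
                                  plot = FALSE)$counts
    vol <- if (!is.null(box)) prod(box) else 4 / 3 * pi * rMax^3
    dens[f] <- nrow(frames[[f]]$water) / vol
  }
  shellVol <- 4 / 3 * pi * (edges[-1]^3 - edges[-length(edges)]^3)
  gMat <- sweep(counts, 2, shellVol, "/") / dens
  data.frame(r = mids, g = colMeans(gMat), count = colMeans(counts))
}

#' Hydration-shell boundary radii from g(r)
#'
#' Boundaries are the first \code{nShells} local minima of g(r) that follow
#' successive maxima. Boundary SDs are estimated by relocating each minimum
#' on bootstrap-resampled (noise-perturbed) copies of the curve.
#'
#' @param gCurve data.frame from \code{\link{radialDistribution}}.
#' @param nShells integer, requested number of boundaries (default 3).
#' @param nResample integer, resampling iterations for the SDs (default 50).
#' @param seed integer seed for the resampling.
#' @return data.frame with columns \code{shell}, \code{radius},
#'   \code{radiusSd}; fewer rows than requested (with attribute
#'   \code{"short"} = TRUE) when g has too few minima, zero rows for a
#'   monotone curve.
#' @export
shellBoundaries <- function(gCurve, nShells = 3, nResample = 50, seed = 1) {
  g <- gCurve$g; r <- gCurve$r
  locate <- function(g) {
    n <- length(g)
    ## indices of local minima that follow at least one maximum
    dmax <- which(diff(sign(diff(g))) < 0) + 1L
    dmin <- which(diff(sign(diff(g))) > 0) + 1L
    if (!length(dmax)) return(integer(0))
    dmin[dmin > min(dmax)]
  }
  mins <- locate(g)
  if (!length(mins)) {
    out <- data.frame(shell = integer(0), radius = numeric(0),
                      radiusSd = numeric(0))
    attr(out, "short") <- TRUE
    return(out)
  }
  mins <- mins[seq_len(min(nShells, length(mins)))]
  ## SDs by perturbing g with its sampling noise scale and relocating
  set.seed(seed)
  noiseScale <- stats::mad(diff(g)) / sqrt(2)
  reloc <- matrix(NA_real_, nResample, length(mins))
  for (b in seq_len(nResample)) {
    gb <- g + stats::rnorm(length(g), 0, noiseScale)
    mb <- locate(gb)
    for (k in seq_along(mins)) {
      if (!length(mb)) next
      reloc[b, k] <- r[mb[which.min(abs(r[mb] - r[mins[k]]))]]
    }
  }
  out <- data.frame(shell = seq_along(mins), radius = r[mins],
                    radiusSd = apply(reloc, 2, stats::sd, na.rm = TRUE))
  attr(out, "short") <- length(mins) < nShells
  out
}

#' Count waters within successive hydration shells
#'
#' Cumulative counts of waters whose nearest-solute distance lies below each
#' boundary radius, mean +/- SD over frames, by exact brute-force distance
#' evaluation.
#'
#' @param frames list of coordinate frames (see
#'   \code{\link{radialDistribution}}).
#' @param boundaries numeric, strictly increasing boundary radii (Angstrom),
#'   or the data.frame from \code{\link{shellBoundaries}}.
#' @param box,convention as in \code{\link{radialDistribution}}.
#' @return data.frame with columns \code{shell}, \code{boundary},
#'   \code{waterCount} (mean over frames), \code{waterCountSd}.
#' @export
countWatersInShells <- function(frames, boundaries, box = NULL,
                                convention = c("nearest", "com")) {
  convention <- match.arg(convention)
  if (is.data.frame(boundaries)) boundaries <- boundaries$radius
  if (any(diff(boundaries) <= 0))
    stop("boundaries must be strictly increasing", call. = FALSE)
  counts <- matrix(0, length(frames), length(boundaries))
  for (f in seq_along(frames)) {
    dd <- nearestSoluteDistances(frames[[f]], box, convention)
    counts[f, ] <- vapply(boundaries, function(b) sum(dd < b), numeric(1))
  }
  data.frame(shell = seq_along(boundaries), boundary = boundaries,
             waterCount = colMeans(counts),
             waterCountSd = apply(counts, 2, stats::sd))
}

#' Read XYZ coordinate frames with a solute/water label split
#'
#' Reads multi-frame XYZ (atom count line, comment line, then
#' \code{label x y z} records) and splits atoms into solute and water point
#' sets by label.
#'
#' @param path XYZ file path.
#' @param soluteLabels character, labels counted as solute.
#' @param waterLabels character, labels counted as water (default
#'   \code{c("O", "OW", "W")}).
#' @return list of frames, each a list with \code{solute}, \code{water}
#'   and \code{frameId}.
#' @export
readXYZFrames <- function(path, soluteLabels, waterLabels = c("O", "OW", "W")) {
  lines <- readLines(path)
  frames <- list()
  i <- 1L
  fid <- 0L
  while (i <= length(lines)) {
    nAtoms <- suppressWarnings(as.integer(trimws(lines[i])))
    if (is.na(nAtoms)) break
    rec <- lines[(i + 2):(i + 1 + nAtoms)]
    tok <- do.call(rbind, strsplit(trimws(rec), "\\s+"))
    lab <- tok[, 1]
    xyz <- matrix(as.numeric(tok[, 2:4]), ncol = 3)
    fid <- fid + 1L
    frames[[fid]] <- list(solute = xyz[lab %in% soluteLabels, , drop = FALSE],
                          water = xyz[lab %in% waterLabels, , drop = FALSE],
                          frameId = fid)
    i <- i + 2L + nAtoms
  }
  if (!length(frames)) stop("no frames found in ", path, call. = FALSE)
  frames
}

#' Write coordinate frames to XYZ
#'
#' @param frames list of frames with \code{solute} and \code{water}
#'   matrices.
#' @param path output file path.
#' @param soluteLabel,waterLabel labels to write (defaults "P" and "O").
#' @return invisibly, the path.
#' @export
writeXYZFrames <- function(frames, path, soluteLabel = "P", waterLabel = "O") {
  con <- file(path, "w")
  on.exit(close(con))
  for (fr in frames) {
    n <- nrow(fr$solute) + nrow(fr$water)
    writeLines(c(as.character(n), sprintf("frame %d", fr$frameId %||% 0)), con)
    writeCoords <- function(m, lab)
      apply(m, 1, function(p) sprintf("%s %.4f %.4f %.4f", lab, p[1], p[2], p[3]))
    if (nrow(fr$solute)) writeLines(writeCoords(fr$solute, soluteLabel), con)
    if (nrow(fr$water)) writeLines(writeCoords(fr$water, waterLabel), con)
  }
  invisible(path)
}
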