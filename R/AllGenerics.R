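#' Repeat spacing accessor
#'
#' Returns the lamellar repeat spacing d (Angstrom) stored in an object.
#'
#' @param x a \linkS4class{LatticeFit}, \linkS4class{StructureFactorSet},
#'   \linkS4class{SLDProfile}, \linkS4class{ContrastSeries} or
#'   \linkS4class{BilayerModel}.
#' @return numeric(1), d in Angstrom.
#' @export
setGeneric("repeatSpacing", function(x) standardGeneric("repeatSpacing"))

#' Structure-factor table accessor
#'
#' @param x a \linkS4class{StructureFactorSet} or \linkS4class{ContrastSeries}.
#' @return For a set: data.frame with columns \code{h}, \code{f}, \code{sd},
#'   \code{d2oFraction}, \code{d7Fraction}, \code{signed}. For a series: the
#'   row-bound table over all sets.
#' @export
setGeneric("structureFactors", function(x) standardGeneric("structureFactors"))

#' Posterior medians accessor
#' @param x a \linkS4class{BindingPosterior}.
#' @return named numeric vector of posterior medians.
#' @export
setGeneric("posteriorMedians", function(x) standardGeneric("posteriorMedians"))

#' 68% credible interval accessor
#' @param x a \linkS4class{BindingPosterior}.
#' @return 2 x p matrix of central 68\% bounds (rows: lower, upper).
#' @export
setGeneric("credibleInterval", function(x) standardGeneric("credibleInterval"))

#' Posterior samples accessor
#' @param x a \linkS4class{BindingPosterior}.
#' @return matrix of post burn-in draws.
#' @export
setGeneric("posteriorSamples", function(x) standardGeneric("posteriorSamples"))

#' Quality/processing flags accessor
#' @param x any lamellar result object carrying flags.
#' @return character vector of flags (possibly empty).
#' @export
setGeneric("flags", function(x) standardGeneric("flags"))

#' Planted ground-truth audit accessor
#'
#' Synthetic-data generators record every planted value in a ground-truth
#' audit list attached to the object they return; recovery tests read the
#' truth from here rather than from repeated literals.
#'
#' @param x a synthetic object (curve, pattern, series, model).
#' @return list of planted values (empty for experimental data).
#' @export
setGeneric("groundTruth", function(x) standardGeneric("groundTruth"))

#' Titration points accessor
#' @param x a \linkS4class{TitrationCurve}.
#' @return data.frame of titration points.
#' @export
setGeneric("titrationPoints", function(x) standardGeneric("titrationPoints"))
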