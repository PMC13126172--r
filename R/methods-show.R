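#' @describeIn repeatSpacing method for LatticeFit
#' @export
setMethod("repeatSpacing", "LatticeFit", function(x) x@d)

#' @describeIn repeatSpacing method for StructureFactorSet
#' @export
setMethod("repeatSpacing", "StructureFactorSet", function(x) x@d)

#' @describeIn repeatSpacing method for SLDProfile
#' @export
setMethod("repeatSpacing", "SLDProfile", function(x) x@d)

#' @describeIn repeatSpacing method for ContrastSeries
#' @export
setMethod("repeatSpacing", "ContrastSeries", function(x) x@sets[[1]]@d)

#' @describeIn repeatSpacing method for BilayerModel
#' @export
setMethod("repeatSpacing", "BilayerModel", function(x) x@d)

#' @describeIn structureFactors method for StructureFactorSet
#' @export
setMethod("structureFactors", "StructureFactorSet", function(x) {
  data.frame(h = x@h, f = x@f, sd = x@sd,
             d2oFraction = x@d2oFraction, d7Fraction = x@d7Fraction,
             signed = x@signed)
})

#' @describeIn structureFactors method for ContrastSeries
#' @export
setMethod("structureFactors", "ContrastSeries", function(x) {
  do.call(rbind, lapply(x@sets, structureFactors))
})

#' @describeIn posteriorMedians method for BindingPosterior
#' @export
setMethod("posteriorMedians", "BindingPosterior", function(x) x@medians)

#' @describeIn credibleInterval method for BindingPosterior
#' @export
setMethod("credibleInterval", "BindingPosterior", function(x) x@ci68)

#' @describeIn posteriorSamples method for BindingPosterior
#' @export
setMethod("posteriorSamples", "BindingPosterior", function(x) x@samples)

#' @describeIn flags method for TitrationCurve
#' @export
setMethod("flags", "TitrationCurve", function(x) x@flags)

#' @describeIn flags method for BindingPosterior
#' @export
setMethod("flags", "BindingPosterior", function(x) {
  fl <- character()
  if (isTRUE(x@diagnostics$noBinding)) fl <- c(fl, "no.binding.detected")
  if (!isTRUE(x@diagnostics$converged)) fl <- c(fl, "not.converged")
  fl
})

#' @describeIn flags method for LatticeFit
#' @export
setMethod("flags", "LatticeFit", function(x) x@flags)

#' @describeIn flags method for StructureFactorSet
#' @export
setMethod("flags", "StructureFactorSet", function(x) x@flags)

#' @describeIn flags method for SLDProfile
#' @export
setMethod("flags", "SLDProfile", function(x) x@flags)

#' @describeIn flags method for WaterQuantification
#' @export
setMethod("flags", "WaterQuantification", function(x) x@flags)

#' @describeIn groundTruth method for TitrationCurve
#' @export
setMethod("groundTruth", "TitrationCurve", function(x) x@groundTruth)

#' @describeIn groundTruth method for DiffractionPattern
#' @export
setMethod("groundTruth", "DiffractionPattern", function(x) x@groundTruth)

#' @describeIn groundTruth method for ContrastSeries
#' @export
setMethod("groundTruth", "ContrastSeries", function(x) x@groundTruth)

#' @describeIn groundTruth method for BilayerModel
#' @export
setMethod("groundTruth", "BilayerModel", function(x) x@groundTruth)

#' @describeIn titrationPoints method for TitrationCurve
#' @export
setMethod("titrationPoints", "TitrationCurve", function(x) x@points)

setMethod("show", "TitrationCurve", function(object) {
  p <- object@points
  cat("TitrationCurve:", object@compositionLabel, "\n")
  cat(sprintf("  peptide %.3g umol/L, %d points, lipid %.3g-%.3g umol/L\n",
              object@peptideConc * 1e6, nrow(p),
              min(p$lipidConc) * 1e6, max(p$lipidConc) * 1e6))
  cat(sprintf("  nmre range %.3g-%.3g\n", min(p$nmre), max(p$nmre)))
  if (length(object@flags)) cat("  flags:", paste(object@flags, collapse = ", "), "\n")
})

setMethod("show", "BindingPosterior", function(object) {
  cat("BindingPosterior (", nrow(object@samples), " draws)\n", sep = "")
  if (isTRUE(object@diagnostics$noBinding)) {
    cat("  no binding detected\n")
    return(invisible(NULL))
  }
  m <- object@medians; ci <- object@ci68
  for (nm in names(m)) {
    sc <- if (nm == "kd") 1e6 else 1
    un <- if (nm == "kd") " umol/L" else ""
    cat(sprintf("  %-8s %.3g [%.3g, %.3g]%s\n", nm, m[nm] * sc,
                ci[1, nm] * sc, ci[2, nm] * sc, un))
  }
  cat(sprintf("  rhat max %.3f, acceptance %.2f%s\n",
              max(object@diagnostics$rhat), object@diagnostics$acceptance,
              if (isTRUE(object@diagnostics$converged)) "" else " [NOT CONVERGED]"))
})

setMethod("show", "DiffractionPattern", function(object) {
  cat(sprintf("DiffractionPattern: %d bins, Q %.4g-%.4g 1/A, lambda %.3g A\n",
              length(object@q), min(object@q), max(object@q), object@wavelength))
})

setMethod("show", "LatticeFit", function(object) {
  cat(sprintf("LatticeFit: d = %.2f +/- %.3f A (orders %s)\n",
              object@d, object@dSd, paste(object@orders, collapse = ",")))
  if (length(object@flags)) cat("  flags:", paste(object@flags, collapse = ", "), "\n")
})

setMethod("show", "StructureFactorSet", function(object) {
  cat(sprintf("StructureFactorSet: d = %.2f A, x(D2O) = %.2f, d7 = %.2f, %s\n",
              object@d, object@d2oFraction, object@d7Fraction,
              if (object@signed) "signed" else "unsigned"))
  print(data.frame(h = object@h, f = signif(object@f, 4), sd = signif(object@sd, 3)),
        row.names = FALSE)
})

setMethod("show", "ContrastSeries", function(object) {
  xs <- vapply(object@sets, function(s) s@d2oFraction, numeric(1))
  cat(sprintf("ContrastSeries: %d sets, d = %.2f A, x(D2O) = %s\n",
              length(object@sets), object@sets[[1]]@d,
              paste(format(xs), collapse = ", ")))
})

setMethod("show", "SLDProfile", function(object) {
  cat(sprintf("SLDProfile (%s): d = %.2f A, hmax = %d, %d grid points\n",
              object@scale, object@d, object@hmax, length(object@z)))
})

setMethod("show", "WaterQuantification", function(object) {
  cat(sprintf("WaterQuantification: %.1f +/- %.1f waters per peptide\n",
              object@watersPerPeptide, object@sd))
  if (length(object@flags)) cat("  flags:", paste(object@flags, collapse = ", "), "\n")
})

setMethod("show", "BilayerModel", function(object) {
  cat(sprintf("BilayerModel: d = %.2f A, %d components\n",
              object@d, nrow(object@components)))
  print(object@components, row.names = FALSE)
})
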