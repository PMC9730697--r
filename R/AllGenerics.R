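#' @rdname ThetaGrid-class
#' @param x a `ThetaGrid`, `SplineBasis`, `RamsayDensity` or `SAEMFit`.
#' @export
setGeneric("gridPoints", function(x) standardGeneric("gridPoints"))

#' @rdname SplineBasis-class
#' @param x object to extract from.
#' @export
setGeneric("basisMatrix", function(x) standardGeneric("basisMatrix"))

#' @rdname SplineBasis-class
#' @export
setGeneric("basisDim", function(x) standardGeneric("basisDim"))

#' @rdname RamsayDensity-class
#' @param x object to extract from.
#' @export
setGeneric("densityMass", function(x) standardGeneric("densityMass"))

#' @rdname RamsayDensity-class
#' @export
setGeneric("densityEta", function(x) standardGeneric("densityEta"))

#' Moments of a density on a grid
#'
#' Mean, standard deviation, skewness and kurtosis of the discrete
#' distribution placing mass `g_q` at grid point `x_q`.  Kurtosis is the
#' plain fourth standardized moment (3 for a normal density), not excess
#' kurtosis.
#'
#' @param x a [RamsayDensity-class], a [SAEMFit-class], or a numeric mass
#'   vector (nonnegative, summing to 1).
#' @param grid a [ThetaGrid-class]; required when `x` is a bare mass vector.
#' @return named numeric vector `(mean, sd, skewness, kurtosis)`.
#' @examples
#' g <- buildGrid(-6, 6, 0.1)
#' densityMoments(normalDensityOnGrid(g), g)
#' @export
setGeneric("densityMoments",
           function(x, grid) standardGeneric("densityMoments"))

#' @rdname SAEMFit-class
#' @param x a fitted model.
#' @export
setGeneric("itemParams", function(x) standardGeneric("itemParams"))

#' @rdname SAEMFit-class
#' @export
setGeneric("criteria", function(x) standardGeneric("criteria"))

setMethod("gridPoints", "ThetaGrid", function(x) x@points)
setMethod("gridPoints", "SplineBasis", function(x) x@grid@points)
setMethod("gridPoints", "RamsayDensity", function(x) x@basis@grid@points)
setMethod("gridPoints", "SAEMFit", function(x) x@grid@points)

setMethod("basisMatrix", "SplineBasis", function(x) x@matrix)
setMethod("basisMatrix", "RamsayDensity", function(x) x@basis@matrix)
setMethod("basisDim", "SplineBasis", function(x) x@m)
setMethod("basisDim", "RamsayDensity", function(x) x@basis@m)

setMethod("densityMass", "RamsayDensity", function(x) x@mass)
setMethod("densityMass", "SAEMFit", function(x) x@mass)
setMethod("densityEta", "RamsayDensity", function(x) x@eta)
setMethod("densityEta", "SAEMFit", function(x) x@eta)

setMethod("itemParams", "SAEMFit", function(x) x@items)
setMethod("criteria", "SAEMFit", function(x) x@criteria)

setMethod("show", "ThetaGrid", function(object) {
  cat(sprintf("ThetaGrid: %d points on [%g, %g], step %g\n",
              object@Q, object@lo, object@hi, object@step))
})

setMethod("show", "SplineBasis", function(object) {
  cat(sprintf(
    "SplineBasis: %d x %d (knots = %d, degree = %d) on [%g, %g]\n",
    object@grid@Q, object@m, object@knots, object@degree,
    object@grid@lo, object@grid@hi))
})

setMethod("show", "RamsayDensity", function(object) {
  mom <- densityMoments(object)
  cat(sprintf("RamsayDensity on %d grid points (m = %d)\n",
              object@basis@grid@Q, object@basis@m))
  cat(sprintf("  mean %.3f  sd %.3f  skewness %.3f  kurtosis %.3f\n",
              mom["mean"], mom["sd"], mom["skewness"], mom["kurtosis"]))
})

setMethod("show", "SAEMFit", function(object) {
  cat(sprintf("SAEMFit (%s mode): %d items, %d examinee-free parameters\n",
              object@mode, nrow(object@items), object@nParams))
  if (object@mode == "rc")
    cat(sprintf("  spline: knots = %d, degree = %d (m = %d)\n",
                object@knots, object@degree, length(object@eta)))
  cat(sprintf("  %s after %d iterations (last max change %.2e)\n",
              if (object@converged) "converged" else "iteration cap reached",
              object@iterations,
              object@trajectory[length(object@trajectory)]))
  cat(sprintf("  marginal logLik %.2f | AIC %.1f  BIC %.1f  HQIC %.1f\n",
              object@logLik, object@criteria["aic"], object@criteria["bic"],
              object@criteria["hqic"]))
  cat("Item parameter summary:\n")
  print(summary(object@items))
})
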