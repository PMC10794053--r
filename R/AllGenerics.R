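# Accessor generics and show methods for the core classes.

#' @rdname PointAnnotation-class
#' @param x,object a ShootCount object.
#' @export
setGeneric("imageId", function(x) standardGeneric("imageId"))
#' @rdname PointAnnotation-class
#' @export
setMethod("imageId", "PointAnnotation", function(x) x@imageId)
#' @rdname BoxAnnotation-class
#' @export
setMethod("imageId", "BoxAnnotation", function(x) x@imageId)

#' @rdname PointAnnotation-class
#' @export
setGeneric("imageSize", function(x) standardGeneric("imageSize"))
#' @rdname PointAnnotation-class
#' @export
setMethod("imageSize", "PointAnnotation",
          function(x) c(width = x@width, height = x@height))

#' @rdname PointAnnotation-class
#' @export
setGeneric("shootPoints", function(x) standardGeneric("shootPoints"))
#' @rdname PointAnnotation-class
#' @export
setMethod("shootPoints", "PointAnnotation", function(x) x@points)

#' @rdname PointAnnotation-class
#' @export
setGeneric("pointCount", function(x) standardGeneric("pointCount"))
#' @rdname PointAnnotation-class
#' @export
setMethod("pointCount", "PointAnnotation", function(x) nrow(x@points))

#' @rdname BoxAnnotation-class
#' @export
setGeneric("boxTable", function(x) standardGeneric("boxTable"))
#' @rdname BoxAnnotation-class
#' @export
setMethod("boxTable", "BoxAnnotation", function(x) x@boxes)

#' @rdname DensityMap-class
#' @export
setGeneric("densityGrid", function(x) standardGeneric("densityGrid"))
#' @rdname DensityMap-class
#' @export
setMethod("densityGrid", "DensityMap", function(x) x@grid)

#' @rdname DensityMap-class
#' @export
setGeneric("mapStride", function(x) standardGeneric("mapStride"))
#' @rdname DensityMap-class
#' @export
setMethod("mapStride", "DensityMap", function(x) x@stride)

#' Total mass of a density map (the predicted count)
#' @param x a [DensityMap-class].
#' @return numeric(1), the grid sum.
#' @export
setGeneric("densityCount", function(x) standardGeneric("densityCount"))
#' @rdname densityCount
#' @export
setMethod("densityCount", "DensityMap", function(x) sum(x@grid))

#' @rdname TransportPlan-class
#' @export
setGeneric("transportPlan", function(x) standardGeneric("transportPlan"))
#' @rdname TransportPlan-class
#' @export
setMethod("transportPlan", "TransportPlan", function(x) x@plan)

#' @rdname LossBreakdown-class
#' @export
setGeneric("lossTotal", function(x) standardGeneric("lossTotal"))
#' @rdname LossBreakdown-class
#' @export
setMethod("lossTotal", "LossBreakdown", function(x) x@total)

#' @rdname LossBreakdown-class
#' @export
setGeneric("lossTerms", function(x) standardGeneric("lossTerms"))
#' @rdname LossBreakdown-class
#' @export
setMethod("lossTerms", "LossBreakdown", function(x)
  c(countLoss = x@countLoss, otLoss = x@otLoss, pixelMse = x@pixelMse,
    lambda1 = x@lambda1, lambda2 = x@lambda2, total = x@total))

#' @rdname PRCurve-class
#' @export
setGeneric("averagePrecision", function(x) standardGeneric("averagePrecision"))
#' @rdname PRCurve-class
#' @export
setMethod("averagePrecision", "PRCurve", function(x) x@ap)

setMethod("show", "PointAnnotation", function(object) {
  cat(sprintf("PointAnnotation '%s' (%g x %g px): %d points\n",
              object@imageId, object@width, object@height, nrow(object@points)))
})

setMethod("show", "BoxAnnotation", function(object) {
  conf <- !all(is.na(object@boxes$confidence))
  cat(sprintf("BoxAnnotation '%s': %d boxes%s\n", object@imageId,
              nrow(object@boxes), if (conf) " (with confidences)" else ""))
})

setMethod("show", "DensityMap", function(object) {
  cat(sprintf("DensityMap '%s': %d x %d grid, stride %d, count %.4f\n",
              object@sourceId, nrow(object@grid), ncol(object@grid),
              object@stride, sum(object@grid)))
})

setMethod("show", "TransportPlan", function(object) {
  cat(sprintf("TransportPlan %d x %d: objective %.6g, %d iterations, %s\n",
              nrow(object@plan), ncol(object@plan), object@objective,
              object@iterations,
              if (object@converged) "converged" else "not converged"))
})

setMethod("show", "LossBreakdown", function(object) {
  cat(sprintf(paste0("LossBreakdown: total %.6g = count %.6g + %.3g * OT %.6g",
                     " + %.3g * MSE %.6g\n"),
              object@total, object@countLoss, object@lambda1, object@otLoss,
              object@lambda2, object@pixelMse))
})

setMethod("show", "DetectionMatchResult", function(object) {
  cat(sprintf("DetectionMatchResult '%s': TP %d, FP %d, FN %d\n",
              object@imageId, object@tp, object@fp, object@fn))
})

setMethod("show", "PRCurve", function(object) {
  cat(sprintf("PRCurve: %d points, AP = %.4f\n",
              length(object@recall), object@ap))
})

setMethod("show", "CountMetrics", function(object) {
  cat(sprintf("CountMetrics over %d images: MAE %.4f, MSE %.4f\n",
              object@n, object@mae, object@mse))
})
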