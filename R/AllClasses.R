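#' @import methods
NULL

#' Point annotations for a single image
#'
#' Holds the dot-map ground truth for one image: one (x, y) coordinate per
#' annotated shoot, together with the image dimensions. Coordinates follow the
#' toolkit-wide convention: 0-based, continuous, with pixel (i, j) covering
#' the half-open square `[j, j+1) x [i, i+1)`. Every point must satisfy
#' `0 <= x < width` and `0 <= y < height`.
#'
#' @slot imageId character(1) identifier of the source image.
#' @slot width,height image dimensions in pixels.
#' @slot points numeric matrix with columns `x` and `y`, one row per shoot.
#'
#' @seealso [readPoints()], [renderDensity()], [pointAnnotation()]
#' @exportClass PointAnnotation
setClass("PointAnnotation",
  representation(imageId = "character", width = "numeric",
                 height = "numeric", points = "matrix"),
  validity = function(object) {
    msg <- character()
    if (length(object@imageId) != 1L) msg <- c(msg, "imageId must be a single string")
    if (length(object@width) != 1L || length(object@height) != 1L ||
        object@width < 1 || object@height < 1)
      msg <- c(msg, "width and height must be positive scalars")
    p <- object@points
    if (ncol(p) != 2L) msg <- c(msg, "points must have two columns (x, y)")
    else if (nrow(p) > 0) {
      if (!is.numeric(p) || anyNA(p) || any(!is.finite(p)))
        msg <- c(msg, "points must be finite numeric coordinates")
      else {
        bad <- which(p[, 1] < 0 | p[, 1] >= object@width |
                     p[, 2] < 0 | p[, 2] >= object@height)
        if (length(bad))
          msg <- c(msg, sprintf("point %d is outside [0,width) x [0,height)", bad[1]))
      }
    }
    if (length(msg)) msg else TRUE
  })

#' Construct a PointAnnotation
#'
#' @param imageId image identifier.
#' @param width,height image dimensions in pixels.
#' @param points numeric matrix (or two-column data.frame) of x, y coordinates;
#'   may have zero rows.
#' @return A [PointAnnotation-class] object.
#' @examples
#' pointAnnotation("img1", 100, 100, cbind(x = c(10, 20), y = c(30, 40)))
#' @export
pointAnnotation <- function(imageId, width, height, points) {
  points <- as.matrix(points)
  if (length(points) == 0L) points <- matrix(numeric(), 0L, 2L)
  storage.mode(points) <- "double"
  colnames(points) <- c("x", "y")
  new("PointAnnotation", imageId = as.character(imageId),
      width = as.numeric(width), height = as.numeric(height), points = points)
}

#' Bounding-box annotations for a single image
#'
#' Axis-aligned boxes in the toolkit's 0-based, half-open convention
#' `[xmin, xmax) x [ymin, ymax)`. Ground-truth boxes carry `NA` confidence;
#' predicted boxes carry a confidence in `[0, 1]`.
#'
#' @slot imageId character(1) identifier of the source image.
#' @slot boxes data.frame with columns `xmin`, `ymin`, `xmax`, `ymax`,
#'   `label` (character) and `confidence` (numeric, `NA` on ground truth).
#'
#' @seealso [readVocBoxes()], [matchDetections()], [boxAnnotation()]
#' @exportClass BoxAnnotation
setClass("BoxAnnotation",
  representation(imageId = "character", boxes = "data.frame"),
  validity = function(object) {
    b <- object@boxes
    need <- c("xmin", "ymin", "xmax", "ymax", "label", "confidence")
    if (!all(need %in% names(b)))
      return(paste("boxes must have columns:", paste(need, collapse = ", ")))
    if (nrow(b)) {
      if (any(b$xmin >= b$xmax) || any(b$ymin >= b$ymax))
        return("boxes must satisfy xmin < xmax and ymin < ymax")
      conf <- b$confidence[!is.na(b$confidence)]
      if (length(conf) && (any(conf < 0) || any(conf > 1)))
        return("confidence must lie in [0, 1]")
    }
    TRUE
  })

#' Construct a BoxAnnotation
#'
#' @param imageId image identifier.
#' @param boxes data.frame with columns `xmin`, `ymin`, `xmax`, `ymax` and
#'   optionally `label`, `confidence`.
#' @return A [BoxAnnotation-class] object.
#' @export
boxAnnotation <- function(imageId, boxes = NULL) {
  if (is.null(boxes) || nrow(boxes) == 0L) {
    boxes <- data.frame(xmin = numeric(), ymin = numeric(), xmax = numeric(),
                        ymax = numeric(), label = character(),
                        confidence = numeric())
  } else {
    boxes <- as.data.frame(boxes)
    if (is.null(boxes$label)) boxes$label <- "object"
    if (is.null(boxes$confidence)) boxes$confidence <- NA_real_
    boxes <- boxes[c("xmin", "ymin", "xmax", "ymax", "label", "confidence")]
    for (cl in c("xmin", "ymin", "xmax", "ymax", "confidence"))
      boxes[[cl]] <- as.numeric(boxes[[cl]])
    boxes$label <- as.character(boxes$label)
    rownames(boxes) <- NULL
  }
  new("BoxAnnotation", imageId = as.character(imageId), boxes = boxes)
}

#' A non-negative density grid whose sum is the count
#'
#' The intermediate representation for counting: a 2-D grid of non-negative
#' reals aligned with the source image at an integer stride (grid cell (i, j)
#' covers source pixels `[j*stride, (j+1)*stride) x [i*stride, (i+1)*stride)`).
#' Ground-truth maps are rendered so that the grid total equals the number of
#' annotated points.
#'
#' @slot grid numeric matrix of non-negative values.
#' @slot stride integer downsampling factor relative to the source image.
#' @slot sourceId identifier of the source image.
#'
#' @seealso [renderDensity()], [downsampleDensity()], [densityCount()]
#' @exportClass DensityMap
setClass("DensityMap",
  representation(grid = "matrix", stride = "integer", sourceId = "character"),
  validity = function(object) {
    if (length(object@stride) != 1L || object@stride < 1L)
      return("stride must be a positive integer")
    g <- object@grid
    if (!is.numeric(g) || anyNA(g)) return("grid must be numeric without NA")
    if (any(g < 0)) return("density grid must be non-negative")
    TRUE
  })

densityMap <- function(grid, stride = 1L, sourceId = "") {
  new("DensityMap", grid = grid, stride = as.integer(stride),
      sourceId = as.character(sourceId))
}

#' Transport cost matrix
#'
#' Pairwise transport costs between predicted pixel locations (rows) and
#' annotated points (columns). `kind` records the cost family: `"euclid"`
#' (Euclidean distance), `"squared"` (squared distance), `"exp"`
#' (exponential of the normalized distance) or `"perspective"` (exponential
#' of the normalized distance divided by the perspective coefficient, the
#' mean of the two locations' normalized image heights).
#'
#' @slot entries numeric n x m matrix of costs.
#' @slot kind cost family, one of `euclid`, `squared`, `exp`, `perspective`.
#'
#' @seealso [costMatrix()], [perspectiveCoeff()]
#' @exportClass CostMatrix
setClass("CostMatrix",
  representation(entries = "matrix", kind = "character"),
  validity = function(object) {
    if (!object@kind %in% c("euclid", "squared", "exp", "perspective"))
      return("unknown cost kind")
    e <- object@entries
    if (anyNA(e) || any(!is.finite(e))) return("cost entries must be finite")
    if (object@kind %in% c("exp", "perspective")) {
      if (length(e) && any(e <= 0)) return("exponential costs must be > 0")
    } else if (length(e) && any(e < 0)) return("costs must be >= 0")
    TRUE
  })

#' @rdname CostMatrix-class
#' @param x a `CostMatrix`.
#' @export
costEntries <- function(x) x@entries

#' Transport plan returned by the unbalanced OT solver
#'
#' @slot plan non-negative n x m matrix coupling predicted pixel mass (rows)
#'   to annotated points (columns).
#' @slot objective value of the unbalanced entropic OT objective at `plan`.
#' @slot iterations accepted descent iterations used.
#' @slot converged whether the relative-change tolerance was met.
#'
#' @seealso [solveUot()]
#' @exportClass TransportPlan
setClass("TransportPlan",
  representation(plan = "matrix", objective = "numeric",
                 iterations = "integer", converged = "logical"),
  validity = function(object) {
    if (any(object@plan < 0)) return("transport plan must be non-negative")
    if (object@converged && !is.finite(object@objective))
      return("objective must be finite when converged")
    TRUE
  })

#' Decomposition of the composite counting loss
#'
#' Total loss = `countLoss + lambda1 * otLoss + lambda2 * pixelMse`:
#' a smooth-L1 penalty on the predicted total count, the unbalanced OT term,
#' and the mean squared difference between predicted and ground-truth density
#' grids.
#'
#' @slot countLoss smooth-L1 on predicted vs. true totals.
#' @slot otLoss unbalanced entropic OT objective.
#' @slot pixelMse mean squared grid difference.
#' @slot lambda1,lambda2 loss coefficients.
#' @slot total weighted sum of the three terms.
#'
#' @seealso [compositeLoss()]
#' @exportClass LossBreakdown
setClass("LossBreakdown",
  representation(countLoss = "numeric", otLoss = "numeric",
                 pixelMse = "numeric", lambda1 = "numeric",
                 lambda2 = "numeric", total = "numeric"),
  validity = function(object) {
    expect <- object@countLoss + object@lambda1 * object@otLoss +
      object@lambda2 * object@pixelMse
    if (is.finite(expect) &&
        abs(object@total - expect) > 1e-9 * max(1, abs(expect)))
      return("total must equal countLoss + lambda1*otLoss + lambda2*pixelMse")
    TRUE
  })

#' Per-image detection matching result
#'
#' Tallies from greedy confidence-ordered matching of predicted to ground
#' truth boxes at a fixed IoU threshold. Invariants: `tp + fn` equals the
#' number of ground-truth boxes and `tp + fp` the number of predictions.
#'
#' @slot imageId image identifier.
#' @slot tp,fp,fn true positive / false positive / false negative counts.
#' @slot matchedPairs data.frame with columns `pred`, `gt`, `iou` (1-based
#'   indices into the prediction and ground-truth box tables).
#' @slot nGt,nPred box counts the tallies must be consistent with.
#'
#' @seealso [matchDetections()], [tallyDetections()]
#' @exportClass DetectionMatchResult
setClass("DetectionMatchResult",
  representation(imageId = "character", tp = "integer", fp = "integer",
                 fn = "integer", matchedPairs = "data.frame",
                 nGt = "integer", nPred = "integer"),
  validity = function(object) {
    if (object@tp + object@fn != object@nGt)
      return("tp + fn must equal the number of ground-truth boxes")
    if (object@tp + object@fp != object@nPred)
      return("tp + fp must equal the number of predicted boxes")
    if (min(object@tp, object@fp, object@fn) < 0)
      return("tallies must be non-negative")
    TRUE
  })

#' Precision-recall curve and average precision
#'
#' @slot recall non-decreasing recall points of the confidence sweep.
#' @slot precision precision at each recall point.
#' @slot ap area under the all-point interpolated (precision-envelope) curve.
#'
#' @seealso [prCurve()]
#' @exportClass PRCurve
setClass("PRCurve",
  representation(recall = "numeric", precision = "numeric", ap = "numeric"),
  validity = function(object) {
    if (length(object@recall) != length(object@precision))
      return("recall and precision must have equal length")
    if (is.unsorted(object@recall)) return("recall must be non-decreasing")
    if (object@ap < 0 || object@ap > 1) return("ap must lie in [0, 1]")
    TRUE
  })

#' Counting accuracy metrics
#'
#' Mean absolute error and mean squared error between predicted and true
#' per-image counts. By Jensen's inequality `mae <= sqrt(mse)`.
#'
#' @slot mae mean absolute error.
#' @slot mse mean squared error.
#' @slot n number of images.
#'
#' @seealso [countMetrics()]
#' @exportClass CountMetrics
setClass("CountMetrics",
  representation(mae = "numeric", mse = "numeric", n = "integer"),
  validity = function(object) {
    if (object@mae < 0 || object@mse < 0) return("mae and mse must be >= 0")
    if (object@mae > sqrt(object@mse) + 1e-9)
      return("mae must not exceed sqrt(mse)")
    TRUE
  })
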