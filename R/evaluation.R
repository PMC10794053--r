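# Detection and counting evaluation: IoU matching, precision/recall/AP at a
# fixed IoU threshold, per-image tally summaries, MAE/MSE counting metrics,
# and the deterministic train/validation/test split.

#' Intersection over union of two boxes
#'
#' Boxes are half-open `[xmin, xmax) x [ymin, ymax)` so areas are exact
#' products of side lengths.
#'
#' @param boxA,boxB numeric vectors `c(xmin, ymin, xmax, ymax)`.
#' @return IoU in `[0, 1]`; 0 for disjoint boxes.
#' @examples
#' boxIoU(c(0, 0, 10, 10), c(5, 0, 15, 10))  # 1/3
#' @export
boxIoU <- function(boxA, boxB) {
  a <- as.numeric(boxA)[1:4]; b <- as.numeric(boxB)[1:4]
  areaA <- (a[3] - a[1]) * (a[4] - a[2])
  areaB <- (b[3] - b[1]) * (b[4] - b[2])
  if (areaA <= 0 || areaB <= 0) stop("degenerate box with zero area")
  iw <- min(a[3], b[3]) - max(a[1], b[1])
  ih <- min(a[4], b[4]) - max(a[2], b[2])
  if (iw <= 0 || ih <= 0) return(0)
  inter <- iw * ih
  inter / (areaA + areaB - inter)
}

#' Match predicted to ground-truth boxes at an IoU threshold
#'
#' Greedy matching in descending confidence: each prediction claims the
#' unmatched ground-truth box of highest IoU; it is a true positive iff that
#' IoU reaches the threshold, otherwise a false positive (so duplicated
#' detections of one object count as false). Unmatched ground truth are
#' false negatives.
#'
#' @param pred [BoxAnnotation-class] of predictions; missing confidences are
#'   treated as 1 (file order kept on ties).
#' @param gt [BoxAnnotation-class] of ground truth.
#' @param iouThreshold matching threshold in `(0, 1)` (default 0.5).
#' @return A [DetectionMatchResult-class].
#' @export
matchDetections <- function(pred, gt, iouThreshold = 0.5) {
  stopifnot(is(pred, "BoxAnnotation"), is(gt, "BoxAnnotation"))
  if (iouThreshold <= 0 || iouThreshold >= 1)
    stop("iouThreshold must lie in (0, 1)")
  p <- boxTable(pred); g <- boxTable(gt)
  conf <- ifelse(is.na(p$confidence), 1, p$confidence)
  ord <- order(-conf)
  gtFree <- rep(TRUE, nrow(g))
  tp <- 0L; fp <- 0L
  pairs <- list()
  for (i in ord) {
    best <- 0; bestJ <- 0L
    for (j in which(gtFree)) {
      v <- boxIoU(unlist(p[i, 1:4]), unlist(g[j, 1:4]))
      if (v > best) { best <- v; bestJ <- j }
    }
    if (bestJ > 0L && best >= iouThreshold) {
      tp <- tp + 1L
      gtFree[bestJ] <- FALSE
      pairs[[length(pairs) + 1L]] <- data.frame(pred = i, gt = bestJ, iou = best)
    } else fp <- fp + 1L
  }
  mp <- if (length(pairs)) do.call(rbind, pairs)
        else data.frame(pred = integer(), gt = integer(), iou = numeric())
  new("DetectionMatchResult", imageId = imageId(gt), tp = tp, fp = fp,
      fn = sum(gtFree), matchedPairs = mp,
      nGt = nrow(g), nPred = nrow(p))
}

#' Precision-recall curve and average precision over a test set
#'
#' Sweeps the confidence threshold from high to low over all predictions
#' (across images), accumulating true/false positives by the greedy matching
#' rule of [matchDetections()]. AP is the area under the all-point
#' interpolated curve (precision envelope), the usual Pascal-VOC "area under
#' the entire P-R curve".
#'
#' @param preds list of prediction [BoxAnnotation-class] objects (one per
#'   image, with confidences).
#' @param gts list of ground-truth [BoxAnnotation-class] objects with
#'   matching `imageId`s.
#' @param iouThreshold matching threshold (default 0.5).
#' @return A [PRCurve-class].
#' @export
prCurve <- function(preds, gts, iouThreshold = 0.5) {
  if (is(preds, "BoxAnnotation")) preds <- list(preds)
  if (is(gts, "BoxAnnotation")) gts <- list(gts)
  gtById <- stats::setNames(gts, vapply(gts, imageId, character(1)))
  nGt <- sum(vapply(gts, function(g) nrow(boxTable(g)), integer(1)))
  if (nGt == 0L) stop("no ground-truth boxes: recall is undefined")
  rows <- do.call(rbind, lapply(preds, function(p) {
    b <- boxTable(p)
    if (nrow(b) == 0L) return(NULL)
    data.frame(imageId = imageId(p), idx = seq_len(nrow(b)),
               conf = ifelse(is.na(b$confidence), 1, b$confidence))
  }))
  if (is.null(rows) || nrow(rows) == 0L)
    return(new("PRCurve", recall = 0, precision = 0, ap = 0))
  rows <- rows[order(-rows$conf), , drop = FALSE]
  free <- lapply(gtById, function(g) rep(TRUE, nrow(boxTable(g))))
  isTp <- logical(nrow(rows))
  predById <- stats::setNames(preds, vapply(preds, imageId, character(1)))
  for (r in seq_len(nrow(rows))) {
    id <- rows$imageId[r]
    g <- gtById[[id]]
    if (is.null(g)) next
    pb <- unlist(boxTable(predById[[id]])[rows$idx[r], 1:4])
    gb <- boxTable(g)
    best <- 0; bestJ <- 0L
    for (j in which(free[[id]])) {
      v <- boxIoU(pb, unlist(gb[j, 1:4]))
      if (v > best) { best <- v; bestJ <- j }
    }
    if (bestJ > 0L && best >= iouThreshold) {
      isTp[r] <- TRUE
      free[[id]][bestJ] <- FALSE
    }
  }
  cumTp <- cumsum(isTp); cumFp <- cumsum(!isTp)
  recall <- cumTp / nGt
  precision <- cumTp / (cumTp + cumFp)
  # all-point interpolation: precision envelope over recall
  mrec <- c(0, recall)
  mpre <- c(0, precision)
  for (i in rev(seq_len(length(mpre) - 1L))) mpre[i] <- max(mpre[i], mpre[i + 1L])
  ap <- sum(diff(mrec) * mpre[-1L])
  new("PRCurve", recall = recall, precision = precision, ap = ap)
}

#' Sum per-image detection tallies into a Table-style summary row
#'
#' Accepts either a list of [DetectionMatchResult-class] objects or a
#' data.frame with columns `image_id`, `total`, `correct`, `false`, `missed`
#' (the layout of a published per-image tally table). With `check = TRUE`
#' each row must satisfy `correct + missed == total`; published hand-counted
#' tables occasionally violate this, so `check = FALSE` sums the columns as
#' printed.
#'
#' @param results list of match results or a tally data.frame.
#' @param check verify per-row invariants before summing (default `TRUE`).
#' @return one-row data.frame with columns `total`, `correct`, `false`,
#'   `missed`.
#' @export
tallyDetections <- function(results, check = TRUE) {
  if (is.data.frame(results)) {
    df <- results
    need <- c("image_id", "total", "correct", "false", "missed")
    if (!all(need %in% names(df)))
      stop("tally data.frame needs columns: ", paste(need, collapse = ", "))
  } else {
    if (length(results) == 0L) stop("no per-image results to tally")
    df <- do.call(rbind, lapply(results, function(r) {
      stopifnot(is(r, "DetectionMatchResult"))
      data.frame(image_id = r@imageId, total = r@nGt, correct = r@tp,
                 false = r@fp, missed = r@fn)
    }))
  }
  if (nrow(df) == 0L) stop("no per-image results to tally")
  if (check) {
    bad <- which(df$correct + df$missed != df$total |
                 df$correct < 0 | df$false < 0 | df$missed < 0)
    if (length(bad))
      stop("tally invariant violated (correct + missed != total) for image ",
           df$image_id[bad[1]])
  }
  data.frame(total = sum(df$total), correct = sum(df$correct),
             false = sum(df$false), missed = sum(df$missed))
}

#' Published per-image crown-detection tallies
#'
#' A 26-image hand-counted evaluation of four crown detectors (per-image
#' totals, correct, false and missed detections), shipped as a plain-text
#' fixture for the tally machinery.
#'
#' @param model optional detector name to filter on (`"yolox"`, `"yolov5"`,
#'   `"efficientnet"`, `"faster-rcnn"`).
#' @return data.frame with columns `model`, `image_id`, `total`, `correct`,
#'   `false`, `missed`.
#' @export
uavDetectionTally <- function(model = NULL) {
  path <- system.file("extdata", "uav_detection_tally.csv",
                      package = "ShootCount", mustWork = TRUE)
  df <- utils::read.csv(path)
  if (!is.null(model)) df <- df[df$model == model, , drop = FALSE]
  rownames(df) <- NULL
  df
}

#' Counting accuracy: MAE and MSE
#'
#' Standard definitions: `MAE = mean(|P_i - G_i|)`,
#' `MSE = mean((P_i - G_i)^2)` over per-image predicted and true counts.
#'
#' @param predCounts,gtCounts numeric vectors of equal length `>= 1`.
#' @return A [CountMetrics-class].
#' @export
countMetrics <- function(predCounts, gtCounts) {
  if (length(predCounts) != length(gtCounts))
    stop("predicted and true count vectors must have equal length")
  if (length(predCounts) < 1L) stop("need at least one image")
  e <- as.numeric(predCounts) - as.numeric(gtCounts)
  new("CountMetrics", mae = mean(abs(e)), mse = mean(e^2),
      n = length(e))
}

#' Deterministic train/validation/test split
#'
#' Shuffles the ids with the given seed, then takes
#' `floor(N * r_train / sum(r))` for training; of the remainder, validation
#' gets the floor of its proportional share and test the rest. With the
#' 7:1.5:1.5 ratios this yields 1302/279/279 for 1860 items and 219/47/47
#' for 313 items.
#'
#' @param ids vector of unique ids (length `>= 3`).
#' @param ratios positive `c(train, val, test)` weights (default
#'   `c(7, 1.5, 1.5)`).
#' @param seed shuffle seed.
#' @return list with elements `train`, `val`, `test`; an exact disjoint
#'   partition of `ids`.
#' @export
splitDataset <- function(ids, ratios = c(7, 1.5, 1.5), seed = 1L) {
  if (anyDuplicated(ids)) stop("ids must be unique")
  if (length(ratios) != 3L || any(ratios <= 0))
    stop("ratios must be three positive weights")
  n <- length(ids)
  if (n < 3L) stop("need at least 3 ids to split")
  shuffled <- withSceneSeed(seed, 0L, sample(ids))
  nTrain <- floor(n * ratios[1] / sum(ratios))
  rem <- n - nTrain
  nVal <- floor(rem * ratios[2] / (ratios[2] + ratios[3]))
  list(train = shuffled[seq_len(nTrain)],
       val = shuffled[nTrain + seq_len(nVal)],
       test = shuffled[(nTrain + nVal + 1L):n])
}
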