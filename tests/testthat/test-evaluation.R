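# Detection matching, P-R/AP, tallies, counting metrics, dataset split.

test_that("IoU follows half-open box arithmetic", {
  expect_equal(boxIoU(c(0, 0, 10, 10), c(0, 0, 10, 10)), 1)
  expect_equal(boxIoU(c(0, 0, 10, 10), c(5, 0, 15, 10)), 1 / 3)
  expect_equal(boxIoU(c(0, 0, 10, 10), c(20, 20, 30, 30)), 0)
  expect_error(boxIoU(c(0, 0, 0, 10), c(0, 0, 10, 10)), "degenerate")
})

test_that("greedy matching tallies TP/FP/FN with one-to-one GT use", {
  gt <- fixBoxes(data.frame(xmin = c(0, 20, 40), ymin = 0,
                            xmax = c(10, 30, 50), ymax = 10))
  exact <- fixBoxes(data.frame(xmin = c(0, 20, 40), ymin = 0,
                               xmax = c(10, 30, 50), ymax = 10,
                               confidence = c(0.9, 0.8, 0.7)))
  r <- matchDetections(exact, gt)
  expect_equal(c(r@tp, r@fp, r@fn), c(3L, 0L, 0L))
  expect_true(all(r@matchedPairs$iou >= 0.5))

  # duplicate detections of one object: second counts false
  dup <- fixBoxes(data.frame(xmin = c(0, 1), ymin = c(0, 0),
                             xmax = c(10, 11), ymax = c(10, 10),
                             confidence = c(0.9, 0.85)))
  one <- fixBoxes(data.frame(xmin = 0, ymin = 0, xmax = 10, ymax = 10))
  r2 <- matchDetections(dup, one)
  expect_equal(c(r2@tp, r2@fp, r2@fn), c(1L, 1L, 0L))

  r3 <- matchDetections(fixBoxes(NULL), gt)
  expect_equal(c(r3@tp, r3@fp, r3@fn), c(0L, 0L, 3L))
  # type invariants
  expect_equal(r2@tp + r2@fn, r2@nGt)
  expect_equal(r2@tp + r2@fp, r2@nPred)
})

test_that("P-R sweep reproduces the hand-enumerated AP of 5/6", {
  gt <- fixBoxes(data.frame(xmin = c(0, 100), ymin = 0,
                            xmax = c(10, 110), ymax = 10))
  preds <- fixBoxes(data.frame(
    xmin = c(0, 50, 100), ymin = 0,
    xmax = c(10, 60, 110), ymax = 10,
    confidence = c(0.9, 0.8, 0.7)))
  pr <- prCurve(preds, gt)
  expect_equal(pr@recall, c(0.5, 0.5, 1.0))
  expect_equal(pr@precision, c(1.0, 0.5, 2 / 3))
  expect_equal(averagePrecision(pr), 5 / 6, tolerance = 1e-12)
})

test_that("perfect and useless detectors bound AP at 1 and 0", {
  gt <- fixBoxes(data.frame(xmin = c(0, 20), ymin = 0,
                            xmax = c(10, 30), ymax = 10))
  perfect <- fixBoxes(data.frame(xmin = c(0, 20), ymin = 0,
                                 xmax = c(10, 30), ymax = 10,
                                 confidence = c(0.9, 0.8)))
  expect_equal(averagePrecision(prCurve(perfect, gt)), 1)
  misses <- fixBoxes(data.frame(xmin = c(50, 70), ymin = 50,
                                xmax = c(60, 80), ymax = 60,
                                confidence = c(0.9, 0.8)))
  expect_equal(averagePrecision(prCurve(misses, gt)), 0)
  expect_error(prCurve(perfect, fixBoxes(NULL)), "recall")
})

test_that("AP is invariant to monotone rescaling of confidences", {
  set.seed(21)
  gt <- fixBoxes(data.frame(xmin = seq(0, 90, by = 10) * 2, ymin = 0,
                            xmax = seq(0, 90, by = 10) * 2 + 8, ymax = 8))
  conf <- runif(10)
  jitter <- runif(10, -3, 3)
  mk <- function(cf) fixBoxes(data.frame(
    xmin = seq(0, 90, by = 10) * 2 + jitter, ymin = 0,
    xmax = seq(0, 90, by = 10) * 2 + 8 + jitter, ymax = 8,
    confidence = cf))
  ap1 <- averagePrecision(prCurve(mk(conf), gt))
  ap2 <- averagePrecision(prCurve(mk(conf^3 * 0.5 + 0.1), gt))
  expect_equal(ap1, ap2)
  expect_gte(ap1, 0); expect_lte(ap1, 1)
})

test_that("tallies sum per-image rows and police their invariants", {
  rows <- data.frame(image_id = c("a", "b"), total = c(3, 3),
                     correct = c(3, 2), false = c(0, 1), missed = c(0, 1))
  s <- tallyDetections(rows)
  expect_equal(unlist(s), c(total = 6, correct = 5, false = 1, missed = 1))
  bad <- rows; bad$missed[2] <- 5
  expect_error(tallyDetections(bad), "image b")
  expect_error(tallyDetections(list()), "no per-image")
})

test_that("the published 26-image tally reproduces its printed sums", {
  yolox <- uavDetectionTally("yolox")
  expect_equal(nrow(yolox), 26L)
  s <- tallyDetections(yolox, check = FALSE)
  expect_equal(s$correct, 296)
  expect_equal(s$total, 303)
  expect_equal(s$false, 12)
  expect_equal(s$missed, 7)
})

test_that("count metrics equal a brute-force recomputation", {
  expect_equal(countMetrics(c(4, 7), c(4, 7))@mae, 0)
  cm <- countMetrics(c(5, 7), c(4, 7))
  expect_equal(cm@mae, 0.5)
  expect_equal(cm@mse, 0.5)
  set.seed(3)
  for (i in 1:20) {
    n <- sample(1:50, 1)
    p <- rnorm(n, 20, 5); g <- rnorm(n, 20, 5)
    cm <- countMetrics(p, g)
    expect_equal(cm@mae, sum(abs(p - g)) / n, tolerance = 1e-12)
    expect_equal(cm@mse, sum((p - g)^2) / n, tolerance = 1e-12)
    expect_lte(cm@mae, sqrt(cm@mse) + 1e-12)
  }
  expect_error(countMetrics(1:3, 1:4), "equal length")
})

test_that("the 7:1.5:1.5 split reproduces the published sizes", {
  s1 <- splitDataset(seq_len(1860), seed = 42)
  expect_equal(lengths(s1), c(train = 1302L, val = 279L, test = 279L))
  s2 <- splitDataset(seq_len(313), seed = 42)
  expect_equal(lengths(s2), c(train = 219L, val = 47L, test = 47L))
})

test_that("splits are exact disjoint partitions for any ratios", {
  ids <- paste0("im", 1:10)
  s <- splitDataset(ids, ratios = c(1, 1, 1), seed = 7)
  expect_equal(sum(lengths(s)), 10L)
  expect_equal(sort(unname(unlist(s))), sort(ids))
  expect_equal(anyDuplicated(unlist(s)), 0L)
  # deterministic given the seed
  expect_identical(s, splitDataset(ids, ratios = c(1, 1, 1), seed = 7))
  expect_error(splitDataset(1:2), "at least 3")
  expect_error(splitDataset(c(1, 1, 2)), "unique")
})
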