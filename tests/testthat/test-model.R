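# The small density-regression network and its trainer.

test_that("model maps H x W x 3 to a non-negative strided grid", {
  m <- buildModel(modelConfig(seed = 1))
  img <- array(runif(64 * 64 * 3), c(64, 64, 3))
  out <- predictCount(m, img)
  expect_equal(dim(densityGrid(out$density)), c(16, 16))
  expect_true(all(densityGrid(out$density) >= 0))
  expect_true(all(is.finite(densityGrid(out$density))))
  expect_equal(out$count, densityCount(out$density), tolerance = 1e-6)
})

test_that("initialization is deterministic in the seed", {
  m1 <- buildModel(modelConfig(seed = 5))
  m2 <- buildModel(modelConfig(seed = 5))
  expect_identical(m1$enc[[1]]$w, m2$enc[[1]]$w)
  expect_identical(m1$out$w, m2$out$w)
  m3 <- buildModel(modelConfig(seed = 6))
  expect_false(identical(m1$enc[[1]]$w, m3$enc[[1]]$w))
})

test_that("zeroed output layer yields a zero count on any image", {
  m <- buildModel(modelConfig(seed = 1))
  m$out$w[] <- 0; m$out$b <- 0
  img <- array(0, c(64, 64, 3))
  expect_equal(predictCount(m, img)$count, 0)
})

test_that("images not divisible by the stride are padded reflectively", {
  m <- buildModel(modelConfig(seed = 2))
  img <- array(runif(61 * 66 * 3), c(61, 66, 3))
  out <- predictCount(m, img)
  expect_equal(dim(densityGrid(out$density)), c(16, 17))
})

test_that("invalid architectures are rejected", {
  expect_error(modelConfig(headDilations = integer(0)), "dilation")
  expect_error(modelConfig(outputStride = 3), "power of 2")
  expect_error(modelConfig(outputStride = 16), "too few blocks")
})

test_that("backward pass agrees with finite differences", {
  set.seed(12)
  m <- buildModel(modelConfig(encoderChannels = c(4, 6, 6),
                              headDilations = c(1, 2), headChannels = 4,
                              seed = 3))
  img <- array(runif(16 * 16 * 3), c(16, 16, 3))
  gD <- matrix(rnorm(16), 4, 4)
  fw <- modelForward(m, img, keep = TRUE)
  gr <- modelBackward(m, fw, gD)
  lossAt <- function(mm) sum(modelForward(mm, img)$density * gD)
  w <- m$enc[[2]]$w
  idx <- sample(length(w), 8)
  for (k in idx) {
    e <- 1e-5
    mp <- m; mp$enc[[2]]$w[k] <- w[k] + e
    mn <- m; mn$enc[[2]]$w[k] <- w[k] - e
    fd <- (lossAt(mp) - lossAt(mn)) / (2 * e)
    expect_equal(gr$enc[[2]]$w[k], fd, tolerance = 1e-6)
  }
})

test_that("one-epoch training runs, logs consistent losses, and checkpoints", {
  cfg <- sceneConfig(shootsPerCrown = c(4, 10), seed = 21)
  dir <- tempfile("train8")
  mf <- generateDataset(cfg, 8, dir)
  m <- buildModel(modelConfig(seed = 1))
  tc <- trainConfig(batchSize = 4, learningRate = 1e-3, epochs = 1, seed = 1)
  rec <- trainCounter(m, mf, tc, dataDir = dir)
  expect_equal(nrow(rec$history), 1L)
  expect_true(all(is.finite(unlist(rec$history))))
  # logged total respects the breakdown identity
  h <- rec$history
  expect_equal(h$total, h$countLoss + 0.1 * h$otLoss + 0.01 * h$pixelMse,
               tolerance = 1e-6)
  # checkpoint round trip
  f <- tempfile(fileext = ".rds")
  saveModel(rec$model, f)
  back <- loadModel(f)
  img <- readImageFile(file.path(dir, mf$image[1]))
  expect_identical(predictCount(back, img)$count,
                   predictCount(rec$model, img)$count)
})

test_that("with lambda1 = lambda2 = 0 the loop reduces to count regression", {
  cfg <- sceneConfig(shootsPerCrown = c(5, 15), seed = 33)
  dir <- tempfile("cnt")
  mf <- generateDataset(cfg, 8, dir)
  m <- buildModel(modelConfig(seed = 2))
  tc <- trainConfig(batchSize = 4, learningRate = 1e-3, epochs = 5,
                    loss = list(lambda1 = 0, lambda2 = 0), seed = 2)
  rec <- trainCounter(m, mf, tc, dataDir = dir, valIds = mf$image_id[7:8])
  h <- rec$history
  expect_equal(h$total, h$countLoss, tolerance = 1e-9)
  expect_lt(h$countLoss[5], h$countLoss[1])
})

test_that("degenerate training inputs are rejected", {
  m <- buildModel(modelConfig(seed = 1))
  empty <- data.frame(image_id = character(), image = character(),
                      points = character())
  expect_error(trainCounter(m, empty, trainConfig()), "empty")
})
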