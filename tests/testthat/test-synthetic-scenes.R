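# Synthetic crown/shoot scene generator.

test_that("configured counts are honored exactly", {
  sc <- generateScene(sceneConfig(nCrowns = c(1, 1),
                                  shootsPerCrown = c(5, 5)), 1)
  expect_equal(nrow(boxTable(sc$boxes)), 1L)
  expect_equal(pointCount(sc$points), 5L)
  expect_equal(dim(sc$image), c(64, 64, 3))
  expect_true(all(sc$image >= 0 & sc$image <= 1))
})

test_that("generation is bit-reproducible given (seed, index)", {
  cfg <- sceneConfig(shootsPerCrown = c(10, 20), seed = 9)
  a <- generateScene(cfg, 3)
  b <- generateScene(cfg, 3)
  expect_identical(a$image, b$image)
  expect_identical(shootPoints(a$points), shootPoints(b$points))
  expect_identical(boxTable(a$boxes), boxTable(b$boxes))
  # different index gives a different scene
  c2 <- generateScene(cfg, 4)
  expect_false(identical(shootPoints(a$points), shootPoints(c2$points)))
})

test_that("all shoots lie inside their crown's bounding box", {
  cfg <- sceneConfig(nCrowns = c(2, 2), imageSize = 128,
                     crownRadius = c(15, 25), shootsPerCrown = c(5, 15),
                     seed = 5)
  for (i in 1:5) {
    sc <- generateScene(cfg, i)
    p <- shootPoints(sc$points)
    b <- boxTable(sc$boxes)
    inAny <- vapply(seq_len(nrow(p)), function(k) {
      any(p[k, 1] >= b$xmin & p[k, 1] <= b$xmax &
          p[k, 2] >= b$ymin & p[k, 2] <= b$ymax)
    }, logical(1))
    expect_true(all(inAny))
  }
})

test_that("perspective gain skews shoots toward the image bottom", {
  # cluster spread comparable to the crown radius makes the point process
  # essentially the inhomogeneous law itself, so the closed-form bottom
  # fraction (~0.63 for a crown spanning the image) applies; with 200 shoots
  # the bottom half should then dominate in nearly every scene.  Under
  # strong clustering the same dominance holds but is noisier (cluster-level
  # sampling variance).
  cfg <- sceneConfig(imageSize = 64, crownRadius = c(28, 28),
                     shootsPerCrown = c(200, 200), perspectiveGain = 4,
                     clusterSpread = 28, seed = 2)
  hit <- 0L
  for (i in 1:100) {
    p <- shootPoints(generateScene(cfg, i)$points)
    if (sum(p[, 2] >= 32) > sum(p[, 2] < 32)) hit <- hit + 1L
  }
  expect_gte(hit, 95L)
})

test_that("mean shoots per crown matches the configured mean", {
  cfg <- sceneConfig(shootsPerCrown = c(5, 30), seed = 17)
  counts <- vapply(1:200, function(i)
    pointCount(generateScene(cfg, i)$points), numeric(1))
  se <- stats::sd(counts) / sqrt(length(counts))
  expect_lt(abs(mean(counts) - 17.5), 3 * se)
})

test_that("impossible crown packings raise a helpful generation error", {
  cfg <- sceneConfig(imageSize = 64, nCrowns = c(6, 6),
                     crownRadius = c(25, 28), seed = 1)
  expect_error(generateScene(cfg, 1), "fewer or smaller crowns")
})

test_that("datasets round trip through disk with conserved counts", {
  cfg <- sceneConfig(shootsPerCrown = c(3, 12), seed = 4)
  dir1 <- tempfile("ds1")
  mf <- generateDataset(cfg, 10, dir1)
  expect_equal(nrow(mf), 10L)
  perFile <- vapply(seq_len(nrow(mf)), function(i)
    pointCount(readPoints(file.path(dir1, mf$points[i]))), integer(1))
  expect_equal(sum(mf$n_points), sum(perFile))
  # regeneration is byte-identical
  dir2 <- tempfile("ds2")
  generateDataset(cfg, 10, dir2)
  for (f in mf$points)
    expect_identical(readLines(file.path(dir1, f)),
                     readLines(file.path(dir2, f)))
})

test_that("degenerate scene configurations are rejected", {
  expect_error(sceneConfig(shootsPerCrown = c(10, 5)), "range")
  expect_error(sceneConfig(perspectiveGain = -1), "perspectiveGain")
})
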