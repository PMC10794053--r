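# Pascal-VOC and point-annotation I/O, crop extraction, density persistence.

test_that("VOC boxes convert 1-based inclusive to 0-based half-open", {
  f <- tempfile(fileext = ".xml")
  writeRawVoc(f, list(list(xmin = 1, ymin = 1, xmax = 11, ymax = 11,
                           name = "pine")))
  ba <- readVocBoxes(f)
  b <- boxTable(ba)
  expect_equal(nrow(b), 1L)
  expect_equal(unlist(b[1, 1:4], use.names = FALSE), c(0, 0, 11, 11))
  expect_equal(b$label, "pine")
  expect_true(is.na(b$confidence))
})

test_that("VOC reader handles empty files and reports malformed objects", {
  f <- tempfile(fileext = ".xml")
  writeRawVoc(f, list())
  expect_equal(nrow(boxTable(readVocBoxes(f))), 0L)

  g <- tempfile(fileext = ".xml")
  writeRawVoc(g, list(list(xmin = 1, ymin = 1, xmax = 5, ymax = 5),
                      list(xmin = 2, ymin = 2, ymax = 9)))  # no xmax
  expect_error(readVocBoxes(g), "object 2")
  expect_error(readVocBoxes(tempfile(fileext = ".xml")), "not found")
})

test_that("VOC write/read round trip preserves coordinates exactly", {
  ba <- fixBoxes(data.frame(xmin = c(0, 12.5), ymin = c(3, 7),
                            xmax = c(40, 60.25), ymax = c(20, 90),
                            label = c("a", "b"), confidence = c(NA, 0.75)))
  f <- tempfile(fileext = ".xml")
  writeVocBoxes(ba, f, width = 100, height = 100)
  back <- readVocBoxes(f)
  expect_equal(boxTable(back)[, 1:4], boxTable(ba)[, 1:4])
  expect_equal(boxTable(back)$confidence, c(NA, 0.75))
})

test_that("point files round trip in CSV and JSON and validate bounds", {
  pa <- fixPoints(cbind(c(1.5, 20, 99), c(0, 50.25, 99.5)))
  for (ext in c(".csv", ".json")) {
    f <- tempfile(fileext = ext)
    writePoints(pa, f)
    back <- readPoints(f)
    expect_equal(shootPoints(back), shootPoints(pa))
    expect_equal(unname(imageSize(back)), c(100, 100))
  }
  # empty annotation
  f <- tempfile(fileext = ".csv")
  writePoints(fixPoints(matrix(numeric(), 0, 2)), f)
  expect_equal(pointCount(readPoints(f)), 0L)
  # boundary is exclusive: x == width must fail, naming the row
  f2 <- tempfile(fileext = ".csv")
  writeLines(c("image_id,width,height", "bad,100,100", "x,y", "100,0"), f2)
  expect_error(readPoints(f2), "row 1")
})

test_that("crop extraction pads, clamps and reports offsets", {
  img <- array(stats::runif(100 * 100 * 3), c(100, 100, 3))
  ba <- fixBoxes(data.frame(xmin = 10, ymin = 10, xmax = 50, ymax = 50))
  cr0 <- cropSingleTrees(img, ba, pad = 0)
  expect_equal(dim(cr0[[1]]$image)[1:2], c(40, 40))
  cr20 <- cropSingleTrees(img, ba, pad = 20)
  expect_equal(unname(cr20[[1]]$box), c(0, 0, 70, 70))
  expect_equal(dim(cr20[[1]]$image)[1:2], c(70, 70))
  # crop content matches direct slicing
  expect_equal(cr0[[1]]$image, img[11:50, 11:50, ])

  two <- fixBoxes(data.frame(xmin = c(5, 60), ymin = c(5, 60),
                             xmax = c(20, 80), ymax = c(20, 80)))
  crs <- cropSingleTrees(img, two, pad = 2)
  expect_length(crs, 2L)
  expect_equal(unname(crs[[1]]$offset), c(3, 3))
  expect_equal(unname(crs[[2]]$offset), c(58, 58))
  expect_length(cropSingleTrees(img, fixBoxes(NULL)), 0L)
})

test_that("points remap into a crop and back exactly", {
  pa <- fixPoints(cbind(c(12, 30, 70), c(15, 40, 90)))
  off <- c(x = 10, y = 10)
  local <- pointsToCrop(pa, off, size = c(50, 50))
  expect_equal(pointCount(local), 2L)   # the point at (70, 90) is outside
  back <- pointsToParent(local, off, parentSize = c(100, 100))
  expect_equal(shootPoints(back), shootPoints(pa)[1:2, ])
})

test_that("density maps persist as TIFF + sidecar within float precision", {
  pa <- fixPoints(cbind(c(10, 20, 21), c(10, 20, 20)), 40, 40)
  d <- renderDensity(pa, shape = c(40, 40))
  f <- tempfile(fileext = ".tif")
  writeDensityMap(d, f)
  back <- readDensityMap(f)
  expect_equal(mapStride(back), 1L)
  expect_lt(max(abs(densityGrid(back) - densityGrid(d))), 1e-6)
  expect_equal(densityCount(back), densityCount(d), tolerance = 1e-6)
})

test_that("annotation validity catches out-of-bounds points and bad boxes", {
  expect_error(fixPoints(cbind(100, 0)), "outside")
  expect_error(fixBoxes(data.frame(xmin = 5, ymin = 0, xmax = 5, ymax = 3)),
               "xmin < xmax")
})
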