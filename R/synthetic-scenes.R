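# Synthetic crown/shoot scenes with the statistical structure the counting
# method assumes: elliptical crowns, clustered (Neyman-Scott) shoot point
# processes, and a local shoot density that grows linearly with normalized
# image height -- the perspective effect of nadir UAV imagery, where shoots
# further from the camera appear denser.

#' Configuration for the synthetic scene generator
#'
#' @param imageSize side length of the square scene in pixels.
#' @param nCrowns integer range `c(lo, hi)` of crowns per scene.
#' @param crownRadius pixel range of ellipse semi-axes.
#' @param shootsPerCrown integer range of shoots per crown.
#' @param clusterSpread Gaussian spread (px) of shoots around cluster parents.
#' @param perspectiveGain non-negative linear gain `g`: expected local shoot
#'   density is proportional to `1 + g * h` at normalized height `h = y / H`.
#' @param blobSigma Gaussian radius (px) of the rendered shoot blobs.
#' @param backgroundTextureScale correlation length (px) of the low-frequency
#'   background texture.
#' @param seed integer RNG seed; with a fixed seed the generator is
#'   bit-reproducible.
#' @return A validated `SceneConfig` list.
#' @export
sceneConfig <- function(imageSize = 64L, nCrowns = c(1L, 1L),
                        crownRadius = c(18, 28), shootsPerCrown = c(5L, 30L),
                        clusterSpread = 2, perspectiveGain = 2,
                        blobSigma = 1, backgroundTextureScale = 16,
                        seed = 1L) {
  cfg <- list(imageSize = as.integer(imageSize),
              nCrowns = as.integer(round(nCrowns)),
              crownRadius = as.numeric(crownRadius),
              shootsPerCrown = as.integer(round(shootsPerCrown)),
              clusterSpread = as.numeric(clusterSpread),
              perspectiveGain = as.numeric(perspectiveGain),
              blobSigma = as.numeric(blobSigma),
              backgroundTextureScale = as.numeric(backgroundTextureScale),
              seed = as.integer(seed))
  rng <- function(r, what) {
    if (length(r) != 2L || anyNA(r) || r[1] > r[2] || r[1] < 0)
      stop(what, " must be a non-degenerate non-negative range c(lo, hi)")
  }
  rng(cfg$nCrowns, "nCrowns"); rng(cfg$crownRadius, "crownRadius")
  rng(cfg$shootsPerCrown, "shootsPerCrown")
  if (cfg$imageSize < 16L) stop("imageSize must be at least 16")
  if (cfg$perspectiveGain < 0) stop("perspectiveGain must be >= 0")
  if (cfg$clusterSpread <= 0 || cfg$blobSigma <= 0)
    stop("clusterSpread and blobSigma must be positive")
  class(cfg) <- "SceneConfig"
  cfg
}

# run expr under a derived deterministic seed, restoring the caller's RNG
withSceneSeed <- function(seed, index, expr) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
          else suppressWarnings(rm(".Random.seed", envir = globalenv())))
  set.seed((as.numeric(seed) * 7919 + as.numeric(index) * 104729) %% 2147483646 + 1)
  force(expr)
}

# bilinear upsample of a coarse matrix to H x W
bilinearUpsample <- function(m, H, W) {
  gi <- seq(1, nrow(m), length.out = H)
  gj <- seq(1, ncol(m), length.out = W)
  i0 <- pmin(floor(gi), nrow(m) - 1L); fi <- gi - i0
  j0 <- pmin(floor(gj), ncol(m) - 1L); fj <- gj - j0
  a <- m[cbind(rep(i0, W), rep(j0, each = H))]
  b <- m[cbind(rep(i0 + 1, W), rep(j0, each = H))]
  cc <- m[cbind(rep(i0, W), rep(j0 + 1, each = H))]
  d <- m[cbind(rep(i0 + 1, W), rep(j0 + 1, each = H))]
  wfi <- rep(fi, W); wfj <- rep(fj, each = H)
  matrix(a * (1 - wfi) * (1 - wfj) + b * wfi * (1 - wfj) +
         cc * (1 - wfi) * wfj + d * wfi * wfj, H, W)
}

sampleRange <- function(r) if (r[1] == r[2]) r[1] else stats::runif(1, r[1], r[2])
sampleIntRange <- function(r) if (r[1] == r[2]) r[1] else sample(r[1]:r[2], 1L)

# place non-overlapping ellipses by rejection sampling
placeCrowns <- function(cfg) {
  n <- sampleIntRange(cfg$nCrowns)
  S <- cfg$imageSize
  crowns <- list()
  attempts <- 0L
  while (length(crowns) < n) {
    if (attempts >= 1000L)
      stop("could not place ", n, " non-overlapping crowns in ", S, "x", S,
           " px after 1000 attempts; use fewer or smaller crowns")
    attempts <- attempts + 1L
    rx <- sampleRange(cfg$crownRadius); ry <- sampleRange(cfg$crownRadius)
    rmax <- max(rx, ry)
    if (2 * rmax >= S) next
    cx <- stats::runif(1, rmax, S - rmax)
    cy <- stats::runif(1, rmax, S - rmax)
    ok <- all(vapply(crowns, function(cr) {
      sqrt((cr$cx - cx)^2 + (cr$cy - cy)^2) > rmax + max(cr$rx, cr$ry)
    }, logical(1)))
    if (ok) crowns[[length(crowns) + 1L]] <- list(cx = cx, cy = cy, rx = rx, ry = ry)
  }
  crowns
}

# clustered shoots inside one crown, thinned to the linear perspective law
sampleShoots <- function(crown, m, cfg) {
  S <- cfg$imageSize; g <- cfg$perspectiveGain
  inEllipse <- function(x, y)
    ((x - crown$cx) / crown$rx)^2 + ((y - crown$cy) / crown$ry)^2 <= 1
  nParents <- max(1L, ceiling(m / 6))
  parents <- matrix(NA_real_, nParents, 2L)
  got <- 0L
  while (got < nParents) {
    x <- stats::runif(1, crown$cx - crown$rx, crown$cx + crown$rx)
    y <- stats::runif(1, crown$cy - crown$ry, crown$cy + crown$ry)
    if (inEllipse(x, y)) { got <- got + 1L; parents[got, ] <- c(x, y) }
  }
  pts <- matrix(NA_real_, m, 2L)
  got <- 0L; tries <- 0L
  while (got < m && tries < 10000L * (m + 1L)) {
    tries <- tries + 1L
    par <- parents[sample.int(nParents, 1L), ]
    x <- par[1] + stats::rnorm(1, sd = cfg$clusterSpread)
    y <- par[2] + stats::rnorm(1, sd = cfg$clusterSpread)
    if (!inEllipse(x, y) || x < 0 || x >= S || y < 0 || y >= S) next
    # thinning: keep with probability proportional to 1 + g * h
    if (stats::runif(1) > (1 + g * y / S) / (1 + g)) next
    got <- got + 1L
    pts[got, ] <- c(x, y)
  }
  if (got < m) stop("failed to sample the requested number of shoots")
  pts
}

#' Generate one synthetic crown/shoot scene
#'
#' Produces an RGB scene with textured background, non-overlapping elliptical
#' crowns, and clustered shoot points whose local density follows
#' `1 + perspectiveGain * h` in normalized height. Shoots are rendered as
#' small bright blobs. Ground-truth boxes are the crown bounding rectangles
#' and ground-truth points the shoot centers. Deterministic given
#' `(config$seed, index)`.
#'
#' @param config a [sceneConfig()].
#' @param index scene index (distinct indices give distinct scenes under one
#'   seed).
#' @return list with `image` (`H x W x 3` array in `[0, 1]`), `points`
#'   ([PointAnnotation-class]) and `boxes` ([BoxAnnotation-class]).
#' @examples
#' sc <- generateScene(sceneConfig(shootsPerCrown = c(5, 5)), 1)
#' pointCount(sc$points)  # 5
#' @export
generateScene <- function(config, index = 1L) {
  stopifnot(inherits(config, "SceneConfig"))
  withSceneSeed(config$seed, index, {
    S <- config$imageSize
    crowns <- placeCrowns(config)
    id <- sprintf("scene_%04d", as.integer(index))

    allPts <- matrix(numeric(), 0L, 2L)
    boxRows <- NULL
    for (cr in crowns) {
      m <- sampleIntRange(config$shootsPerCrown)
      pts <- sampleShoots(cr, m, config)
      allPts <- rbind(allPts, pts)
      boxRows <- rbind(boxRows, data.frame(
        xmin = max(0, cr$cx - cr$rx), ymin = max(0, cr$cy - cr$ry),
        xmax = min(S, cr$cx + cr$rx), ymax = min(S, cr$cy + cr$ry),
        label = "crown", confidence = NA_real_))
    }

    # low-frequency background texture in green hues
    nc <- max(2L, ceiling(S / config$backgroundTextureScale) + 1L)
    tex <- bilinearUpsample(matrix(stats::runif(nc * nc), nc, nc), S, S)
    img <- array(0, c(S, S, 3L))
    img[, , 1] <- 0.10 + 0.10 * tex
    img[, , 2] <- 0.22 + 0.18 * tex
    img[, , 3] <- 0.07 + 0.07 * tex

    # darker crown foliage inside each ellipse
    xs <- matrix(rep(seq_len(S) - 0.5, each = S), S, S)   # x by column
    ys <- matrix(rep(seq_len(S) - 0.5, times = S), S, S)  # y by row
    for (cr in crowns) {
      mask <- ((xs - cr$cx) / cr$rx)^2 + ((ys - cr$cy) / cr$ry)^2 <= 1
      for (ch in 1:3) {
        pl <- img[, , ch]
        pl[mask] <- pl[mask] * 0.45 + c(0.05, 0.16, 0.05)[ch]
        img[, , ch] <- pl
      }
    }

    # shoots as bright yellow-green Gaussian blobs
    if (nrow(allPts)) {
      bs <- config$blobSigma
      r <- ceiling(3 * bs)
      for (jj in seq_len(nrow(allPts))) {
        x <- allPts[jj, 1]; y <- allPts[jj, 2]
        c0 <- max(0L, floor(x - r)); c1 <- min(S - 1L, ceiling(x + r))
        r0 <- max(0L, floor(y - r)); r1 <- min(S - 1L, ceiling(y + r))
        gx <- exp(-((c0:c1) + 0.5 - x)^2 / (2 * bs^2))
        gy <- exp(-((r0:r1) + 0.5 - y)^2 / (2 * bs^2))
        blob <- outer(gy, gx)
        rows <- (r0 + 1):(r1 + 1); cols <- (c0 + 1):(c1 + 1)
        img[rows, cols, 1] <- img[rows, cols, 1] + 0.55 * blob
        img[rows, cols, 2] <- img[rows, cols, 2] + 0.65 * blob
        img[rows, cols, 3] <- img[rows, cols, 3] + 0.15 * blob
      }
    }
    img[img > 1] <- 1; img[img < 0] <- 0

    list(image = img,
         points = pointAnnotation(id, S, S, allPts),
         boxes = boxAnnotation(id, boxRows))
  })
}

#' Write a labeled synthetic dataset to disk
#'
#' Generates `nImages` scenes and writes, per scene, a PNG image, a point CSV
#' and a Pascal-VOC XML of crown boxes, plus a `manifest.csv` listing ids,
#' file paths and per-scene counts.
#'
#' @param config a [sceneConfig()].
#' @param nImages number of scenes.
#' @param outDir output directory (created if missing).
#' @return the manifest as a data.frame (invisibly written to
#'   `outDir/manifest.csv`).
#' @export
generateDataset <- function(config, nImages, outDir) {
  stopifnot(inherits(config, "SceneConfig"), nImages >= 1)
  dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(outDir)) stop("cannot create output directory: ", outDir)
  rows <- lapply(seq_len(nImages), function(i) {
    sc <- generateScene(config, i)
    id <- imageId(sc$points)
    imgPath <- file.path(outDir, paste0(id, ".png"))
    ptsPath <- file.path(outDir, paste0(id, "_points.csv"))
    boxPath <- file.path(outDir, paste0(id, "_boxes.xml"))
    png::writePNG(sc$image, imgPath)
    writePoints(sc$points, ptsPath)
    writeVocBoxes(sc$boxes, boxPath, width = config$imageSize,
                  height = config$imageSize)
    data.frame(image_id = id, image = basename(imgPath),
               points = basename(ptsPath), boxes = basename(boxPath),
               n_points = pointCount(sc$points),
               n_boxes = nrow(boxTable(sc$boxes)))
  })
  manifest <- do.call(rbind, rows)
  utils::write.csv(manifest, file.path(outDir, "manifest.csv"),
                   row.names = FALSE)
  manifest
}
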