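# Ground-truth density maps via the geometry-adaptive Gaussian kernel.

#' Geometry-adaptive kernel bandwidths
#'
#' For each annotated point, the Gaussian bandwidth is `beta` times the mean
#' Euclidean distance to its `k` nearest other points, so smoothing adapts to
#' local crowding: tight kernels in dense tufts, wide kernels for isolated
#' shoots. Points with fewer than `k` neighbours get `fallbackSigma`;
#' bandwidths below `minSigma` (e.g. duplicate coordinates) are floored.
#'
#' @param points a [PointAnnotation-class].
#' @param k number of nearest neighbours (default 3).
#' @param beta bandwidth multiplier (default 0.3).
#' @param fallbackSigma bandwidth in px used when fewer than `k` other points
#'   exist (default 4).
#' @param minSigma lower floor on the bandwidth in px (default 1).
#' @return numeric vector of bandwidths, one per point.
#' @examples
#' pa <- pointAnnotation("p", 40, 40, cbind(c(0, 10, 20), c(5, 5, 5)))
#' adaptiveSigmas(pa, k = 2, beta = 0.3)  # middle point: 0.3 * 10 = 3
#' @export
adaptiveSigmas <- function(points, k = 3L, beta = 0.3,
                           fallbackSigma = 4, minSigma = 1) {
  stopifnot(is(points, "PointAnnotation"), k >= 1L, beta > 0)
  p <- shootPoints(points)
  m <- nrow(p)
  if (m == 0L) return(numeric(0))
  if (m - 1L < k) return(rep(fallbackSigma, m))
  dm <- as.matrix(stats::dist(p))
  sig <- vapply(seq_len(m), function(j) {
    d <- sort(dm[j, -j], partial = k)[seq_len(k)]
    beta * mean(d)
  }, numeric(1))
  pmax(sig, minSigma)
}

#' Render points into a ground-truth density map
#'
#' Each point contributes a discretized Gaussian of its own bandwidth,
#' evaluated at pixel centers, truncated at 4 sigma and at the image
#' boundary, then renormalized so its in-image mass is exactly one. The grid
#' total therefore equals the point count to floating-point precision.
#'
#' @param points a [PointAnnotation-class].
#' @param sigmas bandwidths from [adaptiveSigmas()] (one per point).
#' @param shape `c(H, W)` of the output grid; defaults to the annotation's
#'   image size.
#' @return A [DensityMap-class] with stride 1.
#' @export
renderDensity <- function(points, sigmas = adaptiveSigmas(points),
                          shape = NULL) {
  stopifnot(is(points, "PointAnnotation"))
  sz <- imageSize(points)
  if (is.null(shape)) shape <- c(sz["height"], sz["width"])
  H <- as.integer(shape[1]); W <- as.integer(shape[2])
  if (H < 1L || W < 1L) stop("density shape must be at least 1 x 1")
  p <- shootPoints(points)
  if (nrow(p) != length(sigmas))
    stop("need one bandwidth per point (", nrow(p), " points, ",
         length(sigmas), " bandwidths)")
  grid <- matrix(0, H, W)
  for (j in seq_len(nrow(p))) {
    x <- p[j, 1]; y <- p[j, 2]; s <- sigmas[j]
    r <- 4 * s
    c0 <- max(0L, as.integer(floor(x - r))); c1 <- min(W - 1L, as.integer(ceiling(x + r)))
    r0 <- max(0L, as.integer(floor(y - r))); r1 <- min(H - 1L, as.integer(ceiling(y + r)))
    if (c1 < c0 || r1 < r0) { # support fell entirely outside: nearest pixel
      c0 <- c1 <- min(max(as.integer(floor(x)), 0L), W - 1L)
      r0 <- r1 <- min(max(as.integer(floor(y)), 0L), H - 1L)
    }
    cx <- (c0:c1) + 0.5; cy <- (r0:r1) + 0.5
    gx <- exp(-(cx - x)^2 / (2 * s^2))
    gy <- exp(-(cy - y)^2 / (2 * s^2))
    ker <- outer(gy, gx)
    ker <- ker / sum(ker)
    grid[(r0 + 1):(r1 + 1), (c0 + 1):(c1 + 1)] <-
      grid[(r0 + 1):(r1 + 1), (c0 + 1):(c1 + 1)] + ker
  }
  densityMap(grid, stride = 1L, sourceId = imageId(points))
}

#' Downsample a density map by sum pooling
#'
#' Aggregates `factor x factor` blocks by summation, preserving total mass
#' exactly; the stride is multiplied by `factor`. Grids whose dimensions are
#' not divisible by `factor` are zero-padded at the bottom/right first.
#'
#' @param d a [DensityMap-class].
#' @param factor positive integer pooling factor.
#' @return A [DensityMap-class] with stride `stride * factor`.
#' @export
downsampleDensity <- function(d, factor) {
  stopifnot(is(d, "DensityMap"))
  factor <- as.integer(factor)
  if (is.na(factor) || factor < 1L) stop("pooling factor must be >= 1")
  if (factor == 1L) return(d)
  g <- densityGrid(d)
  H <- nrow(g); W <- ncol(g)
  Hp <- ceiling(H / factor) * factor; Wp <- ceiling(W / factor) * factor
  if (Hp != H || Wp != W) {
    gp <- matrix(0, Hp, Wp)
    gp[seq_len(H), seq_len(W)] <- g
    g <- gp
  }
  # sum-pool via row then column block sums
  rowsum1 <- rowsum(g, rep(seq_len(Hp / factor), each = factor))
  pooled <- t(rowsum(t(rowsum1), rep(seq_len(Wp / factor), each = factor)))
  dimnames(pooled) <- NULL
  densityMap(pooled, stride = mapStride(d) * factor, sourceId = d@sourceId)
}

#' Grid-cell center coordinates of a density map
#'
#' Returns the source-image coordinates of each grid cell center, in
#' column-major (R matrix) order — the coordinate system used for the
#' transport cost between predicted pixel mass and annotated points.
#'
#' @param d a [DensityMap-class].
#' @return matrix with columns `x`, `y`, one row per grid cell.
#' @export
densityCoords <- function(d) {
  stopifnot(is(d, "DensityMap"))
  g <- densityGrid(d); s <- mapStride(d)
  ij <- expand.grid(i = seq_len(nrow(g)) - 1L, j = seq_len(ncol(g)) - 1L)
  cbind(x = (ij$j + 0.5) * s, y = (ij$i + 0.5) * s)
}
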