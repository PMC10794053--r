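# A small convolutional density regressor: a few strided encoder blocks
# followed by a multiscale dilated-convolution regression head whose parallel
# branches are summed, then a 1x1 projection with a final rectifier so the
# predicted density is non-negative.  Forward/backward passes run on
# RcppArmadillo kernels; the network is deliberately desk-scale.

#' Configuration of the density-regression network
#'
#' @param encoderChannels channel widths of the 3x3 encoder blocks; average
#'   pooling halves the resolution after each of the first
#'   `log2(outputStride)` blocks.
#' @param headDilations dilation rates of the parallel 3x3 head branches
#'   (summed before the rectifier); at least one.
#' @param headChannels width of each head branch.
#' @param outputStride total downsampling factor; must be a power of two no
#'   larger than `2^length(encoderChannels)`.
#' @param seed RNG seed for the deterministic parameter initialization.
#' @return A validated `ModelConfig` list.
#' @export
modelConfig <- function(encoderChannels = c(8L, 16L, 16L),
                        headDilations = c(1L, 2L, 3L),
                        headChannels = 8L,
                        outputStride = 4L, seed = 1L) {
  cfg <- list(encoderChannels = as.integer(encoderChannels),
              headDilations = as.integer(headDilations),
              headChannels = as.integer(headChannels),
              outputStride = as.integer(outputStride),
              seed = as.integer(seed))
  if (length(cfg$headDilations) < 1L) stop("need at least one head dilation")
  s <- cfg$outputStride
  if (s < 1L || bitwAnd(s, s - 1L) != 0L)
    stop("outputStride must be a power of 2")
  if (2L^length(cfg$encoderChannels) < s)
    stop("encoder has too few blocks for outputStride ", s)
  if (any(cfg$encoderChannels < 1L) || cfg$headChannels < 1L)
    stop("channel widths must be positive")
  class(cfg) <- "ModelConfig"
  cfg
}

heInit <- function(fanIn, nOut, scale = 1) {
  matrix(stats::rnorm(fanIn * nOut, sd = scale * sqrt(2 / fanIn)), fanIn, nOut)
}

#' Build a density-regression model
#'
#' Maps an `H x W x 3` RGB array to a non-negative `(H/stride) x (W/stride)`
#' density grid. Parameter initialization is deterministic given
#' `config$seed`.
#'
#' @param config a [modelConfig()].
#' @return a `ShootCountModel` list of parameters (weights as unrolled-patch
#'   matrices, biases as vectors) plus the architecture description.
#' @export
buildModel <- function(config = modelConfig()) {
  stopifnot(inherits(config, "ModelConfig"))
  withSceneSeed(config$seed, 7L, {
    chans <- c(3L, config$encoderChannels)
    enc <- lapply(seq_along(config$encoderChannels), function(b) {
      list(w = heInit(9L * chans[b], chans[b + 1L]),
           b = rep(0, chans[b + 1L]))
    })
    cLast <- utils::tail(chans, 1L)
    head <- lapply(config$headDilations, function(d) {
      list(w = heInit(9L * cLast, config$headChannels,
                      scale = 1 / sqrt(length(config$headDilations))),
           b = rep(0, config$headChannels), dil = d)
    })
    out <- list(w = heInit(config$headChannels, 1L, scale = 0.1),
                b = 0.01)
    structure(list(config = config, enc = enc, head = head, out = out),
              class = "ShootCountModel")
  })
}

#' @export
print.ShootCountModel <- function(x, ...) {
  np <- sum(vapply(c(x$enc, x$head, list(x$out)),
                   function(l) length(l$w) + length(l$b), numeric(1)))
  cat(sprintf("ShootCountModel: encoder %s, head dilations %s, stride %d, %d parameters\n",
              paste(x$config$encoderChannels, collapse = "-"),
              paste(x$config$headDilations, collapse = ","),
              x$config$outputStride, as.integer(np)))
  invisible(x)
}

nPoolBlocks <- function(config) as.integer(log2(config$outputStride))

# forward pass; keep = TRUE retains intermediates for the backward pass
modelForward <- function(model, image, keep = FALSE) {
  cfg <- model$config
  x <- image
  nPool <- nPoolBlocks(cfg)
  cache <- list(encIn = list(), encPre = list())
  for (b in seq_along(model$enc)) {
    if (keep) cache$encIn[[b]] <- x
    pre <- .conv2d_fwd_cpp(x, model$enc[[b]]$w, model$enc[[b]]$b, 3L, 1L)
    if (keep) cache$encPre[[b]] <- pre
    x <- pmax(pre, 0)
    if (b <= nPool) x <- .avgpool2_fwd_cpp(x)
  }
  if (keep) cache$headIn <- x
  hsum <- NULL
  for (br in model$head) {
    y <- .conv2d_fwd_cpp(x, br$w, br$b, 3L, br$dil)
    hsum <- if (is.null(hsum)) y else hsum + y
  }
  if (keep) cache$headPre <- hsum
  h <- pmax(hsum, 0)
  if (keep) cache$outIn <- h
  pre <- .conv2d_fwd_cpp(h, model$out$w, model$out$b, 1L, 1L)
  if (keep) cache$outPre <- pre
  dens <- pmax(pre[, , 1], 0)
  if (keep) list(density = dens, cache = cache) else list(density = dens)
}

# backward pass: gDens is d(loss)/d(density grid); returns gradients in the
# same shape as the parameter list
modelBackward <- function(model, fw, gDens) {
  cfg <- model$config
  cache <- fw$cache
  nPool <- nPoolBlocks(cfg)
  grads <- list(enc = vector("list", length(model$enc)),
                head = vector("list", length(model$head)))
  g <- gDens * (cache$outPre[, , 1] > 0)
  g <- array(g, c(dim(g), 1L))
  bo <- .conv2d_bwd_cpp(cache$outIn, model$out$w, g, 1L, 1L)
  grads$out <- list(w = bo$gw, b = bo$gb)
  gh <- bo$gx * (cache$headPre > 0)
  gx <- NULL
  for (i in seq_along(model$head)) {
    br <- model$head[[i]]
    bb <- .conv2d_bwd_cpp(cache$headIn, br$w, gh, 3L, br$dil)
    grads$head[[i]] <- list(w = bb$gw, b = bb$gb)
    gx <- if (is.null(gx)) bb$gx else gx + bb$gx
  }
  for (b in rev(seq_along(model$enc))) {
    if (b <= nPool) gx <- .avgpool2_bwd_cpp(gx)
    gx <- gx * (cache$encPre[[b]] > 0)
    bb <- .conv2d_bwd_cpp(cache$encIn[[b]], model$enc[[b]]$w, gx, 3L, 1L)
    grads$enc[[b]] <- list(w = bb$gw, b = bb$gb)
    gx <- bb$gx
  }
  grads
}

# reflective padding of an H x W x C array to multiples of `s`
padReflect <- function(image, s) {
  d <- dim(image)
  H <- d[1]; W <- d[2]
  Hp <- ceiling(H / s) * s; Wp <- ceiling(W / s) * s
  if (Hp == H && Wp == W) return(image)
  ri <- c(seq_len(H), rev(seq_len(H)))[seq_len(Hp)]
  ci <- c(seq_len(W), rev(seq_len(W)))[seq_len(Wp)]
  image[ri, ci, , drop = FALSE]
}

#' Predict a density map and count for an image
#'
#' @param model a trained `ShootCountModel`.
#' @param image `H x W x 3` array in `[0, 1]`; dimensions not divisible by
#'   the model stride are padded reflectively.
#' @param sourceId identifier stored in the returned density map.
#' @return list with `density` (a [DensityMap-class] at the model stride)
#'   and `count` (its grid sum).
#' @export
predictCount <- function(model, image, sourceId = "") {
  stopifnot(inherits(model, "ShootCountModel"))
  if (length(dim(image)) == 2L)
    image <- array(rep(image, 3L), c(dim(image), 3L))
  image <- padReflect(image, model$config$outputStride)
  fw <- modelForward(model, image)
  dm <- densityMap(fw$density, stride = model$config$outputStride,
                   sourceId = sourceId)
  list(density = dm, count = sum(fw$density))
}

#' Save / load a model checkpoint
#'
#' @param model a `ShootCountModel`.
#' @param path checkpoint path (RDS).
#' @return `path` (save) or the restored model (load).
#' @export
saveModel <- function(model, path) {
  stopifnot(inherits(model, "ShootCountModel"))
  saveRDS(model, path)
  invisible(path)
}

#' @rdname saveModel
#' @export
loadModel <- function(path) {
  m <- readRDS(path)
  if (!inherits(m, "ShootCountModel")) stop("not a ShootCountModel checkpoint")
  m
}
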