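# Training loop for the density regressor under the composite loss:
# Adam updates, per-epoch loss breakdown logging and validation MAE.

#' Training configuration
#'
#' @param batchSize images per gradient step (default 16).
#' @param learningRate Adam learning rate (default 1e-5).
#' @param epochs passes over the training set (default 30).
#' @param loss list of composite-loss settings: `lambda1`, `lambda2`, `eps`,
#'   `tau`, `costKind`, `tol`, `maxIter`.
#' @param seed RNG seed for shuffling.
#' @return A validated `TrainConfig` list.
#' @export
trainConfig <- function(batchSize = 16L, learningRate = 1e-5, epochs = 30L,
                        loss = list(), seed = 1L) {
  defaults <- list(lambda1 = 0.1, lambda2 = 0.01, eps = 0.05, tau = 0.5,
                   costKind = "perspective", tol = 1e-5, maxIter = 100L)
  loss <- utils::modifyList(defaults, loss)
  cfg <- list(batchSize = as.integer(batchSize),
              learningRate = as.numeric(learningRate),
              epochs = as.integer(epochs), loss = loss,
              seed = as.integer(seed))
  if (cfg$batchSize < 1L) stop("batchSize must be >= 1")
  if (cfg$learningRate <= 0) stop("learningRate must be positive")
  if (cfg$epochs < 1L) stop("epochs must be >= 1")
  class(cfg) <- "TrainConfig"
  cfg
}

adamStep <- function(model, grads, state, lr, t, beta1 = 0.9, beta2 = 0.999,
                     epsAdam = 1e-8) {
  upd <- function(p, g, m, v) {
    m <- beta1 * m + (1 - beta1) * g
    v <- beta2 * v + (1 - beta2) * g^2
    mh <- m / (1 - beta1^t); vh <- v / (1 - beta2^t)
    list(p = p - lr * mh / (sqrt(vh) + epsAdam), m = m, v = v)
  }
  for (b in seq_along(model$enc)) for (f in c("w", "b")) {
    r <- upd(model$enc[[b]][[f]], grads$enc[[b]][[f]],
             state$m$enc[[b]][[f]], state$v$enc[[b]][[f]])
    model$enc[[b]][[f]] <- r$p
    state$m$enc[[b]][[f]] <- r$m; state$v$enc[[b]][[f]] <- r$v
  }
  for (b in seq_along(model$head)) for (f in c("w", "b")) {
    r <- upd(model$head[[b]][[f]], grads$head[[b]][[f]],
             state$m$head[[b]][[f]], state$v$head[[b]][[f]])
    model$head[[b]][[f]] <- r$p
    state$m$head[[b]][[f]] <- r$m; state$v$head[[b]][[f]] <- r$v
  }
  for (f in c("w", "b")) {
    r <- upd(model$out[[f]], grads$out[[f]],
             state$m$out[[f]], state$v$out[[f]])
    model$out[[f]] <- r$p
    state$m$out[[f]] <- r$m; state$v$out[[f]] <- r$v
  }
  list(model = model, state = state)
}

zeroLike <- function(model) {
  list(enc = lapply(model$enc, function(l) list(w = l$w * 0, b = l$b * 0)),
       head = lapply(model$head, function(l) list(w = l$w * 0, b = l$b * 0)),
       out = list(w = model$out$w * 0, b = model$out$b * 0))
}

addGrads <- function(acc, g, scale = 1) {
  for (b in seq_along(acc$enc)) for (f in c("w", "b"))
    acc$enc[[b]][[f]] <- acc$enc[[b]][[f]] + scale * g$enc[[b]][[f]]
  for (b in seq_along(acc$head)) for (f in c("w", "b"))
    acc$head[[b]][[f]] <- acc$head[[b]][[f]] + scale * g$head[[b]][[f]]
  for (f in c("w", "b"))
    acc$out[[f]] <- acc$out[[f]] + scale * g$out[[f]]
  acc
}

# load images and annotations named by a manifest into memory
loadManifest <- function(manifest, dataDir) {
  lapply(seq_len(nrow(manifest)), function(i) {
    list(id = manifest$image_id[i],
         image = readImageFile(file.path(dataDir, manifest$image[i])),
         points = readPoints(file.path(dataDir, manifest$points[i])))
  })
}

#' Train the density regressor on a synthetic-scene dataset
#'
#' Runs mini-batch Adam under the composite loss ([compositeLoss()]),
#' logging every loss term per epoch together with the validation MAE, and
#' returns the trained model. Ground-truth density maps are rendered with
#' the geometry-adaptive kernel and sum-pooled to the model stride, so the
#' OT term compares the strided prediction with the annotated dots in source
#' coordinates.
#'
#' @param model a `ShootCountModel` from [buildModel()].
#' @param manifest data.frame from [generateDataset()] (or the same columns:
#'   `image_id`, `image`, `points`).
#' @param config a [trainConfig()].
#' @param dataDir directory the manifest paths are relative to.
#' @param valIds image ids held out for validation; must be disjoint from
#'   training (default: the last 20% of the manifest).
#' @return A `TrainingRecord` list: `model` (trained), `history` (per-epoch
#'   data.frame of mean loss terms and validation MAE), `valIds`, `config`.
#' @export
trainCounter <- function(model, manifest, config = trainConfig(),
                         dataDir = ".", valIds = NULL) {
  stopifnot(inherits(model, "ShootCountModel"), inherits(config, "TrainConfig"))
  if (nrow(manifest) == 0L) stop("empty training manifest")
  if (is.null(valIds))
    valIds <- utils::tail(manifest$image_id, max(1L, ceiling(nrow(manifest) * 0.2)))
  trainIds <- setdiff(manifest$image_id, valIds)
  if (length(trainIds) == 0L) stop("empty training set after holding out valIds")

  data <- loadManifest(manifest, dataDir)
  names(data) <- manifest$image_id
  stride <- model$config$outputStride
  for (i in seq_along(data)) {
    gt <- renderDensity(data[[i]]$points)
    data[[i]]$gtDensity <- downsampleDensity(gt, stride)
  }

  lc <- config$loss
  state <- list(m = zeroLike(model), v = zeroLike(model))
  history <- NULL
  t <- 0L
  withSceneSeed(config$seed, 13L, {
    for (epoch in seq_len(config$epochs)) {
      ord <- sample(trainIds)
      batches <- split(ord, ceiling(seq_along(ord) / config$batchSize))
      terms <- c(countLoss = 0, otLoss = 0, pixelMse = 0, total = 0)
      for (bi in seq_along(batches)) {
        ids <- batches[[bi]]
        acc <- zeroLike(model)
        for (id in ids) {
          d <- data[[id]]
          fw <- modelForward(model, d$image, keep = TRUE)
          pred <- densityMap(fw$density, stride = stride, sourceId = id)
          res <- .compositeLossImpl(pred, d$points, d$gtDensity,
                                    lc$lambda1, lc$lambda2, lc$eps, lc$tau,
                                    lc$costKind, lc$tol, lc$maxIter,
                                    withGrad = TRUE)
          lb <- res$breakdown
          if (!is.finite(lossTotal(lb)))
            stop("non-finite loss in epoch ", epoch, ", batch ", bi,
                 ", image ", id)
          terms <- terms + lossTerms(lb)[c("countLoss", "otLoss", "pixelMse",
                                           "total")]
          acc <- addGrads(acc, modelBackward(model, fw, res$grad),
                          scale = 1 / length(ids))
        }
        t <- t + 1L
        st <- adamStep(model, acc, state, config$learningRate, t)
        model <- st$model; state <- st$state
      }
      valMae <- NA_real_
      if (length(valIds)) {
        err <- vapply(valIds, function(id) {
          d <- data[[id]]
          abs(predictCount(model, d$image)$count - pointCount(d$points))
        }, numeric(1))
        valMae <- mean(err)
      }
      nTrainImg <- length(ord)
      history <- rbind(history, data.frame(
        epoch = epoch,
        countLoss = terms[["countLoss"]] / nTrainImg,
        otLoss = terms[["otLoss"]] / nTrainImg,
        pixelMse = terms[["pixelMse"]] / nTrainImg,
        total = terms[["total"]] / nTrainImg,
        valMAE = valMae))
    }
  })
  structure(list(model = model, history = history, valIds = valIds,
                 config = config),
            class = "TrainingRecord")
}

#' @export
print.TrainingRecord <- function(x, ...) {
  last <- utils::tail(x$history, 1)
  cat(sprintf("TrainingRecord: %d epochs, final total loss %.4f, val MAE %.3f\n",
              nrow(x$history), last$total, last$valMAE))
  invisible(x)
}

#' Mean-count baseline MAE
#'
#' MAE of the constant predictor that always outputs the mean training-set
#' count -- the reference any trained counter must beat.
#'
#' @param trainCounts counts of the training images.
#' @param valCounts counts of the evaluation images.
#' @return the baseline mean absolute error.
#' @export
meanCountBaseline <- function(trainCounts, valCounts) {
  mean(abs(valCounts - mean(trainCounts)))
}
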