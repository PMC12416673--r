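#' Training configuration
#'
#' Adam with a staged learning rate: `lrInitial` for the first
#' `lrSwitchEpoch` epochs, `lrAfter` from then on. Weights are
#' checkpointed every `checkpointEvery` epochs and at the best validation
#' loss.
#'
#' @param epochs number of training epochs
#' @param lrInitial learning rate for the first stage (default 0.003)
#' @param lrAfter learning rate after the switch (default 0.0001)
#' @param lrSwitchEpoch last epoch of the first stage (default 150)
#' @param beta1,beta2 Adam moment decay rates (defaults 0.9 / 0.999)
#' @param batchSize mini-batch size; `NULL` picks 8 for images up to
#'   128 px and 2 for larger ones
#' @param checkpointEvery checkpoint period in epochs
#' @param seed RNG seed governing initialization, shuffling and
#'   augmentation
#' @param variant model variant, see [modelConfig()]
#' @param augment apply one random augmentation per training image per
#'   epoch
#' @param valRatio training fraction of the train/validation split
#'   (`1` disables validation)
#' @return validated list of class `hardvessel_train_config`
#' @export
trainConfig <- function(epochs = 150L, lrInitial = 0.003, lrAfter = 1e-4,
                        lrSwitchEpoch = 150L, beta1 = 0.9, beta2 = 0.999,
                        batchSize = NULL, checkpointEvery = 20L,
                        seed = 1L, variant = "full", augment = TRUE,
                        valRatio = 0.9) {
  stopifnot(epochs >= 1, lrInitial > 0, lrAfter > 0, checkpointEvery >= 1,
            beta1 >= 0, beta1 < 1, beta2 >= 0, beta2 < 1,
            valRatio > 0, valRatio <= 1)
  structure(list(epochs = as.integer(epochs), lrInitial = lrInitial,
                 lrAfter = lrAfter, lrSwitchEpoch = as.integer(lrSwitchEpoch),
                 beta1 = beta1, beta2 = beta2,
                 batchSize = if (!is.null(batchSize)) as.integer(batchSize),
                 checkpointEvery = as.integer(checkpointEvery),
                 seed = as.integer(seed), variant = variant,
                 augment = isTRUE(augment), valRatio = valRatio),
            class = "hardvessel_train_config")
}

#' Learning rate at a given epoch
#'
#' Staged schedule: `lrInitial` through `lrSwitchEpoch`, `lrAfter`
#' afterwards (with defaults: 0.003 for epochs 1..150, then 0.0001).
#'
#' @param epoch epoch number, `>= 1`
#' @param config a [trainConfig()]
#' @return learning rate
#' @export
lrAt <- function(epoch, config = trainConfig()) {
  if (epoch < 1) stop("epoch must be >= 1")
  if (epoch <= config$lrSwitchEpoch) config$lrInitial else config$lrAfter
}

# -- checkpoints -------------------------------------------------------------

modelStateGet <- function(model) {
  list(params = lapply(model$params, function(p) p$val),
       bns = lapply(model$bns, function(b) {
         list(runMean = b$runMean, runVar = b$runVar)
       }))
}

modelStateSet <- function(model, state) {
  stopifnot(length(state$params) == length(model$params),
            length(state$bns) == length(model$bns))
  for (i in seq_along(model$params)) {
    p <- model$params[[i]]
    v <- state$params[[i]]
    if (length(v) != length(p$val) ||
        !identical(dim(v), dim(p$val)))
      stop("stored weight ", i, " (", p$name, ") has the wrong shape")
    p$val <- v
  }
  for (i in seq_along(model$bns)) {
    model$bns[[i]]$runMean <- state$bns[[i]]$runMean
    model$bns[[i]]$runVar <- state$bns[[i]]$runVar
  }
  invisible(model)
}

#' Save / load a model checkpoint
#'
#' Checkpoints embed the model configuration, so [loadCheckpoint()]
#' rebuilds the architecture and restores weights and normalization
#' statistics; a mismatch between the stored weights and the rebuilt
#' architecture is an error.
#'
#' @param model a `hardvessel_model`
#' @param path file to write
#' @param meta optional list stored alongside (epoch, history, ...)
#' @export
saveCheckpoint <- function(model, path, meta = NULL) {
  dir.create(dirname(path), recursive = TRUE, showWarnings = FALSE)
  saveRDS(list(config = unclass(model$config), state = modelStateGet(model),
               meta = meta), path)
  invisible(path)
}

#' @rdname saveCheckpoint
#' @return `loadCheckpoint`: list with `model` and `meta`
#' @export
loadCheckpoint <- function(path) {
  ck <- readRDS(path)
  model <- buildModel(do.call(modelConfig, ck$config))
  ok <- tryCatch({
    modelStateSet(model, ck$state)
    TRUE
  }, error = function(e) FALSE)
  if (!ok) stop("checkpoint weights do not match the model built from its config")
  list(model = model, meta = ck$meta)
}

# -- batch helpers -----------------------------------------------------------

samplesToBatch <- function(samples) {
  d <- dim(sampleImage(samples[[1]]))
  x <- array(0, c(d[1], d[2], 3L, length(samples)))
  for (i in seq_along(samples)) x[, , , i] <- sampleImage(samples[[i]])
  x
}

diceFromCounts <- function(counts) {
  2 * counts@tp / (2 * counts@tp + counts@fp + counts@fn)
}

# -- training ----------------------------------------------------------------

#' Train a segmentation model
#'
#' Full training loop: deterministic 9:1 train/validation split by sorted
#' id, per-epoch shuffled mini-batches with one random augmentation per
#' image, forward pass, edge-weighted IoU+BCE loss, Adam update at the
#' staged learning rate, per-epoch validation (loss, accuracy, Dice), and
#' periodic + best-validation checkpoints. Fully reproducible from
#' `config$seed`.
#'
#' @param data a dataset root directory (DRIVE-style, see [loadDataset()])
#'   or a list of [FundusSample-class] objects
#' @param config a [trainConfig()]
#' @param modelCfg a [modelConfig()]; defaults to the config's `variant`
#' @param lossCfg a [lossConfig()]
#' @param runDir directory for checkpoints and `history.csv`; `NULL` uses
#'   a temporary directory
#' @param model optionally, an existing model to continue training
#' @return list of class `hardvessel_history`: `history` (per-epoch data
#'   frame), `model`, `checkpoints`, `bestEpoch`, `runDir`
#' @export
trainModel <- function(data, config = trainConfig(),
                       modelCfg = modelConfig(config$variant),
                       lossCfg = lossConfig(), runDir = NULL,
                       model = NULL) {
  samples <- if (is.character(data)) loadDataset(data) else data
  if (length(samples) == 0L) stop("empty dataset")
  if (is.null(runDir)) runDir <- tempfile("hardvessel_run_")
  dir.create(file.path(runDir, "checkpoints"), recursive = TRUE,
             showWarnings = FALSE)
  set.seed(config$seed)
  if (is.null(model)) model <- buildModel(modelCfg)

  ids <- vapply(samples, sampleId, "")
  names(samples) <- ids
  if (config$valRatio < 1 && length(samples) >= 2L) {
    sp <- splitTrainVal(ids, config$valRatio)
  } else {
    sp <- list(train = sort(ids), val = character(0))
  }
  trainSet <- samples[sp$train]
  valSet <- samples[sp$val]
  d <- dim(sampleImage(trainSet[[1]]))
  bs <- if (!is.null(config$batchSize)) config$batchSize
        else if (max(d[1:2]) <= 128L) 8L else 2L
  optState <- new.env(parent = emptyenv()); optState$t <- 0L
  # Edge-weight maps depend only on the mask; cache per sample and flip
  # alongside geometric augmentations instead of recomputing per step.
  wCache <- lapply(trainSet, function(s) {
    edgeWeightMap(vesselMask(s), lossCfg$window, lossCfg$gamma,
                  lossCfg$border)
  })

  hist <- vector("list", config$epochs)
  checkpoints <- character(0)
  bestVal <- Inf; bestEpoch <- NA_integer_
  for (epoch in seq_len(config$epochs)) {
    lr <- lrAt(epoch, config)
    ord <- sample(length(trainSet))
    epochLoss <- 0; nBatches <- 0L
    epochCounts <- ConfusionCounts()
    for (b in split(ord, ceiling(seq_along(ord) / bs))) {
      batch <- lapply(trainSet[b], function(s) {
        if (config$augment) augmentRandom(s) else s
      })
      x <- samplesToBatch(batch)
      tape <- agTape()
      out <- modelForward(model, x, training = TRUE, tape = tape)
      N <- length(batch)
      gProb <- array(0, dim(out$prob))
      gAux <- if (!is.null(out$aux))
        lapply(out$aux, function(a) array(0, dim(a)))
      batchLoss <- 0
      for (i in seq_len(N)) {
        G <- vesselMask(batch[[i]])
        Wi <- wCache[[b[i]]]
        ch <- attr(batch[[i]], "augmentChoice")
        if (!is.null(ch)) {
          if (ch$kind == "hflip") Wi <- Wi[, rev(seq_len(ncol(Wi)))]
          if (ch$kind == "vflip") Wi <- Wi[rev(seq_len(nrow(Wi))), ]
        }
        aux_i <- if (!is.null(out$aux))
          lapply(out$aux, function(a) a[, , 1L, i])
        li <- totalLoss(out$prob[, , 1L, i], G, lossCfg, aux = aux_i,
                        grad = TRUE, W = Wi)
        batchLoss <- batchLoss + li$total / N
        gProb[, , 1L, i] <- li$grad / N
        if (!is.null(gAux)) for (k in seq_along(gAux))
          gAux[[k]][, , 1L, i] <- li$auxGrad[[k]] / N
        epochCounts <- epochCounts +
          confusion(out$prob[, , 1L, i], G, fovMask(batch[[i]]))
      }
      if (!is.finite(batchLoss))
        stop(sprintf("non-finite loss at epoch %d (lr %g): training aborted",
                     epoch, lr))
      seeds <- list(out$nodes$prob)
      grads <- list(gProb)
      if (!is.null(gAux)) {
        seeds <- c(seeds, out$nodes$aux)
        grads <- c(grads, gAux)
      }
      agZeroGrad(model$params)
      agBackward(tape, seeds, grads)
      adamStep(model$params, optState, lr, config$beta1, config$beta2)
      epochLoss <- epochLoss + batchLoss
      nBatches <- nBatches + 1L
    }
    trainDice <- diceFromCounts(epochCounts)
    val <- evalOnSamples(model, valSet, lossCfg)
    row <- data.frame(epoch = epoch, lr = lr,
                      trainLoss = epochLoss / nBatches,
                      trainDice = trainDice,
                      valLoss = val$loss, valAcc = val$acc,
                      valDice = val$dice)
    hist[[epoch]] <- row
    if (epoch %% config$checkpointEvery == 0L) {
      p <- file.path(runDir, "checkpoints", sprintf("epoch_%04d.rds", epoch))
      saveCheckpoint(model, p, meta = list(epoch = epoch))
      checkpoints <- c(checkpoints, p)
    }
    if (!is.na(val$loss) && val$loss < bestVal) {
      bestVal <- val$loss; bestEpoch <- epoch
      saveCheckpoint(model, file.path(runDir, "checkpoints", "best.rds"),
                     meta = list(epoch = epoch, valLoss = val$loss))
    }
  }
  history <- do.call(rbind, hist)
  utils::write.csv(history, file.path(runDir, "history.csv"),
                   row.names = FALSE)
  structure(list(history = history, model = model,
                 checkpoints = checkpoints, bestEpoch = bestEpoch,
                 runDir = runDir),
            class = "hardvessel_history")
}

# Validation pass: loss, FOV accuracy and Dice in eval mode.
evalOnSamples <- function(model, samples, lossCfg) {
  if (length(samples) == 0L)
    return(list(loss = NA_real_, acc = NA_real_, dice = NA_real_))
  totLoss <- 0
  counts <- ConfusionCounts()
  for (s in samples) {
    out <- modelForward(model, sampleImage(s), training = FALSE)
    S <- out$prob[, , 1L, 1L]
    totLoss <- totLoss + totalLoss(S, vesselMask(s), lossCfg)$total
    counts <- counts + confusion(S, vesselMask(s), fovMask(s))
  }
  m <- metricsFromConfusion(counts)
  list(loss = totLoss / length(samples), acc = m@acc,
       dice = diceFromCounts(counts))
}

#' Predict vessel probability maps
#'
#' Runs inference on images or samples, pads each to the model grid
#' internally and crops back to native size, and (optionally) writes per
#' image a 16-bit TIFF probability map and an 8-bit PNG binary mask
#' (values 0/255) thresholded at 0.5.
#'
#' @param model a `hardvessel_model` or a checkpoint path
#' @param inputs list of [FundusSample-class] objects, or a character
#'   vector of image paths
#' @param outDir directory for `*_prob.tiff` / `*_mask.png` outputs;
#'   `NULL` skips writing
#' @param threshold binarization threshold
#' @return named list of probability matrices (native geometry)
#' @export
predictSamples <- function(model, inputs, outDir = NULL, threshold = 0.5) {
  if (is.character(model)) model <- loadCheckpoint(model)$model
  if (is.character(inputs)) {
    ids <- tools::file_path_sans_ext(basename(inputs))
    imgs <- lapply(inputs, readImageHW)
  } else {
    ids <- vapply(inputs, sampleId, "")
    imgs <- lapply(inputs, sampleImage)
  }
  if (!is.null(outDir)) dir.create(outDir, recursive = TRUE,
                                   showWarnings = FALSE)
  out <- vector("list", length(imgs))
  for (i in seq_along(imgs)) {
    img <- imgs[[i]]
    if (length(dim(img)) == 2L) img <- array(rep(img, 3L), c(dim(img), 3L))
    S <- modelForward(model, img, training = FALSE)$prob[, , 1L, 1L]
    out[[i]] <- S
    if (!is.null(outDir)) {
      tiff::writeTIFF(S, file.path(outDir, paste0(ids[i], "_prob.tiff")),
                      bits.per.sample = 16L)
      png::writePNG((S >= threshold) * 1,
                    file.path(outDir, paste0(ids[i], "_mask.png")))
    }
  }
  names(out) <- ids
  out
}

#' Evaluate a model on a labelled dataset
#'
#' Predicts every sample, computes FOV-restricted confusion counts, Se,
#' Sp, precision, F1, ACC and AUC per image, and aggregates them both
#' pooled and as per-image mean +/- sd. Optionally writes
#' `metrics_per_image.csv` and `metrics_summary.json`.
#'
#' @param model a `hardvessel_model` or checkpoint path
#' @param data dataset root or list of [FundusSample-class] objects
#' @param outDir optional directory for report files
#' @param threshold operating threshold
#' @return list as [aggregateOverDataset()], plus `predictions`
#' @export
evaluateModel <- function(model, data, outDir = NULL, threshold = 0.5) {
  if (is.character(model)) model <- loadCheckpoint(model)$model
  samples <- if (is.character(data)) loadDataset(data) else data
  if (length(samples) == 0L) stop("empty dataset")
  preds <- predictSamples(model, samples)
  pooledS <- numeric(0); pooledG <- numeric(0)
  perImage <- lapply(seq_along(samples), function(i) {
    s <- samples[[i]]
    S <- preds[[i]]
    fov <- fovMask(s)
    keep <- fov == 1
    pooledS <<- c(pooledS, S[keep])
    pooledG <<- c(pooledG, vesselMask(s)[keep])
    list(id = sampleId(s),
         counts = confusion(S, vesselMask(s), fov, threshold),
         auc = rocAuc(S, vesselMask(s), fov)$auc)
  })
  pooledAuc <- rocAuc(matrix(pooledS), matrix(pooledG))$auc
  agg <- aggregateOverDataset(perImage, threshold, pooledAuc = pooledAuc)
  if (!is.null(outDir)) {
    dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
    utils::write.csv(agg$table, file.path(outDir, "metrics_per_image.csv"),
                     row.names = FALSE)
    jsonlite::write_json(
      list(pooled = asMetricsRow(agg$pooled), mean = as.list(agg$mean),
           sd = as.list(agg$sd)),
      file.path(outDir, "metrics_summary.json"), auto_unbox = TRUE,
      digits = NA, pretty = TRUE)
  }
  c(agg, list(predictions = preds))
}
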