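#' Segmentation model configuration
#'
#' Describes one of the four ablation variants of the vessel-segmentation
#' network and its channel plan. The encoder is a two-conv stride-2 stem
#' followed by four stages (block, 1x1 transition, 2x2 downsample between
#' stages) producing features at 1/4, 1/8, 1/16 and 1/32 of the input
#' resolution; skip modules feed the three deepest scales to a partial
#' decoder that aggregates them multiplicatively into logits at 1/8 scale.
#'
#' @param variant `"baseline"` (plain double-conv stages, plain 1x1 skips),
#'   `"hard"` (harmonic dense blocks, plain skips), `"rfb"` (plain stages,
#'   receptive-field-block skips) or `"full"` (both)
#' @param growthRates per-stage base width of the harmonic blocks
#' @param multiplier geometric widening factor of the harmonic blocks
#' @param layersPerBlock conv layers per stage block
#' @param stemChannels widths of the two stem convs
#' @param transChannels per-stage transition (stage output) widths
#' @param aggChannels width of the skip/decoder streams
#' @param deepSupervision if `TRUE`, auxiliary full-resolution probability
#'   maps are produced from each skip stream and share the training loss
#' @return a validated list of class `hardvessel_model_config`
#' @export
modelConfig <- function(variant = c("full", "baseline", "hard", "rfb"),
                        growthRates = c(10L, 16L, 18L, 24L),
                        multiplier = 1.7,
                        layersPerBlock = c(4L, 4L, 8L, 8L),
                        stemChannels = c(16L, 16L),
                        transChannels = c(24L, 32L, 40L, 48L),
                        aggChannels = 24L,
                        deepSupervision = FALSE) {
  variant <- match.arg(variant)
  stopifnot(length(growthRates) == 4, length(layersPerBlock) == 4,
            length(transChannels) == 4, length(stemChannels) == 2,
            multiplier >= 1, all(layersPerBlock >= 1), aggChannels >= 1)
  structure(list(variant = variant,
                 growthRates = as.integer(growthRates),
                 multiplier = multiplier,
                 layersPerBlock = as.integer(layersPerBlock),
                 stemChannels = as.integer(stemChannels),
                 transChannels = as.integer(transChannels),
                 aggChannels = as.integer(aggChannels),
                 deepSupervision = isTRUE(deepSupervision)),
            class = "hardvessel_model_config")
}

#' Build a segmentation model
#'
#' Instantiates the network described by a [modelConfig()] with randomly
#' initialized weights (He-normal convs, unit-gain batch norm). Weight
#' initialization draws from R's RNG; seed it for reproducible models.
#'
#' @param config a [modelConfig()]
#' @return an object of class `hardvessel_model`
#' @export
buildModel <- function(config = modelConfig()) {
  if (!inherits(config, "hardvessel_model_config"))
    config <- do.call(modelConfig, config)
  ctx <- newCtx()
  useHard <- config$variant %in% c("hard", "full")
  useRfb <- config$variant %in% c("rfb", "full")
  tc <- config$transChannels
  stem <- list(ctxCbr(ctx, 3L, 3L, config$stemChannels[1], "stem1"),
               ctxCbr(ctx, 3L, config$stemChannels[1],
                      config$stemChannels[2], "stem2"))
  inCh <- config$stemChannels[2]
  stages <- vector("list", 4L)
  for (i in 1:4) {
    if (useHard) {
      spec <- hardBlockSpec(inCh, config$layersPerBlock[i],
                            config$growthRates[i], config$multiplier)
      block <- buildHardBlock(ctx, spec, sprintf("stage%d", i))
      blockOut <- spec$outChannels
    } else {
      block <- list(ctxCbr(ctx, 3L, inCh, tc[i], sprintf("stage%d.c1", i)),
                    ctxCbr(ctx, 3L, tc[i], tc[i], sprintf("stage%d.c2", i)))
      blockOut <- tc[i]
    }
    trans <- ctxCbr(ctx, 1L, blockOut, tc[i], sprintf("stage%d.trans", i))
    stages[[i]] <- list(block = block, trans = trans, hard = useHard)
    inCh <- tc[i]
  }
  skips <- lapply(2:4, function(i) {
    if (useRfb) {
      buildRfb(ctx, rfbSpec(tc[i], config$aggChannels),
               sprintf("skip%d", i))
    } else {
      ctxCbr(ctx, 1L, tc[i], config$aggChannels, sprintf("skip%d", i))
    }
  })
  agg <- buildAggregator(ctx, 3L, config$aggChannels)
  auxHeads <- if (config$deepSupervision) {
    lapply(1:3, function(i) {
      ctxConv(ctx, 1L, config$aggChannels, 1L, sprintf("aux%d", i))
    })
  }
  structure(list(config = config, stem = stem, stages = stages,
                 skips = skips, agg = agg, auxHeads = auxHeads,
                 useRfb = useRfb, params = ctx$params, bns = ctx$bns),
            class = "hardvessel_model")
}

#' @export
print.hardvessel_model <- function(x, ...) {
  cfg <- x$config
  cat("<hardvessel_model>\n")
  cat("  variant:        ", cfg$variant, "\n")
  cat("  stage widths:   ", paste(cfg$transChannels, collapse = "/"), "\n")
  if (cfg$variant %in% c("hard", "full"))
    cat("  harmonic blocks:", paste(cfg$layersPerBlock, collapse = "/"),
        "layers, growth", paste(cfg$growthRates, collapse = "/"),
        "x", cfg$multiplier, "\n")
  cat("  decoder width:  ", cfg$aggChannels, "\n")
  cat("  deep supervision:", cfg$deepSupervision, "\n")
  cat("  parameters:     ", countParameters(x), "\n")
  invisible(x)
}

#' Count trainable parameters
#'
#' @param model a `hardvessel_model`, or any nested structure of parameter
#'   environments
#' @return integer count of trainable scalars
#' @examples
#' \dontrun{countParameters(buildModel(modelConfig("baseline")))}
#' @export
countParameters <- function(model) {
  params <- if (inherits(model, "hardvessel_model")) model$params
            else collectParams(model)
  sum(vapply(params, function(p) {
    if (isFALSE(p$trainable)) 0L else length(p$val)
  }, integer(1)))
}

# Recursively harvest ag_param environments from nested lists/envs.
collectParams <- function(x) {
  if (inherits(x, "ag_param")) return(list(x))
  if (is.environment(x)) x <- as.list(x)
  if (is.list(x)) return(do.call(c, lapply(x, collectParams)))
  list()
}

#' Forward pass of the segmentation network
#'
#' Runs a batch of images through the configured variant. Inputs whose
#' height or width is not divisible by 32 are zero-padded (centered) to the
#' next multiple internally and the output map is cropped back, so e.g.
#' 592 x 592 inputs are processed at 608 x 608 and returned at 592 x 592.
#'
#' @param model a `hardvessel_model`
#' @param x numeric array `H x W x 3 x N` (a single `H x W x 3` image is
#'   promoted to a batch of one) with values in `[0, 1]`
#' @param training use batch statistics (`TRUE`) or running statistics
#'   (`FALSE`) in the normalization layers
#' @param tape optionally, a tape from [agTape()] to record the pass for
#'   gradient computation; when supplied, nodes are returned in `$nodes`
#' @return list with `prob` (`H x W x 1 x N` array of vessel probabilities),
#'   `aux` (list of auxiliary probability arrays when deep supervision is
#'   on), and when a tape was supplied, `nodes` (list with `prob` and `aux`
#'   output nodes for [agBackward()])
#' @export
modelForward <- function(model, x, training = FALSE, tape = NULL) {
  if (length(dim(x)) == 3L) dim(x) <- c(dim(x), 1L)
  d <- dim(x)
  if (d[3] != 3L) stop("input must have 3 channels, got ", d[3])
  keepNodes <- !is.null(tape)
  if (is.null(tape)) tape <- agTape()
  H <- d[1]; W <- d[2]
  Hp <- 32L * ((H + 31L) %/% 32L)
  Wp <- 32L * ((W + 31L) %/% 32L)
  offR <- (Hp - H) %/% 2L; offC <- (Wp - W) %/% 2L
  if (Hp != H || Wp != W) {
    xp <- array(0, c(Hp, Wp, d[3], d[4]))
    xp[offR + seq_len(H), offC + seq_len(W), , ] <- x
    x <- xp
  }
  nd <- opInput(tape, x)
  nd <- fwdCbr(tape, nd, model$stem[[1]], training, stride = 2L)
  nd <- fwdCbr(tape, nd, model$stem[[2]], training, stride = 2L)
  feats <- vector("list", 4L)
  for (i in 1:4) {
    if (i > 1L) nd <- opAvgPool2(tape, nd)
    st <- model$stages[[i]]
    nd <- if (st$hard) hardBlockForward(tape, nd, st$block, training)
          else fwdCbr(tape, fwdCbr(tape, nd, st$block[[1]], training),
                      st$block[[2]], training)
    nd <- fwdCbr(tape, nd, st$trans, training)
    feats[[i]] <- nd
  }
  # cascaded partial decoder: the shallow 1/4 features are discarded
  sk <- lapply(1:3, function(i) {
    if (model$useRfb) rfbForward(tape, feats[[i + 1L]], model$skips[[i]],
                                 training)
    else fwdCbr(tape, feats[[i + 1L]], model$skips[[i]], training)
  })
  logits <- aggregateForward(tape, sk, model$agg, training)
  up <- opBilinear(tape, logits, Hp, Wp)
  if (Hp != H || Wp != W) up <- opCrop(tape, up, H, W, offR, offC)
  prob <- opSigmoid(tape, up)
  auxNodes <- NULL
  if (model$config$deepSupervision) {
    auxNodes <- lapply(1:3, function(i) {
      a <- fwdConv(tape, sk[[i]], model$auxHeads[[i]])
      a <- opBilinear(tape, a, Hp, Wp)
      if (Hp != H || Wp != W) a <- opCrop(tape, a, H, W, offR, offC)
      opSigmoid(tape, a)
    })
  }
  out <- list(prob = prob$val,
              aux = if (!is.null(auxNodes)) lapply(auxNodes, `[[`, "val"))
  if (keepNodes) out$nodes <- list(prob = prob, aux = auxNodes)
  out
}
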