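#' Harmonic shortcut pattern of a dense block layer
#'
#' In a harmonic dense block, layer `k` receives shortcut connections only
#' from layers `k - 2^n` for every non-negative integer `n` such that `2^n`
#' divides `k` (layer 0 being the block input). This prunes the all-pairs
#' connectivity of a classic dense block to a logarithmic number of
#' shortcuts, which is the defining feature of the harmonic design.
#'
#' @param k layer index within the block, `k >= 1`
#' @return integer vector of input layer indices, in decreasing order
#' @examples
#' hardBlockLinks(1)  # 0
#' hardBlockLinks(6)  # 5 4
#' hardBlockLinks(8)  # 7 6 4 0
#' @export
hardBlockLinks <- function(k) {
  k <- as.integer(k)
  if (length(k) != 1L || is.na(k) || k < 1L)
    stop("layer index k must be a single integer >= 1")
  pows <- 1L
  links <- integer(0)
  while (pows <= k) {
    if (k %% pows == 0L) links <- c(links, k - pows)
    pows <- pows * 2L
  }
  sort(links, decreasing = TRUE)
}

#' Channel width of a harmonic dense block layer
#'
#' Layers sitting at positions divisible by high powers of two carry more
#' shortcut traffic and are widened geometrically: the width is
#' `growthRate * growthMultiplier^p` where `p` is the largest `n` with
#' `2^n` dividing `k`, rounded down to an even integer (`2 * floor(x / 2)`).
#'
#' @param k layer index, `k >= 1`
#' @param growthRate base channel count per layer
#' @param growthMultiplier geometric widening factor (>= 1)
#' @return integer channel count
#' @examples
#' hardBlockChannels(3, 16, 1.7)  # 16 (odd index)
#' hardBlockChannels(2, 16, 1.7)  # 26
#' hardBlockChannels(4, 16, 1.7)  # 46
#' @export
hardBlockChannels <- function(k, growthRate, growthMultiplier) {
  k <- as.integer(k)
  if (length(k) != 1L || is.na(k) || k < 1L)
    stop("layer index k must be a single integer >= 1")
  p <- 0L
  while (k %% (2L^(p + 1L)) == 0L) p <- p + 1L
  2L * as.integer(floor(growthRate * growthMultiplier^p / 2))
}

#' Layout of one harmonic dense block
#'
#' Precomputes, for a block of `nLayers` layers on top of `inChannels` input
#' channels, the shortcut links, per-layer widths, per-layer conv input
#' widths, and the set of layers whose outputs are concatenated into the
#' block output (the last layer plus all odd-indexed layers; even-indexed
#' intermediate outputs can be dropped once consumed).
#'
#' @param inChannels channels entering the block (layer 0)
#' @param nLayers number of conv layers
#' @param growthRate base width per layer
#' @param growthMultiplier geometric widening factor
#' @return a list with elements `nLayers`, `inChannels`, `links`,
#'   `layerChannels`, `convIn`, `outLayers`, `outChannels`
#' @export
hardBlockSpec <- function(inChannels, nLayers, growthRate, growthMultiplier) {
  stopifnot(nLayers >= 1, inChannels >= 1)
  ch <- vapply(seq_len(nLayers), hardBlockChannels, integer(1),
               growthRate = growthRate, growthMultiplier = growthMultiplier)
  links <- lapply(seq_len(nLayers), hardBlockLinks)
  chOf <- function(j) if (j == 0L) inChannels else ch[j]
  convIn <- vapply(links, function(l) sum(vapply(l, chOf, integer(1))),
                   integer(1))
  outLayers <- sort(unique(c(seq(1L, nLayers, by = 2L), nLayers)))
  list(nLayers = as.integer(nLayers), inChannels = as.integer(inChannels),
       growthRate = growthRate, growthMultiplier = growthMultiplier,
       links = links, layerChannels = ch, convIn = convIn,
       outLayers = outLayers, outChannels = sum(ch[outLayers]))
}

buildHardBlock <- function(ctx, spec, name = "hard") {
  units <- lapply(seq_len(spec$nLayers), function(k) {
    ctxCbr(ctx, 3L, spec$convIn[k], spec$layerChannels[k],
           sprintf("%s.l%d", name, k))
  })
  list(spec = spec, units = units)
}

# Forward pass of one harmonic block. Layer 0 is the input; each layer k is
# conv3x3+BN+ReLU over the channel concat of its linked layers' outputs;
# the block output concatenates the last and all odd-indexed layers.
hardBlockForward <- function(tape, x, block, training = TRUE) {
  spec <- block$spec
  if (dim(x$val)[3] != spec$inChannels)
    stop(sprintf("hard block expects %d input channels, got %d",
                 spec$inChannels, dim(x$val)[3]))
  outs <- vector("list", spec$nLayers + 1L)
  outs[[1L]] <- x
  for (k in seq_len(spec$nLayers)) {
    ins <- lapply(spec$links[[k]], function(j) outs[[j + 1L]])
    xin <- if (length(ins) == 1L) ins[[1L]] else opConcat(tape, ins)
    if (dim(xin$val)[3] != spec$convIn[k])
      stop(sprintf("hard block layer %d: expected %d channels, got %d",
                   k, spec$convIn[k], dim(xin$val)[3]))
    outs[[k + 1L]] <- fwdCbr(tape, xin, block$units[[k]], training)
  }
  keep <- lapply(spec$outLayers, function(j) outs[[j + 1L]])
  if (length(keep) == 1L) keep[[1L]] else opConcat(tape, keep)
}
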