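#' Receptive field block specification
#'
#' A multi-branch module that widens the effective receptive field of a
#' feature map before it enters the decoder. Each branch reduces channels
#' with a 1x1 conv and (except the first) applies a 3x3 conv at its own
#' dilation rate; branch outputs are concatenated, fused by a 3x3 conv, and
#' a 1x1 shortcut of the input is added before the final activation.
#'
#' @param inChannels input channel count
#' @param outChannels output channel count
#' @param dilations dilation rate per 3x3 branch; the leading 1x1-only
#'   branch is always present, so the default gives four branches
#'   (1x1; 3x3 d=1; 3x3 d=3; 3x3 d=5)
#' @param branchChannels width of each branch
#' @return list describing the module layout
#' @export
rfbSpec <- function(inChannels, outChannels, dilations = c(1L, 3L, 5L),
                    branchChannels = max(4L, outChannels %/% 3L)) {
  stopifnot(length(dilations) >= 1, !anyDuplicated(dilations))
  list(inChannels = as.integer(inChannels),
       outChannels = as.integer(outChannels),
       dilations = as.integer(dilations),
       branchChannels = as.integer(branchChannels))
}

buildRfb <- function(ctx, spec, name = "rfb") {
  br <- spec$branchChannels
  reduce0 <- ctxCbr(ctx, 1L, spec$inChannels, br, paste0(name, ".b0"))
  branches <- lapply(seq_along(spec$dilations), function(i) {
    list(reduce = ctxCbr(ctx, 1L, spec$inChannels, br,
                         sprintf("%s.b%d.reduce", name, i)),
         dilconv = ctxCbr(ctx, 3L, br, br, sprintf("%s.b%d.dil", name, i)))
  })
  nb <- length(spec$dilations) + 1L
  fuse <- ctxCbr(ctx, 3L, nb * br, spec$outChannels, paste0(name, ".fuse"))
  shortcut <- ctxCbr(ctx, 1L, spec$inChannels, spec$outChannels,
                     paste0(name, ".shortcut"))
  list(spec = spec, reduce0 = reduce0, branches = branches, fuse = fuse,
       shortcut = shortcut)
}

rfbForward <- function(tape, x, rfb, training = TRUE) {
  spec <- rfb$spec
  if (dim(x$val)[3] != spec$inChannels)
    stop(sprintf("rfb expects %d input channels, got %d",
                 spec$inChannels, dim(x$val)[3]))
  outs <- list(fwdCbr(tape, x, rfb$reduce0, training))
  for (i in seq_along(spec$dilations)) {
    b <- rfb$branches[[i]]
    y <- fwdCbr(tape, x, b$reduce, training)
    y <- fwdCbr(tape, y, b$dilconv, training, dil = spec$dilations[i])
    outs[[i + 1L]] <- y
  }
  y <- opConcat(tape, outs)
  y <- fwdCbr(tape, y, rfb$fuse, training, relu = FALSE)
  s <- fwdCbr(tape, x, rfb$shortcut, training, relu = FALSE)
  opRelu(tape, opAdd(tape, y, s))
}
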