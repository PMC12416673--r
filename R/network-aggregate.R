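# Dense aggregation decoder. Takes skip-processed feature maps at
# successively coarser dyadic scales (finest first), upsamples the coarser
# maps bilinearly to the finest scale, refines each with conv+BN+ReLU, and
# fuses them by progressive element-wise multiplication. The multiplicative
# streams are concatenated, transformed by a conv+activation, combined
# additively with a 1x1 shortcut of the finest map, and projected to
# single-channel logits at the finest input scale.

buildAggregator <- function(ctx, nMaps, ch, name = "agg") {
  refine <- lapply(seq_len(nMaps), function(i) {
    ctxCbr(ctx, 3L, ch, ch, sprintf("%s.refine%d", name, i))
  })
  trans <- ctxCbr(ctx, 3L, nMaps * ch, ch, paste0(name, ".trans"))
  skip <- ctxConv(ctx, 1L, ch, ch, paste0(name, ".skip"))
  head <- ctxConv(ctx, 1L, ch, 1L, paste0(name, ".head"))
  list(nMaps = nMaps, ch = ch, refine = refine, trans = trans,
       skip = skip, head = head)
}

aggregateForward <- function(tape, maps, agg, training = TRUE) {
  n <- length(maps)
  if (n < 2L) stop("aggregation needs at least 2 feature maps")
  d0 <- dim(maps[[1L]]$val)
  for (i in seq_len(n)[-1L]) {
    di <- dim(maps[[i]]$val)
    if (any(di[1:2] * 2L != dim(maps[[i - 1L]]$val)[1:2]))
      stop("aggregation inputs must form a dyadic scale chain ",
           "(each map half the resolution of its predecessor)")
  }
  up <- vector("list", n)
  up[[1L]] <- maps[[1L]]
  for (i in seq_len(n)[-1L])
    up[[i]] <- opBilinear(tape, maps[[i]], d0[1], d0[2])
  ref <- lapply(seq_len(n), function(i) {
    fwdCbr(tape, up[[i]], agg$refine[[i]], training)
  })
  streams <- vector("list", n)
  streams[[1L]] <- ref[[1L]]
  for (i in seq_len(n)[-1L])
    streams[[i]] <- opMul(tape, streams[[i - 1L]], ref[[i]])
  fcat <- opConcat(tape, streams)
  ftrans <- fwdCbr(tape, fcat, agg$trans, training)
  fout <- opAdd(tape, ftrans, fwdConv(tape, maps[[1L]], agg$skip))
  fwdConv(tape, fout, agg$head)
}
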