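# Layer constructors. A "ctx" (builder context) registers every parameter it
# creates so the model ends up with one flat parameter list for the optimizer
# and for countParameters().

newCtx <- function() {
  ctx <- new.env(parent = emptyenv())
  ctx$params <- list()
  ctx$bns <- list()
  ctx
}

ctxRegister <- function(ctx, p) {
  ctx$params[[length(ctx$params) + 1L]] <- p
  p
}

# He-normal initialization for a kh x kw conv, cin -> cout.
ctxConv <- function(ctx, kh, cin, cout, name = "conv", kw = kh) {
  sdv <- sqrt(2 / (kh * kw * cin))
  w <- array(rnorm(kh * kw * cin * cout, sd = sdv), c(kh, kw, cin, cout))
  lay <- new.env(parent = emptyenv())
  lay$w <- ctxRegister(ctx, agParam(w, paste0(name, ".w")))
  lay$b <- ctxRegister(ctx, agParam(rep(0, cout), paste0(name, ".b")))
  lay$kh <- kh
  lay
}

ctxBn <- function(ctx, C, name = "bn") {
  bn <- bnLayer(C, name)
  ctxRegister(ctx, bn$gamma)
  ctxRegister(ctx, bn$beta)
  ctx$bns[[length(ctx$bns) + 1L]] <- bn
  bn
}

# conv -> batchnorm -> relu unit
ctxCbr <- function(ctx, kh, cin, cout, name = "cbr") {
  list(conv = ctxConv(ctx, kh, cin, cout, paste0(name, ".conv")),
       bn = ctxBn(ctx, cout, paste0(name, ".bn")))
}

fwdConv <- function(tape, x, lay, stride = 1L, dil = 1L) {
  opConv(tape, x, lay$w, lay$b, stride = stride, dil = dil)
}

fwdCbr <- function(tape, x, unit, training, stride = 1L, dil = 1L,
                   relu = TRUE) {
  y <- fwdConv(tape, x, unit$conv, stride = stride, dil = dil)
  y <- opBatchNorm(tape, y, unit$bn, training = training)
  if (relu) y <- opRelu(tape, y) else y
}
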