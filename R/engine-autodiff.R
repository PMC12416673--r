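#' @useDynLib hardvessel, .registration = TRUE
#' @importFrom Rcpp evalCpp
#' @importFrom methods new validObject is slot
#' @importFrom stats rnorm runif sd
NULL

# ---------------------------------------------------------------------------
# Reverse-mode differentiation tape.
#
# A "tape" records every tensor operation of one forward pass in execution
# order; agBackward() replays it in reverse, accumulating gradients into node
# environments and, for leaves bound to parameters, into the parameter's
# $grad slot. Tensors are plain R arrays [H, W, C, N]. The op vocabulary is
# exactly what the segmentation network needs: convolution (C++ im2col/GEMM),
# batch norm, ReLU, sigmoid, channel concat, elementwise add/multiply,
# 2x2 average pooling, bilinear resize (C++) and spatial crop. Backward
# implementations are shared top-level functions (not per-node closures);
# whatever state they need is stored as fields on the node.
# ---------------------------------------------------------------------------

agTape <- function() {
  t <- new.env(parent = emptyenv())
  t$nodes <- vector("list", 256L)
  t$n <- 0L
  t
}

agNode <- function(tape, val, parents = list(), backward = NULL) {
  nd <- new.env(parent = emptyenv())
  nd$val <- val
  nd$grad <- NULL
  nd$parents <- parents
  nd$backward <- backward
  nd$param <- NULL
  tape$n <- tape$n + 1L
  if (tape$n > length(tape$nodes)) {
    tape$nodes <- c(tape$nodes, vector("list", length(tape$nodes)))
  }
  tape$nodes[[tape$n]] <- nd
  nd
}

agAccum <- function(node, g) {
  node$grad <- if (is.null(node$grad)) g else node$grad + g
  invisible(NULL)
}

#' Run reverse-mode accumulation over a tape
#'
#' Seeds the given output nodes with cotangents and replays the tape in
#' reverse. Gradients of parameter leaves accumulate into each parameter's
#' `$grad` field (cleared beforehand with [agZeroGrad()]).
#'
#' @param tape tape created by `agTape()` that recorded the forward pass
#' @param seeds an output node or list of output nodes
#' @param grads array / list of arrays matching the seed value shapes
#' @keywords internal
agBackward <- function(tape, seeds, grads) {
  if (!is.list(seeds)) { seeds <- list(seeds); grads <- list(grads) }
  for (i in seq_along(seeds)) agAccum(seeds[[i]], grads[[i]])
  for (k in seq_len(tape$n)[tape$n:1]) {
    nd <- tape$nodes[[k]]
    if (is.null(nd$grad)) next
    if (!is.null(nd$param)) {
      p <- nd$param
      p$grad <- if (is.null(p$grad)) nd$grad else p$grad + nd$grad
    }
    if (!is.null(nd$backward)) {
      nd$backward(nd)
      nd$grad <- NULL  # release memory as we walk back (leaves keep theirs)
    }
  }
  invisible(NULL)
}

# -- parameters --------------------------------------------------------------

agParam <- function(val, name = "param") {
  p <- new.env(parent = emptyenv())
  p$val <- val
  p$grad <- NULL
  p$m <- NULL   # Adam first moment
  p$v <- NULL   # Adam second moment
  p$name <- name
  class(p) <- "ag_param"
  p
}

agZeroGrad <- function(params) {
  for (p in params) p$grad <- NULL
  invisible(NULL)
}

paramAccum <- function(p, g) {
  p$grad <- if (is.null(p$grad)) g else p$grad + g
  invisible(NULL)
}

# -- leaf ops ----------------------------------------------------------------

opInput <- function(tape, x) agNode(tape, x)

# -- convolution -------------------------------------------------------------

bwConv <- function(nd) {
  r <- nn_conv2d_backward(nd$parents[[1]]$val, nd$w$val, nd$grad,
                          nd$stride, nd$pad, nd$dil)
  agAccum(nd$parents[[1]], r$dx)
  paramAccum(nd$w, r$dw)
  paramAccum(nd$b, r$db)
}

# 'same' padding for odd kernels at stride 1; explicit pad otherwise.
opConv <- function(tape, x, w, b, stride = 1L, dil = 1L,
                   pad = dil * (dim(w$val)[1] - 1L) %/% 2L) {
  y <- nn_conv2d(x$val, w$val, b$val, as.integer(stride), as.integer(pad),
                 as.integer(dil))
  nd <- agNode(tape, y, parents = list(x), backward = bwConv)
  nd$w <- w; nd$b <- b
  nd$stride <- as.integer(stride); nd$pad <- as.integer(pad)
  nd$dil <- as.integer(dil)
  nd
}

# -- batch normalization -----------------------------------------------------

bwBatchNorm <- function(nd) {
  bn <- nd$bn
  dy <- nd$grad
  xh <- nd$xhat
  dgamma <- nn_chan_dot(dy, xh)
  dbeta <- nn_chan_sums(dy)$sum
  paramAccum(bn$gamma, dgamma)
  paramAccum(bn$beta, dbeta)
  gs <- bn$gamma$val * nd$invstd
  dx <- if (nd$training) {
    nn_bn_bwd(dy, xh, gs, dbeta / nd$M, dgamma / nd$M)
  } else {
    nn_chan_affine(dy, gs, numeric(length(gs)))
  }
  agAccum(nd$parents[[1]], dx)
}

# Layer state (gamma/beta params + running mean/var) lives in `bn`, an
# environment from bnLayer().
opBatchNorm <- function(tape, x, bn, training = TRUE, eps = 1e-5,
                        momentum = 0.1) {
  d <- dim(x$val)
  M <- d[1] * d[2] * d[4]
  if (training) {
    st <- nn_chan_sums(x$val)
    mu <- st$sum / M
    va <- pmax(st$sumsq / M - mu^2, 0)
    bn$runMean <- (1 - momentum) * bn$runMean + momentum * mu
    bn$runVar <- (1 - momentum) * bn$runVar + momentum * va
  } else {
    mu <- bn$runMean
    va <- bn$runVar
  }
  invstd <- 1 / sqrt(va + eps)
  xhat <- nn_chan_affine(x$val, invstd, -mu * invstd)
  y <- nn_chan_affine(xhat, bn$gamma$val, bn$beta$val)
  nd <- agNode(tape, y, parents = list(x), backward = bwBatchNorm)
  nd$bn <- bn; nd$xhat <- xhat; nd$invstd <- invstd
  nd$training <- training; nd$M <- M
  nd
}

bnLayer <- function(C, name = "bn") {
  bn <- new.env(parent = emptyenv())
  bn$gamma <- agParam(rep(1, C), paste0(name, ".gamma"))
  bn$beta <- agParam(rep(0, C), paste0(name, ".beta"))
  bn$runMean <- rep(0, C)
  bn$runVar <- rep(1, C)
  bn
}

# -- pointwise ---------------------------------------------------------------

bwRelu <- function(nd) {
  agAccum(nd$parents[[1]], nn_relu_bwd(nd$grad, nd$parents[[1]]$val))
}

opRelu <- function(tape, x) {
  agNode(tape, nn_relu(x$val), parents = list(x), backward = bwRelu)
}

bwSigmoid <- function(nd) {
  agAccum(nd$parents[[1]], nd$grad * nd$val * (1 - nd$val))
}

opSigmoid <- function(tape, x) {
  agNode(tape, 1 / (1 + exp(-x$val)), parents = list(x),
         backward = bwSigmoid)
}

bwAdd <- function(nd) {
  agAccum(nd$parents[[1]], nd$grad)
  agAccum(nd$parents[[2]], nd$grad)
}

opAdd <- function(tape, a, b) {
  agNode(tape, a$val + b$val, parents = list(a, b), backward = bwAdd)
}

bwMul <- function(nd) {
  agAccum(nd$parents[[1]], nd$grad * nd$parents[[2]]$val)
  agAccum(nd$parents[[2]], nd$grad * nd$parents[[1]]$val)
}

opMul <- function(tape, a, b) {
  agNode(tape, a$val * b$val, parents = list(a, b), backward = bwMul)
}

# -- shape ops ---------------------------------------------------------------

bwConcat <- function(nd) {
  at <- 0L
  for (i in seq_along(nd$parents)) {
    ci <- nd$ch[i]
    agAccum(nd$parents[[i]], nd$grad[, , at + seq_len(ci), , drop = FALSE])
    at <- at + ci
  }
}

opConcat <- function(tape, xs) {
  ds <- lapply(xs, function(x) dim(x$val))
  ch <- vapply(ds, `[`, integer(1), 3L)
  d0 <- ds[[1]]
  out <- array(0, c(d0[1], d0[2], sum(ch), d0[4]))
  at <- 0L
  for (i in seq_along(xs)) {
    out[, , at + seq_len(ch[i]), ] <- xs[[i]]$val
    at <- at + ch[i]
  }
  nd <- agNode(tape, out, parents = xs, backward = bwConcat)
  nd$ch <- ch
  nd
}

bwAvgPool2 <- function(nd) {
  g <- 0.25 * nd$grad
  dx <- array(0, nd$d)
  dx[nd$io, nd$jo, , ] <- g; dx[nd$ie, nd$jo, , ] <- g
  dx[nd$io, nd$je, , ] <- g; dx[nd$ie, nd$je, , ] <- g
  agAccum(nd$parents[[1]], dx)
}

opAvgPool2 <- function(tape, x) {
  d <- dim(x$val)
  io <- seq(1L, d[1], 2L); ie <- io + 1L
  jo <- seq(1L, d[2], 2L); je <- jo + 1L
  v <- x$val
  y <- 0.25 * (v[io, jo, , , drop = FALSE] + v[ie, jo, , , drop = FALSE] +
               v[io, je, , , drop = FALSE] + v[ie, je, , , drop = FALSE])
  nd <- agNode(tape, y, parents = list(x), backward = bwAvgPool2)
  nd$d <- d; nd$io <- io; nd$ie <- ie; nd$jo <- jo; nd$je <- je
  nd
}

bwBilinear <- function(nd) {
  agAccum(nd$parents[[1]], nn_bilinear_backward(nd$grad, nd$d[1], nd$d[2]))
}

opBilinear <- function(tape, x, oh, ow) {
  y <- nn_bilinear(x$val, as.integer(oh), as.integer(ow))
  nd <- agNode(tape, y, parents = list(x), backward = bwBilinear)
  nd$d <- dim(x$val)
  nd
}

bwCrop <- function(nd) {
  dx <- array(0, nd$d)
  dx[nd$offR + seq_len(nd$h), nd$offC + seq_len(nd$w), , ] <- nd$grad
  agAccum(nd$parents[[1]], dx)
}

opCrop <- function(tape, x, h, w, offR = 0L, offC = 0L) {
  y <- x$val[offR + seq_len(h), offC + seq_len(w), , , drop = FALSE]
  nd <- agNode(tape, y, parents = list(x), backward = bwCrop)
  nd$d <- dim(x$val); nd$h <- h; nd$w <- w; nd$offR <- offR; nd$offC <- offC
  nd
}

# -- optimizer ---------------------------------------------------------------

#' One Adam update over a set of parameters
#'
#' Standard Adam with bias correction. Parameters with a `NULL` gradient are
#' skipped. `state$t` (step counter) is advanced by one.
#'
#' @param params list of parameter environments
#' @param state environment with step counter `t`
#' @param lr learning rate
#' @param beta1,beta2 exponential decay rates for the moment estimates
#' @param eps numerical stabilizer
#' @keywords internal
adamStep <- function(params, state, lr, beta1 = 0.9, beta2 = 0.999,
                     eps = 1e-8) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (p in params) {
    if (is.null(p$grad)) next
    g <- p$grad
    if (is.null(p$m)) { p$m <- g * 0; p$v <- g * 0 }
    p$m <- beta1 * p$m + (1 - beta1) * g
    p$v <- beta2 * p$v + (1 - beta2) * g * g
    p$val <- p$val - lr * (p$m / bc1) / (sqrt(p$v / bc2) + eps)
  }
  invisible(NULL)
}
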