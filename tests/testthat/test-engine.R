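# Gradient correctness of the compute engine: every op is checked against
# central finite differences through small random graphs.

randArr <- function(d, seed) withr::with_seed(seed, array(rnorm(prod(d)), d))

test_that("convolution gradients match finite differences", {
  x <- randArr(c(6, 8, 3, 2), 1)
  for (cfg in list(list(k = 3, stride = 1, dil = 1),
                   list(k = 3, stride = 2, dil = 1),
                   list(k = 3, stride = 1, dil = 3),
                   list(k = 1, stride = 1, dil = 1))) {
    wl <- withr::with_seed(2, {
      w <- hardvessel:::agParam(array(rnorm(cfg$k^2 * 3 * 4, sd = 0.3),
                                      c(cfg$k, cfg$k, 3, 4)))
      b <- hardvessel:::agParam(rnorm(4))
      list(w = w, b = b)
    })
    R <- randArr(c(dim(hardvessel:::nn_conv2d(x, wl$w$val, wl$b$val,
                                              cfg$stride,
                                              cfg$dil * (cfg$k - 1) %/% 2,
                                              cfg$dil))), 3)
    fx <- function(xx) {
      tp <- hardvessel:::agTape()
      nd <- hardvessel:::opConv(tp, hardvessel:::opInput(tp, xx), wl$w, wl$b,
                                stride = cfg$stride, dil = cfg$dil)
      sum(nd$val * R)
    }
    tp <- hardvessel:::agTape()
    xin <- hardvessel:::opInput(tp, x)
    nd <- hardvessel:::opConv(tp, xin, wl$w, wl$b, stride = cfg$stride,
                              dil = cfg$dil)
    hardvessel:::agZeroGrad(list(wl$w, wl$b))
    hardvessel:::agBackward(tp, nd, R)
    idx <- withr::with_seed(4, sample(length(x), 5))
    expect_equal(xin$grad[idx], numGradAt(fx, x, idx), tolerance = 1e-5)
    fw <- function(ww) {
      sum(hardvessel:::nn_conv2d(x, ww, wl$b$val, cfg$stride,
                                 cfg$dil * (cfg$k - 1) %/% 2, cfg$dil) * R)
    }
    widx <- withr::with_seed(5, sample(length(wl$w$val), 5))
    expect_equal(wl$w$grad[widx], numGradAt(fw, wl$w$val, widx),
                 tolerance = 1e-5)
  }
})

test_that("batch norm matches finite differences in training mode", {
  x <- randArr(c(4, 5, 3, 2), 6)
  bn <- hardvessel:::bnLayer(3)
  bn$gamma$val <- c(1.2, 0.8, 1.5)
  bn$beta$val <- c(0.1, -0.2, 0.3)
  R <- randArr(dim(x), 7)
  fx <- function(xx) {
    tp <- hardvessel:::agTape()
    nd <- hardvessel:::opBatchNorm(tp, hardvessel:::opInput(tp, xx), bn,
                                   training = TRUE)
    sum(nd$val * R)
  }
  tp <- hardvessel:::agTape()
  xin <- hardvessel:::opInput(tp, x)
  nd <- hardvessel:::opBatchNorm(tp, xin, bn, training = TRUE)
  hardvessel:::agZeroGrad(list(bn$gamma, bn$beta))
  hardvessel:::agBackward(tp, nd, R)
  idx <- withr::with_seed(8, sample(length(x), 8))
  expect_equal(xin$grad[idx], numGradAt(fx, x, idx), tolerance = 1e-4)
  fg <- function(gv) {
    bn2 <- hardvessel:::bnLayer(3)
    bn2$gamma$val <- gv; bn2$beta$val <- bn$beta$val
    tp <- hardvessel:::agTape()
    nd <- hardvessel:::opBatchNorm(tp, hardvessel:::opInput(tp, x), bn2,
                                   training = TRUE)
    sum(nd$val * R)
  }
  expect_equal(bn$gamma$grad, numGradAt(fg, bn$gamma$val, 1:3),
               tolerance = 1e-5)
})

test_that("bilinear resize reproduces the closed-form interpolation", {
  # 2x2 -> 4x4, half-pixel centers: source coords (i+0.5)/2 - 0.5, clamped
  x <- array(c(1, 5, 3, 7), c(2, 2, 1, 1))  # [[1,3],[5,7]]
  y <- hardvessel:::nn_bilinear(x, 4L, 4L)
  sv <- pmin(pmax((0:3 + 0.5) * 0.5 - 0.5, 0), 1)
  m <- matrix(c(1, 3, 5, 7), 2, byrow = TRUE)
  ref <- outer(sv, sv, function(a, b) {
    h0 <- floor(a); h1 <- pmin(h0 + 1, 1); fa <- a - h0
    w0 <- floor(b); w1 <- pmin(w0 + 1, 1); fb <- b - w0
    (1 - fa) * (1 - fb) * m[cbind(h0 + 1, w0 + 1)] +
      (1 - fa) * fb * m[cbind(h0 + 1, w1 + 1)] +
      fa * (1 - fb) * m[cbind(h1 + 1, w0 + 1)] +
      fa * fb * m[cbind(h1 + 1, w1 + 1)]
  })
  expect_equal(y[, , 1, 1], ref)
  # gradient is the transpose of the interpolation
  xb <- randArr(c(5, 6, 2, 1), 9)
  R <- randArr(c(10, 12, 2, 1), 10)
  g <- hardvessel:::nn_bilinear_backward(R, 5L, 6L)
  fx <- function(xx) sum(hardvessel:::nn_bilinear(xx, 10L, 12L) * R)
  idx <- withr::with_seed(11, sample(length(xb), 6))
  expect_equal(g[idx], numGradAt(fx, xb, idx), tolerance = 1e-6)
})

test_that("pooling, multiply, concat, crop and sigmoid backprop correctly", {
  x <- randArr(c(6, 6, 2, 2), 12)
  y <- randArr(c(6, 6, 2, 2), 13)
  R3 <- randArr(c(3, 3, 2, 2), 14)
  fx <- function(xx) {
    tp <- hardvessel:::agTape()
    sum(hardvessel:::opAvgPool2(tp, hardvessel:::opInput(tp, xx))$val * R3)
  }
  tp <- hardvessel:::agTape()
  xin <- hardvessel:::opInput(tp, x)
  hardvessel:::agBackward(tp, hardvessel:::opAvgPool2(tp, xin), R3)
  idx <- withr::with_seed(15, sample(length(x), 6))
  expect_equal(xin$grad[idx], numGradAt(fx, x, idx), tolerance = 1e-6)

  # composite graph: sigmoid(crop(concat(x*y, x)))
  Rc <- randArr(c(4, 4, 4, 2), 16)
  fboth <- function(xx) {
    tp <- hardvessel:::agTape()
    a <- hardvessel:::opInput(tp, xx)
    b <- hardvessel:::opInput(tp, y)
    nd <- hardvessel:::opConcat(tp, list(hardvessel:::opMul(tp, a, b), a))
    nd <- hardvessel:::opCrop(tp, nd, 4L, 4L, 1L, 1L)
    sum(hardvessel:::opSigmoid(tp, nd)$val * Rc)
  }
  tp <- hardvessel:::agTape()
  a <- hardvessel:::opInput(tp, x)
  b <- hardvessel:::opInput(tp, y)
  nd <- hardvessel:::opConcat(tp, list(hardvessel:::opMul(tp, a, b), a))
  nd <- hardvessel:::opCrop(tp, nd, 4L, 4L, 1L, 1L)
  nd <- hardvessel:::opSigmoid(tp, nd)
  hardvessel:::agBackward(tp, nd, Rc)
  expect_equal(a$grad[idx], numGradAt(fboth, x, idx), tolerance = 1e-5)
})

test_that("adam takes a descent step on a quadratic", {
  p <- hardvessel:::agParam(c(3, -2))
  st <- new.env(); st$t <- 0L
  for (i in 1:200) {
    p$grad <- 2 * p$val
    hardvessel:::adamStep(list(p), st, lr = 0.1)
  }
  expect_lt(sum(p$val^2), 1e-3)
})
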