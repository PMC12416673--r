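test_that("harmonic links and widths match brute-force enumeration", {
  # oracle: j links to k iff k - j is a power of two dividing k
  for (k in 1:32) {
    expect_equal(hardBlockLinks(k), linksOracle(k), info = paste("k =", k))
  }
  expect_equal(hardBlockLinks(1), 0L)
  expect_equal(hardBlockLinks(6), c(5L, 4L))
  expect_equal(hardBlockLinks(8), c(7L, 6L, 4L, 0L))
  expect_error(hardBlockLinks(0), ">= 1")
  settings <- list(c(16, 1.7), c(10, 1.7), c(24, 1.6), c(18, 2.0), c(7, 1.0))
  for (s in settings) {
    for (k in 1:32) {
      expect_equal(hardBlockChannels(k, s[1], s[2]),
                   channelsOracle(k, s[1], s[2]),
                   info = sprintf("k=%d growth=%g mult=%g", k, s[1], s[2]))
    }
  }
  expect_equal(hardBlockChannels(3, 16, 1.7), 16L)
  expect_equal(hardBlockChannels(2, 16, 1.7), 26L)  # 2*floor(27.2/2)
  expect_equal(hardBlockChannels(4, 16, 1.7), 46L)  # 2*floor(46.24/2)
})

test_that("harmonic block forward honors the channel layout", {
  spec <- hardBlockSpec(16L, 4L, 10L, 1.7)
  # output = layers 1, 3, 4
  expect_equal(spec$outLayers, c(1L, 3L, 4L))
  expect_equal(spec$outChannels,
               sum(spec$layerChannels[c(1, 3, 4)]))
  ctx <- hardvessel:::newCtx()
  blk <- withr::with_seed(1, hardvessel:::buildHardBlock(ctx, spec))
  tp <- hardvessel:::agTape()
  x <- hardvessel:::opInput(tp, array(rnorm(8 * 8 * 16 * 2), c(8, 8, 16, 2)))
  y <- hardvessel:::hardBlockForward(tp, x, blk)
  expect_equal(dim(y$val), c(8L, 8L, spec$outChannels, 2L))
  # single-layer block: output is just that layer
  spec1 <- hardBlockSpec(6L, 1L, 8L, 1.7)
  expect_equal(spec1$outChannels, spec1$layerChannels[1])
  ctx1 <- hardvessel:::newCtx()
  blk1 <- withr::with_seed(2, hardvessel:::buildHardBlock(ctx1, spec1))
  tp1 <- hardvessel:::agTape()
  x1 <- hardvessel:::opInput(tp1, array(rnorm(6 * 6 * 6), c(6, 6, 6, 1)))
  expect_equal(dim(hardvessel:::hardBlockForward(tp1, x1, blk1)$val),
               c(6L, 6L, spec1$layerChannels[1], 1L))
  # channel mismatch is reported
  tpb <- hardvessel:::agTape()
  xb <- hardvessel:::opInput(tpb, array(0, c(8, 8, 7, 1)))
  expect_error(hardvessel:::hardBlockForward(tpb, xb, blk), "channels")
})

test_that("receptive field block widens the response footprint", {
  spec <- rfbSpec(8L, 12L)
  ctx <- hardvessel:::newCtx()
  rfb <- withr::with_seed(3, hardvessel:::buildRfb(ctx, spec))
  # make every conv weight positive so ReLUs cannot mask the footprint
  for (p in ctx$params) if (length(dim(p$val)) == 4L) p$val <- abs(p$val) + 0.01
  probe <- function(mod, fwd) {
    z <- array(0, c(15, 15, 8, 1))
    tp <- hardvessel:::agTape()
    y0 <- fwd(tp, hardvessel:::opInput(tp, z), mod)$val
    z[8, 8, , 1] <- 1
    tp <- hardvessel:::agTape()
    y1 <- fwd(tp, hardvessel:::opInput(tp, z), mod)$val
    apply(abs(y1 - y0) > 1e-10, c(1, 2), any)
  }
  fp <- probe(rfb, function(tp, x, m) {
    hardvessel:::rfbForward(tp, x, m, training = FALSE)
  })
  # dilation-5 branch alone spans 11x11; with the 3x3 fusion >= 13x13
  expect_gte(sum(range(which(apply(fp, 1, any))) * c(-1, 1)) + 1, 11)
  expect_gte(sum(range(which(apply(fp, 2, any))) * c(-1, 1)) + 1, 11)
  # a plain 3x3 conv spans exactly 3x3
  ctx2 <- hardvessel:::newCtx()
  unit <- withr::with_seed(4, hardvessel:::ctxCbr(ctx2, 3L, 8L, 12L))
  unit$conv$w$val <- abs(unit$conv$w$val) + 0.01
  fp2 <- probe(unit, function(tp, x, m) {
    hardvessel:::fwdCbr(tp, x, m, training = FALSE)
  })
  expect_equal(sum(range(which(apply(fp2, 1, any))) * c(-1, 1)) + 1, 3)
  # shape contracts
  tp <- hardvessel:::agTape()
  x <- hardvessel:::opInput(tp, array(rnorm(10 * 12 * 8), c(10, 12, 8, 1)))
  y <- hardvessel:::rfbForward(tp, x, rfb, training = FALSE)
  expect_equal(dim(y$val), c(10L, 12L, 12L, 1L))
})

test_that("dense aggregation fuses dyadic scales into finest-scale logits", {
  ctx <- hardvessel:::newCtx()
  agg <- withr::with_seed(5, hardvessel:::buildAggregator(ctx, 3L, 6L))
  mk <- function(h, v = NULL) {
    a <- if (is.null(v)) array(rnorm(h * h * 6), c(h, h, 6, 1))
         else array(v, c(h, h, 6, 1))
    a
  }
  tp <- hardvessel:::agTape()
  maps <- list(hardvessel:::opInput(tp, mk(16)),
               hardvessel:::opInput(tp, mk(8)),
               hardvessel:::opInput(tp, mk(4)))
  y <- hardvessel:::aggregateForward(tp, maps, agg, training = FALSE)
  expect_equal(dim(y$val), c(16L, 16L, 1L, 1L))
  # constant inputs with identity refinement convs stay spatially constant
  for (u in c(agg$refine, list(agg$trans))) {
    w <- u$conv$w$val * 0
    cin <- dim(w)[3]; cout <- dim(w)[4]
    for (co in seq_len(cout)) w[2, 2, (co - 1L) %% cin + 1L, co] <- 1
    u$conv$w$val <- w
    u$conv$b$val <- u$conv$b$val * 0
  }
  tp <- hardvessel:::agTape()
  maps <- list(hardvessel:::opInput(tp, mk(16, 0.7)),
               hardvessel:::opInput(tp, mk(8, 0.7)),
               hardvessel:::opInput(tp, mk(4, 0.7)))
  y <- hardvessel:::aggregateForward(tp, maps, agg, training = FALSE)
  expect_lt(diff(range(y$val)), 1e-9)
  # non-dyadic chains are rejected
  tp <- hardvessel:::agTape()
  bad <- list(hardvessel:::opInput(tp, mk(16)),
              hardvessel:::opInput(tp, mk(6)))
  expect_error(hardvessel:::aggregateForward(tp, bad, agg), "dyadic")
})

test_that("all four ablation variants run the same forward contract", {
  x <- withr::with_seed(6, array(runif(64 * 64 * 3 * 1), c(64, 64, 3, 1)))
  for (v in c("baseline", "hard", "rfb", "full")) {
    m <- withr::with_seed(7, buildModel(smallModelConfig(v)))
    out <- modelForward(m, x)
    expect_equal(dim(out$prob), c(64L, 64L, 1L, 1L), info = v)
    expect_true(all(out$prob >= 0 & out$prob <= 1), info = v)
  }
})

test_that("inputs not divisible by 32 are padded internally and cropped back", {
  m <- withr::with_seed(8, buildModel(smallModelConfig()))
  # 96 x 80 is divisible; 92 x 70 is not
  x <- withr::with_seed(9, array(runif(92 * 70 * 3), c(92, 70, 3, 1)))
  out <- modelForward(m, x)
  expect_equal(dim(out$prob)[1:2], c(92L, 70L))
  expect_true(all(out$prob >= 0 & out$prob <= 1))
  # the DRIVE protocol geometry (592 = 18.5 * 32) pads to 608 internally
  x2 <- array(0.5, c(592, 592, 3, 1))
  out2 <- modelForward(m, x2)
  expect_equal(dim(out2$prob)[1:2], c(592L, 592L))
})

test_that("the forward pass is deterministic and batch-equivariant", {
  m <- withr::with_seed(10, buildModel(smallModelConfig()))
  x <- withr::with_seed(11, array(runif(64 * 64 * 3 * 3), c(64, 64, 3, 3)))
  o1 <- modelForward(m, x)$prob
  o2 <- modelForward(m, x)$prob
  expect_identical(o1, o2)
  # permuting the batch permutes the outputs identically (eval mode)
  perm <- c(3L, 1L, 2L)
  o3 <- modelForward(m, x[, , , perm, drop = FALSE])$prob
  expect_equal(o3, o1[, , , perm, drop = FALSE], tolerance = 1e-12)
})

test_that("parameter counting is exact and input-size invariant", {
  ctx <- hardvessel:::newCtx()
  withr::with_seed(12, hardvessel:::ctxConv(ctx, 3L, 3L, 8L))
  expect_equal(countParameters(ctx$params), 3 * 3 * 3 * 8 + 8)  # 224
  m <- withr::with_seed(13, buildModel(smallModelConfig()))
  n1 <- countParameters(m)
  expect_gt(n1, 0)
  modelForward(m, array(0.5, c(64, 64, 3, 1)))
  modelForward(m, array(0.5, c(96, 96, 3, 1)))
  expect_equal(countParameters(m), n1)
  # freezing everything counts zero
  for (p in m$params) p$trainable <- FALSE
  expect_equal(countParameters(m), 0L)
})

test_that("training-mode gradients are finite for every parameter", {
  m <- withr::with_seed(14, buildModel(smallModelConfig()))
  s <- simulateDataset(2, simConfig(imageHeight = 64L, imageWidth = 64L,
                                    seed = 15L))
  x <- hardvessel:::samplesToBatch(s)
  tape <- hardvessel:::agTape()
  out <- modelForward(m, x, training = TRUE, tape = tape)
  g <- array(0, dim(out$prob))
  for (i in 1:2) {
    li <- totalLoss(out$prob[, , 1, i], vesselMask(s[[i]]), lossConfig(),
                    grad = TRUE)
    g[, , 1, i] <- li$grad / 2
  }
  hardvessel:::agZeroGrad(m$params)
  hardvessel:::agBackward(tape, out$nodes$prob, g)
  for (p in m$params) {
    expect_false(is.null(p$grad), info = p$name)
    expect_true(all(is.finite(p$grad)), info = p$name)
  }
})
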