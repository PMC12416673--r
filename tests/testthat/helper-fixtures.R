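# Shared fixtures and independent oracles used across the suite.

# Central finite difference of scalar function f at selected flat indices.
numGradAt <- function(f, x, idx, eps = 1e-6) {
  vapply(idx, function(i) {
    xp <- x; xp[i] <- xp[i] + eps
    xm <- x; xm[i] <- xm[i] - eps
    (f(xp) - f(xm)) / (2 * eps)
  }, numeric(1))
}

# Naive double-loop edge-weight oracle (both border policies).
edgeWeightOracle <- function(G, window, gamma, border = "valid") {
  H <- nrow(G); W <- ncol(G); r <- window %/% 2
  out <- matrix(0, H, W)
  for (i in seq_len(H)) {
    for (j in seq_len(W)) {
      rs <- max(1, i - r):min(H, i + r)
      cs <- max(1, j - r):min(W, j + r)
      s <- sum(G[rs, cs])
      m <- if (border == "valid") s / (length(rs) * length(cs))
           else s / (window * window)
      out[i, j] <- 1 + gamma * abs(m - G[i, j])
    }
  }
  out
}

# Scalar double-loop oracles for the weighted losses.
iouLossOracle <- function(S, G, W) {
  num <- 0; den <- 0
  for (i in seq_len(nrow(S))) {
    for (j in seq_len(ncol(S))) {
      num <- num + W[i, j] * S[i, j] * G[i, j]
      den <- den + W[i, j] * (S[i, j] + G[i, j] - S[i, j] * G[i, j])
    }
  }
  1 - num / den
}

bceLossOracle <- function(S, G, W, eps = 1e-7) {
  acc <- 0; sw <- 0
  for (i in seq_len(nrow(S))) {
    for (j in seq_len(ncol(S))) {
      s <- min(max(S[i, j], eps), 1 - eps)
      acc <- acc + W[i, j] * (-G[i, j] * log(s) - (1 - G[i, j]) * log(1 - s))
      sw <- sw + W[i, j]
    }
  }
  acc / sw
}

# O(n^2) pairwise ranking AUC oracle.
aucPairwiseOracle <- function(s, g) {
  pos <- s[g == 1]; neg <- s[g == 0]
  acc <- 0
  for (p in pos) for (q in neg) {
    acc <- acc + (p > q) + 0.5 * (p == q)
  }
  acc / (length(pos) * length(neg))
}

# Brute-force connectivity rule oracle for the harmonic block.
linksOracle <- function(k) {
  sort(Filter(function(j) {
    n <- k - j
    # j is a link iff n = 2^m for some m >= 0 and 2^m divides k
    (bitwAnd(n, n - 1L) == 0L) && n >= 1L && (k %% n == 0L)
  }, 0:(k - 1)), decreasing = TRUE)
}

channelsOracle <- function(k, growth, mult) {
  p <- 0L
  while (k %% 2L == 0L) { k <- k %/% 2L; p <- p + 1L }
  2L * floor(growth * mult^p / 2)
}

# A tiny deterministic sample for geometry/augmentation tests.
tinySample <- function(H = 32L, W = 32L, seed = 11L) {
  withr::with_seed(seed, {
    img <- array(runif(H * W * 3), c(H, W, 3))
    fov <- hardvessel:::fovDisc(H, W, 0.95)
    vessel <- matrix(0, H, W)
    vessel[H %/% 2, 3:(W - 3)] <- 1
    vessel <- vessel * fov
    FundusSample(img, vessel, fov, sampleId = sprintf("tiny_%d", seed))
  })
}

smallModelConfig <- function(variant = "full") {
  modelConfig(variant, growthRates = c(6L, 8L, 8L, 10L),
              layersPerBlock = c(2L, 2L, 4L, 4L),
              stemChannels = c(8L, 8L),
              transChannels = c(12L, 16L, 20L, 24L), aggChannels = 12L)
}
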