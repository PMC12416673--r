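#' Edge-emphasis weight map for the segmentation loss
#'
#' For every pixel, the mean of the ground-truth mask over its
#' `window x window` neighborhood is compared with the pixel's own label;
#' the absolute difference measures how close the pixel sits to a vessel
#' boundary. Weights are `1 + gamma * |boxmean(G) - G|`, so interior and
#' far-background pixels keep weight 1 and boundary pixels are emphasized
#' up to `1 + gamma`.
#'
#' @param G binary mask (matrix of 0/1)
#' @param window odd neighborhood side length in pixels (default 31, i.e. a
#'   15-pixel reach in the four cardinal directions)
#' @param gamma proportionality constant between local contrast and weight
#' @param border `"valid"` averages over in-bounds pixels only
#'   (count-corrected, keeps weights exactly 1 on constant masks at the
#'   border); `"zero"` treats out-of-bounds pixels as background
#' @return matrix of weights `>= 1`, same shape as `G`
#' @export
edgeWeightMap <- function(G, window = 31L, gamma = 5,
                          border = c("valid", "zero")) {
  border <- match.arg(border)
  window <- as.integer(window)
  if (window < 1L || window %% 2L == 0L)
    stop("window must be a positive odd integer")
  if (!all(G %in% c(0, 1))) stop("G must be a binary mask")
  G <- as.matrix(G)
  r <- window %/% 2L
  s <- boxSum(G, r)
  if (border == "valid") {
    cnt <- boxSum(matrix(1, nrow(G), ncol(G)), r)
    m <- s / cnt
  } else {
    m <- s / (window * window)
  }
  1 + gamma * abs(m - G)
}

# Box-filter sum over a (2r+1)^2 window via integral image (exact).
boxSum <- function(x, r) {
  H <- nrow(x); W <- ncol(x)
  ii <- matrix(0, H + 1L, W + 1L)
  ii[-1L, -1L] <- apply(apply(x, 2L, cumsum), 1L, cumsum) |> t()
  lo_r <- pmax(0L, seq_len(H) - r - 1L); hi_r <- pmin(H, seq_len(H) + r)
  lo_c <- pmax(0L, seq_len(W) - r - 1L); hi_c <- pmin(W, seq_len(W) + r)
  ii[hi_r + 1L, hi_c + 1L] - ii[lo_r + 1L, hi_c + 1L] -
    ii[hi_r + 1L, lo_c + 1L] + ii[lo_r + 1L, lo_c + 1L]
}

#' Loss configuration
#'
#' @param lambda1 weight of the edge-weighted IoU term (default 0.5)
#' @param lambda2 weight of the edge-weighted BCE term (default 0.5)
#' @param gamma edge-weight proportionality constant
#' @param window edge-weight neighborhood side (odd)
#' @param border edge-weight border policy, see [edgeWeightMap()]
#' @param epsilon probability clamp for the logarithms
#' @return validated list of class `hardvessel_loss_config`
#' @export
lossConfig <- function(lambda1 = 0.5, lambda2 = 0.5, gamma = 5,
                       window = 31L, border = "valid", epsilon = 1e-7) {
  stopifnot(lambda1 >= 0, lambda2 >= 0, gamma >= 0, epsilon > 0,
            epsilon < 0.5)
  structure(list(lambda1 = lambda1, lambda2 = lambda2, gamma = gamma,
                 window = as.integer(window), border = border,
                 epsilon = epsilon),
            class = "hardvessel_loss_config")
}

checkShapes <- function(S, G, W = NULL) {
  if (!identical(dim(as.matrix(S)), dim(as.matrix(G))))
    stop("prediction and mask shapes differ")
  if (!is.null(W) && !identical(dim(as.matrix(W)), dim(as.matrix(S))))
    stop("weight map shape differs from prediction")
  invisible(NULL)
}

#' Edge-weighted soft IoU loss
#'
#' `1 - sum(W*S*G) / sum(W*(S + G - S*G))`, the real-valued (soft)
#' intersection-over-union complement with per-pixel weights inside both
#' numerator and denominator. With `W = 1` everywhere this is the plain
#' soft IoU loss.
#'
#' @param S probability map in `[0, 1]`
#' @param G binary mask
#' @param W weight map (default all ones)
#' @param grad also return `d loss / d S`
#' @return scalar loss, or `list(loss, grad)` when `grad = TRUE`
#' @export
weightedIouLoss <- function(S, G, W = NULL, grad = FALSE) {
  checkShapes(S, G, W)
  if (is.null(W)) W <- array(1, dim(as.matrix(S)))
  I <- sum(W * S * G)
  U <- sum(W * (S + G - S * G))
  loss <- 1 - I / U
  if (!grad) return(loss)
  g <- -(W * G * U - I * W * (1 - G)) / U^2
  list(loss = loss, grad = g)
}

#' Edge-weighted binary cross-entropy loss
#'
#' Weight-normalized mean of the per-pixel cross entropy:
#' `sum(W * (-G*log(S) - (1-G)*log(1-S))) / sum(W)`, with `S` clamped to
#' `[epsilon, 1 - epsilon]` before the logarithms.
#'
#' @inheritParams weightedIouLoss
#' @param epsilon probability clamp
#' @export
weightedBceLoss <- function(S, G, W = NULL, epsilon = 1e-7, grad = FALSE) {
  checkShapes(S, G, W)
  if (is.null(W)) W <- array(1, dim(as.matrix(S)))
  Sc <- pmin(pmax(S, epsilon), 1 - epsilon)
  sw <- sum(W)
  loss <- sum(W * (-G * log(Sc) - (1 - G) * log(1 - Sc))) / sw
  if (!grad) return(loss)
  g <- W * (-G / Sc + (1 - G) / (1 - Sc)) / sw
  g[S < epsilon | S > 1 - epsilon] <- 0  # clamped region: flat
  list(loss = loss, grad = g)
}

#' Composite edge-weighted segmentation loss
#'
#' `L = lambda1 * L_IoU^w + lambda2 * L_BCE^w`, with the edge weight map
#' computed once from the ground truth. Both terms are also reported
#' separately. When `aux` maps are supplied (deep supervision), the same
#' composite loss is evaluated on each and summed into the total.
#'
#' @param S probability map
#' @param G binary ground-truth mask
#' @param config a [lossConfig()]
#' @param aux optional list of auxiliary probability maps
#' @param grad also return gradients w.r.t. `S` (and each aux map)
#' @param W optionally, a precomputed [edgeWeightMap()] for `G` (the
#'   training loop caches these, since the map depends only on the mask)
#' @return list with `total`, `iou`, `bce` and, when requested, `grad`
#'   (+ `auxGrad`)
#' @export
totalLoss <- function(S, G, config = lossConfig(), aux = NULL, grad = FALSE,
                      W = NULL) {
  if (is.null(W))
    W <- edgeWeightMap(as.matrix(G), config$window, config$gamma,
                       config$border)
  iou <- weightedIouLoss(S, G, W, grad = grad)
  bce <- weightedBceLoss(S, G, W, epsilon = config$epsilon, grad = grad)
  if (!grad) {
    total <- config$lambda1 * iou + config$lambda2 * bce
    if (!is.null(aux)) {
      for (a in aux) total <- total + totalLoss(a, G, config, W = W)$total
    }
    return(list(total = total, iou = iou, bce = bce))
  }
  total <- config$lambda1 * iou$loss + config$lambda2 * bce$loss
  g <- config$lambda1 * iou$grad + config$lambda2 * bce$grad
  auxGrad <- NULL
  if (!is.null(aux)) {
    auxGrad <- vector("list", length(aux))
    for (i in seq_along(aux)) {
      la <- totalLoss(aux[[i]], G, config, grad = TRUE, W = W)
      total <- total + la$total
      auxGrad[[i]] <- la$grad
    }
  }
  list(total = total, iou = iou$loss, bce = bce$loss, grad = g,
       auxGrad = auxGrad)
}
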