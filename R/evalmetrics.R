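#' Pixel-wise confusion counts inside the FOV
#'
#' Thresholds the probability map (`prediction = S >= threshold`) and
#' tallies TP/FP/FN/TN against the ground truth, counting only pixels
#' where the FOV mask is 1.
#'
#' @param S probability map (matrix)
#' @param G binary ground-truth mask
#' @param fov binary FOV mask; `NULL` evaluates the whole frame
#' @param threshold operating threshold in (0, 1)
#' @return a [ConfusionCounts-class]
#' @export
confusion <- function(S, G, fov = NULL, threshold = 0.5) {
  checkShapes(S, G, fov)
  stopifnot(threshold > 0, threshold < 1)
  keep <- if (is.null(fov)) rep(TRUE, length(S)) else fov == 1
  s <- S[keep]
  g <- G[keep]
  p <- s >= threshold
  ConfusionCounts(tp = sum(p & g == 1), fp = sum(p & g == 0),
                  fn = sum(!p & g == 1), tn = sum(!p & g == 0))
}

#' Segmentation metrics from confusion counts
#'
#' Sensitivity `TP/(TP+FN)`, specificity `TN/(TN+FP)`, precision
#' `TP/(TP+FP)`, F1 `2*precision*recall/(precision+recall)` and accuracy
#' `(TP+TN)/total`. Empty denominators yield `NaN` and the metric name is
#' recorded in the report's `undefined` slot rather than raising an error.
#'
#' @param counts a [ConfusionCounts-class]
#' @param threshold threshold recorded in the report
#' @return a [MetricsReport-class] (without AUC)
#' @export
metricsFromConfusion <- function(counts, threshold = 0.5) {
  stopifnot(is(counts, "ConfusionCounts"))
  tp <- counts@tp; fp <- counts@fp; fn <- counts@fn; tn <- counts@tn
  undef <- character(0)
  ratio <- function(num, den, name) {
    if (den == 0) { undef <<- c(undef, name); return(NaN) }
    num / den
  }
  se <- ratio(tp, tp + fn, "se")
  sp <- ratio(tn, tn + fp, "sp")
  prec <- ratio(tp, tp + fp, "precision")
  f1 <- if (is.nan(se) || is.nan(prec) || prec + se == 0) {
    undef <- c(undef, "f1"); NaN
  } else 2 * prec * se / (prec + se)
  acc <- ratio(tp + tn, tp + fp + fn + tn, "acc")
  MetricsReport(se = se, sp = sp, precision = prec, f1 = f1, acc = acc,
                nPixels = tp + fp + fn + tn, threshold = threshold,
                undefined = undef)
}

#' Squared macro-averaged F1
#'
#' The squared mean of the per-class F1 scores over the vessel and
#' background classes. Provided for completeness alongside the standard
#' binary F1 of [metricsFromConfusion()], which is the package default
#' (the squared form produces values on a different scale than commonly
#' reported vessel-segmentation F1 numbers).
#'
#' @param counts a [ConfusionCounts-class]
#' @return squared macro F1 value
#' @export
f1MacroSquared <- function(counts) {
  f1c <- function(tp, fp, fn) {
    p <- tp / (tp + fp); r <- tp / (tp + fn)
    2 * p * r / (p + r)
  }
  fPos <- f1c(counts@tp, counts@fp, counts@fn)
  fNeg <- f1c(counts@tn, counts@fn, counts@fp)
  mean(c(fPos, fNeg))^2
}

#' ROC curve and AUC inside the FOV
#'
#' Sweeps the threshold over all distinct predicted values, computing
#' (FPR, TPR) pairs, and integrates by the trapezoidal rule. The result
#' equals the pairwise ranking probability
#' `P(S_pos > S_neg) + 0.5 * P(S_pos == S_neg)`.
#'
#' @param S probability map
#' @param G binary ground truth
#' @param fov binary FOV mask or `NULL`
#' @return list with `auc` and `curve` (data frame of fpr, tpr)
#' @export
rocAuc <- function(S, G, fov = NULL) {
  checkShapes(S, G, fov)
  keep <- if (is.null(fov)) rep(TRUE, length(S)) else fov == 1
  s <- as.numeric(S)[keep]
  g <- as.numeric(G)[keep]
  nPos <- sum(g == 1)
  nNeg <- sum(g == 0)
  if (nPos == 0L || nNeg == 0L)
    stop("AUC needs at least one positive and one negative pixel inside the FOV")
  o <- order(s, decreasing = TRUE)
  s <- s[o]; g <- g[o]
  tps <- cumsum(g == 1)
  fps <- cumsum(g == 0)
  last <- c(s[-1] != s[-length(s)], TRUE)  # threshold boundaries (ties merged)
  tpr <- c(0, tps[last] / nPos)
  fpr <- c(0, fps[last] / nNeg)
  auc <- sum(diff(fpr) * (tpr[-1] + tpr[-length(tpr)]) / 2)
  list(auc = auc, curve = data.frame(fpr = fpr, tpr = tpr))
}

#' Aggregate metrics over a dataset
#'
#' Pooled mode sums the per-image confusion counts before computing
#' metrics; per-image mode averages per-image metric values and reports
#' their dispersion. Both views are returned.
#'
#' @param perImage list of per-image results, each a list with `counts`
#'   (a [ConfusionCounts-class]) and optionally `auc`
#' @param threshold operating threshold recorded in the reports
#' @param pooledAuc optional AUC computed over the pooled pixels of all
#'   images (counts alone cannot produce it); defaults to the mean of the
#'   per-image AUCs
#' @return list with `pooled` (a [MetricsReport-class]), `mean` and `sd`
#'   (named numeric vectors over per-image metrics), and `table`
#'   (per-image data frame)
#' @export
aggregateOverDataset <- function(perImage, threshold = 0.5,
                                 pooledAuc = NULL) {
  if (length(perImage) == 0L) stop("no per-image results to aggregate")
  total <- Reduce(`+`, lapply(perImage, `[[`, "counts"))
  pooled <- metricsFromConfusion(total, threshold)
  rows <- do.call(rbind, lapply(perImage, function(r) {
    row <- asMetricsRow(metricsFromConfusion(r$counts, threshold))
    row$auc <- if (!is.null(r$auc)) r$auc else NA_real_
    row$id <- if (!is.null(r$id)) r$id else NA_character_
    row
  }))
  metricCols <- c("se", "sp", "precision", "f1", "acc", "auc")
  mu <- vapply(rows[metricCols], function(v) mean(v, na.rm = TRUE),
               numeric(1))
  sdv <- vapply(rows[metricCols], function(v) {
    if (sum(!is.na(v)) > 1L) sd(v, na.rm = TRUE) else 0
  }, numeric(1))
  if (!is.null(pooledAuc)) {
    pooled@auc <- pooledAuc
  } else if (!any(is.na(rows$auc))) {
    pooled@auc <- mu[["auc"]]  # counts cannot pool AUC; fall back to mean
  }
  list(pooled = pooled, mean = mu, sd = sdv, table = rows)
}
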