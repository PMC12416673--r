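#' FundusSample: a fundus image with paired ground truth
#'
#' Central data container: an RGB fundus image in `[0, 1]` with its binary
#' vessel gold standard and binary field-of-view (FOV) mask, plus the
#' native geometry (recorded so padded maps can be cropped back) and a
#' sample identifier. Validity enforces that masks are strictly binary,
#' that every vessel pixel lies inside the FOV, and that all planes share
#' one geometry.
#'
#' @slot image numeric array `H x W x 3`, values in `[0, 1]`
#' @slot vesselMask numeric matrix `H x W`, values in `{0, 1}`
#' @slot fovMask numeric matrix `H x W`, values in `{0, 1}`
#' @slot nativeHeight,nativeWidth original (pre-padding) size in pixels
#' @slot sampleId identifier string
#' @aliases FundusSample-class
#' @exportClass FundusSample
setClass("FundusSample",
         representation(image = "array", vesselMask = "matrix",
                        fovMask = "matrix", nativeHeight = "integer",
                        nativeWidth = "integer", sampleId = "character"))

setValidity("FundusSample", function(object) {
  d <- dim(object@image)
  msgs <- character(0)
  if (length(d) != 3L || d[3] != 3L)
    msgs <- c(msgs, "image must be an H x W x 3 array")
  if (min(object@image) < 0 || max(object@image) > 1)
    msgs <- c(msgs, "image values must lie in [0, 1]")
  if (!identical(dim(object@vesselMask), d[1:2]) ||
      !identical(dim(object@fovMask), d[1:2]))
    msgs <- c(msgs, "mask dimensions must match the image")
  if (!all(object@vesselMask %in% c(0, 1)))
    msgs <- c(msgs, "vesselMask must contain only 0/1")
  if (!all(object@fovMask %in% c(0, 1)))
    msgs <- c(msgs, "fovMask must contain only 0/1")
  if (any(object@vesselMask > object@fovMask))
    msgs <- c(msgs, "vessel pixels must lie inside the FOV")
  if (object@nativeHeight > d[1] || object@nativeWidth > d[2])
    msgs <- c(msgs, "native size cannot exceed current size")
  if (length(msgs)) msgs else TRUE
})

#' Construct a FundusSample
#'
#' @param image numeric array `H x W x 3` in `[0, 1]`
#' @param vesselMask,fovMask binary `H x W` matrices
#' @param nativeHeight,nativeWidth original geometry (defaults: current)
#' @param sampleId identifier
#' @return a validated [FundusSample-class] object
#' @export
FundusSample <- function(image, vesselMask, fovMask,
                         nativeHeight = dim(image)[1],
                         nativeWidth = dim(image)[2],
                         sampleId = "sample") {
  new("FundusSample", image = image,
      vesselMask = matrix(as.numeric(vesselMask), nrow(vesselMask)),
      fovMask = matrix(as.numeric(fovMask), nrow(fovMask)),
      nativeHeight = as.integer(nativeHeight),
      nativeWidth = as.integer(nativeWidth),
      sampleId = as.character(sampleId))
}

#' @describeIn FundusSample-class the RGB image array
#' @param x a `FundusSample`
#' @export
sampleImage <- function(x) x@image

#' @describeIn FundusSample-class the binary vessel gold standard
#' @export
vesselMask <- function(x) x@vesselMask

#' @describeIn FundusSample-class the binary field-of-view mask
#' @export
fovMask <- function(x) x@fovMask

#' @describeIn FundusSample-class the sample identifier
#' @export
sampleId <- function(x) x@sampleId

#' @describeIn FundusSample-class native (pre-padding) height and width
#' @export
nativeDim <- function(x) c(x@nativeHeight, x@nativeWidth)

setMethod("show", "FundusSample", function(object) {
  d <- dim(object@image)
  cat(sprintf("FundusSample '%s': %d x %d (native %d x %d), %.1f%% vessel, %.1f%% FOV\n",
              object@sampleId, d[1], d[2], object@nativeHeight,
              object@nativeWidth, 100 * mean(object@vesselMask),
              100 * mean(object@fovMask)))
})

#' ConfusionCounts: pixel-wise confusion tallies
#'
#' TP/FP/FN/TN counts over the evaluated (in-FOV) pixels of one or more
#' images.
#'
#' @slot tp,fp,fn,tn non-negative pixel counts
#' @aliases ConfusionCounts-class
#' @exportClass ConfusionCounts
setClass("ConfusionCounts",
         representation(tp = "numeric", fp = "numeric", fn = "numeric",
                        tn = "numeric"))

setValidity("ConfusionCounts", function(object) {
  v <- c(object@tp, object@fp, object@fn, object@tn)
  if (any(v < 0) || any(v != round(v))) "counts must be non-negative integers"
  else TRUE
})

#' Construct ConfusionCounts
#' @param tp,fp,fn,tn pixel counts
#' @return a [ConfusionCounts-class] object
#' @export
ConfusionCounts <- function(tp = 0, fp = 0, fn = 0, tn = 0) {
  new("ConfusionCounts", tp = as.numeric(tp), fp = as.numeric(fp),
      fn = as.numeric(fn), tn = as.numeric(tn))
}

setMethod("show", "ConfusionCounts", function(object) {
  cat(sprintf("ConfusionCounts: TP=%g FP=%g FN=%g TN=%g (n=%g)\n",
              object@tp, object@fp, object@fn, object@tn,
              object@tp + object@fp + object@fn + object@tn))
})

#' @describeIn ConfusionCounts-class total evaluated pixels
#' @param x a `ConfusionCounts`
#' @export
nPixels <- function(x) x@tp + x@fp + x@fn + x@tn

#' Add two confusion tallies
#' @param e1,e2 `ConfusionCounts`
#' @export
setMethod("+", signature("ConfusionCounts", "ConfusionCounts"),
          function(e1, e2) {
  ConfusionCounts(e1@tp + e2@tp, e1@fp + e2@fp, e1@fn + e2@fn,
                  e1@tn + e2@tn)
})

#' MetricsReport: FOV-restricted segmentation metrics
#'
#' Sensitivity, specificity, precision, F1, accuracy and (optionally) AUC
#' for one image or an aggregate. Metrics with an empty denominator are
#' `NaN` and listed in `undefined`.
#'
#' @slot se,sp,precision,f1,acc,auc metric values in `[0, 1]` (or `NaN`)
#' @slot nPixels evaluated pixel count
#' @slot threshold operating threshold used for the binary metrics
#' @slot undefined names of metrics with empty denominators
#' @aliases MetricsReport-class
#' @exportClass MetricsReport
setClass("MetricsReport",
         representation(se = "numeric", sp = "numeric",
                        precision = "numeric", f1 = "numeric",
                        acc = "numeric", auc = "numeric",
                        nPixels = "numeric", threshold = "numeric",
                        undefined = "character"))

MetricsReport <- function(se, sp, precision, f1, acc, auc = NA_real_,
                          nPixels = 0, threshold = 0.5,
                          undefined = character(0)) {
  new("MetricsReport", se = se, sp = sp, precision = precision, f1 = f1,
      acc = acc, auc = auc, nPixels = nPixels, threshold = threshold,
      undefined = undefined)
}

setMethod("show", "MetricsReport", function(object) {
  cat(sprintf(
    "MetricsReport (threshold %.2f, %g px): Se=%.4f Sp=%.4f P=%.4f F1=%.4f ACC=%.4f AUC=%s\n",
    object@threshold, object@nPixels, object@se, object@sp,
    object@precision, object@f1, object@acc,
    ifelse(is.na(object@auc), "-", sprintf("%.4f", object@auc))))
  if (length(object@undefined))
    cat("  undefined:", paste(object@undefined, collapse = ", "), "\n")
})

#' Turn a MetricsReport into a one-row data frame
#' @param report a [MetricsReport-class]
#' @export
asMetricsRow <- function(report) {
  data.frame(se = report@se, sp = report@sp, precision = report@precision,
             f1 = report@f1, acc = report@acc, auc = report@auc,
             nPixels = report@nPixels, threshold = report@threshold)
}
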