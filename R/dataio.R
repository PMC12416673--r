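# Reading images: EBImage handles PNG/TIFF/JPEG; its arrays are
# width x height, so everything is transposed into row-major H x W here.
readImageHW <- function(path) {
  img <- EBImage::readImage(path)
  a <- EBImage::imageData(img)
  if (length(dim(a)) == 2L) {
    t(a)
  } else {
    aperm(a[, , seq_len(min(dim(a)[3], 3L)), drop = FALSE], c(2L, 1L, 3L))
  }
}

binarizeMask <- function(m) {
  if (length(dim(m)) == 3L) m <- m[, , 1L]
  rng <- range(m)
  if (rng[2] > rng[1]) {
    (m >= rng[1] + 0.5 * (rng[2] - rng[1])) * 1
  } else {
    (m > 0.5) * 1
  }
}

#' Load a fundus sample from image + mask files
#'
#' Reads an image (PNG/TIFF/JPEG) and its vessel and FOV mask files,
#' scales intensities to `[0, 1]`, binarizes the masks at 0.5 of their
#' dynamic range (annotation files can carry anti-aliased borders) and
#' records the native geometry.
#'
#' @param imagePath path to the color fundus image
#' @param vesselPath path to the vessel gold-standard mask
#' @param fovPath path to the FOV mask; `NULL` means whole-frame FOV
#' @param sampleId identifier (default: image file stem)
#' @return a [FundusSample-class]
#' @export
loadSample <- function(imagePath, vesselPath, fovPath = NULL,
                       sampleId = NULL) {
  for (p in c(imagePath, vesselPath, fovPath))
    if (!file.exists(p)) stop("file not found: ", p)
  img <- readImageHW(imagePath)
  if (length(dim(img)) == 2L) img <- array(rep(img, 3L), c(dim(img), 3L))
  img <- pmin(pmax(img, 0), 1)
  d <- dim(img)[1:2]
  vm <- readImageHW(vesselPath)
  if (!identical(dim(vm)[1:2], d))
    stop("mask size differs from image: ", vesselPath)
  vessel <- binarizeMask(vm)
  if (is.null(fovPath)) {
    fov <- matrix(1, d[1], d[2])
  } else {
    fm <- readImageHW(fovPath)
    if (!identical(dim(fm)[1:2], d))
      stop("mask size differs from image: ", fovPath)
    fov <- binarizeMask(fm)
  }
  vessel <- vessel * fov  # gold standard is defined within the FOV
  if (is.null(sampleId))
    sampleId <- tools::file_path_sans_ext(basename(imagePath))
  FundusSample(image = img, vesselMask = vessel, fovMask = fov,
               sampleId = sampleId)
}

#' Load every sample of a DRIVE-style directory tree
#'
#' Expects `images/`, `manual/` and (optionally) `fov/` subdirectories with
#' matching file stems, as produced by [writeDataset()].
#'
#' @param rootPath dataset root
#' @return list of [FundusSample-class] objects, ordered by id
#' @export
loadDataset <- function(rootPath) {
  imgs <- sort(dir(file.path(rootPath, "images"), full.names = TRUE))
  if (length(imgs) == 0L) stop("no images under ", rootPath)
  lapply(imgs, function(ip) {
    id <- tools::file_path_sans_ext(basename(ip))
    vp <- dir(file.path(rootPath, "manual"), pattern = paste0("^", id, "\\."),
              full.names = TRUE)[1]
    fp <- dir(file.path(rootPath, "fov"), pattern = paste0("^", id, "\\."),
              full.names = TRUE)[1]
    if (is.na(vp)) stop("no vessel mask for sample ", id)
    loadSample(ip, vp, if (!is.na(fp)) fp, sampleId = id)
  })
}

#' Min-max normalize an image to [0, 1]
#'
#' Per-image linear rescaling; a constant image maps to all zeros.
#'
#' @param image numeric array or matrix
#' @return array of the same shape with range within `[0, 1]`
#' @export
normalizeImage <- function(image) {
  rng <- range(image)
  if (rng[2] > rng[1]) (image - rng[1]) / (rng[2] - rng[1])
  else image * 0
}

#' Histogram equalization
#'
#' Classic 256-bin equalization applied per channel: each intensity is
#' mapped to the empirical CDF of its channel, flattening the histogram.
#' Channels with no contrast are returned unchanged.
#'
#' @param image numeric array (`H x W` or `H x W x C`) with values in
#'   `[0, 1]`
#' @param levels number of histogram bins
#' @return equalized image, values in `[0, 1]`, rank order preserved
#' @export
equalizeImage <- function(image, levels = 256L) {
  eq1 <- function(ch) {
    if (diff(range(ch)) == 0) return(ch)
    bin <- pmin(floor(ch * levels) + 1L, levels)
    cdf <- cumsum(tabulate(bin, nbins = levels)) / length(ch)
    out <- cdf[bin]
    dim(out) <- dim(ch)
    out
  }
  if (length(dim(image)) == 3L) {
    for (ch in seq_len(dim(image)[3])) {
      image[, , ch] <- eq1(image[, , ch])
    }
    image
  } else {
    eq1(image)
  }
}

#' Pad a sample to a target canvas
#'
#' Places image and masks centered on a zero canvas of the target size and
#' records the offsets, so network outputs can be cropped back losslessly
#' — a DRIVE-sized 584 x 565 sample padded to 592 x 592 gets offsets
#' (4, 13). Padding (not interpolation) preserves single-pixel vessels
#' bit-exactly.
#'
#' @param sample a [FundusSample-class]
#' @param targetH,targetW target canvas size, `>=` the sample size
#' @return list with `sample` (padded) and `record` (a pad record holding
#'   native/target geometry and offsets for [cropBack()])
#' @export
padTo <- function(sample, targetH, targetW) {
  d <- dim(sampleImage(sample))
  if (targetH < d[1] || targetW < d[2])
    stop("target size is smaller than the sample; down-scaling is not supported")
  offR <- (targetH - d[1]) %/% 2L
  offC <- (targetW - d[2]) %/% 2L
  record <- padRecord(d[1], d[2], targetH, targetW, offR, offC)
  img <- array(0, c(targetH, targetW, 3L))
  img[offR + seq_len(d[1]), offC + seq_len(d[2]), ] <- sampleImage(sample)
  vm <- matrix(0, targetH, targetW)
  vm[offR + seq_len(d[1]), offC + seq_len(d[2])] <- vesselMask(sample)
  fm <- matrix(0, targetH, targetW)
  fm[offR + seq_len(d[1]), offC + seq_len(d[2])] <- fovMask(sample)
  padded <- FundusSample(img, vm, fm, nativeHeight = d[1],
                         nativeWidth = d[2], sampleId = sampleId(sample))
  list(sample = padded, record = record)
}

#' @rdname padTo
#' @param nativeH,nativeW,offR,offC pad geometry
#' @export
padRecord <- function(nativeH, nativeW, targetH, targetW, offR, offC) {
  stopifnot(offR >= 0, offC >= 0, nativeH + offR <= targetH,
            nativeW + offC <= targetW)
  structure(list(nativeHeight = as.integer(nativeH),
                 nativeWidth = as.integer(nativeW),
                 targetHeight = as.integer(targetH),
                 targetWidth = as.integer(targetW),
                 offsetRow = as.integer(offR),
                 offsetCol = as.integer(offC)),
            class = "hardvessel_pad_record")
}

#' Crop a padded map back to native geometry
#'
#' Inverse of [padTo()] for any per-pixel map (probability map, mask,
#' image): extracts the native-size window at the recorded offsets.
#'
#' @param map matrix or array with the record's target dimensions
#' @param record pad record from [padTo()]
#' @return the `nativeHeight x nativeWidth` window
#' @export
cropBack <- function(map, record) {
  stopifnot(inherits(record, "hardvessel_pad_record"))
  d <- dim(map)
  if (d[1] != record$targetHeight || d[2] != record$targetWidth)
    stop(sprintf("map is %d x %d but the pad record expects %d x %d",
                 d[1], d[2], record$targetHeight, record$targetWidth))
  rows <- record$offsetRow + seq_len(record$nativeHeight)
  cols <- record$offsetCol + seq_len(record$nativeWidth)
  if (length(d) == 3L) map[rows, cols, , drop = FALSE]
  else map[rows, cols, drop = FALSE]
}

#' Bilinearly resize a map or image
#'
#' Interpolation-based geometric normalization, provided as the non-default
#' alternative to [padTo()]/[cropBack()]. Interpolation is lossy for
#' single-pixel vessels, which is why the padding route is the default
#' protocol; this helper exists for workflows that require true resizing.
#'
#' @param map matrix (`H x W`) or array (`H x W x C`)
#' @param targetH,targetW output size in pixels
#' @return resized map with half-pixel-center bilinear sampling
#' @export
resizeImage <- function(map, targetH, targetW) {
  d <- dim(map)
  x <- if (length(d) == 2L) array(map, c(d, 1L, 1L)) else array(map, c(d, 1L))
  y <- nn_bilinear(x, as.integer(targetH), as.integer(targetW))
  if (length(d) == 2L) y[, , 1L, 1L] else y[, , , 1L]
}

#' Deterministic train/validation split
#'
#' Splits unique sample ids by sorted order: the first
#' `floor(ratio * n)` become training, the remainder validation (the 9:1
#' convention by default).
#'
#' @param sampleIds character or integer vector of unique ids
#' @param ratio training fraction; `ratio = 1` yields an empty validation
#'   set
#' @return list with `train` and `val` id vectors
#' @export
splitTrainVal <- function(sampleIds, ratio = 0.9) {
  if (anyDuplicated(sampleIds)) stop("sample ids must be unique")
  n <- length(sampleIds)
  if (n < 2L) stop("need at least 2 samples to split")
  stopifnot(ratio > 0, ratio <= 1)
  ids <- sort(sampleIds)
  k <- floor(ratio * n)
  list(train = ids[seq_len(k)],
       val = if (k < n) ids[(k + 1L):n] else ids[0])
}

#' Draw one augmentation choice
#'
#' One of the four augmentations — horizontal flip, vertical flip,
#' contrast adjustment, additive Gaussian noise — selected uniformly, with
#' its magnitude drawn where applicable (contrast factor uniform in
#' [0.8, 1.2]; noise s.d. uniform in [0.005, 0.03]).
#'
#' @return list with `kind` and `magnitude`
#' @export
augmentChoice <- function() {
  kind <- c("hflip", "vflip", "contrast", "gaussian_noise")[sample.int(4L, 1L)]
  magnitude <- switch(kind,
                      contrast = runif(1, 0.8, 1.2),
                      gaussian_noise = runif(1, 0.005, 0.03),
                      0)
  list(kind = kind, magnitude = magnitude)
}

#' Apply one augmentation to a sample
#'
#' Geometric augmentations (flips) are applied identically to the image
#' and both masks; intensity augmentations (contrast, noise) touch only
#' the image and are clipped back to `[0, 1]`.
#'
#' @param sample a [FundusSample-class]
#' @param choice an [augmentChoice()] result
#' @return augmented [FundusSample-class]
#' @export
applyAugment <- function(sample, choice) {
  img <- sampleImage(sample)
  vm <- vesselMask(sample)
  fm <- fovMask(sample)
  switch(choice$kind,
    hflip = {
      img <- img[, rev(seq_len(ncol(vm))), , drop = FALSE]
      vm <- vm[, rev(seq_len(ncol(vm))), drop = FALSE]
      fm <- fm[, rev(seq_len(ncol(fm))), drop = FALSE]
    },
    vflip = {
      img <- img[rev(seq_len(nrow(vm))), , , drop = FALSE]
      vm <- vm[rev(seq_len(nrow(vm))), , drop = FALSE]
      fm <- fm[rev(seq_len(nrow(fm))), , drop = FALSE]
    },
    contrast = {
      mu <- mean(img)
      img <- pmin(pmax(mu + (img - mu) * choice$magnitude, 0), 1)
    },
    gaussian_noise = {
      img <- pmin(pmax(img + rnorm(length(img), 0, choice$magnitude), 0), 1)
    },
    stop("unknown augmentation kind: ", choice$kind))
  FundusSample(img, vm, fm, nativeHeight = nativeDim(sample)[1],
               nativeWidth = nativeDim(sample)[2],
               sampleId = sampleId(sample))
}

#' Randomly augment a sample
#'
#' Draws one [augmentChoice()] from R's RNG and applies it.
#'
#' @param sample a [FundusSample-class]
#' @return augmented sample; the choice made is attached as attribute
#'   `"augmentChoice"`
#' @export
augmentRandom <- function(sample) {
  ch <- augmentChoice()
  out <- applyAugment(sample, ch)
  attr(out, "augmentChoice") <- ch
  out
}
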