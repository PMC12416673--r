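#' Simulator configuration
#'
#' Parameters of the synthetic fundus generator. Defaults emulate a
#' 128 x 128 fundus photograph: a bright circular field-of-view disc on a
#' dark background, four branching vessel trees entering from the FOV rim
#' with trunk widths of a few pixels tapering toward the periphery, a
#' smooth radial background gradient and additive Gaussian noise, giving a
#' vessel density of roughly 10-15% of the FOV area.
#'
#' @param imageHeight,imageWidth canvas size in pixels
#' @param nTrees number of vessel trees rooted on the FOV rim
#' @param maxDepth maximum branching depth (a depth-0 tree is one segment)
#' @param branchProb probability that a segment spawns a second child
#' @param initialWidth root segment width in pixels
#' @param widthDecay multiplicative width factor per generation, in (0, 1]
#' @param segmentLength mean segment length in pixels
#' @param angleJitter s.d. (radians) of the direction perturbation per
#'   segment
#' @param vesselContrast intensity deficit of vessels below the local
#'   background, in [0, 1] (vessels are darker, as in fundus photography;
#'   a negative value renders bright vessels)
#' @param backgroundLevel base background intensity in [0, 1]
#' @param noiseSigma s.d. of the additive Gaussian pixel noise
#' @param fovRadiusFrac FOV disc radius as a fraction of `min(H, W) / 2`
#' @param seed integer seed; each sample derives its own RNG stream from
#'   `(seed, sample index)` so datasets are order-independent
#' @return validated list of class `hardvessel_sim_config`
#' @export
simConfig <- function(imageHeight = 128L, imageWidth = 128L, nTrees = 4L,
                      maxDepth = 5L, branchProb = 0.3, initialWidth = 4.5,
                      widthDecay = 0.88, segmentLength = 9,
                      angleJitter = 0.15, vesselContrast = 0.35,
                      backgroundLevel = 0.55, noiseSigma = 0.03,
                      fovRadiusFrac = 0.95, seed = 1L) {
  cfg <- list(imageHeight = as.integer(imageHeight),
              imageWidth = as.integer(imageWidth),
              nTrees = as.integer(nTrees), maxDepth = as.integer(maxDepth),
              branchProb = branchProb, initialWidth = initialWidth,
              widthDecay = widthDecay, segmentLength = segmentLength,
              angleJitter = angleJitter, vesselContrast = vesselContrast,
              backgroundLevel = backgroundLevel, noiseSigma = noiseSigma,
              fovRadiusFrac = fovRadiusFrac, seed = as.integer(seed))
  if (cfg$imageHeight < 1L || cfg$imageWidth < 1L || cfg$nTrees < 1L)
    stop("image dimensions and nTrees must be >= 1")
  if (cfg$maxDepth < 0L) stop("maxDepth must be >= 0")
  if (cfg$branchProb < 0 || cfg$branchProb > 1)
    stop("branchProb must lie in [0, 1]")
  if (cfg$initialWidth < 1) stop("initialWidth must be >= 1 pixel")
  if (cfg$widthDecay <= 0 || cfg$widthDecay > 1)
    stop("widthDecay must lie in (0, 1]")
  if (cfg$segmentLength < 1) stop("segmentLength must be >= 1 pixel")
  if (cfg$noiseSigma < 0) stop("noiseSigma must be >= 0")
  if (cfg$fovRadiusFrac <= 0 || cfg$fovRadiusFrac > 1)
    stop("fovRadiusFrac must lie in (0, 1]")
  structure(cfg, class = "hardvessel_sim_config")
}

#' Generate a synthetic vessel tree
#'
#' Grows `nTrees` recursive binary trees of straight segments, rooted on
#' the FOV rim and directed toward the disc interior. Every segment of
#' depth `< maxDepth` continues with one child whose direction is the
#' parent's plus `Normal(0, angleJitter)` noise, and with probability
#' `branchProb` bifurcates into a second child; at a bifurcation the two
#' children split at a fixed +/- pi/6 to the parent direction. Child width
#' is parent width times `widthDecay`.
#'
#' @param config a [simConfig()]; the RNG must already be positioned (the
#'   function draws from R's RNG — use [withr::with_seed()] or
#'   [renderSample()]/[simulateDataset()] which manage streams per sample)
#' @return list of class `hardvessel_vessel_tree` with `segments`, a data
#'   frame (startRow, startCol, endRow, endCol, width, depth)
#' @export
generateTree <- function(config) {
  stopifnot(inherits(config, "hardvessel_sim_config"))
  H <- config$imageHeight; W <- config$imageWidth
  ctr <- c((H + 1) / 2, (W + 1) / 2)
  R <- config$fovRadiusFrac * min(H, W) / 2
  segs <- vector("list", 0L)
  grow <- function(start, angle, width, depth) {
    len <- config$segmentLength * runif(1, 0.75, 1.25)
    end <- start + len * c(sin(angle), cos(angle))
    segs[[length(segs) + 1L]] <<- c(start, end, width, depth)
    if (depth >= config$maxDepth) return(invisible(NULL))
    w2 <- width * config$widthDecay
    if (runif(1) < config$branchProb) {
      grow(end, angle + pi / 6 + rnorm(1, 0, config$angleJitter), w2,
           depth + 1L)
      grow(end, angle - pi / 6 + rnorm(1, 0, config$angleJitter), w2,
           depth + 1L)
    } else {
      grow(end, angle + rnorm(1, 0, config$angleJitter), w2, depth + 1L)
    }
  }
  for (t in seq_len(config$nTrees)) {
    theta <- runif(1, 0, 2 * pi)
    root <- ctr + R * c(sin(theta), cos(theta))
    inward <- atan2(ctr[1] - root[1], ctr[2] - root[2])
    grow(root, inward + rnorm(1, 0, config$angleJitter),
         config$initialWidth, 0L)
  }
  m <- do.call(rbind, segs)
  segments <- data.frame(startRow = m[, 1], startCol = m[, 2],
                         endRow = m[, 3], endCol = m[, 4],
                         width = m[, 5], depth = as.integer(m[, 6]))
  if (any(!is.finite(as.matrix(segments[, 1:5]))))
    stop("non-finite segment geometry generated")
  structure(list(segments = segments, config = config),
            class = "hardvessel_vessel_tree")
}

# Rasterize one segment: pixels whose center lies within width/2 of the
# segment (as a point set) are vessel. Vectorized over the bounding box.
rasterizeSegment <- function(mask, p0, p1, width) {
  H <- nrow(mask); W <- ncol(mask)
  r <- width / 2
  rows <- max(1L, floor(min(p0[1], p1[1]) - r)):min(H, ceiling(max(p0[1], p1[1]) + r))
  cols <- max(1L, floor(min(p0[2], p1[2]) - r)):min(W, ceiling(max(p0[2], p1[2]) + r))
  if (rows[1] > rows[length(rows)] || cols[1] > cols[length(cols)])
    return(mask)
  rr <- matrix(rows, length(rows), length(cols))
  cc <- matrix(cols, length(rows), length(cols), byrow = TRUE)
  v <- p1 - p0
  L2 <- sum(v * v)
  if (L2 == 0) {
    d2 <- (rr - p0[1])^2 + (cc - p0[2])^2
  } else {
    t <- pmin(pmax(((rr - p0[1]) * v[1] + (cc - p0[2]) * v[2]) / L2, 0), 1)
    d2 <- (rr - (p0[1] + t * v[1]))^2 + (cc - (p0[2] + t * v[2]))^2
  }
  hit <- d2 <= r^2
  mask[rows, cols] <- mask[rows, cols] | hit
  mask
}

fovDisc <- function(H, W, frac) {
  ctr <- c((H + 1) / 2, (W + 1) / 2)
  R <- frac * min(H, W) / 2
  rr <- matrix(seq_len(H), H, W)
  cc <- matrix(seq_len(W), H, W, byrow = TRUE)
  ((rr - ctr[1])^2 + (cc - ctr[2])^2 <= R^2) * 1
}

#' Render a vessel tree into a fundus sample
#'
#' Rasterizes the tree into a binary vessel mask (union of segment strokes
#' at their widths, clipped to the FOV disc), composes an RGB image —
#' smooth vignetted background at `backgroundLevel`, vessels darker by
#' `vesselContrast`, additive Gaussian noise of s.d. `noiseSigma`, clipped
#' to [0, 1] — and the centered circular FOV mask.
#'
#' @param tree a [generateTree()] result
#' @param config a [simConfig()] (defaults to the tree's own)
#' @param sampleId identifier stored in the sample
#' @return a [FundusSample-class] object
#' @export
renderSample <- function(tree, config = tree$config, sampleId = "sim") {
  stopifnot(inherits(tree, "hardvessel_vessel_tree"))
  H <- config$imageHeight; W <- config$imageWidth
  mask <- matrix(FALSE, H, W)
  for (i in seq_len(nrow(tree$segments))) {
    s <- tree$segments[i, ]
    mask <- rasterizeSegment(mask, c(s$startRow, s$startCol),
                             c(s$endRow, s$endCol), s$width)
  }
  fov <- fovDisc(H, W, config$fovRadiusFrac)
  vessel <- (mask & (fov > 0)) * 1
  ctr <- c((H + 1) / 2, (W + 1) / 2)
  rr <- matrix(seq_len(H), H, W)
  cc <- matrix(seq_len(W), H, W, byrow = TRUE)
  rad2 <- ((rr - ctr[1])^2 + (cc - ctr[2])^2) / (min(H, W) / 2)^2
  bg <- config$backgroundLevel * (1 - 0.25 * rad2) +
    0.03 * (cc - ctr[2]) / W
  field <- bg - config$vesselContrast * vessel
  field <- field * fov + 0.02 * (1 - fov)
  chanScale <- c(1, 0.62, 0.3)  # reddish fundus hue
  img <- array(0, c(H, W, 3))
  for (ch in 1:3) {
    noisy <- field * chanScale[ch] +
      if (config$noiseSigma > 0) rnorm(H * W, 0, config$noiseSigma) else 0
    img[, , ch] <- pmin(pmax(noisy, 0), 1)
  }
  FundusSample(image = img, vesselMask = vessel, fovMask = fov,
               sampleId = sampleId)
}

#' Simulate a dataset of fundus samples
#'
#' Draws `n` independent samples. Each sample uses its own RNG stream
#' derived from `(seed, index)`, so sample `i` is identical no matter how
#' many other samples are generated.
#'
#' @param n number of samples
#' @param config a [simConfig()]; its `seed` is the dataset seed
#' @return list of [FundusSample-class] objects
#' @export
simulateDataset <- function(n, config = simConfig()) {
  stopifnot(n >= 1)
  lapply(seq_len(n), function(i) {
    sseed <- (config$seed + 7919L * i) %% .Machine$integer.max
    withr::with_seed(sseed, {
      tree <- generateTree(config)
      renderSample(tree, config, sampleId = sprintf("sim_%03d", i))
    })
  })
}

#' Write samples to a DRIVE-style directory tree
#'
#' Creates `images/`, `manual/` (vessel gold standard) and `fov/` PNG files
#' plus a `manifest.json` listing ids and relative paths. Masks are written
#' losslessly (8-bit PNG, values 0/255) so a write/load round trip
#' reproduces them bit-exactly.
#'
#' @param samples non-empty list of [FundusSample-class] objects
#' @param rootPath output directory
#' @param force overwrite an existing non-empty directory
#' @return the manifest, invisibly (list with `ids` and per-sample paths)
#' @export
writeDataset <- function(samples, rootPath, force = FALSE) {
  if (length(samples) == 0L) stop("no samples to write")
  if (dir.exists(rootPath) && length(dir(rootPath)) > 0L && !force)
    stop("refusing to overwrite non-empty directory ", rootPath,
         " (use force = TRUE)")
  for (d in c("images", "manual", "fov"))
    dir.create(file.path(rootPath, d), recursive = TRUE,
               showWarnings = FALSE)
  entries <- lapply(samples, function(s) {
    id <- sampleId(s)
    paths <- list(image = file.path("images", paste0(id, ".png")),
                  vessel = file.path("manual", paste0(id, ".png")),
                  fov = file.path("fov", paste0(id, ".png")))
    png::writePNG(sampleImage(s), file.path(rootPath, paths$image))
    png::writePNG(vesselMask(s), file.path(rootPath, paths$vessel))
    png::writePNG(fovMask(s), file.path(rootPath, paths$fov))
    c(list(id = id), paths)
  })
  manifest <- list(ids = vapply(entries, `[[`, "", "id"),
                   samples = entries)
  jsonlite::write_json(manifest, file.path(rootPath, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(manifest)
}
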