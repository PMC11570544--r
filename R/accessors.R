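# Constructors, accessors and show() methods for the S4 containers.

#' Create a scene configuration
#'
#' Defaults describe the sparse, high-contrast source condition used
#' throughout the package: 10 moderately sized elliptical cells on a dimly
#' textured background with mild noise and small frame-to-frame motion.
#'
#' @param frameSize height/width in pixels (scalar or length 2).
#' @param nCells number of cells in the first frame.
#' @param cellRadiusRange min/max semi-major axis (px).
#' @param eccentricityRange ellipse eccentricity range in [0, 1).
#' @param intensityFg,intensityBg mean foreground/background intensity.
#' @param noiseSigma additive Gaussian noise std.
#' @param illuminationGradient illumination plane slope.
#' @param motionSigma per-frame displacement std (px).
#' @param divisionProb per-cell per-frame division probability.
#' @param nFrames number of frames.
#' @param maxOverlap maximum fractional overlap tolerated at placement.
#' @param minSeparation minimum center-to-center distance (px) at
#'   placement; 0 disables.
#' @param seed integer RNG seed.
#' @return A [SceneConfig-class] object.
#' @examples
#' cfg <- sceneConfig(nCells = 5L, seed = 1L)
#' @export
sceneConfig <- function(frameSize = 96L, nCells = 10L,
                        cellRadiusRange = c(4, 6),
                        eccentricityRange = c(0, 0.6),
                        intensityFg = 0.75, intensityBg = 0.25,
                        noiseSigma = 0.03, illuminationGradient = 0,
                        motionSigma = 1, divisionProb = 0,
                        nFrames = 1L, maxOverlap = 0.2,
                        minSeparation = 0, seed = 1L) {
  if (length(frameSize) == 1L) frameSize <- c(frameSize, frameSize)
  methods::new("SceneConfig", frameSize = as.integer(frameSize),
               nCells = as.integer(nCells),
               cellRadiusRange = as.numeric(cellRadiusRange),
               eccentricityRange = as.numeric(eccentricityRange),
               intensityFg = intensityFg, intensityBg = intensityBg,
               noiseSigma = noiseSigma,
               illuminationGradient = illuminationGradient,
               motionSigma = motionSigma, divisionProb = divisionProb,
               nFrames = as.integer(nFrames), maxOverlap = maxOverlap,
               minSeparation = minSeparation, seed = as.integer(seed))
}

#' Create a photometric shift specification
#'
#' The default is the identity shift. The default *target-domain* shift used
#' in the examples and experiments is `shiftSpec(gamma = 1.6, contrast = 0.6,
#' brightness = 0.08, noiseSigma = 0.05)`: lower contrast, brighter
#' background, heavier noise.
#'
#' @param gamma,contrast,brightness,invert,illuminationGradient,noiseSigma
#'   see [ShiftSpec-class].
#' @param seed seed for the redrawn noise.
#' @return A [ShiftSpec-class] object.
#' @export
shiftSpec <- function(gamma = 1, contrast = 1, brightness = 0,
                      invert = FALSE, illuminationGradient = 0,
                      noiseSigma = 0, seed = 1L) {
  methods::new("ShiftSpec", gamma = gamma, contrast = contrast,
               brightness = brightness, invert = invert,
               illuminationGradient = illuminationGradient,
               noiseSigma = noiseSigma, seed = as.integer(seed))
}

#' @rdname CellVideo-class
#' @param frames,masks,trackTable see slots.
#' @export
cellVideo <- function(frames, masks, trackTable) {
  methods::new("CellVideo", frames = frames, masks = masks,
               trackTable = trackTable)
}

#' @describeIn CellVideo-class frames accessor.
#' @param x a `CellVideo`.
#' @export
frames <- function(x) x@frames

#' @describeIn CellVideo-class instance mask accessor.
#' @export
masks <- function(x) x@masks

#' @describeIn CellVideo-class lineage table accessor.
#' @export
trackTable <- function(x) x@trackTable

#' @describeIn CellVideo-class number of frames.
#' @export
nFrames <- function(x) length(x@frames)

setMethod("show", "SceneConfig", function(object) {
  cat(sprintf(
    "SceneConfig: %dx%d px, %d cells, r %.1f-%.1f, fg %.2f / bg %.2f,\n",
    object@frameSize[1], object@frameSize[2], object@nCells,
    object@cellRadiusRange[1], object@cellRadiusRange[2],
    object@intensityFg, object@intensityBg))
  cat(sprintf(
    "  noise %.3f, motion %.2f px/frame, division p=%.3f, %d frame(s), seed %d\n",
    object@noiseSigma, object@motionSigma, object@divisionProb,
    object@nFrames, object@seed))
})

setMethod("show", "CellVideo", function(object) {
  h <- nrow(object@frames[[1]]); w <- ncol(object@frames[[1]])
  cat(sprintf("CellVideo: %d frame(s) of %dx%d px, %d track(s)\n",
              length(object@frames), h, w, nrow(object@trackTable)))
  if (nrow(object@trackTable))
    cat(sprintf("  labels %s; %d division(s)\n",
                paste(range(object@trackTable$label), collapse = "-"),
                sum(object@trackTable$parent != 0) %/% 2L))
})

setMethod("show", "SegModel", function(object) {
  part <- parameterPartition(object)
  cat(sprintf(
    "SegModel: %d conv/BN nodes, %d trainable parameters (%d BN affine)\n",
    length(object@graph), part$total, part$bnAffine))
  if (nrow(object@trainLog))
    cat(sprintf("  trained %d epoch(s), final soft-Dice loss %.4f\n",
                max(object@trainLog$epoch),
                object@trainLog$loss[nrow(object@trainLog)]))
})

setMethod("show", "JointModel", function(object) {
  cat(sprintf(
    "JointModel: detection head at strides 8/16/32, %s ReID branch, D=%d, C=%d ids\n",
    if (isTRUE(object@config$useSAM)) "spatial-attention" else "stacked-conv",
    object@config$embedDim, object@config$nIds))
})

setMethod("show", "TrackSet", function(object) {
  st <- vapply(object@tracks, function(t) t$status, character(1))
  cat(sprintf("TrackSet: %d tracklet(s) over %d frame(s) (%s)\n",
              length(object@tracks), object@nFrames,
              paste(names(table(st)), table(st), sep = ":", collapse = ", ")))
})

setMethod("show", "MetricsReport", function(object) {
  cat("MetricsReport\n")
  if (nrow(object@segmentation))
    cat(sprintf("  segmentation: Dice %.3f, IOU %.3f, AJI %.3f (frame means)\n",
                mean(object@segmentation$dice), mean(object@segmentation$iou),
                mean(object@segmentation$aji)))
  tr <- object@tracking
  if (length(tr))
    cat(sprintf("  tracking: MOTA %.3f, CT %.3f, TF %.3f, MT %.1f%%, ML %.1f%%, IDSW %d\n",
                tr$mota, tr$ct, tr$tf, tr$mt, tr$ml, tr$idsw))
})

#' Per-frame segmentation scores of a report
#' @param x a [MetricsReport-class].
#' @export
segScores <- function(x) x@segmentation

#' Tracking scores of a report
#' @param x a [MetricsReport-class].
#' @export
trackScores <- function(x) x@tracking
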