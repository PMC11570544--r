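#' Scene configuration for the synthetic cell video generator
#'
#' Describes one imaging condition: geometry and number of cells, foreground
#' and background intensity, noise, illumination, frame-to-frame motion and
#' division behaviour. Identical configurations (including `seed`) generate
#' bit-identical videos.
#'
#' @slot frameSize integer(2), frame height and width in pixels.
#' @slot nCells number of cells placed in frame 0.
#' @slot cellRadiusRange numeric(2), min/max semi-major axis in pixels.
#' @slot eccentricityRange numeric(2) in [0, 1); 0 is a circle.
#' @slot intensityFg mean foreground intensity in [0, 1].
#' @slot intensityBg mean background intensity in [0, 1].
#' @slot noiseSigma additive Gaussian noise standard deviation.
#' @slot illuminationGradient slope of an additive illumination plane
#'   (intensity change from frame centre to border).
#' @slot motionSigma per-frame centroid displacement standard deviation (px).
#' @slot divisionProb per-cell per-frame division probability.
#' @slot nFrames number of frames.
#' @slot maxOverlap maximum allowed fractional overlap of a newly placed cell
#'   with already placed cells before the placement is retried.
#' @slot minSeparation minimum center-to-center distance (px) enforced at
#'   placement (0 disables the constraint).
#' @slot seed integer RNG seed.
#' @export
setClass("SceneConfig", representation(
  frameSize = "integer", nCells = "integer", cellRadiusRange = "numeric",
  eccentricityRange = "numeric", intensityFg = "numeric",
  intensityBg = "numeric", noiseSigma = "numeric",
  illuminationGradient = "numeric", motionSigma = "numeric",
  divisionProb = "numeric", nFrames = "integer", maxOverlap = "numeric",
  minSeparation = "numeric", seed = "integer"))

setValidity("SceneConfig", function(object) {
  msg <- character()
  if (any(object@frameSize < 8L)) msg <- c(msg, "frameSize must be >= 8 px")
  if (object@nCells < 0L) msg <- c(msg, "nCells must be >= 0")
  if (object@nFrames < 1L) msg <- c(msg, "nFrames must be >= 1")
  if (object@intensityFg < 0 || object@intensityFg > 1 ||
      object@intensityBg < 0 || object@intensityBg > 1)
    msg <- c(msg, "intensities must lie in [0, 1]")
  if (object@divisionProb < 0 || object@divisionProb > 1)
    msg <- c(msg, "divisionProb must lie in [0, 1]")
  if (diff(object@cellRadiusRange) < 0 || object@cellRadiusRange[1] <= 0)
    msg <- c(msg, "cellRadiusRange must be positive and ordered")
  if (length(msg)) msg else TRUE
})

#' Photometric domain-shift specification
#'
#' Parameterizes the photometric perturbation applied to frames (masks are
#' untouched): gamma remap, contrast scaling about 0.5, brightness offset,
#' optional inversion, an added illumination plane and redrawn noise.
#'
#' @slot gamma gamma exponent (1 = identity).
#' @slot contrast multiplicative contrast about mid-grey (1 = identity).
#' @slot brightness additive offset.
#' @slot invert logical; reverse foreground/background intensity order.
#' @slot illuminationGradient slope of an added illumination plane.
#' @slot noiseSigma std of re-drawn additive Gaussian noise.
#' @slot seed integer seed for the noise draw.
#' @export
setClass("ShiftSpec", representation(
  gamma = "numeric", contrast = "numeric", brightness = "numeric",
  invert = "logical", illuminationGradient = "numeric",
  noiseSigma = "numeric", seed = "integer"))

#' Synthetic cell video with instance masks and a lineage table
#'
#' Frames are grayscale matrices in [0, 1] (quantized to 16-bit depth);
#' masks are integer label matrices (0 = background, labels 1..K are cell
#' instances); the track table has one row per track:
#' (label, begin frame, end frame, parent label), frames 0-based,
#' parent 0 = no parent (Cell Tracking Challenge convention).
#'
#' @slot frames list of numeric H x W matrices.
#' @slot masks list of integer H x W matrices.
#' @slot trackTable data.frame with columns label, begin, end, parent.
#' @export
setClass("CellVideo", representation(
  frames = "list", masks = "list", trackTable = "data.frame"))

setValidity("CellVideo", function(object) {
  msg <- character()
  if (length(object@frames) != length(object@masks))
    msg <- c(msg, "frames and masks must have equal length")
  tt <- object@trackTable
  need <- c("label", "begin", "end", "parent")
  if (!all(need %in% names(tt)))
    return("trackTable needs columns label, begin, end, parent")
  for (f in seq_along(object@masks)) {
    labs <- setdiff(unique(as.vector(object@masks[[f]])), 0)
    for (L in labs) {
      rows <- tt$label == L & tt$begin <= (f - 1L) & tt$end >= (f - 1L)
      if (sum(rows) != 1L)
        msg <- c(msg, sprintf("label %d in frame %d covered by %d track rows",
                              L, f - 1L, sum(rows)))
    }
  }
  for (i in seq_len(nrow(tt))) {
    p <- tt$parent[i]
    if (p != 0) {
      pr <- tt[tt$label == p, , drop = FALSE]
      if (nrow(pr) != 1L || pr$end != tt$begin[i] - 1L)
        msg <- c(msg, sprintf("parent %d of track %d must end the frame before",
                              p, tt$label[i]))
    }
  }
  if (length(msg)) msg[seq_len(min(3, length(msg)))] else TRUE
})

#' Batch-normalized encoder-decoder segmentation network
#'
#' The segmentation unit: a compact U-Net-style encoder-decoder with batch
#' normalization after every convolution, producing a per-pixel foreground
#' probability map, with feature-pyramid taps at strides 8, 16 and 32.
#' Parameters live in a named store partitioned into BN affine parameters
#' (gamma/beta), BN running statistics, and all other weights.
#'
#' @slot graph node list of the computation graph.
#' @slot params named list of trainable parameters.
#' @slot state named list of BN running statistics.
#' @slot arch architecture description (channels, pyramid tap names).
#' @slot trainLog data.frame (epoch, loss) filled by [trainSource()].
#' @export
setClass("SegModel", representation(
  graph = "list", params = "list", state = "list", arch = "list",
  trainLog = "data.frame"))

#' Joint detection + re-identification head
#'
#' Anchor-based detection branches at strides 8/16/32 plus the
#' spatial-attention ReID branch producing an ID-embedding map at stride 8,
#' both consuming the segmentation model's feature pyramid.
#'
#' @slot seg the underlying [SegModel-class] backbone.
#' @slot graph head computation graph.
#' @slot params head parameters (includes the training-time ID classifier).
#' @slot state head BN state (empty; the head uses no BN).
#' @slot config head configuration (embedding dim, anchor sizes, flags).
#' @slot trainLog data.frame (epoch, loss components).
#' @export
setClass("JointModel", representation(
  seg = "SegModel", graph = "list", params = "list", state = "list",
  config = "list", trainLog = "data.frame"))

#' Set of tracklets produced by the online tracker
#'
#' @slot tracks list of tracklets (id, frames, boxes, embedding, status,
#'   parent).
#' @slot nFrames number of frames processed.
#' @export
setClass("TrackSet", representation(tracks = "list", nFrames = "integer"))

#' Segmentation and tracking evaluation report
#'
#' @slot segmentation per-frame data.frame with dice, iou, aji columns.
#' @slot tracking named list with mota, ct, tf, mt, ml and CLEAR counts.
#' @slot settings evaluation settings used.
#' @export
setClass("MetricsReport", representation(
  segmentation = "data.frame", tracking = "list", settings = "list"))
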