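# Joint tracking head on the CMTT feature pyramid: an anchor-based
# detection branch (one anchor per location, YOLO-style decode) trained
# with focal + CIOU losses at strides 8/16/32, and the spatial-attention
# ReID branch producing an ID-embedding map at stride 8, trained with a
# classification loss over cell identities. The backbone is frozen during
# head training; pyramids are precomputed per frame.

#' Focal loss configuration
#'
#' The printed form applies `alphaC` to positives and negatives alike;
#' `printedAlpha = FALSE` switches to the standard convention
#' (alpha for positives, 1 - alpha for negatives).
#'
#' @param alphaC balance weight (default 0.25).
#' @param gammaC focusing exponent (default 2).
#' @param printedAlpha apply alphaC to both classes (default TRUE).
#' @return Named list.
#' @export
focalConfig <- function(alphaC = 0.25, gammaC = 2, printedAlpha = TRUE) {
  list(alphaC = alphaC, gammaC = gammaC, printedAlpha = printedAlpha)
}

#' Detection / ReID loss weights
#'
#' @param betaC box-regression weight inside the detection loss
#'   (default 0.05, as in YOLO-v5).
#' @param eta ReID weight in the joint loss (default 0.05).
#' @return Named list.
#' @export
lossWeights <- function(betaC = 0.05, eta = 0.05) {
  list(betaC = betaC, eta = eta)
}

#' Assign ground-truth boxes to anchor locations
#'
#' Each box with center (x, y) marks location (floor(x/r), floor(y/r)) of
#' the stride-r map positive. Collisions (two boxes on one anchor) are
#' resolved toward the larger box area and counted.
#'
#' @param boxes data.frame with x, y, w, h (0-based center px) and
#'   optionally id.
#' @param r downsample ratio (8, 16 or 32).
#' @param gridH,gridW map size (rows, cols).
#' @return list(grid = integer gridH x gridW matrix of box indices
#'   (0 = negative), collisions = count).
#' @export
assignPositives <- function(boxes, r, gridH, gridW) {
  stopifnot(r %in% c(8L, 16L, 32L))
  grid <- matrix(0L, gridH, gridW)
  collisions <- 0L
  if (!nrow(boxes)) return(list(grid = grid, collisions = 0L))
  ax <- floor(boxes$x / r); ay <- floor(boxes$y / r)
  if (any(ax < 0 | ay < 0 | ax >= gridW | ay >= gridH))
    stop("box center outside the image")
  for (i in seq_len(nrow(boxes))) {
    rr <- ay[i] + 1L; cc <- ax[i] + 1L
    prev <- grid[rr, cc]
    if (prev == 0L) grid[rr, cc] <- i
    else {
      collisions <- collisions + 1L
      if (boxes$w[i] * boxes$h[i] > boxes$w[prev] * boxes$h[prev])
        grid[rr, cc] <- i
    }
  }
  list(grid = grid, collisions = collisions)
}

#' Focal classification loss (elementwise)
#'
#' `-alphaC * (1 - p_t)^gammaC * log(p_t)` with `p_t = p` at positive
#' anchors and `1 - p` elsewhere. Probabilities are clipped to
#' [1e-7, 1 - 1e-7].
#'
#' @param p foreground probabilities (vector).
#' @param isPositive logical vector of the same length.
#' @param cfg a [focalConfig()] list.
#' @return Vector of per-location losses.
#' @export
focalLoss <- function(p, isPositive, cfg = focalConfig()) {
  p <- pmin(pmax(p, 1e-7), 1 - 1e-7)
  pt <- ifelse(isPositive, p, 1 - p)
  alpha <- if (cfg$printedAlpha) cfg$alphaC
           else ifelse(isPositive, cfg$alphaC, 1 - cfg$alphaC)
  -alpha * (1 - pt)^cfg$gammaC * log(pt)
}

# CIOU of box rows (x, y, w, h): IoU - center-distance/diagonal penalty -
# aspect-ratio consistency term
ciou <- function(pred, gt) {
  pred <- matrix(pred, ncol = 4); gt <- matrix(gt, ncol = 4)
  px1 <- pred[, 1] - pred[, 3] / 2; px2 <- pred[, 1] + pred[, 3] / 2
  py1 <- pred[, 2] - pred[, 4] / 2; py2 <- pred[, 2] + pred[, 4] / 2
  gx1 <- gt[, 1] - gt[, 3] / 2; gx2 <- gt[, 1] + gt[, 3] / 2
  gy1 <- gt[, 2] - gt[, 4] / 2; gy2 <- gt[, 2] + gt[, 4] / 2
  iw <- pmax(0, pmin(px2, gx2) - pmax(px1, gx1))
  ih <- pmax(0, pmin(py2, gy2) - pmax(py1, gy1))
  inter <- iw * ih
  un <- pred[, 3] * pred[, 4] + gt[, 3] * gt[, 4] - inter
  iouV <- inter / pmax(un, 1e-12)
  rho2 <- (pred[, 1] - gt[, 1])^2 + (pred[, 2] - gt[, 2])^2
  cw <- pmax(px2, gx2) - pmin(px1, gx1)
  chh <- pmax(py2, gy2) - pmin(py1, gy1)
  c2 <- cw^2 + chh^2
  v <- (4 / pi^2) * (atan(gt[, 3] / gt[, 4]) - atan(pred[, 3] / pred[, 4]))^2
  alpha <- v / pmax(1 - iouV + v, 1e-12)
  iouV - rho2 / pmax(c2, 1e-12) - alpha * v
}

#' CIOU box-regression loss
#'
#' `1 - CIOU(gt, pred)` at positive anchors; 0 elsewhere by definition.
#'
#' @param predBox,gtBox numeric length-4 vectors or n x 4 matrices in
#'   (x, y, w, h) center format.
#' @param positive logical (vector); non-positive locations contribute 0.
#' @return Vector of losses.
#' @export
ciouLoss <- function(predBox, gtBox, positive = TRUE) {
  predBox <- matrix(predBox, ncol = 4)
  if (any(positive & (predBox[, 3] <= 0 | predBox[, 4] <= 0)))
    stop("degenerate predicted box (zero area)")
  ifelse(positive, 1 - ciou(predBox, gtBox), 0)
}

#' Combined detection loss
#'
#' `(1/N_pos) * sum over resolutions and locations of
#' (L_cls + betaC * L_reg)`.
#'
#' @param clsTerms,regTerms numeric vectors (concatenated over resolutions
#'   and locations; reg terms are 0 at negatives).
#' @param nPos number of positive samples (>= 1; an image with none is
#'   skipped upstream).
#' @param weights a [lossWeights()] list.
#' @return Scalar loss.
#' @export
detectionLoss <- function(clsTerms, regTerms, nPos,
                          weights = lossWeights()) {
  if (nPos < 1) stop("nPos must be >= 1 (skip images without positives)")
  (sum(clsTerms) + weights$betaC * sum(regTerms)) / nPos
}

#' ReID classification loss
#'
#' A linear classifier maps ID embeddings to a C-class distribution; the
#' printed form is `(1/N) * sum_i sum_c Y_i(c) log p_i(c)` (no leading
#' minus). Both it and the conventional negative cross-entropy used for
#' optimization are returned.
#'
#' @param emb N x D matrix of embeddings at positive anchors.
#' @param labels integer identity labels in 1..C.
#' @param W,b classifier weights (D x C) and bias (length C).
#' @return list(printed, negative, probs).
#' @export
reidLoss <- function(emb, labels, W, b) {
  C <- ncol(W)
  if (any(labels < 1 | labels > C)) stop("identity label outside 1..C")
  logits <- emb %*% W + matrix(b, nrow(emb), C, byrow = TRUE)
  logits <- logits - apply(logits, 1, max)
  P <- exp(logits) / rowSums(exp(logits))
  printed <- mean(log(pmax(P[cbind(seq_len(nrow(emb)), labels)], 1e-12)))
  list(printed = printed, negative = -printed, probs = P)
}

#' Joint loss
#'
#' `L_det + eta * L_id`.
#'
#' @param det detection loss value.
#' @param id ReID loss value (conventional negative form).
#' @param eta ReID weight (default 0.05).
#' @return Scalar.
#' @export
totalLoss <- function(det, id, eta = 0.05) {
  stopifnot(eta >= 0)
  det + eta * id
}

#' Non-maximum suppression
#'
#' Greedy suppression by descending score; survivors have pairwise
#' IoU <= threshold.
#'
#' @param boxes data.frame with x, y, w, h, score.
#' @param iouThreshold suppression threshold (default 0.5).
#' @return The surviving subset of `boxes` (original order of survivors by
#'   descending score).
#' @export
nms <- function(boxes, iouThreshold = 0.5) {
  if (!nrow(boxes)) return(boxes)
  ord <- order(-boxes$score)
  keep <- integer()
  for (i in ord) {
    if (length(keep)) {
      io <- boxIou(boxes[i, , drop = FALSE], boxes[keep, , drop = FALSE])
      if (any(io > iouThreshold)) next
    }
    keep <- c(keep, i)
  }
  boxes[keep, , drop = FALSE]
}

#' Score-weighted box fusion
#'
#' Greedy grouping by descending score (like [nms()]), but each surviving
#' detection is replaced by the score-weighted average of its suppressed
#' group, which merges the near-duplicate boxes the three detection
#' scales emit for one cell.
#'
#' @inheritParams nms
#' @return data.frame of fused boxes.
#' @export
fuseBoxes <- function(boxes, iouThreshold = 0.5) {
  if (!nrow(boxes)) return(boxes)
  ord <- order(-boxes$score)
  taken <- rep(FALSE, nrow(boxes))
  out <- list()
  for (i in ord) {
    if (taken[i]) next
    io <- boxIou(boxes[i, , drop = FALSE], boxes)
    grp <- which(!taken & as.vector(io) > iouThreshold)
    grp <- union(i, grp)
    taken[grp] <- TRUE
    w <- boxes$score[grp]
    out[[length(out) + 1L]] <- data.frame(
      x = sum(boxes$x[grp] * w) / sum(w),
      y = sum(boxes$y[grp] * w) / sum(w),
      w = sum(boxes$w[grp] * w) / sum(w),
      h = sum(boxes$h[grp] * w) / sum(w),
      score = max(w))
  }
  do.call(rbind, out)
}

# ---- head network ----------------------------------------------------------

headGraph <- function(tapChannels, encC = 16L, embedDim = 128L,
                      useSAM = TRUE) {
  g <- list(nnNode("p8", "input"), nnNode("p16", "input"),
            nnNode("p32", "input"))
  scales <- c("8", "16", "32")
  for (i in 1:3) {
    s <- scales[i]
    g <- c(g, list(
      nnNode(paste0("det", s, ".c1"), "conv", paste0("p", s), k = 1L,
             s = 1L, pad = 0L, cin = tapChannels[i], cout = 32L),
      nnNode(paste0("det", s, ".r1"), "relu", paste0("det", s, ".c1")),
      nnNode(paste0("det", s, ".out"), "conv", paste0("det", s, ".r1"),
             k = 1L, s = 1L, pad = 0L, cin = 32L, cout = 5L)))
  }
  # ReID branch: upsample 1/16 and 1/32 to 1/8, encode, attend, fuse
  for (i in 1:3) {
    s <- scales[i]
    src <- if (i == 1) "p8" else paste0("re", s, ".up")
    if (i > 1)
      g <- c(g, list(nnNode(paste0("re", s, ".up"), "resize",
                            c(paste0("p", s), "p8"))))
    g <- c(g, list(
      nnNode(paste0("re", s, ".enc"), "conv", src, k = 3L, s = 1L,
             pad = 1L, cin = tapChannels[i], cout = encC)))
    if (useSAM) {
      g <- c(g, list(
        nnNode(paste0("re", s, ".cp"), "chanpool", paste0("re", s, ".enc")),
        nnNode(paste0("re", s, ".att"), "conv", paste0("re", s, ".cp"),
               k = 7L, s = 1L, pad = 3L, cin = 2L, cout = 1L),
        nnNode(paste0("re", s, ".sig"), "sigmoid", paste0("re", s, ".att")),
        nnNode(paste0("re", s, ".mul"), "mul",
               c(paste0("re", s, ".enc"), paste0("re", s, ".sig"))),
        nnNode(paste0("re", s, ".fuse"), "add",
               c(paste0("re", s, ".enc"), paste0("re", s, ".mul")))))
    } else {
      # ablation: plain stacked convolutions instead of the SAM
      g <- c(g, list(
        nnNode(paste0("re", s, ".sc"), "conv", paste0("re", s, ".enc"),
               k = 3L, s = 1L, pad = 1L, cin = encC, cout = encC),
        nnNode(paste0("re", s, ".fuse"), "relu", paste0("re", s, ".sc"))))
    }
  }
  g <- c(g, list(
    nnNode("re.cat", "concat", paste0("re", scales, ".fuse")),
    nnNode("emb", "conv", "re.cat", k = 3L, s = 1L, pad = 1L,
           cin = 3L * encC, cout = embedDim)))
  g
}

#' Create a joint detection + ReID head on a segmentation backbone
#'
#' @param seg a trained [SegModel-class] (frozen backbone).
#' @param nIds number of cell identities C in the training set.
#' @param embedDim ID-embedding dimension (default 128).
#' @param encC per-scale encoder channels in the ReID branch.
#' @param useSAM use the spatial attention module (FALSE = stacked-conv
#'   ablation).
#' @param anchorScale base box size at stride r is `anchorScale * r`.
#' @param seed weight-init seed.
#' @return A [JointModel-class].
#' @export
jointModel <- function(seg, nIds, embedDim = 128L, encC = 16L,
                       useSAM = TRUE, anchorScale = 2, seed = 1L) {
  tc <- seg@arch$tapChannels
  g <- headGraph(tc, encC, embedDim, useSAM)
  ini <- withSeed(seed, {
    x <- graphInitParams(g)
    x$params[["id.W"]] <- matrix(stats::rnorm(embedDim * nIds,
                                              sd = sqrt(1 / embedDim)),
                                 embedDim, nIds)
    x$params[["id.b"]] <- numeric(nIds)
    x
  })
  methods::new("JointModel", seg = seg, graph = g, params = ini$params,
               state = ini$state,
               config = list(embedDim = as.integer(embedDim),
                             encC = as.integer(encC), useSAM = useSAM,
                             nIds = as.integer(nIds),
                             anchorScale = anchorScale),
               trainLog = data.frame())
}

arrayToTensor <- function(a) {
  d <- dim(a)
  x <- matrix(aperm(a, c(2, 1, 3)), d[1] * d[2], d[3])
  nnTensor(x, 1L, d[1], d[2])
}

pyramidTensors <- function(seg, image) {
  py <- extractPyramid(seg, image)
  list(p8 = arrayToTensor(py$p8), p16 = arrayToTensor(py$p16),
       p32 = arrayToTensor(py$p32))
}

#' Spatial attention map of a feature map
#'
#' Channel-wise mean and max maps, concatenated, convolved 7x7 and passed
#' through a sigmoid: one attention value in (0, 1) per location.
#'
#' @param feature H x W x C array.
#' @param W,b 7x7 conv parameters ((49*2) x 1 matrix and length-1 bias);
#'   randomly initialized from `seed` when omitted.
#' @param seed init seed used when `W` is missing.
#' @return H x W matrix in (0, 1).
#' @export
spatialAttention <- function(feature, W = NULL, b = 0, seed = 1L) {
  t <- arrayToTensor(feature)
  if (is.null(W)) W <- withSeed(seed, convInit(7L, 2L, 1L))
  cp <- chanPoolForward(t$x)
  ct <- nnTensor(cp$y, 1L, t$H, t$W)
  conv <- convForward(ct, W, b, 7L, 1L, 3L)
  matrix(sigmoidStable(conv$x), t$H, t$W, byrow = TRUE)
}

#' ReID embedding map of a feature pyramid
#'
#' Runs the SA-ReID branch: upsample to stride 8, encode, spatial
#' attention, `f + f * attention` fusion, concatenation across scales,
#' final 3x3 conv to the embedding dimension.
#'
#' @param model a [JointModel-class].
#' @param pyramid list with p8, p16, p32 arrays from [extractPyramid()].
#' @return H/8 x W/8 x D embedding array.
#' @export
saReidForward <- function(model, pyramid) {
  if (!all(c("p8", "p16", "p32") %in% names(pyramid)))
    stop("pyramid must provide p8, p16 and p32")
  ins <- list(p8 = arrayToTensor(pyramid$p8),
              p16 = arrayToTensor(pyramid$p16),
              p32 = arrayToTensor(pyramid$p32))
  fwd <- graphForward(model@graph, model@params, model@state, ins)
  tensorToArray(fwd$vals$emb)
}

# decode raw 5-channel map (tensor rows, row-major) at stride r into boxes
decodeDetections <- function(raw, r, anchorScale) {
  H <- raw$H; W <- raw$W
  gr <- rep(0:(H - 1L), each = W); gc <- rep(0:(W - 1L), H)
  tx <- raw$x[, 1]; ty <- raw$x[, 2]
  tw <- pmin(pmax(raw$x[, 3], -4), 4); th <- pmin(pmax(raw$x[, 4], -4), 4)
  data.frame(
    x = (gc + sigmoidStable(tx)) * r,
    y = (gr + sigmoidStable(ty)) * r,
    w = exp(tw) * r * anchorScale,
    h = exp(th) * r * anchorScale,
    score = sigmoidStable(raw$x[, 5]))
}

# gradient helper: d(box)/d(raw t); used inside head training
rawFromBoxGrad <- function(raw, r, anchorScale, dBox) {
  tx <- raw$x[, 1]; ty <- raw$x[, 2]
  tw <- pmin(pmax(raw$x[, 3], -4), 4); th <- pmin(pmax(raw$x[, 4], -4), 4)
  sx <- sigmoidStable(tx); sy <- sigmoidStable(ty)
  cbind(dBox[, 1] * r * sx * (1 - sx),
        dBox[, 2] * r * sy * (1 - sy),
        dBox[, 3] * exp(tw) * r * anchorScale,
        dBox[, 4] * exp(th) * r * anchorScale)
}

# reconcile detections with the pre-segmentation mask: a detection whose
# center lies on predicted background is dropped (the mask is the
# framework's recall-dominant cue, and such boxes are almost always the
# coarse-stride branch firing between cells); others snap to the bounding
# box of their component unless it is oversized (> 3x median area, likely
# merged cells). Detections landing on one component are duplicates of a
# single cell: only the highest-scoring one is kept.
refineBoxesWithMask <- function(boxes, binMask) {
  lab <- labelInstances(binMask)
  comp <- boxesFromMask(lab)
  if (!nrow(comp)) return(boxes)
  medArea <- stats::median(comp$area)
  H <- nrow(lab); W <- ncol(lab)
  compOf <- integer(nrow(boxes))
  keep <- rep(TRUE, nrow(boxes))
  for (i in seq_len(nrow(boxes))) {
    rr <- pmin(pmax(round(boxes$y[i]) + 1L, 1L), H)
    cc <- pmin(pmax(round(boxes$x[i]) + 1L, 1L), W)
    L <- lab[rr, cc]
    if (L == 0L) { keep[i] <- FALSE; next }
    cb <- comp[comp$label == L, ]
    if (cb$area > 3 * medArea) next
    compOf[i] <- L
    boxes$x[i] <- cb$x; boxes$y[i] <- cb$y
    boxes$w[i] <- cb$w; boxes$h[i] <- cb$h
  }
  for (L in unique(compOf[compOf > 0L])) {
    grp <- which(compOf == L)
    if (length(grp) > 1L)
      keep[grp[-which.max(boxes$score[grp])]] <- FALSE
  }
  boxes[keep, , drop = FALSE]
}

#' Detect cells in one frame
#'
#' Runs the frozen backbone pyramid, the detection branches at all three
#' strides, decodes boxes, filters by score, applies [nms()] and attaches
#' the ReID embedding at each surviving box's stride-8 anchor.
#'
#' @param model a trained [JointModel-class].
#' @param image H x W matrix in [0, 1].
#' @param scoreThreshold minimum foreground probability (default 0.3).
#' @param nmsThreshold NMS IoU threshold (default 0.5).
#' @param fusion use score-weighted fusion of suppressed boxes
#'   ([fuseBoxes()]); the three scales predict near-duplicate boxes per
#'   cell and averaging them localizes better than keeping one.
#' @param maskRefine snap each surviving box to the bounding box of the
#'   segmentation component under its center (the pre-segmentation mask
#'   is the framework's sharpest localization cue); components larger
#'   than `3 x` the median are left alone (likely merged cells).
#' @return list(boxes = data.frame(x, y, w, h, score), emb = n x D
#'   matrix).
#' @export
detectFrame <- function(model, image, scoreThreshold = 0.3,
                        nmsThreshold = 0.5, fusion = TRUE,
                        maskRefine = TRUE) {
  py <- extractPyramid(model@seg, image)
  ins <- list(p8 = arrayToTensor(py$p8), p16 = arrayToTensor(py$p16),
              p32 = arrayToTensor(py$p32))
  fwd <- graphForward(model@graph, model@params, model@state, ins)
  dets <- do.call(rbind, lapply(c(8L, 16L, 32L), function(r) {
    decodeDetections(fwd$vals[[paste0("det", r, ".out")]], r,
                     model@config$anchorScale)
  }))
  dets <- dets[dets$score >= scoreThreshold, , drop = FALSE]
  dets <- if (fusion) fuseBoxes(dets, nmsThreshold)
          else nms(dets, nmsThreshold)
  if (maskRefine && nrow(dets)) {
    dets <- refineBoxesWithMask(dets, binarizeProb(py$prob))
    dets <- nms(dets, max(nmsThreshold, 0.5))  # dedupe snapped boxes
  }
  embT <- fwd$vals$emb
  if (nrow(dets)) {
    rr <- pmin(pmax(floor(dets$y / 8), 0), embT$H - 1L)
    cc <- pmin(pmax(floor(dets$x / 8), 0), embT$W - 1L)
    emb <- embT$x[rr * embT$W + cc + 1L, , drop = FALSE]
  } else emb <- matrix(0, 0, model@config$embedDim)
  list(boxes = dets, emb = emb)
}

#' Train the joint detection + ReID head
#'
#' Supervised training on frames with ground-truth boxes and identity
#' labels. The backbone stays frozen (pyramids are precomputed once) and
#' all frames form one batch per step; the head and the training-time ID
#' classifier are optimized with Adam on `L_det + eta * L_id`. The CIOU
#' gradient with respect to the decoded box is evaluated by central
#' finite differences.
#'
#' @param model a [JointModel-class].
#' @param images list of frames.
#' @param gtBoxes list of data.frames (x, y, w, h, id) per frame; ids in
#'   1..nIds.
#' @param epochs,learningRate,seed optimization settings.
#' @param focal a [focalConfig()] list.
#' @param weights a [lossWeights()] list.
#' @param verbose print per-epoch losses.
#' @return The trained [JointModel-class] (trainLog filled).
#' @export
trainJointHead <- function(model, images, gtBoxes, epochs = 60L,
                           learningRate = 5e-3, seed = 1L,
                           focal = focalConfig(), weights = lossWeights(),
                           verbose = FALSE) {
  stopifnot(length(images) == length(gtBoxes), epochs >= 1)
  nF <- length(images)
  pyr <- lapply(images, function(im) pyramidTensors(model@seg, im))
  stack <- function(key) {
    ts <- lapply(pyr, `[[`, key)
    nnTensor(do.call(rbind, lapply(ts, `[[`, "x")), nF, ts[[1]]$H,
             ts[[1]]$W)
  }
  ins <- list(p8 = stack("p8"), p16 = stack("p16"), p32 = stack("p32"))
  anchorScale <- model@config$anchorScale
  C <- model@config$nIds
  # static positive-anchor layout per scale (batched row indices)
  layout <- lapply(c(8L, 16L, 32L), function(r) {
    H <- ins[[paste0("p", r)]]$H; W <- ins[[paste0("p", r)]]$W
    posRows <- integer(); gtMat <- NULL
    isPos <- logical(nF * H * W)
    for (f in seq_len(nF)) {
      asg <- assignPositives(gtBoxes[[f]], r, H, W)
      pg <- as.vector(t(asg$grid))  # row-major like tensor rows
      pos <- which(pg > 0L)
      if (length(pos)) {
        posRows <- c(posRows, (f - 1L) * H * W + pos)
        gtMat <- rbind(gtMat, as.matrix(
          gtBoxes[[f]][pg[pos], c("x", "y", "w", "h")]))
        isPos[(f - 1L) * H * W + pos] <- TRUE
      }
    }
    list(r = r, posRows = posRows, gt = gtMat, isPos = isPos)
  })
  nPos <- sum(vapply(layout, function(l) length(l$posRows), 1L))
  if (nPos == 0L) stop("no positive anchors in the training set")
  # ReID lookup at stride-8 anchors
  H8 <- ins$p8$H; W8 <- ins$p8$W
  reidRows <- integer(); reidLab <- integer()
  for (f in seq_len(nF)) {
    asg <- assignPositives(gtBoxes[[f]], 8L, H8, W8)
    pg <- as.vector(t(asg$grid))
    pos <- which(pg > 0L)
    reidRows <- c(reidRows, (f - 1L) * H8 * W8 + pos)
    reidLab <- c(reidLab, gtBoxes[[f]]$id[pg[pos]])
  }
  params <- model@params
  opt <- adamInit(params)
  log <- data.frame(epoch = integer(), det = numeric(), id = numeric(),
                    total = numeric())
  withSeed(seed, {
    for (ep in seq_len(epochs)) {
      fwd <- graphForward(model@graph, params, model@state, ins)
      dOut <- list()
      clsSum <- 0; regSum <- 0
      for (l in layout) {
        raw <- fwd$vals[[paste0("det", l$r, ".out")]]
        p <- sigmoidStable(raw$x[, 5])
        clsSum <- clsSum + sum(focalLoss(p, l$isPos, focal))
        pc <- pmin(pmax(p, 1e-7), 1 - 1e-7)
        a <- if (focal$printedAlpha) focal$alphaC else
          ifelse(l$isPos, focal$alphaC, 1 - focal$alphaC)
        gma <- focal$gammaC
        dp <- ifelse(l$isPos,
          -a * (-gma * (1 - pc)^(gma - 1) * log(pc) + (1 - pc)^gma / pc),
          -a * (gma * pc^(gma - 1) * log(1 - pc) - pc^gma / (1 - pc)))
        dRaw <- matrix(0, nrow(raw$x), 5)
        dRaw[, 5] <- dp * p * (1 - p)
        if (length(l$posRows)) {
          dec <- decodeDetections(raw, l$r, anchorScale)
          pb <- as.matrix(dec[l$posRows, c("x", "y", "w", "h")])
          # undo the per-image row offset the decoder ignores: grid coords
          # repeat every H*W rows, so decoded centers are already correct
          gb <- l$gt
          regSum <- regSum + sum(1 - ciou(pb, gb))
          hstep <- 1e-4
          dBox <- matrix(0, length(l$posRows), 4)
          for (j in 1:4) {
            bp <- pb; bp[, j] <- bp[, j] + hstep
            bm <- pb; bm[, j] <- bm[, j] - hstep
            dBox[, j] <- ((1 - ciou(bp, gb)) - (1 - ciou(bm, gb))) /
              (2 * hstep)
          }
          dRawBox <- rawFromBoxGrad(
            list(x = raw$x[l$posRows, , drop = FALSE]), l$r, anchorScale,
            dBox)
          dRaw[l$posRows, 1:4] <- weights$betaC * dRawBox
        }
        dOut[[paste0("det", l$r, ".out")]] <- dRaw / nPos
      }
      detL <- detectionLoss(clsSum, regSum, nPos, weights)
      idL <- 0; dW <- NULL; db <- NULL
      if (length(reidRows) && C > 1) {
        embT <- fwd$vals$emb
        E <- embT$x[reidRows, , drop = FALSE]
        rl <- reidLoss(E, reidLab, params$id.W, params$id.b)
        idL <- rl$negative
        N <- length(reidRows)
        dLogit <- rl$probs
        dLogit[cbind(seq_len(N), reidLab)] <-
          dLogit[cbind(seq_len(N), reidLab)] - 1
        dLogit <- dLogit / N
        dW <- crossprod(E, dLogit) * weights$eta
        db <- colSums(dLogit) * weights$eta
        dEmb <- matrix(0, nrow(embT$x), ncol(embT$x))
        dEmb[reidRows, ] <- dLogit %*% t(params$id.W) * weights$eta
        dOut[["emb"]] <- dEmb
      }
      bk <- graphBackward(model@graph, params, fwd, dOut)
      grads <- bk$dparams
      if (!is.null(dW)) { grads[["id.W"]] <- dW; grads[["id.b"]] <- db }
      st <- adamStep(params, grads, opt, learningRate,
                     which = names(grads))
      params <- st$params; opt <- st$state
      tl <- totalLoss(detL, idL, weights$eta)
      log <- rbind(log, data.frame(epoch = ep, det = detL, id = idL,
                                   total = tl))
      if (verbose)
        message(sprintf("epoch %d det %.4f id %.4f total %.4f", ep, detL,
                        idL, tl))
    }
  })
  methods::initialize(model, params = params,
                      trainLog = rbind(model@trainLog, log))
}
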