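# Evaluation metrics: pixel-level Dice / IOU, object-level AJI, the
# CLEAR-MOT tracking measures (MOTA with FN/FP/identity switches under
# persistent IoU matching), the lineage-oriented CT / TF measures, MT / ML,
# and the cell-imaging-density statistic.

#' Dice coefficient of two binary masks
#'
#' `2|G intersect S| / (|S| + |G|)`; both masks empty gives 1 by
#' convention.
#'
#' @param G,S binary (logical or 0/1) matrices of equal shape.
#' @return Scalar in [0, 1].
#' @export
dice <- function(G, S) {
  if (!identical(dim(G), dim(S))) stop("shape mismatch")
  g <- G > 0; s <- S > 0
  denom <- sum(g) + sum(s)
  if (denom == 0) return(1)
  2 * sum(g & s) / denom
}

#' Intersection-over-union (Jaccard) of two binary masks
#'
#' `|G intersect S| / |G union S|`; both masks empty gives 1 by convention.
#'
#' @inheritParams dice
#' @return Scalar in [0, 1].
#' @export
iou <- function(G, S) {
  if (!identical(dim(G), dim(S))) stop("shape mismatch")
  g <- G > 0; s <- S > 0
  u <- sum(g | s)
  if (u == 0) return(1)
  sum(g & s) / u
}

#' Aggregated Jaccard index (AJI) of two instance masks
#'
#' For each ground-truth object G_i, S_i is the predicted object
#' maximizing the Jaccard index with G_i (ties broken toward the lower
#' prediction label); the score is
#' `sum |G_i ∩ S_i| / (sum |G_i ∪ S_i| + sum_{r in R} |S_r|)` where R is
#' the set of predicted objects never selected as any S_i. More stringent
#' than IOU: under-, over- and mis-segmentation all lower it.
#'
#' @param G,S integer instance masks (0 = background).
#' @return Scalar in [0, 1].
#' @export
aji <- function(G, S) {
  if (!identical(dim(G), dim(S))) stop("shape mismatch")
  gl <- setdiff(sort(unique(as.vector(G))), 0)
  if (!length(gl)) stop("no ground-truth objects")
  sl <- setdiff(sort(unique(as.vector(S))), 0)
  num <- 0; den <- 0
  used <- integer()
  for (g in gl) {
    gp <- G == g
    bestJ <- -1; bestS <- NA; bestI <- 0; bestU <- sum(gp)
    for (s in sl) {
      sp <- S == s
      i <- sum(gp & sp)
      if (i == 0) next
      u <- sum(gp | sp)
      j <- i / u
      if (j > bestJ + 1e-12) { bestJ <- j; bestS <- s; bestI <- i; bestU <- u }
    }
    num <- num + bestI
    den <- den + bestU
    if (!is.na(bestS)) used <- union(used, bestS)
  }
  for (s in setdiff(sl, used)) den <- den + sum(S == s)
  num / den
}

#' Instance labels of a binary mask
#'
#' Turns a binarized probability map into instance labels. "connected"
#' labels 8-connected components; "watershed" additionally splits touching
#' cells by a watershed on the distance transform (the standard recipe for
#' dense nuclei and what the instance-level evaluation uses).
#'
#' @param mask binary matrix (e.g. a binarized probability map).
#' @param method "connected" (default) or "watershed".
#' @param tolerance,ext watershed parameters (see [EBImage::watershed()]).
#' @return Integer label matrix (0 = background).
#' @export
labelInstances <- function(mask, method = c("connected", "watershed"),
                           tolerance = 1, ext = 1) {
  method <- match.arg(method)
  bin <- (mask > 0) + 0
  lab <- if (method == "connected") EBImage::bwlabel(bin)
         else EBImage::watershed(EBImage::distmap(bin), tolerance, ext)
  storage.mode(lab) <- "integer"
  lab
}

#' Axis-aligned bounding boxes of mask instances
#'
#' Boxes use (center x, center y, w, h) in 0-based pixel coordinates
#' (x = column, y = row).
#'
#' @param mask integer instance mask.
#' @return data.frame with columns label, x, y, w, h, area.
#' @export
boxesFromMask <- function(mask) {
  labs <- setdiff(sort(unique(as.vector(mask))), 0)
  out <- lapply(labs, function(L) {
    w <- which(mask == L, arr.ind = TRUE)
    r0 <- min(w[, 1]) - 1L; r1 <- max(w[, 1]) - 1L
    c0 <- min(w[, 2]) - 1L; c1 <- max(w[, 2]) - 1L
    data.frame(label = L, x = (c0 + c1) / 2, y = (r0 + r1) / 2,
               w = c1 - c0 + 1, h = r1 - r0 + 1, area = nrow(w))
  })
  if (!length(out))
    return(data.frame(label = integer(), x = numeric(), y = numeric(),
                      w = numeric(), h = numeric(), area = numeric()))
  do.call(rbind, out)
}

#' IoU of two box sets
#'
#' @param a,b data.frames with x, y, w, h columns (center format).
#' @return matrix of pairwise IoUs, nrow(a) x nrow(b).
#' @export
boxIou <- function(a, b) {
  if (!nrow(a) || !nrow(b)) return(matrix(0, nrow(a), nrow(b)))
  ax1 <- a$x - a$w / 2; ax2 <- a$x + a$w / 2
  ay1 <- a$y - a$h / 2; ay2 <- a$y + a$h / 2
  bx1 <- b$x - b$w / 2; bx2 <- b$x + b$w / 2
  by1 <- b$y - b$h / 2; by2 <- b$y + b$h / 2
  iw <- pmax(0, outer(ax2, bx2, pmin) - outer(ax1, bx1, pmax))
  ih <- pmax(0, outer(ay2, by2, pmin) - outer(ay1, by1, pmax))
  inter <- iw * ih
  u <- outer(a$w * a$h, b$w * b$h, "+") - inter
  inter / pmax(u, 1e-12)
}

# CLEAR-MOT frame-by-frame persistent matching of two track tables
# (data.frames with frame, id, x, y, w, h)
#' Match predicted against reference tracks (CLEAR protocol)
#'
#' Frame-by-frame one-to-one matching at `iouThreshold`, preferring the
#' previous frame's correspondence (persistent matching) and otherwise
#' solving an optimal assignment on IoU. Returns the global counts used by
#' [motaScore()] and the per-frame correspondences used by the lineage
#' measures.
#'
#' @param pred,ref data.frames with columns frame (0-based), id, x, y, w, h.
#' @param iouThreshold minimum IoU for a valid correspondence (default 0.5).
#' @return list with counts fn, fp, idsw, gt and `matches`
#'   (data.frame frame, refId, predId).
#' @export
trackMatch <- function(pred, ref, iouThreshold = 0.5) {
  frames <- sort(unique(c(pred$frame, ref$frame)))
  lastMatch <- integer()  # names: refId, value: predId
  fn <- 0L; fp <- 0L; idsw <- 0L; gt <- 0L
  matches <- data.frame(frame = integer(), refId = integer(),
                        predId = integer())
  for (f in frames) {
    gfr <- ref[ref$frame == f, , drop = FALSE]
    pfr <- pred[pred$frame == f, , drop = FALSE]
    gt <- gt + nrow(gfr)
    if (!nrow(gfr)) { fp <- fp + nrow(pfr); next }
    iouM <- boxIou(gfr, pfr)
    gMatched <- rep(NA_integer_, nrow(gfr))
    pUsed <- rep(FALSE, max(nrow(pfr), 0L))
    # persistent matches first
    for (gi in seq_len(nrow(gfr))) {
      prev <- lastMatch[as.character(gfr$id[gi])]
      if (length(prev) && !is.na(prev)) {
        pi <- which(pfr$id == prev)
        if (length(pi) == 1L && !pUsed[pi] &&
            iouM[gi, pi] >= iouThreshold) {
          gMatched[gi] <- pi; pUsed[pi] <- TRUE
        }
      }
    }
    # optimal assignment for the rest
    gRem <- which(is.na(gMatched)); pRem <- which(!pUsed)
    if (length(gRem) && length(pRem)) {
      cost <- 1 - iouM[gRem, pRem, drop = FALSE]
      cost[cost > 1 - iouThreshold] <- 1e6
      asg <- hungarian(cost)
      for (k in seq_along(asg)) {
        if (asg[k] > 0 && cost[k, asg[k]] < 1e6) {
          gMatched[gRem[k]] <- pRem[asg[k]]
          pUsed[pRem[asg[k]]] <- TRUE
        }
      }
    }
    for (gi in seq_len(nrow(gfr))) {
      rid <- as.character(gfr$id[gi])
      if (is.na(gMatched[gi])) { fn <- fn + 1L; next }
      pid <- pfr$id[gMatched[gi]]
      prev <- lastMatch[rid]
      if (length(prev) && !is.na(prev) && prev != pid) idsw <- idsw + 1L
      lastMatch[rid] <- pid
      matches <- rbind(matches, data.frame(frame = f, refId = gfr$id[gi],
                                           predId = pid))
    }
    fp <- fp + sum(!pUsed)
  }
  list(fn = fn, fp = fp, idsw = idsw, gt = gt, matches = matches)
}

#' Multiple object tracking accuracy
#'
#' `MOTA = 1 - (FN + FP + IDSW) / GT` over the whole sequence; can be
#' negative.
#'
#' @param match a [trackMatch()] result (or any list with fn, fp, idsw,
#'   gt).
#' @return Scalar.
#' @examples
#' motaScore(list(fn = 2, fp = 1, idsw = 1, gt = 20))  # 0.8
#' @export
motaScore <- function(match) {
  if (match$gt == 0) stop("no ground-truth objects")
  1 - (match$fn + match$fp + match$idsw) / match$gt
}

refSpans <- function(ref) {
  ids <- sort(unique(ref$id))
  lapply(stats::setNames(ids, ids), function(i) sort(ref$frame[ref$id == i]))
}

#' Complete tracks (CT)
#'
#' Fraction of reference tracks fully reconstructed: matched in every
#' frame of their span by one single predicted track.
#'
#' @inheritParams trackMatch
#' @param match optional precomputed [trackMatch()] result.
#' @return Scalar in [0, 1].
#' @export
completeTracks <- function(pred, ref, iouThreshold = 0.5, match = NULL) {
  if (is.null(match)) match <- trackMatch(pred, ref, iouThreshold)
  spans <- refSpans(ref)
  if (!length(spans)) stop("no reference tracks")
  ok <- vapply(names(spans), function(i) {
    m <- match$matches[match$matches$refId == as.integer(i), , drop = FALSE]
    nrow(m) == length(spans[[i]]) && length(unique(m$predId)) == 1L
  }, logical(1))
  mean(ok)
}

longestConstantRun <- function(frames, ids, span) {
  # longest run of consecutive span frames matched by one constant pred id
  best <- 0L
  run <- 0L; prevF <- NA_integer_; prevId <- NA_integer_
  for (f in span) {
    k <- which(frames == f)
    if (!length(k)) { run <- 0L; prevId <- NA_integer_; next }
    id <- ids[k]
    run <- if (!is.na(prevId) && id == prevId) run + 1L else 1L
    best <- max(best, run)
    prevId <- id
  }
  best
}

#' Track fraction (TF)
#'
#' For every reference track that is detected at all, the length of the
#' longest continuously matching predicted tracklet divided by the
#' reference track length; averaged. `NA` if no reference track is
#' detected.
#'
#' @inheritParams completeTracks
#' @return Scalar in [0, 1], or `NA`.
#' @export
trackFraction <- function(pred, ref, iouThreshold = 0.5, match = NULL) {
  if (is.null(match)) match <- trackMatch(pred, ref, iouThreshold)
  spans <- refSpans(ref)
  fr <- vapply(names(spans), function(i) {
    m <- match$matches[match$matches$refId == as.integer(i), , drop = FALSE]
    if (!nrow(m)) return(NA_real_)
    longestConstantRun(m$frame, m$predId, spans[[i]]) / length(spans[[i]])
  }, numeric(1))
  if (all(is.na(fr))) return(NA_real_)
  mean(fr, na.rm = TRUE)
}

#' Mostly tracked / mostly lost percentages
#'
#' MT: percentage of reference tracks matched in at least 80% of their
#' frames; ML: matched in under 20%.
#'
#' @inheritParams completeTracks
#' @return Named numeric c(mt, ml), in percent.
#' @export
mtMl <- function(pred, ref, iouThreshold = 0.5, match = NULL) {
  if (is.null(match)) match <- trackMatch(pred, ref, iouThreshold)
  spans <- refSpans(ref)
  frac <- vapply(names(spans), function(i) {
    m <- match$matches[match$matches$refId == as.integer(i), , drop = FALSE]
    nrow(m) / length(spans[[i]])
  }, numeric(1))
  c(mt = 100 * mean(frac >= 0.8), ml = 100 * mean(frac < 0.2))
}

#' Cell imaging density of an instance mask
#'
#' Reports both conventions of the effective-area/cell-count statistic:
#' `areaPerCell` (effective area divided by the cell count, the printed
#' convention) and `cellsPerKilopixel` (cells per 1000 px2 of effective
#' area). The default effective area excludes a margin of one median
#' equivalent cell radius on each side.
#'
#' @param mask integer instance mask with at least one cell.
#' @param effectiveArea optional effective area in px2 (overrides the
#'   margin rule).
#' @return list(areaPerCell, cellsPerKilopixel, count, effectiveArea).
#' @export
cellImagingDensity <- function(mask, effectiveArea = NULL) {
  labs <- setdiff(unique(as.vector(mask)), 0)
  n <- length(labs)
  if (n == 0) stop("zero cells: density undefined")
  if (is.null(effectiveArea)) {
    areas <- vapply(labs, function(L) sum(mask == L), numeric(1))
    margin <- stats::median(sqrt(areas / pi))
    effectiveArea <- max(1, (nrow(mask) - 2 * margin)) *
      max(1, (ncol(mask) - 2 * margin))
  }
  list(areaPerCell = effectiveArea / n,
       cellsPerKilopixel = 1000 * n / effectiveArea,
       count = n, effectiveArea = effectiveArea)
}

#' Evaluate segmentation and tracking against a reference video
#'
#' @param predMasks list of predicted instance masks (or `NULL`).
#' @param refMasks list of reference instance masks.
#' @param predTracks,refTracks track tables (frame, id, x, y, w, h) or
#'   `NULL` to skip tracking measures.
#' @param iouThreshold CLEAR matching threshold.
#' @return A [MetricsReport-class].
#' @export
evaluateAll <- function(predMasks = NULL, refMasks = NULL,
                        predTracks = NULL, refTracks = NULL,
                        iouThreshold = 0.5) {
  seg <- data.frame(frame = integer(), dice = numeric(), iou = numeric(),
                    aji = numeric())
  if (!is.null(predMasks)) {
    for (i in seq_along(predMasks)) {
      seg <- rbind(seg, data.frame(
        frame = i - 1L,
        dice = dice(refMasks[[i]] > 0, predMasks[[i]] > 0),
        iou = iou(refMasks[[i]] > 0, predMasks[[i]] > 0),
        aji = aji(refMasks[[i]], predMasks[[i]])))
    }
  }
  tr <- list()
  if (!is.null(predTracks) && !is.null(refTracks)) {
    m <- trackMatch(predTracks, refTracks, iouThreshold)
    mm <- mtMl(predTracks, refTracks, match = m)
    tr <- list(mota = motaScore(m),
               ct = completeTracks(predTracks, refTracks, match = m),
               tf = trackFraction(predTracks, refTracks, match = m),
               mt = mm[["mt"]], ml = mm[["ml"]],
               fn = m$fn, fp = m$fp, idsw = m$idsw, gt = m$gt)
  }
  methods::new("MetricsReport", segmentation = seg, tracking = tr,
               settings = list(iouThreshold = iouThreshold))
}
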