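# Online association in the JDE style: detections carrying appearance
# embeddings are linked frame by frame with a two-pass match (embedding
# cosine distance gated by the motion prediction, then IoU fallback),
# solved as an optimal bipartite assignment; motion is a constant-velocity
# Kalman filter on (x, y, w, h).

#' Solve the linear assignment problem
#'
#' Jonker-Volgenant style shortest-augmenting-path algorithm (O(n^3));
#' rectangular matrices are allowed. Entries >= 1e6 are treated as
#' forbidden (can stay unassigned via dummy padding).
#'
#' @param cost numeric cost matrix (rows assigned to columns).
#' @return Integer vector of length nrow(cost): assigned column per row,
#'   0 if unassigned.
#' @export
hungarian <- function(cost) {
  n0 <- nrow(cost); m0 <- ncol(cost)
  if (n0 == 0L) return(integer(0))
  if (m0 == 0L) return(rep(0L, n0))
  # pad to square with a neutral dummy cost so every row gets something
  k <- max(n0, m0)
  big <- 1e6
  a <- matrix(big, k, k)
  a[seq_len(n0), seq_len(m0)] <- cost
  n <- k; m <- k
  INF <- Inf
  u <- numeric(n + 1); v <- numeric(m + 1)
  p <- integer(m + 1); way <- integer(m + 1)  # index 1 = dummy column 0
  for (i in seq_len(n)) {
    p[1] <- i
    j0 <- 1L
    minv <- rep(INF, m + 1); used <- rep(FALSE, m + 1)
    repeat {
      used[j0] <- TRUE
      i0 <- p[j0]; delta <- INF; j1 <- 0L
      for (j in 2:(m + 1)) {
        if (used[j]) next
        cur <- a[i0, j - 1] - u[i0] - v[j]
        if (cur < minv[j]) { minv[j] <- cur; way[j] <- j0 }
        if (minv[j] < delta) { delta <- minv[j]; j1 <- j }
      }
      for (j in seq_len(m + 1)) {
        if (used[j]) { u[p[j]] <- u[p[j]] + delta; v[j] <- v[j] - delta }
        else minv[j] <- minv[j] - delta
      }
      j0 <- j1
      if (p[j0] == 0L) break
    }
    repeat {
      j1 <- way[j0]
      p[j0] <- p[j1]
      j0 <- j1
      if (j0 == 1L) break
    }
  }
  ans <- integer(n0)
  for (j in 2:(m + 1)) {
    if (p[j] >= 1L && p[j] <= n0 && (j - 1) <= m0 &&
        a[p[j], j - 1] < big) ans[p[j]] <- j - 1L
  }
  ans
}

# ---- constant-velocity Kalman filter on (x, y, w, h) ----------------------

.kfF <- local({
  F <- diag(8)
  F[cbind(1:4, 5:8)] <- 1
  F
})
.kfH <- cbind(diag(4), matrix(0, 4, 4))

kfInit <- function(box) {
  list(x = c(as.numeric(box), rep(0, 4)),
       P = diag(c(rep(4, 4), rep(100, 4))))
}

kfPredict <- function(kf, q = 0.05) {
  x <- .kfF %*% kf$x
  P <- .kfF %*% kf$P %*% t(.kfF) + diag(rep(q, 8))
  list(x = as.vector(x), P = P)
}

kfUpdate <- function(kf, z, r = 1) {
  S <- .kfH %*% kf$P %*% t(.kfH) + diag(rep(r, 4))
  K <- kf$P %*% t(.kfH) %*% solve(S)
  x <- kf$x + K %*% (z - .kfH %*% kf$x)
  P <- (diag(8) - K %*% .kfH) %*% kf$P
  list(x = as.vector(x), P = P)
}

# ---- tracker ---------------------------------------------------------------

#' Association configuration (JDE-style defaults)
#'
#' @param embGate max center distance (px) within which embedding matches
#'   are considered in pass 1.
#' @param embThreshold max accepted embedding cosine distance.
#' @param iouThreshold min IoU accepted in the fallback pass.
#' @param patience frames a lost tracklet is kept before finishing.
#' @param embMomentum exponential smoothing of the tracklet embedding.
#' @param divisionGate center distance (px) for the lineage parent
#'   heuristic.
#' @param minScore detections below this score do not start new tracklets.
#' @return Named list.
#' @export
assocConfig <- function(embGate = 24, embThreshold = 0.6,
                        iouThreshold = 0.3, patience = 10L,
                        embMomentum = 0.9, divisionGate = 12,
                        minScore = 0.3) {
  list(embGate = embGate, embThreshold = embThreshold,
       iouThreshold = iouThreshold, patience = as.integer(patience),
       embMomentum = embMomentum, divisionGate = divisionGate,
       minScore = minScore)
}

cosineDistance <- function(E1, E2) {
  n1 <- sqrt(rowSums(E1^2)); n2 <- sqrt(rowSums(E2^2))
  1 - (E1 %*% t(E2)) / pmax(outer(n1, n2), 1e-12)
}

newTracklet <- function(id, frame, box, emb) {
  list(id = id, frames = frame, boxes = matrix(box, 1, 4,
         dimnames = list(NULL, c("x", "y", "w", "h"))),
       emb = emb / max(sqrt(sum(emb^2)), 1e-12), kf = kfInit(box),
       status = "active", lost = 0L, parent = 0L)
}

#' Associate one frame of detections with the current tracklets
#'
#' Two-pass matching: (1) embedding cosine distance, gated by the
#' Kalman-predicted center distance; (2) IoU of predicted vs detected
#' boxes for the leftovers. Both passes use the optimal assignment from
#' [hungarian()]. Unmatched detections start new tracklets; unmatched
#' tracklets become lost and finish after `patience` frames.
#'
#' @param tracklets list of tracklets (internal format; start with
#'   `list()`).
#' @param detections list with `boxes` (data.frame x, y, w, h, score) and
#'   `emb` (nDet x D embedding matrix).
#' @param frame 0-based frame index.
#' @param cfg an [assocConfig()] list.
#' @param nextId next fresh tracklet id.
#' @return list(tracklets, nextId).
#' @export
associateFrame <- function(tracklets, detections, frame,
                           cfg = assocConfig(), nextId = 1L) {
  det <- detections$boxes
  emb <- detections$emb
  live <- which(vapply(tracklets, function(t) t$status != "finished",
                       logical(1)))
  # motion prediction
  predBox <- matrix(0, length(live), 4)
  for (k in seq_along(live)) {
    t <- tracklets[[live[k]]]
    t$kf <- kfPredict(t$kf)
    tracklets[[live[k]]] <- t
    predBox[k, ] <- t$kf$x[1:4]
  }
  nDet <- if (is.null(det)) 0L else nrow(det)
  matchedT <- rep(FALSE, length(live)); matchedD <- rep(FALSE, nDet)
  assignTo <- rep(NA_integer_, nDet)
  if (length(live) && nDet) {
    tEmb <- do.call(rbind, lapply(tracklets[live], `[[`, "emb"))
    cd <- cosineDistance(tEmb, emb)
    centDist <- sqrt(outer(predBox[, 1], det$x, "-")^2 +
                     outer(predBox[, 2], det$y, "-")^2)
    cost <- cd
    cost[centDist > cfg$embGate] <- 1e6
    cost[cd > cfg$embThreshold] <- 1e6
    asg <- hungarian(cost)
    for (k in seq_along(asg)) if (asg[k] > 0) {
      matchedT[k] <- TRUE; matchedD[asg[k]] <- TRUE
      assignTo[asg[k]] <- live[k]
    }
    # IoU fallback
    tRem <- which(!matchedT); dRem <- which(!matchedD)
    if (length(tRem) && length(dRem)) {
      pb <- data.frame(x = predBox[tRem, 1], y = predBox[tRem, 2],
                       w = predBox[tRem, 3], h = predBox[tRem, 4])
      im <- boxIou(pb, det[dRem, , drop = FALSE])
      cost2 <- 1 - im
      cost2[im < cfg$iouThreshold] <- 1e6
      asg2 <- hungarian(cost2)
      for (k in seq_along(asg2)) if (asg2[k] > 0) {
        matchedT[tRem[k]] <- TRUE; matchedD[dRem[asg2[k]]] <- TRUE
        assignTo[dRem[asg2[k]]] <- live[tRem[k]]
      }
    }
  }
  # update matched tracklets
  for (d in which(matchedD)) {
    ti <- assignTo[d]
    t <- tracklets[[ti]]
    z <- as.numeric(det[d, c("x", "y", "w", "h")])
    t$kf <- kfUpdate(t$kf, z)
    t$frames <- c(t$frames, frame)
    t$boxes <- rbind(t$boxes, t$kf$x[1:4])  # filtered box, not raw z
    e <- emb[d, ] / max(sqrt(sum(emb[d, ]^2)), 1e-12)
    t$emb <- cfg$embMomentum * t$emb + (1 - cfg$embMomentum) * e
    t$emb <- t$emb / max(sqrt(sum(t$emb^2)), 1e-12)
    t$status <- "active"; t$lost <- 0L
    tracklets[[ti]] <- t
  }
  # unmatched tracklets -> lost / finished
  for (k in which(!matchedT)) {
    t <- tracklets[[live[k]]]
    t$lost <- t$lost + 1L
    t$status <- if (t$lost > cfg$patience) "finished" else "lost"
    tracklets[[live[k]]] <- t
  }
  # unmatched detections -> new tracklets
  for (d in seq_len(nDet)) {
    if (matchedD[d]) next
    if (det$score[d] < cfg$minScore) next
    tracklets[[length(tracklets) + 1L]] <-
      newTracklet(nextId, frame, as.numeric(det[d, c("x", "y", "w", "h")]),
                  emb[d, ])
    nextId <- nextId + 1L
  }
  list(tracklets = tracklets, nextId = nextId)
}

#' Link a sequence of per-frame detections into tracklets
#'
#' @param detList list (one element per frame, 0-based order) of
#'   detections as in [associateFrame()].
#' @param cfg an [assocConfig()] list.
#' @return A [TrackSet-class].
#' @export
trackDetections <- function(detList, cfg = assocConfig()) {
  tracklets <- list(); nextId <- 1L
  for (f in seq_along(detList)) {
    st <- associateFrame(tracklets, detList[[f]], f - 1L, cfg, nextId)
    tracklets <- st$tracklets; nextId <- st$nextId
  }
  for (i in seq_along(tracklets)) tracklets[[i]]$status <- "finished"
  methods::new("TrackSet", tracks = tracklets,
               nFrames = length(detList))
}

#' Per-frame box table of a track set
#'
#' @param ts a [TrackSet-class].
#' @return data.frame with frame, id, x, y, w, h.
#' @export
trackFrames <- function(ts) {
  out <- lapply(ts@tracks, function(t)
    data.frame(frame = t$frames, id = t$id, x = t$boxes[, 1],
               y = t$boxes[, 2], w = t$boxes[, 3], h = t$boxes[, 4]))
  if (!length(out))
    return(data.frame(frame = integer(), id = integer(), x = numeric(),
                      y = numeric(), w = numeric(), h = numeric()))
  res <- do.call(rbind, out)
  res[order(res$frame, res$id), , drop = FALSE]
}

#' Resolve cell divisions in a finished track set
#'
#' The online associator does not model division: at a division event the
#' parent tracklet usually continues as one child while the other child
#' starts a fresh tracklet. This post-processor applies the division
#' heuristic: a tracklet starting at frame f either (a) gets as parent a
#' tracklet that ended at f-1 within `divisionGate` pixels with a larger
#' box, or (b) splits a nearby tracklet whose box area roughly halved
#' between f-1 and f (the absorbed-child case) — the split tail becomes a
#' new tracklet and both children record the parent. Deliberately
#' best-effort.
#'
#' @param ts a [TrackSet-class].
#' @param cfg an [assocConfig()] list (for `divisionGate`).
#' @return A [TrackSet-class] with parent links set and split tracklets.
#' @export
resolveDivisions <- function(ts, cfg = assocConfig()) {
  tr <- ts@tracks
  if (!length(tr)) return(ts)
  nextId <- max(vapply(tr, `[[`, 0L, "id")) + 1L
  i <- 1L
  while (i <= length(tr)) {
    X <- tr[[i]]
    f <- min(X$frames)
    if (f > 0L && X$parent == 0L) {
      x0 <- X$boxes[1, 1]; y0 <- X$boxes[1, 2]
      a0 <- X$boxes[1, 3] * X$boxes[1, 4]
      bestEnd <- 0L; bestEndD <- Inf
      bestSplit <- 0L; bestSplitD <- Inf
      for (j in seq_along(tr)) {
        if (j == i) next
        Y <- tr[[j]]
        kPrev <- which(Y$frames == f - 1L)
        if (!length(kPrev)) next
        d <- sqrt((Y$boxes[kPrev, 1] - x0)^2 + (Y$boxes[kPrev, 2] - y0)^2)
        if (d > cfg$divisionGate) next
        aPrev <- Y$boxes[kPrev, 3] * Y$boxes[kPrev, 4]
        kCur <- which(Y$frames == f)
        if (!length(kCur)) {
          # candidate (a): Y ended exactly at f-1
          if (max(Y$frames) == f - 1L && aPrev > 1.2 * a0 &&
              d < bestEndD) { bestEnd <- j; bestEndD <- d }
        } else {
          aCur <- Y$boxes[kCur, 3] * Y$boxes[kCur, 4]
          if (aPrev > 1.4 * aCur && d < bestSplitD) {
            bestSplit <- j; bestSplitD <- d
          }
        }
      }
      if (bestEnd > 0L) {
        tr[[i]]$parent <- tr[[bestEnd]]$id
      } else if (bestSplit > 0L) {
        Y <- tr[[bestSplit]]
        keep <- Y$frames <= f - 1L
        tail <- Y
        tail$id <- nextId; nextId <- nextId + 1L
        tail$frames <- Y$frames[!keep]
        tail$boxes <- Y$boxes[!keep, , drop = FALSE]
        tail$parent <- Y$id
        Y$frames <- Y$frames[keep]
        Y$boxes <- Y$boxes[keep, , drop = FALSE]
        tr[[bestSplit]] <- Y
        tr[[i]]$parent <- Y$id
        tr[[length(tr) + 1L]] <- tail
      }
    }
    i <- i + 1L
  }
  methods::new("TrackSet", tracks = tr, nFrames = ts@nFrames)
}

#' Build a CTC lineage table from a track set
#'
#' One row (label, begin, end, parent) per tracklet, after
#' [resolveDivisions()] has linked division events.
#'
#' @param ts a [TrackSet-class].
#' @param cfg an [assocConfig()] list (for `divisionGate`).
#' @param resolve run [resolveDivisions()] first (default TRUE).
#' @return data.frame with label, begin, end, parent.
#' @export
buildLineage <- function(ts, cfg = assocConfig(), resolve = TRUE) {
  if (resolve) ts <- resolveDivisions(ts, cfg)
  tr <- ts@tracks
  if (!length(tr))
    return(data.frame(label = integer(), begin = integer(),
                      end = integer(), parent = integer()))
  tab <- data.frame(
    label = vapply(tr, `[[`, 0L, "id"),
    begin = vapply(tr, function(t) min(t$frames), 0L),
    end = vapply(tr, function(t) max(t$frames), 0L),
    parent = vapply(tr, function(t) as.integer(t$parent), 0L))
  tab <- tab[order(tab$label), , drop = FALSE]
  rownames(tab) <- NULL
  tab
}
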