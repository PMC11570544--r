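# Synthetic cell video generator. Scenes are elliptical cells on a smoothly
# textured background; appearance, density, motion, divisions and photometric
# conditions are all controlled by SceneConfig / ShiftSpec, so source and
# target imaging domains can be emulated without any external data.

clip01 <- function(x) pmin(pmax(x, 0), 1)

# all generated frames live on the 16-bit intensity grid, like real
# 16-bit microscopy acquisitions; this also makes TIFF round trips exact
quantize16 <- function(x) round(clip01(x) * 65535) / 65535

gaussianBlur <- function(img, sigma) {
  if (sigma <= 0) return(img)
  EBImage::gblur(img, sigma = sigma)
}

# smooth background field: base intensity + illumination ramp + coarse texture
backgroundField <- function(H, W, bg, illum, textureAmp = 0.02) {
  cc <- matrix(rep(seq_len(W), each = H), H, W)
  plane <- bg + illum * (cc / W - 0.5)
  ch <- max(2L, H %/% 8L); cw <- max(2L, W %/% 8L)
  coarse <- matrix(stats::rnorm(ch * cw, 0, 1), ch, cw)
  tex <- coarse[pmin(ch, ceiling(seq_len(H) / H * ch)),
                pmin(cw, ceiling(seq_len(W) / W * cw)), drop = FALSE]
  plane + textureAmp * gaussianBlur(tex, 2)
}

# pixels of an ellipse centered at (r0, c0); returns index vector + quad form
ellipsePixels <- function(H, W, r0, c0, a, b, theta) {
  rr <- max(1L, floor(r0 - a)):min(H, ceiling(r0 + a))
  cc <- max(1L, floor(c0 - a)):min(W, ceiling(c0 + a))
  dr <- rep(rr - r0, times = length(cc))
  dc <- rep(cc - c0, each = length(rr))
  u <- (dc * cos(theta) + dr * sin(theta)) / a
  v <- (-dc * sin(theta) + dr * cos(theta)) / b
  q <- u * u + v * v
  keep <- q <= 1
  idx <- (rep(cc, each = length(rr)) - 1L) * H + rep(rr, times = length(cc))
  list(idx = idx[keep], q = q[keep])
}

# draw one scene state (data.frame label,r,c,a,b,theta,shade) -> image + mask
renderScene <- function(state, config) {
  H <- config@frameSize[1]; W <- config@frameSize[2]
  img <- backgroundField(H, W, config@intensityBg,
                         config@illuminationGradient)
  mask <- matrix(0L, H, W)
  if (nrow(state)) for (i in seq_len(nrow(state))) {
    ep <- ellipsePixels(H, W, state$r[i], state$c[i], state$a[i], state$b[i],
                        state$theta[i])
    val <- clip01(config@intensityFg + state$shade[i]) * (1 - 0.15 * ep$q)
    img[ep$idx] <- val
    mask[ep$idx] <- state$label[i]  # later-drawn cell wins ownership
  }
  img <- gaussianBlur(img, 0.7)
  if (config@noiseSigma > 0)
    img <- img + stats::rnorm(length(img), 0, config@noiseSigma)
  list(image = quantize16(img), mask = mask)
}

sampleCellGeometry <- function(config) {
  a <- stats::runif(1, config@cellRadiusRange[1], config@cellRadiusRange[2])
  e <- stats::runif(1, config@eccentricityRange[1], config@eccentricityRange[2])
  list(a = a, b = a * sqrt(1 - e^2), theta = stats::runif(1, 0, pi))
}

# place nCells ellipses with bounded pairwise overlap; RNG comes from caller
placeCells <- function(config, maxAttempts = 200L) {
  H <- config@frameSize[1]; W <- config@frameSize[2]
  owned <- matrix(FALSE, H, W)
  st <- data.frame(label = integer(), r = numeric(), c = numeric(),
                   a = numeric(), b = numeric(), theta = numeric(),
                   shade = numeric())
  for (i in seq_len(config@nCells)) {
    placed <- FALSE
    for (att in seq_len(maxAttempts)) {
      g <- sampleCellGeometry(config)
      m <- g$a + 1
      if (H - 2 * m <= 1 || W - 2 * m <= 1)
        stop("placement overflow: cells larger than frame")
      r0 <- stats::runif(1, m, H - m); c0 <- stats::runif(1, m, W - m)
      if (config@minSeparation > 0 && nrow(st) &&
          min(sqrt((st$r - r0)^2 + (st$c - c0)^2)) < config@minSeparation)
        next
      ep <- ellipsePixels(H, W, r0, c0, g$a, g$b, g$theta)
      if (mean(owned[ep$idx]) <= config@maxOverlap) {
        owned[ep$idx] <- TRUE
        st <- rbind(st, data.frame(label = i, r = r0, c = c0, a = g$a,
                                   b = g$b, theta = g$theta,
                                   shade = stats::rnorm(1, 0, 0.03)))
        placed <- TRUE
        break
      }
    }
    if (!placed)
      stop("placement overflow: could not place ", config@nCells,
           " cells with maxOverlap ", config@maxOverlap)
  }
  st
}

#' Generate a single synthetic frame
#'
#' Places `nCells` ellipses with bounded overlap and renders them on a
#' textured, noisy background. Deterministic in the configuration seed.
#'
#' @param config a [SceneConfig-class].
#' @return list with elements `image` (H x W in [0, 1]) and `mask`
#'   (integer instance labels, 0 = background).
#' @examples
#' fr <- generateFrame(sceneConfig(nCells = 3L, seed = 7L))
#' length(setdiff(unique(as.vector(fr$mask)), 0))
#' @export
generateFrame <- function(config) {
  withSeed(config@seed, {
    st <- placeCells(config)
    renderScene(st, config)
  })
}

# minimum age (frames) before a cell may divide again
.divisionRefractory <- 2L

#' Generate a synthetic cell video with lineage
#'
#' Cells from [generateFrame()] move with Gaussian per-frame displacements,
#' keep their labels, and (optionally) divide: the parent track ends and two
#' child tracks start in the next frame at offset centroids, recording the
#' parent label (CTC semantics). Newborn cells wait two frames before they
#' can divide again.
#'
#' @param config a [SceneConfig-class] with `nFrames >= 1`.
#' @return A [CellVideo-class].
#' @examples
#' vid <- generateSequence(sceneConfig(nCells = 4L, nFrames = 3L, seed = 2L))
#' trackTable(vid)
#' @export
generateSequence <- function(config) {
  H <- config@frameSize[1]; W <- config@frameSize[2]
  withSeed(config@seed, {
    st <- placeCells(config)
    st$born <- 0L
    tt <- data.frame(label = st$label, begin = 0L, end = 0L,
                     parent = 0L)
    nextLabel <- if (nrow(st)) max(st$label) + 1L else 1L
    framesL <- vector("list", config@nFrames)
    masksL <- vector("list", config@nFrames)
    rs <- renderScene(st, config)
    framesL[[1]] <- rs$image; masksL[[1]] <- rs$mask
    if (config@nFrames > 1L) for (f in seq_len(config@nFrames - 1L)) {
      # divisions decided at frame f based on state at f-1
      newSt <- st[0, ]
      for (i in seq_len(nrow(st))) {
        age <- f - st$born[i]
        if (config@divisionProb > 0 && age >= .divisionRefractory &&
            stats::runif(1) < config@divisionProb) {
          tt$end[tt$label == st$label[i]] <- f - 1L
          phi <- stats::runif(1, 0, 2 * pi)
          off <- st$a[i] / 2
          for (s in c(-1, 1)) {
            child <- st[i, ]
            child$label <- nextLabel; nextLabel <- nextLabel + 1L
            child$r <- min(max(st$r[i] + s * off * sin(phi), child$a + 1),
                           H - child$a - 1)
            child$c <- min(max(st$c[i] + s * off * cos(phi), child$a + 1),
                           W - child$a - 1)
            child$a <- max(2, st$a[i] * 0.75)
            child$b <- max(1.5, st$b[i] * 0.75)
            child$born <- f
            newSt <- rbind(newSt, child)
            tt <- rbind(tt, data.frame(label = child$label, begin = f,
                                       end = f, parent = st$label[i]))
          }
        } else {
          cur <- st[i, ]
          if (config@motionSigma > 0) {
            cur$r <- min(max(cur$r + stats::rnorm(1, 0, config@motionSigma),
                             cur$a + 1), H - cur$a - 1)
            cur$c <- min(max(cur$c + stats::rnorm(1, 0, config@motionSigma),
                             cur$a + 1), W - cur$a - 1)
          }
          newSt <- rbind(newSt, cur)
          tt$end[tt$label == cur$label] <- f
        }
      }
      st <- newSt
      rs <- renderScene(st, config)
      framesL[[f + 1L]] <- rs$image; masksL[[f + 1L]] <- rs$mask
    }
    cellVideo(framesL, masksL, tt)
  })
}

#' Apply a photometric domain shift to a frame
#'
#' Applies, in order: gamma remap, contrast scaling about mid-grey,
#' brightness offset, optional inversion, an additive illumination plane and
#' re-drawn Gaussian noise; the result is clipped to [0, 1] and re-quantized.
#' Instance masks are untouched by design: a photometric shift changes the
#' imaging, not the objects.
#'
#' @param image numeric matrix in [0, 1].
#' @param shift a [ShiftSpec-class].
#' @return Shifted image matrix.
#' @examples
#' img <- matrix(0.5, 8, 8)
#' applyDomainShift(img, shiftSpec(gamma = 2))[1, 1]  # 0.25
#' @export
applyDomainShift <- function(image, shift) {
  stopifnot(min(image) >= 0, max(image) <= 1)
  y <- image^shift@gamma
  y <- 0.5 + shift@contrast * (y - 0.5)
  y <- y + shift@brightness
  if (shift@invert) y <- 1 - y
  if (shift@illuminationGradient != 0) {
    W <- ncol(y)
    cc <- matrix(rep(seq_len(W), each = nrow(y)), nrow(y), W)
    y <- y + shift@illuminationGradient * (cc / W - 0.5)
  }
  if (shift@noiseSigma > 0)
    y <- y + withSeed(shift@seed,
                      matrix(stats::rnorm(length(y), 0, shift@noiseSigma),
                             nrow(y), ncol(y)))
  quantize16(y)
}

#' Shift every frame of a video
#'
#' @param video a [CellVideo-class].
#' @param shift a [ShiftSpec-class]; the per-frame noise seed is offset by
#'   the frame index so noise is independent across frames.
#' @return A [CellVideo-class] with shifted frames and unchanged masks.
#' @export
shiftVideo <- function(video, shift) {
  fr <- lapply(seq_along(video@frames), function(i) {
    s <- shift; s@seed <- shift@seed + i - 1L
    applyDomainShift(video@frames[[i]], s)
  })
  cellVideo(fr, video@masks, video@trackTable)
}
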