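# Shared fixtures. Heavyweight artifacts (trained models) are built lazily
# and memoized so several test files can reuse them.

.fixtures <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (is.null(.fixtures[[key]])) .fixtures[[key]] <- force(expr)
  .fixtures[[key]]
}

# sparse high-contrast source condition (96 px, used by adaptation tests)
sourceSceneCfg <- function(seed) {
  sceneConfig(frameSize = 96L, nCells = 10L, cellRadiusRange = c(4, 6),
              noiseSigma = 0.03, motionSigma = 1, seed = seed)
}

# dense target condition: 3x the source cell count, photometrically shifted
targetSceneCfg <- function(seed) {
  sceneConfig(frameSize = 96L, nCells = 30L, cellRadiusRange = c(4, 6),
              noiseSigma = 0.03, motionSigma = 1, seed = seed)
}

targetShiftCfg <- function(seed = 9L) {
  shiftSpec(gamma = 1.6, contrast = 0.6, brightness = 0.08,
            noiseSigma = 0.05, seed = seed)
}

# easy tracking condition: 10 well-separated cells, 20 frames, low noise
easyTrackCfg <- function(seed) {
  sceneConfig(frameSize = 128L, nCells = 10L, cellRadiusRange = c(5, 7),
              motionSigma = 1, noiseSigma = 0.02, maxOverlap = 0,
              minSeparation = 26, nFrames = 20L, seed = seed)
}

sourceFrames <- function(n = 8L, baseSeed = 100L, cfgFun = sourceSceneCfg) {
  key <- paste0("src_", n, "_", baseSeed)
  memo(key, {
    imgs <- list(); msks <- list()
    for (s in seq_len(n)) {
      f <- generateFrame(cfgFun(baseSeed + s))
      imgs[[s]] <- f$image; msks[[s]] <- f$mask
    }
    list(images = imgs, masks = msks)
  })
}

# a small trained segmentation model shared across test files
trainedSegModel <- function() {
  memo("segmodel", {
    d <- sourceFrames()
    m <- segModel(seed = 1L)
    trainSource(m, d$images, d$masks,
                trainConfig(epochs = 25L, learningRate = 1e-3,
                            batchSize = 4L, seed = 1L))
  })
}

# full tracking run (backbone + head + tracker on one video seed); the
# backbone is trained on the video's own first frames and reused by both
# the end-to-end and the SA-ReID ablation checks
trackingRun <- function(seed, useSAM = TRUE, backbone = NULL) {
  key <- paste0("track_", seed, "_", useSAM)
  memo(key, {
    vid <- generateSequence(easyTrackCfg(seed))
    imgs <- frames(vid); msks <- masks(vid)
    if (is.null(backbone)) backbone <- memo(paste0("bb_", seed), {
      m <- segModel(seed = seed)
      trainSource(m, imgs[1:8], msks[1:8],
                  trainConfig(epochs = 60L, learningRate = 1e-3,
                              batchSize = 4L, seed = seed))
    })
    gtb <- lapply(msks, function(mk) {
      b <- boxesFromMask(mk); b$id <- b$label; b
    })
    jm <- jointModel(backbone, nIds = 10L, useSAM = useSAM,
                     seed = seed + 1L)
    jm <- trainJointHead(jm, imgs, gtb, epochs = 150L,
                         learningRate = 5e-3, seed = seed + 2L)
    jm <- trainJointHead(jm, imgs, gtb, epochs = 80L,
                         learningRate = 1e-3, seed = seed + 3L)
    detList <- lapply(imgs, function(im)
      detectFrame(jm, im, scoreThreshold = 0.4, nmsThreshold = 0.2))
    ts <- trackDetections(detList, assocConfig(embGate = 12,
                                               minScore = 0.6))
    pt <- trackFrames(ts)
    rt <- do.call(rbind, lapply(seq_along(msks), function(f) {
      b <- boxesFromMask(msks[[f]])
      data.frame(frame = f - 1L, id = b$label, x = b$x, y = b$y,
                 w = b$w, h = b$h)
    }))
    mm <- trackMatch(pt, rt)
    list(video = vid, model = jm, trackSet = ts, pred = pt, ref = rt,
         match = mm, mota = motaScore(mm))
  })
}

numericGradient <- function(f, x, h = 1e-5) {
  vapply(seq_along(x), function(i) {
    xp <- x; xp[i] <- xp[i] + h
    xm <- x; xm[i] <- xm[i] - h
    (f(xp) - f(xm)) / (2 * h)
  }, numeric(1))
}
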