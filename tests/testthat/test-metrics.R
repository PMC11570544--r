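# Metric suite against brute-force oracles and hand-built instances.

test_that("dice and iou match closed forms and each other", {
  A <- matrix(0, 10, 10); A[1:5, 1:5] <- 1
  expect_equal(dice(A, A), 1)
  expect_equal(iou(A, A), 1)
  B <- matrix(0, 10, 10); B[6:10, 6:10] <- 1
  expect_equal(dice(A, B), 0)
  # |G| = |S| = 100, intersection 50
  G <- matrix(0, 20, 20); G[1:10, 1:10] <- 1
  S <- matrix(0, 20, 20); S[1:10, 6:15] <- 1
  expect_equal(dice(G, S), 0.5)
  expect_equal(iou(G, S), 1 / 3)
  # conventions and identities
  Z <- matrix(0, 5, 5)
  expect_equal(dice(Z, Z), 1)
  expect_equal(iou(Z, Z), 1)
  expect_error(dice(A, matrix(0, 3, 3)), "shape")
  set.seed(11)
  for (i in 1:50) {
    G <- matrix(runif(64) > 0.5, 8, 8)
    S <- matrix(runif(64) > 0.5, 8, 8)
    d <- dice(G, S); j <- iou(G, S)
    expect_equal(d, 2 * j / (1 + j), tolerance = 1e-12)
    expect_gte(d, j)
  }
})

ajiOracle <- function(G, S) {
  gl <- setdiff(sort(unique(as.vector(G))), 0)
  sl <- setdiff(sort(unique(as.vector(S))), 0)
  num <- 0; den <- 0; used <- integer()
  for (g in gl) {
    best <- c(j = -1, i = 0, u = sum(G == g), s = NA)
    for (s in sl) {
      i <- sum(G == g & S == s)
      if (i == 0) next
      u <- sum(G == g | S == s)
      if (i / u > best["j"] + 1e-12)
        best <- c(j = i / u, i = i, u = u, s = s)
    }
    num <- num + best["i"]; den <- den + best["u"]
    if (!is.na(best["s"])) used <- union(used, best["s"])
  }
  for (s in setdiff(sl, used)) den <- den + sum(S == s)
  unname(num / den)
}

test_that("aji matches Eq-style worked cases and a brute-force oracle", {
  G <- matrix(0L, 10, 10); G[2:3, 2:6] <- 1L; G[7:8, 2:6] <- 2L
  expect_equal(aji(G, G), 1)
  # two 10-px objects merged into one 20-px prediction covering both
  S <- matrix(0L, 10, 10); S[G > 0] <- 1L
  expect_equal(aji(G, S), 0.5)
  expect_error(aji(matrix(0L, 4, 4), S[1:4, 1:4]), "no ground-truth")
  set.seed(12)
  for (i in 1:25) {
    G <- matrix(sample(0:4, 100, replace = TRUE, prob = c(.5, rep(.125, 4))),
                10, 10)
    S <- matrix(sample(0:5, 100, replace = TRUE, prob = c(.4, rep(.12, 5))),
                10, 10)
    if (!any(G > 0)) next
    expect_equal(aji(G, S), ajiOracle(G, S), tolerance = 1e-12)
  }
})

test_that("aji is at most the binary iou (stringency)", {
  set.seed(13)
  for (i in 1:20) {
    G <- matrix(sample(0:3, 100, replace = TRUE), 10, 10)
    S <- matrix(sample(0:3, 100, replace = TRUE), 10, 10)
    if (!any(G > 0)) next
    expect_lte(aji(G, S), iou(G > 0, S > 0) + 1e-12)
  }
})

test_that("mota follows the CLEAR formula on worked counts", {
  expect_equal(motaScore(list(fn = 0, fp = 0, idsw = 0, gt = 10)), 1)
  expect_equal(motaScore(list(fn = 2, fp = 1, idsw = 1, gt = 20)), 0.8)
  expect_equal(motaScore(list(fn = 20, fp = 0, idsw = 0, gt = 20)), 0)
  expect_error(motaScore(list(fn = 0, fp = 0, idsw = 0, gt = 0)), "ground")
})

mkTracks <- function(...) {
  rows <- list(...)
  do.call(rbind, lapply(rows, function(r)
    data.frame(frame = r[[1]], id = r[[2]], x = r[[3]], y = r[[4]],
               w = 10, h = 10)))
}

test_that("persistent matching counts FN, FP and identity switches", {
  ref <- mkTracks(list(0:4, 1L, 10, 10))
  # identical prediction
  m <- trackMatch(ref, ref)
  expect_identical(c(m$fn, m$fp, m$idsw), c(0L, 0L, 0L))
  expect_equal(motaScore(m), 1)
  # id changes mid-track -> one switch
  pr <- rbind(mkTracks(list(0:2, 5L, 10, 10)),
              mkTracks(list(3:4, 6L, 10, 10)))
  m2 <- trackMatch(pr, ref)
  expect_identical(m2$idsw, 1L)
  # a far-away prediction is a false positive each frame
  pr3 <- rbind(ref, mkTracks(list(0:4, 9L, 80, 80)))
  m3 <- trackMatch(pr3, ref)
  expect_identical(m3$fp, 5L)
  # missing frames are false negatives
  m4 <- trackMatch(mkTracks(list(0:2, 1L, 10, 10)), ref)
  expect_identical(m4$fn, 2L)
})

test_that("CT demands one id over the full span; TF takes the longest run", {
  ref <- rbind(mkTracks(list(0:9, 1L, 10, 10)),
               mkTracks(list(0:9, 2L, 50, 50)),
               mkTracks(list(0:9, 3L, 90, 90)),
               mkTracks(list(0:9, 4L, 130, 130)))
  pred <- rbind(mkTracks(list(0:9, 11L, 10, 10)),   # complete
                mkTracks(list(0:9, 12L, 50, 50)),   # complete
                mkTracks(list(0:6, 13L, 90, 90)),   # longest run 7
                mkTracks(list(0:4, 14L, 130, 130)), # switch at frame 5
                mkTracks(list(5:9, 15L, 130, 130)))
  expect_equal(completeTracks(pred, ref), 0.5)
  tf <- trackFraction(pred, ref)
  expect_equal(tf, mean(c(1, 1, 0.7, 0.5)))
  # a track broken by an identity switch mid-span is not complete
  expect_equal(completeTracks(
    rbind(mkTracks(list(0:4, 1L, 10, 10)), mkTracks(list(5:9, 2L, 10, 10))),
    mkTracks(list(0:9, 1L, 10, 10))), 0)
  expect_equal(tf, 0.8)  # enumerated runs: 10/10, 10/10, 7/10, 5/10
})

test_that("MT/ML follow the 80/20 rules", {
  ref <- rbind(mkTracks(list(0:9, 1L, 10, 10)),
               mkTracks(list(0:9, 2L, 50, 50)),
               mkTracks(list(0:9, 3L, 90, 90)))
  pred <- rbind(mkTracks(list(0:8, 11L, 10, 10)),  # 9/10 -> MT
                mkTracks(list(0L, 12L, 50, 50)),   # 1/10 -> ML
                mkTracks(list(0:4, 13L, 90, 90)))  # 5/10 -> neither
  mm <- mtMl(pred, ref)
  expect_equal(unname(mm["mt"]), 100 / 3)
  expect_equal(unname(mm["ml"]), 100 / 3)
})

test_that("ideal input scores 1/1/1/100/0 across the tracking suite", {
  vid <- generateSequence(sceneConfig(nCells = 6L, nFrames = 8L,
                                      motionSigma = 1, seed = 31L))
  rt <- do.call(rbind, lapply(seq_along(masks(vid)), function(f) {
    b <- boxesFromMask(masks(vid)[[f]])
    data.frame(frame = f - 1L, id = b$label, x = b$x, y = b$y, w = b$w,
               h = b$h)
  }))
  m <- trackMatch(rt, rt)
  expect_equal(motaScore(m), 1)
  expect_equal(completeTracks(rt, rt, match = m), 1)
  expect_equal(trackFraction(rt, rt, match = m), 1)
  mm <- mtMl(rt, rt, match = m)
  expect_equal(unname(mm["mt"]), 100)
  expect_equal(unname(mm["ml"]), 0)
})

test_that("density reports both conventions with the stated arithmetic", {
  mask <- matrix(0L, 40, 40)
  mask[2:4, 2:4] <- 1L; mask[10:12, 10:12] <- 2L
  d <- cellImagingDensity(mask, effectiveArea = 1000)
  expect_equal(d$areaPerCell, 500)
  expect_equal(d$cellsPerKilopixel, 2)
  # doubling the cells at fixed area halves the printed convention
  mask2 <- mask; mask2[20:22, 20:22] <- 3L; mask2[30:32, 30:32] <- 4L
  d2 <- cellImagingDensity(mask2, effectiveArea = 1000)
  expect_equal(d2$areaPerCell, d$areaPerCell / 2)
  expect_error(cellImagingDensity(matrix(0L, 5, 5)), "zero cells")
})
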