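# Adaptation objectives and machinery: entropy, BNM (vs an SVD oracle),
# the similarity kernel, centers, the printed CMC form, patch tiling, and
# the BN-only update contract.

test_that("Shannon entropy matches closed forms and direct arithmetic", {
  expect_equal(shannonEntropyLoss(matrix(0.5, 4, 4)), log(2))
  expect_equal(shannonEntropyLoss(matrix(c(1, 0), 1, 2)), 0)
  # p = (0.9, 0.1): -(0.9 log 0.9 + 0.1 log 0.1)
  expect_equal(shannonEntropyLoss(matrix(c(0.9, 0.1), 1, 2)),
               -(0.9 * log(0.9) + 0.1 * log(0.1)), tolerance = 1e-10)
  expect_equal(round(shannonEntropyLoss(matrix(c(0.9, 0.1), 1, 2)), 5),
               0.32508)
  expect_error(shannonEntropyLoss(matrix(c(-0.1, 1.1), 1, 2)), "negative")
  # extremes: one-hot minimizes, uniform maximizes at log C
  set.seed(1)
  for (C in 2:4) {
    A <- matrix(runif(5 * C), 5); A <- A / rowSums(A)
    e <- shannonEntropyLoss(A)
    expect_gte(e, 0); expect_lte(e, log(C) + 1e-12)
  }
})

test_that("BNM loss equals the negative mean nuclear norm (SVD oracle)", {
  expect_equal(bnmLoss(diag(2)), -1)
  for (B in c(2, 5, 9)) {
    A <- matrix(rep(c(1, 0), each = B), B, 2)[, 1:2]
    A <- matrix(c(rep(1, B), rep(0, B)), B, 2)
    expect_equal(bnmLoss(A), -1 / sqrt(B), tolerance = 1e-12)
  }
  set.seed(2)
  for (i in 1:100) {
    B <- sample(2:16, 1); C <- sample(2:8, 1)
    A <- matrix(runif(B * C), B, C)
    oracle <- -sum(svd(A)$d) / B
    expect_equal(bnmLoss(A), oracle, tolerance = 1e-6)
  }
  expect_error(bnmLoss(matrix(c(1, NA), 1, 2)), "non-finite")
})

test_that("entire-image loss combines entropy and BNM linearly in alpha", {
  p <- matrix(runif(64), 8, 8)
  A <- cmtt:::probsToResponses(p)
  expect_equal(entireImageLoss(p, A, alpha = 0),
               shannonEntropyLoss(p))
  ent <- shannonEntropyLoss(p); bn <- bnmLoss(A)
  expect_equal(entireImageLoss(p, A, alpha = 0.5), ent + 0.5 * bn)
  # affine in alpha at three points
  l <- vapply(c(0, 1, 2), function(a) entireImageLoss(p, A, a), numeric(1))
  expect_equal(l[3] - l[2], l[2] - l[1], tolerance = 1e-10)
  expect_error(entireImageLoss(p, A, alpha = -1), "alpha")
})

test_that("phi is the normalized inverse squared Euclidean distance", {
  expect_equal(phiSimilarity(0.3, 0.3), 1)
  expect_equal(phiSimilarity(0, 1), 0.5)
  expect_equal(phiSimilarity(2, 2 + sqrt(3)), 0.25)
  x <- runif(10)
  expect_true(all(phiSimilarity(x, 0.5) > 0 & phiSimilarity(x, 0.5) <= 1))
})

test_that("computeCenter takes the background statistic with fallback", {
  patch <- matrix(c(0.1, 0.2, 0.3, 0.9), 2, 2)
  m <- matrix(c(0, 0, 0, 1), 2, 2)
  expect_equal(computeCenter(patch, m, "median")$delta, 0.2)
  expect_equal(computeCenter(patch, m, "mean")$delta, 0.2)
  allCell <- matrix(1, 2, 2)
  expect_warning(
    out <- computeCenter(patch, allCell, "median", globalBackground = 0.15),
    "falling back")
  expect_true(out$fallback)
  expect_equal(out$delta, 0.15)
  expect_error(computeCenter(patch, allCell, "median"), "no global fallback")
})

test_that("cmcLoss reproduces the printed form on worked cases", {
  # balanced sums -> log 2
  px <- c(0.2, 0.2, 0.2, 0.2)
  expect_equal(cmcLoss(px, c(1, 2), c(3, 4), 0.2), log(2))
  # empty P- -> -log 1 = 0
  expect_equal(cmcLoss(px, 1:4, integer(0), 0.2), 0)
  # 3 cell pixels at delta (phi = 1), 2 background with phi -> 0:
  # -log(3e / (3e + 2 e^phi0)); phi -> 0 needs a huge distance, use the
  # exact finite version with e^phi at the actual values
  pxe <- c(0.5, 0.5, 0.5, 1000, 1000)
  got <- cmcLoss(pxe, 1:3, 4:5, 0.5)
  phi0 <- 1 / (1 + (1000 - 0.5)^2)
  expect_equal(got, -log(3 * exp(1) / (3 * exp(1) + 2 * exp(phi0))),
               tolerance = 1e-12)
  expect_equal(got, 0.2194, tolerance = 1e-3)
  expect_warning(expect_true(is.na(cmcLoss(px, integer(0), 1:2, 0.2))),
                 "P\\+ is empty")
  expect_error(cmcLoss(px, 1:2, 2:3, 0.2), "disjoint")
})

test_that("cmc objective decreases when P- moves away from the center", {
  base <- c(0.8, 0.8, 0.3, 0.3)
  l1 <- cmcLoss(base, 1:2, 3:4, 0.3)
  moved <- c(0.8, 0.8, 0.6, 0.3)  # one background pixel leaves delta
  l2 <- cmcLoss(moved, 1:2, 3:4, 0.3)
  expect_lt(l2, l1)
})

test_that("patch grids cover the frame and stitch to the identity", {
  img <- matrix(runif(256 * 256), 256, 256)
  g0 <- splitPatches(img, 128, 0)
  expect_identical(length(g0$patches), 4L)
  g64 <- splitPatches(img, 128, 64)
  expect_identical(length(g64$patches), 9L)
  # partition of unity
  tot <- Reduce(`+`, lapply(seq_along(g64$patches), function(k) {
    m <- matrix(0, 256, 256)
    p <- g64$patches[[k]]
    m[p["row0"]:(p["row0"] + 127), p["col0"]:(p["col0"] + 127)] <-
      g64$weights[[k]]
    m
  }))
  expect_lt(max(abs(tot - 1)), 1e-12)
  # stitching crops of a known map reproduces it exactly
  rec <- stitchPatches(g64, g64$pixels)
  expect_equal(rec, img, tolerance = 1e-12)
  expect_error(splitPatches(img, 128, 128), "overlap")
  expect_error(splitPatches(img, 8), "patchSize")
  expect_error(splitPatches(matrix(0, 64, 64), 128), "exceeds")
})

test_that("adaptableParameters returns exactly the BN affine entries", {
  m <- segModel(seed = 1L)
  part <- parameterPartition(m)
  nms <- adaptableParameters(m)
  expect_setequal(nms, part$bnAffineNames)
  expect_identical(part$bnAffine + part$other, part$total)
  # each BN layer over P features contributes exactly 2P entries
  bnC <- vapply(Filter(function(nd) nd$op == "bn", m@graph),
                function(nd) as.integer(nd$C), integer(1))
  expect_identical(part$bnAffine, 2L * sum(bnC))
})

test_that("adaptation updates BN only and leaves other weights bit-exact", {
  m <- trainedSegModel()
  tgt <- lapply(1:4, function(s)
    applyDomainShift(generateFrame(targetSceneCfg(600L + s))$image,
                     targetShiftCfg()))
  cfg <- adaptConfig(stage1Epochs = 2L, stage2Epochs = 1L,
                     patchSize = 48L, patchOverlap = 16L, seed = 1L)
  out <- cmttAdapt(m, tgt, cfg)
  part <- parameterPartition(m)
  for (nm in part$otherNames)
    expect_identical(out$model@params[[nm]], m@params[[nm]])
  expect_false(identical(out$model@params[part$bnAffineNames],
                         m@params[part$bnAffineNames]))
  # BN statistics are re-estimated from the shifted target distribution
  expect_false(identical(out$model@state, m@state))
})

test_that("stage 1 with zero epochs is the identity; losses descend", {
  m <- trainedSegModel()
  tgt <- lapply(1:4, function(s)
    applyDomainShift(generateFrame(targetSceneCfg(600L + s))$image,
                     targetShiftCfg()))
  s0 <- adaptStage1(m, tgt, adaptConfig(stage1Epochs = 0L))
  expect_identical(s0$model@params, m@params)
  expect_equal(s0$pred, lapply(tgt, function(im) predictMask(m, im)))
  s1 <- adaptStage1(m, tgt, adaptConfig(stage1Epochs = 4L, seed = 2L))
  expect_lt(tail(s1$log$loss, 1), s1$log$loss[1])
  s2 <- adaptStage2(s1$model, tgt, s1$pred,
                    adaptConfig(stage2Epochs = 3L, patchSize = 48L,
                                patchOverlap = 16L, seed = 2L))
  expect_lt(tail(s2$log$loss, 1), s2$log$loss[1])
  expect_error(adaptStage1(m, list(), adaptConfig()), "empty target")
})

test_that("background-only targets abort stage 2 via the skip path", {
  m <- trainedSegModel()
  flat <- list(matrix(0.25, 96, 96))
  pred1 <- list(matrix(0.01, 96, 96))
  expect_error(
    adaptStage2(m, flat, pred1, adaptConfig(patchSize = 48L,
                                            patchOverlap = 16L)),
    "all patches skipped")
})

test_that("aggregation is the convex combination of the two predictions", {
  p1 <- matrix(0.2, 4, 4); p2 <- matrix(0.6, 4, 4)
  expect_identical(aggregatePredictions(p1, p2, 1), p1)
  expect_identical(aggregatePredictions(p1, p2, 0), p2)
  expect_equal(aggregatePredictions(p1, p2, 0.5)[1, 1], 0.4)
  expect_error(aggregatePredictions(p1, p2, 1.5), "w")
})
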