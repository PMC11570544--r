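# Detection / ReID head kernels against arithmetic and geometry oracles,
# spatial attention properties, and the embedding branch contracts.

test_that("anchor assignment floors centers and resolves collisions", {
  b <- data.frame(x = 100, y = 60, w = 10, h = 10)
  a <- assignPositives(b, 8L, 12L, 16L)
  expect_identical(a$grid[60 %/% 8 + 1, 100 %/% 8 + 1], 1L)
  expect_identical(sum(a$grid > 0), 1L)
  b2 <- data.frame(x = 7, y = 7, w = 4, h = 4)
  a2 <- assignPositives(b2, 8L, 4L, 4L)
  expect_identical(a2$grid[1, 1], 1L)
  # collision: larger box wins
  b3 <- data.frame(x = c(100, 101), y = c(60, 61), w = c(8, 12),
                   h = c(8, 12))
  a3 <- assignPositives(b3, 8L, 12L, 16L)
  expect_identical(a3$collisions, 1L)
  expect_identical(a3$grid[8, 13], 2L)
  expect_error(assignPositives(data.frame(x = 500, y = 10, w = 2, h = 2),
                               8L, 12L, 12L), "outside")
})

test_that("focal loss matches direct arithmetic at both classes", {
  # positive, p = 0.9: -0.25 * 0.1^2 * ln 0.9
  expect_equal(focalLoss(0.9, TRUE), -0.25 * 0.01 * log(0.9))
  expect_equal(focalLoss(0.9, TRUE), 2.634e-4, tolerance = 1e-4)
  # negative, p = 0.9 (p_t = 0.1): -0.25 * 0.9^2 * ln 0.1
  expect_equal(focalLoss(0.9, FALSE), -0.25 * 0.81 * log(0.1))
  expect_equal(focalLoss(0.9, FALSE), 0.4663, tolerance = 1e-4)
  # p_t -> 1 drives the loss to 0
  expect_lt(focalLoss(1 - 1e-7, TRUE), 1e-12)
  # standard-alpha compatibility switch weights negatives by 1 - alpha
  expect_equal(focalLoss(0.9, FALSE, focalConfig(printedAlpha = FALSE)),
               -0.75 * 0.81 * log(0.1))
  # randomized check of the printed formula
  set.seed(3)
  p <- runif(100, 0.01, 0.99); pos <- runif(100) > 0.5
  pt <- ifelse(pos, p, 1 - p)
  expect_equal(focalLoss(p, pos), -0.25 * (1 - pt)^2 * log(pt))
})

test_that("ciou equals an independent geometry oracle", {
  # identical boxes: loss 0
  expect_equal(ciouLoss(c(5, 5, 10, 10), c(5, 5, 10, 10)), 0,
               tolerance = 1e-12)
  # non-positive anchors contribute 0
  expect_equal(ciouLoss(c(0, 0, 10, 10), c(5, 5, 10, 10),
                        positive = FALSE), 0)
  expect_error(ciouLoss(c(0, 0, 0, 10), c(5, 5, 10, 10)), "degenerate")
  # independent implementation of the CIOU definition
  ciouOracle <- function(p, g) {
    inter <- max(0, min(p[1] + p[3] / 2, g[1] + g[3] / 2) -
                    max(p[1] - p[3] / 2, g[1] - g[3] / 2)) *
             max(0, min(p[2] + p[4] / 2, g[2] + g[4] / 2) -
                    max(p[2] - p[4] / 2, g[2] - g[4] / 2))
    u <- p[3] * p[4] + g[3] * g[4] - inter
    i <- inter / u
    rho2 <- (p[1] - g[1])^2 + (p[2] - g[2])^2
    cw <- max(p[1] + p[3] / 2, g[1] + g[3] / 2) -
          min(p[1] - p[3] / 2, g[1] - g[3] / 2)
    ch <- max(p[2] + p[4] / 2, g[2] + g[4] / 2) -
          min(p[2] - p[4] / 2, g[2] - g[4] / 2)
    v <- 4 / pi^2 * (atan(g[3] / g[4]) - atan(p[3] / p[4]))^2
    i - rho2 / (cw^2 + ch^2) - v^2 / ((1 - i) + v)
  }
  expect_equal(ciouLoss(c(0, 0, 10, 10), c(5, 5, 10, 10)),
               1 - ciouOracle(c(0, 0, 10, 10), c(5, 5, 10, 10)),
               tolerance = 1e-6)
  set.seed(4)
  for (i in 1:100) {
    p <- c(runif(2, 0, 20), runif(2, 2, 15))
    g <- c(runif(2, 0, 20), runif(2, 2, 15))
    expect_equal(ciouLoss(p, g), 1 - ciouOracle(p, g), tolerance = 1e-6)
  }
})

test_that("detection loss normalizes the weighted sum by N_pos", {
  expect_equal(detectionLoss(0, 0, 5), 0)
  cls <- c(0.2, 0.1, 0.3); reg <- c(0.5, 0, 0.2)
  expect_equal(detectionLoss(cls, reg, 2),
               (sum(cls) + 0.05 * sum(reg)) / 2)
  expect_equal(detectionLoss(cls, reg, 2, lossWeights(betaC = 0)),
               sum(cls) / 2)
  expect_error(detectionLoss(cls, reg, 0), "nPos")
})

test_that("reid loss reports the printed (sign-free) and negative forms", {
  D <- 8L; C <- 4L
  W <- matrix(0, D, C); b <- numeric(C)
  emb <- matrix(rnorm(D), 1, D)
  rl <- reidLoss(emb, 2L, W, b)  # uniform predictions
  expect_equal(rl$printed, log(1 / 4), tolerance = 1e-12)
  expect_equal(rl$printed, -1.3863, tolerance = 1e-4)
  expect_equal(rl$negative, -rl$printed)
  # perfect predictions: printed form 0
  b2 <- c(-50, 50, -50, -50)
  expect_equal(reidLoss(emb, 2L, W, b2)$printed, 0, tolerance = 1e-10)
  # N identical objects average to the single-object value
  embN <- emb[rep(1, 5), , drop = FALSE]
  expect_equal(reidLoss(embN, rep(2L, 5), W, b)$printed, rl$printed)
  expect_error(reidLoss(emb, 7L, W, b), "outside")
})

test_that("total loss is affine in eta", {
  expect_equal(totalLoss(1, 2, 0), 1)
  expect_equal(totalLoss(1, 2, 0.05), 1.1)
  l <- vapply(c(0, 0.5, 1), function(e) totalLoss(0.3, 1.7, e), numeric(1))
  expect_equal(l[3] - l[2], l[2] - l[1])
})

test_that("nms matches a brute-force subset oracle on small inputs", {
  two <- data.frame(x = c(5, 5), y = c(5, 5), w = c(10, 10),
                    h = c(10, 10), score = c(0.9, 0.8))
  expect_identical(nrow(nms(two, 0.5)), 1L)
  expect_equal(nms(two, 0.5)$score, 0.9)
  disj <- data.frame(x = c(5, 50), y = c(5, 50), w = c(10, 10),
                     h = c(10, 10), score = c(0.9, 0.8))
  expect_identical(nrow(nms(disj, 0.5)), 2L)
  # oracle: greedy-by-score is the NMS definition; verify the survivor
  # set satisfies maximality and the pairwise constraint on random cases
  set.seed(5)
  for (rep in 1:20) {
    n <- sample(3:6, 1)
    bx <- data.frame(x = runif(n, 0, 30), y = runif(n, 0, 30),
                     w = runif(n, 5, 15), h = runif(n, 5, 15),
                     score = runif(n))
    kept <- nms(bx, 0.4)
    io <- boxIou(kept, kept); diag(io) <- 0
    expect_true(all(io <= 0.4 + 1e-12))
    # every suppressed box overlaps a kept box of higher score
    drop <- bx[!rownames(bx) %in% rownames(kept), , drop = FALSE]
    if (nrow(drop)) for (i in seq_len(nrow(drop))) {
      io2 <- boxIou(drop[i, , drop = FALSE], kept)
      better <- kept$score >= drop$score[i]
      expect_true(any(io2[1, better] > 0.4))
    }
  }
})

test_that("spatial attention maps are sigmoid-bounded and shift-covariant", {
  set.seed(6)
  feat <- array(rnorm(16 * 16 * 4), c(16, 16, 4))
  att <- spatialAttention(feat, seed = 2L)
  expect_identical(dim(att), c(16L, 16L))
  expect_true(all(att > 0 & att < 1))
  # spatially constant input -> constant attention away from borders
  featC <- array(rep(rnorm(4), each = 16 * 16), c(16, 16, 4))
  attC <- spatialAttention(featC, seed = 2L)
  inner <- attC[4:13, 4:13]
  expect_lt(max(inner) - min(inner), 1e-12)
  # single-channel input still yields a well-formed map
  att1 <- spatialAttention(array(rnorm(64), c(8, 8, 1)), seed = 3L)
  expect_identical(dim(att1), c(8L, 8L))
})

test_that("the ReID branch emits a stride-8 embedding map deterministically", {
  m <- segModel(seed = 2L)
  jm <- jointModel(m, nIds = 5L, embedDim = 32L, seed = 3L)
  img <- generateFrame(sceneConfig(frameSize = 96L, nCells = 5L,
                                   seed = 31L))$image
  py <- extractPyramid(m, img)
  e1 <- saReidForward(jm, py)
  expect_identical(dim(e1), c(12L, 12L, 32L))
  expect_identical(e1, saReidForward(jm, py))
  expect_error(saReidForward(jm, py[c("p8", "p16")]), "pyramid")
  # zero attention would fuse to the identity: f + f * 0 = f
  f <- matrix(rnorm(20), 4, 5)
  expect_identical(f + f * 0, f)
})

test_that("head training reduces the joint loss in trend", {
  m <- trainedSegModel()
  d <- sourceFrames()
  gtb <- lapply(d$masks, function(mk) {
    b <- boxesFromMask(mk); b$id <- b$label; b
  })
  jm <- jointModel(m, nIds = 10L, embedDim = 32L, seed = 4L)
  jm <- trainJointHead(jm, d$images[1:5], gtb[1:5], epochs = 25L,
                       learningRate = 5e-3, seed = 5L)
  lg <- jm@trainLog
  expect_lt(mean(tail(lg$total, 5)), mean(head(lg$total, 5)))
  expect_lt(tail(lg$det, 1), lg$det[1])
})
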