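# Association: optimal assignment vs permutation oracle, Kalman sanity,
# frame linking behaviour and lineage construction.

permutations <- function(v) {
  if (length(v) <= 1) return(list(v))
  do.call(c, lapply(seq_along(v), function(i)
    lapply(permutations(v[-i]), function(p) c(v[i], p))))
}

test_that("hungarian equals the brute-force minimum over permutations", {
  set.seed(10)
  for (rep in 1:40) {
    n <- sample(1:6, 1); m <- sample(1:6, 1)
    cost <- matrix(runif(n * m), n, m)
    a <- hungarian(cost)
    got <- sum(cost[cbind(which(a > 0), a[a > 0])])
    k <- min(n, m)
    best <- Inf
    for (rows in utils::combn(seq_len(n), k, simplify = FALSE))
      for (p in permutations(seq_len(m)))
        best <- min(best, sum(cost[cbind(rows, p[seq_len(k)])]))
    expect_equal(got, best, tolerance = 1e-9)
  }
  # hand case
  cost <- matrix(c(4, 2, 8, 4, 3, 7, 3, 1, 6), 3, 3, byrow = TRUE)
  a <- hungarian(cost)
  expect_equal(sum(cost[cbind(1:3, a)]), 12)  # enumerated minimum
})

test_that("the constant-velocity filter tracks linear motion", {
  kf <- cmtt:::kfInit(c(10, 10, 5, 5))
  for (t in 1:12) {
    kf <- cmtt:::kfPredict(kf)
    kf <- cmtt:::kfUpdate(kf, c(10 + 2 * t, 10 - t, 5, 5))
  }
  pred <- cmtt:::kfPredict(kf)
  expect_equal(pred$x[1], 10 + 2 * 13, tolerance = 0.8)
  expect_equal(pred$x[2], 10 - 13, tolerance = 0.8)
  expect_equal(pred$x[5], 2, tolerance = 0.3)
})

mkDet <- function(boxes, D = 8L, seedEmb = 1L) {
  set.seed(seedEmb)
  list(boxes = cbind(boxes, score = rep(0.9, nrow(boxes))),
       emb = matrix(rnorm(nrow(boxes) * D), nrow(boxes), D))
}

test_that("matching preserves ids and handles empty frames", {
  b0 <- data.frame(x = 10, y = 10, w = 8, h = 8)
  st <- associateFrame(list(), mkDet(b0), 0L)
  expect_identical(length(st$tracklets), 1L)
  id0 <- st$tracklets[[1]]$id
  # same embedding, predicted location -> same id
  d1 <- mkDet(data.frame(x = 11, y = 10, w = 8, h = 8))
  st2 <- associateFrame(st$tracklets, d1, 1L, nextId = st$nextId)
  expect_identical(st2$tracklets[[1]]$id, id0)
  expect_identical(st2$tracklets[[1]]$frames, c(0L, 1L))
  # zero detections -> tracklet marked lost
  st3 <- associateFrame(st2$tracklets,
                        list(boxes = NULL, emb = NULL), 2L,
                        nextId = st2$nextId)
  expect_identical(st3$tracklets[[1]]$status, "lost")
})

test_that("well-separated constant cells keep one tracklet each", {
  boxes <- data.frame(x = c(10, 40, 70), y = c(10, 40, 70),
                      w = rep(8, 3), h = rep(8, 3))
  detList <- lapply(1:8, function(f) mkDet(boxes, seedEmb = 99L))
  ts <- trackDetections(detList)
  expect_identical(length(ts@tracks), 3L)
  for (t in ts@tracks) expect_identical(t$frames, 0:7)
})

test_that("lineage tables carry spans and division parents", {
  boxes <- data.frame(x = 20, y = 20, w = 8, h = 8)
  detList <- lapply(1:10, function(f) mkDet(boxes, seedEmb = 7L))
  ts <- trackDetections(detList)
  tab <- buildLineage(ts)
  expect_identical(nrow(tab), 1L)
  expect_identical(tab$begin, 0L)
  expect_identical(tab$end, 9L)
  expect_identical(tab$parent, 0L)
  # empty input
  empty <- trackDetections(list(list(boxes = NULL, emb = NULL)))
  expect_identical(nrow(buildLineage(empty)), 0L)
})

test_that("a simulated division with ideal detections links the parent", {
  cfg <- sceneConfig(frameSize = 96L, nCells = 1L, nFrames = 3L,
                     divisionProb = 1, motionSigma = 0,
                     cellRadiusRange = c(7, 8), seed = 21L)
  vid <- generateSequence(cfg)
  # the generator's own table: one parent, two children born at frame 2
  expect_identical(nrow(trackTable(vid)), 3L)
  # ideal detections from the ground-truth masks; distinct embeddings
  detList <- lapply(masks(vid), function(mk) {
    b <- boxesFromMask(mk)
    set.seed(sum(b$label))
    list(boxes = data.frame(x = b$x, y = b$y, w = b$w, h = b$h,
                            score = 0.95),
         emb = matrix(rnorm(nrow(b) * 8), nrow(b), 8))
  })
  ts <- trackDetections(detList, assocConfig(divisionGate = 12))
  tab <- buildLineage(ts, assocConfig(divisionGate = 12))
  # one parent track ends, two children begin the next frame with the
  # parent's id recorded, mirroring the generator's table
  expect_identical(nrow(tab), 3L)
  children <- tab[tab$parent != 0, , drop = FALSE]
  expect_identical(nrow(children), 2L)
  par <- unique(children$parent)
  expect_identical(length(par), 1L)
  expect_identical(unique(children$begin), 2L)
  expect_identical(tab$end[tab$label == par], 1L)
})
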