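# The NN core must be numerically exact: analytic gradients of every
# primitive are compared with central finite differences on small graphs.

test_that("conv/bn/activation gradients match finite differences", {
  set.seed(7)
  g <- list(nnNode("img", "input"),
            nnNode("c1", "conv", "img", k = 3L, s = 1L, pad = 1L,
                   cin = 1L, cout = 3L),
            nnNode("b1", "bn", "c1", C = 3L),
            nnNode("r1", "relu", "b1"),
            nnNode("c2", "conv", "r1", k = 2L, s = 2L, pad = 0L,
                   cin = 3L, cout = 2L),
            nnNode("cp", "chanpool", "c2"),
            nnNode("c3", "conv", "cp", k = 1L, s = 1L, pad = 0L,
                   cin = 2L, cout = 1L),
            nnNode("out", "sigmoid", "c3"))
  ini <- cmtt:::graphInitParams(g)
  x <- cmtt:::imagesToTensor(list(matrix(runif(49), 7, 7),
                                  matrix(runif(49), 7, 7)))
  lossOf <- function(params, xt = x) {
    fwd <- cmtt:::graphForward(g, params, ini$state, list(img = xt),
                               training = TRUE)
    sum(fwd$vals$out$x^2)
  }
  fwd <- cmtt:::graphForward(g, ini$params, ini$state, list(img = x),
                             training = TRUE)
  bk <- cmtt:::graphBackward(g, ini$params, fwd,
                             list(out = 2 * fwd$vals$out$x))
  for (nm in names(ini$params)) {
    idx <- seq_len(min(5, length(ini$params[[nm]])))
    num <- vapply(idx, function(j) {
      pp <- ini$params; pp[[nm]][j] <- pp[[nm]][j] + 1e-5
      pm <- ini$params; pm[[nm]][j] <- pm[[nm]][j] - 1e-5
      (lossOf(pp) - lossOf(pm)) / 2e-5
    }, numeric(1))
    expect_lt(max(abs(num - bk$dparams[[nm]][idx])), 1e-6)
  }
  num <- vapply(1:6, function(j) {
    xp <- x; xp$x[j] <- xp$x[j] + 1e-5
    xm <- x; xm$x[j] <- xm$x[j] - 1e-5
    (lossOf(ini$params, xp) - lossOf(ini$params, xm)) / 2e-5
  }, numeric(1))
  expect_lt(max(abs(num - bk$dvals$img[1:6, 1])), 1e-6)
})

test_that("resize/mul/add graph (attention-style) gradients are exact", {
  set.seed(8)
  g <- list(nnNode("a", "input"), nnNode("b", "input"),
            nnNode("up", "resize", c("b", "a")),
            nnNode("cp", "chanpool", "up"),
            nnNode("at", "conv", "cp", k = 7L, s = 1L, pad = 3L,
                   cin = 2L, cout = 1L),
            nnNode("sg", "sigmoid", "at"),
            nnNode("ml", "mul", c("up", "sg")),
            nnNode("fs", "add", c("up", "ml")),
            nnNode("out", "conv", "fs", k = 3L, s = 1L, pad = 1L,
                   cin = 2L, cout = 1L))
  ini <- cmtt:::graphInitParams(g)
  a <- cmtt:::nnTensor(matrix(runif(64 * 1), 64, 1), 1L, 8L, 8L)
  b <- cmtt:::nnTensor(matrix(runif(16 * 2), 16, 2), 1L, 4L, 4L)
  lossOf <- function(params, bt = b) {
    fwd <- cmtt:::graphForward(g, params, ini$state,
                               list(a = a, b = bt))
    sum(fwd$vals$out$x^2)
  }
  fwd <- cmtt:::graphForward(g, ini$params, ini$state, list(a = a, b = b))
  bk <- cmtt:::graphBackward(g, ini$params, fwd,
                             list(out = 2 * fwd$vals$out$x))
  for (nm in names(ini$params)) {
    idx <- seq_len(min(4, length(ini$params[[nm]])))
    num <- vapply(idx, function(j) {
      pp <- ini$params; pp[[nm]][j] <- pp[[nm]][j] + 1e-5
      pm <- ini$params; pm[[nm]][j] <- pm[[nm]][j] - 1e-5
      (lossOf(pp) - lossOf(pm)) / 2e-5
    }, numeric(1))
    expect_lt(max(abs(num - bk$dparams[[nm]][idx])), 1e-6)
  }
  num <- vapply(1:6, function(j) {
    bp <- b; bp$x[j] <- bp$x[j] + 1e-5
    bm <- b; bm$x[j] <- bm$x[j] - 1e-5
    (lossOf(ini$params, bp) - lossOf(ini$params, bm)) / 2e-5
  }, numeric(1))
  expect_lt(max(abs(num - bk$dvals$b[1:6, 1])), 1e-6)
})

test_that("BN layer centers and standardizes, then applies gamma/beta", {
  set.seed(9)
  x <- matrix(rnorm(200, mean = 3, sd = 2), 100, 2)
  out <- cmtt:::bnForward(x, gamma = c(2, 0.5), beta = c(1, -1),
                          rmean = c(0, 0), rvar = c(1, 1),
                          training = TRUE)
  xhat <- out$xhat
  expect_lt(max(abs(colMeans(xhat))), 1e-10)
  expect_lt(max(abs(apply(xhat, 2, function(v) mean(v^2)) - 1)), 1e-3)
  expect_equal(out$y[, 1], 2 * xhat[, 1] + 1)
  expect_equal(out$y[, 2], 0.5 * xhat[, 2] - 1)
  # running statistics move toward the batch statistics
  expect_gt(out$rmean[1], 0)
})

test_that("forward passes are deterministic and shape-correct", {
  m <- segModel(seed = 3L)
  img <- matrix(runif(96 * 96), 96, 96)
  p1 <- predictMask(m, img)
  p2 <- predictMask(m, img)
  expect_identical(p1, p2)
  expect_identical(dim(p1), dim(img))
  expect_true(all(p1 >= 0 & p1 <= 1))
})
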