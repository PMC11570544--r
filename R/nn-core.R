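# Compact CPU neural-network core used by the segmentation unit and the
# joint tracking head. Feature maps are stored as (N*H*W) x C matrices
# (row-major within an image: row index = (r-1)*W + c), which turns every
# convolution into one im2col gather plus one BLAS matrix multiply.

#' Evaluate code with a temporary RNG seed
#'
#' Saves and restores the global RNG state so seeded internals never
#' perturb a caller's random stream.
#'
#' @param seed Integer seed.
#' @param code Code to evaluate.
#' @return The value of `code`.
#' @keywords internal
withSeed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# ---- tensors ---------------------------------------------------------------

nnTensor <- function(x, N, H, W) {
  stopifnot(nrow(x) == N * H * W)
  list(x = x, N = N, H = H, W = W, C = ncol(x))
}

# stack a list of H x W matrices (single channel) into a tensor
imagesToTensor <- function(imgs) {
  H <- nrow(imgs[[1]]); W <- ncol(imgs[[1]])
  x <- do.call(rbind, lapply(imgs, function(im) matrix(t(im), ncol = 1)))
  nnTensor(x, length(imgs), H, W)
}

# channel 1 of image n back to an H x W matrix
tensorToImage <- function(t, n = 1L, channel = 1L) {
  off <- (n - 1L) * t$H * t$W
  matrix(t$x[off + seq_len(t$H * t$W), channel], t$H, t$W, byrow = TRUE)
}

# ---- im2col index cache ----------------------------------------------------

.nn_cache <- new.env(parent = emptyenv())

convOutSize <- function(H, k, s, pad) (H + 2L * pad - k) %/% s + 1L

# index matrix (Ho*Wo, k*k) into a padded image vector of length H*W+1
# (row H*W+1 is the zero padding row)
im2colIndex <- function(H, W, k, s, pad) {
  key <- paste("i2c", H, W, k, s, pad, sep = "_")
  if (!is.null(.nn_cache[[key]])) return(.nn_cache[[key]])
  Ho <- convOutSize(H, k, s, pad); Wo <- convOutSize(W, k, s, pad)
  ro <- rep(seq_len(Ho), each = Wo); co <- rep(seq_len(Wo), Ho)
  idx <- matrix(0L, Ho * Wo, k * k)
  for (kr in seq_len(k)) for (kc in seq_len(k)) {
    rr <- (ro - 1L) * s - pad + kr
    cc <- (co - 1L) * s - pad + kc
    inside <- rr >= 1L & rr <= H & cc >= 1L & cc <= W
    idx[, (kr - 1L) * k + kc] <- ifelse(inside, (rr - 1L) * W + cc, H * W + 1L)
  }
  res <- list(idx = idx, Ho = Ho, Wo = Wo)
  .nn_cache[[key]] <- res
  res
}

# ---- primitive forward/backward -------------------------------------------

# 0-based im2col index with -1 marking padding, for the compiled kernels
im2colIndex0 <- function(H, W, k, s, pad) {
  key <- paste("i2c0", H, W, k, s, pad, sep = "_")
  if (!is.null(.nn_cache[[key]])) return(.nn_cache[[key]])
  ii <- im2colIndex(H, W, k, s, pad)
  idx0 <- ii$idx - 1L
  idx0[ii$idx == H * W + 1L] <- -1L
  res <- list(idx = idx0, Ho = ii$Ho, Wo = ii$Wo)
  .nn_cache[[key]] <- res
  res
}

convForward <- function(t, Wm, b, k, s, pad) {
  ii <- im2colIndex0(t$H, t$W, k, s, pad)
  y <- .convForwardCpp(t$x, t$N, t$H * t$W, ii$idx, Wm, as.numeric(b))
  nnTensor(y, t$N, ii$Ho, ii$Wo)
}

convBackward <- function(t, dY, Wm, k, s, pad) {
  ii <- im2colIndex0(t$H, t$W, k, s, pad)
  .convBackwardCpp(t$x, dY, t$N, t$H * t$W, ii$idx, Wm)
}

bnForward <- function(x, gamma, beta, rmean, rvar, training, momentum = 0.1,
                      eps = 1e-5) {
  if (training) {
    mu <- colMeans(x)
    xc <- sweep(x, 2L, mu)
    v <- colMeans(xc * xc)
    rmean <- (1 - momentum) * rmean + momentum * mu
    rvar <- (1 - momentum) * rvar + momentum * v
  } else {
    mu <- rmean; v <- rvar
    xc <- sweep(x, 2L, mu)
  }
  invstd <- 1 / sqrt(v + eps)
  xhat <- sweep(xc, 2L, invstd, "*")
  y <- sweep(sweep(xhat, 2L, gamma, "*"), 2L, beta, "+")
  list(y = y, xhat = xhat, invstd = invstd, rmean = rmean, rvar = rvar,
       training = training)
}

bnBackward <- function(dY, cache, gamma) {
  xhat <- cache$xhat; invstd <- cache$invstd
  dgamma <- colSums(dY * xhat)
  dbeta <- colSums(dY)
  dxhat <- sweep(dY, 2L, gamma, "*")
  if (cache$training) {
    n <- nrow(dY)
    t1 <- sweep(dxhat, 2L, colMeans(dxhat))
    t2 <- sweep(xhat, 2L, colMeans(dxhat * xhat), "*")
    dX <- sweep(t1 - t2, 2L, invstd, "*")
  } else {
    dX <- sweep(dxhat, 2L, invstd, "*")
  }
  list(dX = dX, dgamma = dgamma, dbeta = dbeta)
}

resizeIndex <- function(H, W, Ho, Wo) {
  key <- paste("rz", H, W, Ho, Wo, sep = "_")
  if (!is.null(.nn_cache[[key]])) return(.nn_cache[[key]])
  rr <- pmin(H, floor((seq_len(Ho) - 0.5) * H / Ho) + 1L)
  cc <- pmin(W, floor((seq_len(Wo) - 0.5) * W / Wo) + 1L)
  idx <- as.vector(t(outer((rr - 1L) * W, cc, "+")))  # row-major order
  .nn_cache[[key]] <- idx
  idx
}

resizeForward <- function(t, Ho, Wo) {
  idx <- resizeIndex(t$H, t$W, Ho, Wo)
  big <- rep(idx, t$N) + rep((0:(t$N - 1L)) * t$H * t$W, each = Ho * Wo)
  nnTensor(t$x[big, , drop = FALSE], t$N, Ho, Wo)
}

resizeBackward <- function(dY, t, Ho, Wo) {
  idx <- resizeIndex(t$H, t$W, Ho, Wo)
  big <- rep(idx, t$N) + rep((0:(t$N - 1L)) * t$H * t$W, each = Ho * Wo)
  rs <- rowsum(dY, group = big)
  dX <- matrix(0, t$N * t$H * t$W, ncol(dY))
  dX[as.integer(rownames(rs)), ] <- rs
  dX
}

sigmoidStable <- function(z) 1 / (1 + exp(-pmin(pmax(z, -30), 30)))

# channel pooling for the spatial attention module: mean and max over channels
chanPoolForward <- function(x) {
  mx <- do.call(pmax, lapply(seq_len(ncol(x)), function(j) x[, j]))
  amax <- max.col(x, ties.method = "first")
  list(y = cbind(rowMeans(x), mx), amax = amax)
}

chanPoolBackward <- function(dY, x, amax) {
  C <- ncol(x)
  dX <- matrix(dY[, 1] / C, nrow(x), C)
  dX[cbind(seq_len(nrow(x)), amax)] <- dX[cbind(seq_len(nrow(x)), amax)] + dY[, 2]
  dX
}

# ---- Adam ------------------------------------------------------------------

adamInit <- function(params) {
  list(m = lapply(params, function(p) p * 0),
       v = lapply(params, function(p) p * 0), t = 0L)
}

adamStep <- function(params, grads, state, lr, which = names(grads),
                     beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t; bc2 <- 1 - beta2^state$t
  for (nm in which) {
    g <- grads[[nm]]
    if (is.null(g)) next
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g * g
    params[[nm]] <- params[[nm]] -
      lr * (state$m[[nm]] / bc1) / (sqrt(state$v[[nm]] / bc2) + eps)
  }
  list(params = params, state = state)
}
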