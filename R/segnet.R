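# The segmentation unit: a compact BN-everywhere encoder-decoder (U-Net
# family) trained on the source domain with a soft Dice loss. Downsampling
# uses 2x2 stride-2 convolutions so the feature pyramid sizes are exactly
# floor(H/r) x floor(W/r) for r in {8, 16, 32}.

segGraph <- function(ch = c(8, 12, 16, 24, 32, 32)) {
  g <- list(nnNode("img", "input"))
  cb <- function(g, name, inp, k, s, pad, cin, cout) {
    g <- c(g, list(
      nnNode(paste0(name, ".conv"), "conv", inp, k = k, s = s, pad = pad,
             cin = cin, cout = cout),
      nnNode(paste0(name, ".bn"), "bn", paste0(name, ".conv"), C = cout),
      nnNode(paste0(name, ".relu"), "relu", paste0(name, ".bn"))))
    g
  }
  g <- cb(g, "enc0", "img", 3L, 1L, 1L, 1L, ch[1])
  for (i in 1:5)
    g <- cb(g, paste0("down", i), paste0(if (i == 1) "enc0" else
      paste0("down", i - 1), ".relu"), 2L, 2L, 0L, ch[i], ch[i + 1])
  prev <- "down5.relu"
  for (i in 4:0) {
    skip <- if (i == 0) "enc0.relu" else paste0("down", i, ".relu")
    up <- paste0("up", i)
    g <- c(g, list(
      nnNode(paste0(up, ".rs"), "resize", c(prev, skip)),
      nnNode(paste0(up, ".cat"), "concat", c(paste0(up, ".rs"), skip))))
    cin <- ch[if (i == 4) 6 else i + 2] + ch[i + 1]
    g <- cb(g, up, paste0(up, ".cat"), 3L, 1L, 1L, cin, ch[i + 1])
    prev <- paste0(up, ".relu")
  }
  g <- c(g, list(
    nnNode("head.conv", "conv", "up0.relu", k = 1L, s = 1L, pad = 0L,
           cin = ch[1], cout = 1L),
    nnNode("prob", "sigmoid", "head.conv")))
  g
}

#' Create an untrained segmentation model
#'
#' @param baseChannels channel widths of the six encoder stages
#'   (full, 1/2, 1/4, 1/8, 1/16, 1/32).
#' @param seed seed for weight initialization.
#' @return A [SegModel-class].
#' @export
segModel <- function(baseChannels = c(8, 12, 16, 24, 32, 32), seed = 1L) {
  g <- segGraph(baseChannels)
  ini <- withSeed(seed, graphInitParams(g))
  methods::new("SegModel", graph = g, params = ini$params, state = ini$state,
               arch = list(channels = baseChannels,
                           taps = c(p8 = "down3.relu", p16 = "down4.relu",
                                    p32 = "down5.relu"),
                           tapChannels = baseChannels[4:6]),
               trainLog = data.frame(epoch = integer(), loss = numeric()))
}

#' Training configuration for the source domain
#'
#' Defaults follow the package's standard recipe: Adam, learning rate 1e-4,
#' no augmentation, train split 0.6. `epochs` defaults to 100 for real use;
#' examples and tests use far fewer.
#'
#' @param epochs number of epochs (>= 1).
#' @param learningRate Adam learning rate.
#' @param batchSize minibatch size.
#' @param split train split proportion (used by [crossValidate()] helpers).
#' @param seed RNG seed for weight updates and batching.
#' @return A named list.
#' @export
trainConfig <- function(epochs = 100L, learningRate = 1e-4, batchSize = 4L,
                        split = 0.6, seed = 1L) {
  stopifnot(epochs >= 1L, split > 0, split < 1)
  list(epochs = as.integer(epochs), learningRate = learningRate,
       batchSize = as.integer(batchSize), split = split,
       seed = as.integer(seed))
}

#' Soft Dice loss
#'
#' `1 - (2 * sum(pred*target) + eps) / (sum(pred) + sum(target) + eps)`,
#' the smoothed complement of the Dice coefficient on soft predictions.
#'
#' @param pred numeric array/matrix of probabilities in [0, 1].
#' @param target binary array/matrix of the same shape.
#' @param eps smoothing constant avoiding 0/0 on empty masks.
#' @return Scalar loss in [0, 1].
#' @examples
#' softDiceLoss(matrix(c(1, 0), 1), matrix(c(1, 0), 1))  # ~0
#' @export
softDiceLoss <- function(pred, target, eps = 1e-6) {
  if (!identical(dim(pred), dim(target)))
    stop("shape mismatch between pred and target")
  1 - (2 * sum(pred * target) + eps) / (sum(pred) + sum(target) + eps)
}

# per-image soft-Dice loss and gradient for a batched prob tensor
softDiceGrad <- function(probT, targetX, eps = 1e-6) {
  grp <- rep(seq_len(probT$N), each = probT$H * probT$W)
  Sp <- rowsum(probT$x, grp); St <- rowsum(targetX, grp)
  Spt <- rowsum(probT$x * targetX, grp)
  den <- Sp + St + eps
  loss <- mean(1 - (2 * Spt + eps) / den)
  gPer <- -(2 * targetX * den[grp, ] - (2 * Spt + eps)[grp, ]) / den[grp, ]^2
  list(loss = loss, grad = gPer / probT$N)
}

#' Partition the parameter store of a model
#'
#' Every trainable parameter is classified as BN affine (gamma/beta) or
#' "other"; BN running statistics are tracked separately and are not
#' trainable.
#'
#' @param model a [SegModel-class] or [JointModel-class].
#' @return list with `bnAffineNames`, `otherNames`, counts `bnAffine`,
#'   `other`, `total` (entry counts, not array counts).
#' @export
parameterPartition <- function(model) {
  nms <- names(model@params)
  bn <- nms[grepl("\\.(gamma|beta)$", nms)]
  ot <- setdiff(nms, bn)
  list(bnAffineNames = bn, otherNames = ot,
       bnAffine = sum(vapply(model@params[bn], length, 1L)),
       other = sum(vapply(model@params[ot], length, 1L)),
       total = sum(vapply(model@params, length, 1L)))
}

#' Train the segmentation unit on labelled source data
#'
#' Full supervised training with Adam on the soft Dice loss; no
#' augmentation, deterministic for a fixed seed.
#'
#' @param model a [SegModel-class].
#' @param images list of H x W matrices in [0, 1].
#' @param targets list of binary H x W matrices (foreground = 1).
#' @param cfg a [trainConfig()] list.
#' @param verbose print the per-epoch loss.
#' @return The trained [SegModel-class] with a filled `trainLog`.
#' @export
trainSource <- function(model, images, targets, cfg = trainConfig(),
                        verbose = FALSE) {
  if (!length(images)) stop("empty source dataset")
  stopifnot(length(images) == length(targets))
  n <- length(images)
  tgt <- lapply(targets, function(m) (m > 0) + 0)
  opt <- adamInit(model@params)
  params <- model@params; state <- model@state
  log <- data.frame(epoch = integer(), loss = numeric())
  withSeed(cfg$seed, {
    for (ep in seq_len(cfg$epochs)) {
      idx <- seq_len(n)
      lossSum <- 0; nb <- 0L
      for (start in seq(1L, n, by = cfg$batchSize)) {
        bi <- idx[start:min(n, start + cfg$batchSize - 1L)]
        tin <- imagesToTensor(images[bi])
        ttg <- do.call(rbind, lapply(tgt[bi], function(m)
          matrix(t(m), ncol = 1)))
        fwd <- graphForward(model@graph, params, state,
                            list(img = tin), training = TRUE)
        state <- fwd$state
        sd <- softDiceGrad(fwd$vals$prob, ttg)
        bk <- graphBackward(model@graph, params, fwd,
                            list(prob = sd$grad))
        st <- adamStep(params, bk$dparams, opt, cfg$learningRate)
        params <- st$params; opt <- st$state
        lossSum <- lossSum + sd$loss; nb <- nb + 1L
      }
      log <- rbind(log, data.frame(epoch = ep, loss = lossSum / nb))
      if (verbose) message(sprintf("epoch %d  soft-dice %.4f", ep,
                                   lossSum / nb))
    }
  })
  methods::initialize(model, params = params, state = state,
                      trainLog = rbind(model@trainLog, log))
}

#' Predict the foreground probability map for one frame
#'
#' Inference uses the stored BN running statistics and is deterministic.
#'
#' @param model a [SegModel-class].
#' @param image H x W matrix in [0, 1].
#' @return H x W matrix of foreground probabilities.
#' @export
predictMask <- function(model, image) {
  tin <- imagesToTensor(list(image))
  fwd <- graphForward(model@graph, model@params, model@state,
                      list(img = tin), training = FALSE)
  tensorToImage(fwd$vals$prob)
}

#' Binarize a probability map
#' @param prob probability matrix from [predictMask()].
#' @param threshold foreground threshold (default 0.5).
#' @return Binary 0/1 matrix.
#' @export
binarizeProb <- function(prob, threshold = 0.5) (prob > threshold) + 0

tensorToArray <- function(t, n = 1L) {
  off <- (n - 1L) * t$H * t$W
  a0 <- array(t$x[off + seq_len(t$H * t$W), , drop = FALSE],
              dim = c(t$W, t$H, t$C))
  aperm(a0, c(2, 1, 3))
}

#' Extract the feature pyramid of a frame
#'
#' Taps the encoder at strides 8, 16 and 32 (shared computation with
#' [predictMask()]); map sizes are floor(H/r) x floor(W/r).
#'
#' @param model a [SegModel-class].
#' @param image H x W matrix with H, W >= 32.
#' @return list with arrays `p8`, `p16`, `p32` (H/r x W/r x C) and the
#'   probability map `prob`.
#' @export
extractPyramid <- function(model, image) {
  if (nrow(image) < 32 || ncol(image) < 32)
    stop("image too small for a 1/32 pyramid (need H, W >= 32)")
  tin <- imagesToTensor(list(image))
  fwd <- graphForward(model@graph, model@params, model@state,
                      list(img = tin), training = FALSE)
  taps <- model@arch$taps
  list(p8 = tensorToArray(fwd$vals[[taps["p8"]]]),
       p16 = tensorToArray(fwd$vals[[taps["p16"]]]),
       p32 = tensorToArray(fwd$vals[[taps["p32"]]]),
       prob = tensorToImage(fwd$vals$prob))
}

#' Save / load a model checkpoint
#'
#' @param model a [SegModel-class] or [JointModel-class].
#' @param path checkpoint file.
#' @return `loadModel` returns the model; `saveModel` the path, invisibly.
#' @export
saveModel <- function(model, path) {
  saveRDS(model, path)
  invisible(path)
}

#' @rdname saveModel
#' @export
loadModel <- function(path) readRDS(path)
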