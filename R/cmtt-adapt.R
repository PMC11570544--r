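# Two-stage fully test-time adaptation (CMTT). Only the BN affine
# parameters (gamma, beta) are optimized; BN normalization statistics are
# re-estimated from target batches. Stage 1 minimizes the entire-image
# entropy + BNM objective; Stage 2 minimizes the central-metric contrastive
# objective on overlapping patches, with cell/background pixel sets and the
# background center taken from the (fixed) Stage-1 prediction.

#' Adaptation configuration
#'
#' @param alpha weight of the BNM term in the Stage-1 loss (default 0.5).
#' @param stage1Epochs,stage2Epochs adaptation epochs per stage; the two
#'   defaults keep the total below 10.
#' @param learningRate Adam learning rate for the BN affine parameters.
#' @param batchSize target batch size B_t for Stage 1.
#' @param patchSize,patchOverlap Stage-2 patch geometry in px.
#' @param deltaMode statistic for the background center: "median" or
#'   "mean".
#' @param aggregationWeight weight w of prediction 1 in the final
#'   `w * pred1 + (1 - w) * pred2` aggregate.
#' @param stage2Loss Stage-2 objective: "cmc" (default) or "shannon"
#'   (patch-level entropy, the ablation variant).
#' @param cmcOrientation which pixel set the CMC numerator maximizes
#'   similarity-to-delta for: "background" (default; the orientation under
#'   which the contrast separates cells from the background center) or
#'   "printed" (P+ in the numerator, the literal published form).
#' @param bnRefresh momentum used when re-estimating BN statistics from the
#'   target set after each stage (1 = replace by target statistics).
#' @param seed RNG seed (batch order).
#' @return Named list.
#' @export
adaptConfig <- function(alpha = 0.5, stage1Epochs = 4L, stage2Epochs = 4L,
                        learningRate = 5e-3, batchSize = 4L,
                        patchSize = 128L, patchOverlap = 32L,
                        deltaMode = c("median", "mean"),
                        stage2Loss = c("cmc", "shannon"),
                        aggregationWeight = 0.5,
                        cmcOrientation = c("background", "printed"),
                        bnRefresh = 1, seed = 1L) {
  stopifnot(alpha >= 0, aggregationWeight >= 0, aggregationWeight <= 1)
  list(alpha = alpha, stage1Epochs = as.integer(stage1Epochs),
       stage2Epochs = as.integer(stage2Epochs),
       learningRate = learningRate, batchSize = as.integer(batchSize),
       patchSize = as.integer(patchSize),
       patchOverlap = as.integer(patchOverlap),
       deltaMode = match.arg(deltaMode),
       stage2Loss = match.arg(stage2Loss),
       aggregationWeight = aggregationWeight,
       cmcOrientation = match.arg(cmcOrientation),
       bnRefresh = bnRefresh, seed = as.integer(seed))
}

#' Names of the test-time adaptable parameters
#'
#' Exactly the BN affine parameters (gamma, beta). Everything else is
#' frozen during adaptation; BN running statistics are re-estimated from
#' target batches rather than optimized.
#'
#' @param model a [SegModel-class].
#' @return Character vector of parameter-store names.
#' @export
adaptableParameters <- function(model) {
  nms <- parameterPartition(model)$bnAffineNames
  if (!length(nms)) stop("model has no batch-normalization layers")
  nms
}

# one full-set training-mode pass to (re-)estimate BN statistics
recomputeBNStats <- function(model, images, momentum = 1) {
  tin <- imagesToTensor(images)
  fwd <- graphForward(model@graph, model@params, model@state,
                      list(img = tin), training = TRUE,
                      bnMomentum = momentum)
  methods::initialize(model, state = fwd$state)
}

clampProb <- function(p, eps = 1e-7) pmin(pmax(p, eps), 1 - eps)

# gradient of the Stage-1 objective wrt the foreground probability vector
stage1Grad <- function(p, alpha) {
  p <- clampProb(p)
  A <- cbind(p, 1 - p)
  n <- length(p)
  ent <- shannonEntropyLoss(A)
  dEnt <- log((1 - p) / p) / n
  sv <- svd(A)
  bnm <- -sum(sv$d) / n
  UV <- sv$u %*% t(sv$v)
  dBnm <- -(UV[, 1] - UV[, 2]) / n
  list(loss = ent + alpha * bnm, grad = dEnt + alpha * dBnm,
       entropy = ent, bnm = bnm)
}

#' Stage 1: entire-image test-time adaptation
#'
#' Optimizes the entropy + BNM objective over target batches for
#' `stage1Epochs` epochs, updating only [adaptableParameters()]; BN
#' statistics are re-estimated from the target set. With
#' `stage1Epochs = 0` the model is returned unchanged and the predictions
#' are the source model's.
#'
#' @param model a trained [SegModel-class].
#' @param targetImages list of target-domain frames (unlabelled).
#' @param cfg an [adaptConfig()] list.
#' @return list(model, pred, log): the adapted model, per-frame
#'   probability maps ("prediction 1"), and a per-epoch loss log.
#' @export
adaptStage1 <- function(model, targetImages, cfg = adaptConfig()) {
  if (!length(targetImages)) stop("empty target set")
  bnNames <- adaptableParameters(model)
  log <- data.frame(epoch = integer(), loss = numeric(),
                    entropy = numeric(), bnm = numeric())
  if (cfg$stage1Epochs > 0) {
    params <- model@params; state <- model@state
    opt <- adamInit(model@params[bnNames])
    n <- length(targetImages)
    withSeed(cfg$seed, {
      for (ep in seq_len(cfg$stage1Epochs)) {
        sums <- c(loss = 0, entropy = 0, bnm = 0); nb <- 0L
        for (start in seq(1L, n, by = cfg$batchSize)) {
          bi <- start:min(n, start + cfg$batchSize - 1L)
          tin <- imagesToTensor(targetImages[bi])
          fwd <- graphForward(model@graph, params, state, list(img = tin),
                              training = TRUE)
          state <- fwd$state
          g <- stage1Grad(fwd$vals$prob$x[, 1], cfg$alpha)
          bk <- graphBackward(model@graph, params, fwd,
                              list(prob = matrix(g$grad, ncol = 1)))
          st <- adamStep(params, bk$dparams[bnNames], opt,
                         cfg$learningRate, which = bnNames)
          params[bnNames] <- st$params[bnNames]; opt <- st$state
          sums <- sums + c(g$loss, g$entropy, g$bnm); nb <- nb + 1L
        }
        log <- rbind(log, data.frame(epoch = ep, loss = sums[1] / nb,
                                     entropy = sums[2] / nb,
                                     bnm = sums[3] / nb))
      }
    })
    model <- methods::initialize(model, params = params, state = state)
    model <- recomputeBNStats(model, targetImages, cfg$bnRefresh)
  }
  pred <- lapply(targetImages, function(im) predictMask(model, im))
  list(model = model, pred = pred, log = log)
}

# per-patch Stage-2 ingredients from the fixed Stage-1 prediction
stage2PatchInfo <- function(image, pred1, cfg) {
  grid <- splitPatches(image, cfg$patchSize, cfg$patchOverlap)
  pgrid <- splitPatches(pred1, cfg$patchSize, cfg$patchOverlap)
  globalBg <- stats::median(pred1[pred1 <= 0.5], na.rm = TRUE)
  if (!is.finite(globalBg)) globalBg <- min(pred1)
  info <- lapply(seq_along(grid$patches), function(k) {
    p1 <- pgrid$pixels[[k]]
    cellSet <- which(p1 > 0.5)
    bgSet <- which(p1 <= 0.5)
    if (!length(cellSet)) return(NULL)  # skipped patch
    delta <- if (length(bgSet)) {
      if (cfg$deltaMode == "median") stats::median(p1[bgSet]) else
        mean(p1[bgSet])
    } else globalBg
    list(k = k, cellSet = cellSet, bgSet = bgSet, delta = delta)
  })
  list(grid = grid, info = Filter(Negate(is.null), info))
}

# soft CMC loss + gradient wrt the patch probability vector; sets fixed
cmcGrad <- function(p, cellSet, bgSet, delta, orientation) {
  p <- clampProb(p)
  phi <- phiSimilarity(p, delta)
  e <- exp(phi)
  sPlus <- sum(e[cellSet]); sMinus <- sum(e[bgSet])
  num <- if (orientation == "printed") sPlus else sMinus
  tot <- sPlus + sMinus
  loss <- -log(num / tot)
  dphi <- numeric(length(p))
  inNum <- if (orientation == "printed") cellSet else bgSet
  outNum <- if (orientation == "printed") bgSet else cellSet
  dphi[inNum] <- e[inNum] * (1 / tot - 1 / num)
  dphi[outNum] <- e[outNum] / tot
  dp <- dphi * (-2 * (p - delta)) / (1 + (p - delta)^2)^2
  list(loss = loss, grad = dp)
}

#' Stage 2: patch-level adaptation with the CMC objective
#'
#' Each target frame is split into overlapping patches; the Stage-1
#' prediction fixes, per patch, the cell set P+, background set P- and the
#' background center delta. The CMC objective is then optimized over the
#' patch batches (BN affine parameters only; patch batches also refresh
#' the BN statistics), and the adapted per-patch predictions are stitched
#' into "prediction 2". The optimized pixel feature is the predicted
#' foreground probability, giving the objective a gradient path to the
#' model; [cmcLoss()] on raw intensities is the reported printed form.
#' Patches with empty P+ are skipped; if every patch is skipped the target
#' carries no Stage-1 foreground at all and an error is raised.
#'
#' @param model the Stage-1-adapted [SegModel-class].
#' @param targetImages list of target frames.
#' @param pred1 list of Stage-1 probability maps (fixed during Stage 2).
#' @param cfg an [adaptConfig()] list.
#' @return list(model, pred, log, skipped): adapted model, stitched
#'   "prediction 2" maps, per-epoch loss log, and the number of skipped
#'   patches.
#' @export
adaptStage2 <- function(model, targetImages, pred1, cfg = adaptConfig()) {
  stopifnot(length(targetImages) == length(pred1))
  bnNames <- adaptableParameters(model)
  prep <- lapply(seq_along(targetImages), function(i)
    stage2PatchInfo(targetImages[[i]], pred1[[i]], cfg))
  nPatches <- sum(vapply(prep, function(x) length(x$grid$patches), 1L))
  nKept <- sum(vapply(prep, function(x) length(x$info), 1L))
  if (nKept == 0L)
    stop("all patches skipped: Stage 1 predicts no foreground anywhere")
  log <- data.frame(epoch = integer(), loss = numeric())
  params <- model@params; state <- model@state
  if (cfg$stage2Epochs > 0) {
    opt <- adamInit(model@params[bnNames])
    withSeed(cfg$seed + 1L, {
      for (ep in seq_len(cfg$stage2Epochs)) {
        lossSum <- 0; nb <- 0L
        for (i in seq_along(prep)) {
          pr <- prep[[i]]
          if (!length(pr$info)) next
          patchImgs <- lapply(pr$info, function(x) pr$grid$pixels[[x$k]])
          tin <- imagesToTensor(patchImgs)
          fwd <- graphForward(model@graph, params, state, list(img = tin),
                              training = TRUE)
          state <- fwd$state
          HW <- cfg$patchSize^2
          grad <- matrix(0, nrow(fwd$vals$prob$x), 1)
          lsum <- 0
          for (j in seq_along(pr$info)) {
            x <- pr$info[[j]]
            off <- (j - 1L) * HW
            # patch matrices are column-major; tensor rows are row-major
            pvecRM <- fwd$vals$prob$x[off + seq_len(HW), 1]
            cm2rm <- function(idx) {
              r <- (idx - 1L) %% cfg$patchSize + 1L
              c <- (idx - 1L) %/% cfg$patchSize + 1L
              (r - 1L) * cfg$patchSize + c
            }
            g <- if (cfg$stage2Loss == "shannon") {
              p <- clampProb(pvecRM)
              list(loss = shannonEntropyLoss(p),
                   grad = log((1 - p) / p) / length(p))
            } else cmcGrad(pvecRM, cm2rm(x$cellSet), cm2rm(x$bgSet),
                           x$delta, cfg$cmcOrientation)
            grad[off + seq_len(HW), 1] <- g$grad / length(pr$info)
            lsum <- lsum + g$loss
          }
          bk <- graphBackward(model@graph, params, fwd, list(prob = grad))
          st <- adamStep(params, bk$dparams[bnNames], opt,
                         cfg$learningRate, which = bnNames)
          params[bnNames] <- st$params[bnNames]; opt <- st$state
          lossSum <- lossSum + lsum / length(pr$info); nb <- nb + 1L
        }
        log <- rbind(log, data.frame(epoch = ep, loss = lossSum / max(nb, 1L)))
      }
    })
    model <- methods::initialize(model, params = params, state = state)
    model <- recomputeBNStats(model, targetImages, cfg$bnRefresh)
  }
  pred <- lapply(seq_along(targetImages), function(i) {
    grid <- prep[[i]]$grid
    preds <- lapply(grid$pixels, function(px) predictMask(model, px))
    stitchPatches(grid, preds)
  })
  list(model = model, pred = pred, log = log,
       skipped = nPatches - nKept)
}

#' Aggregate the two stage predictions
#'
#' `w * pred1 + (1 - w) * pred2` on probabilities; binarize the result
#' with [binarizeProb()] for a mask.
#'
#' @param pred1,pred2 probability maps (matrices) or lists thereof.
#' @param w aggregation weight in [0, 1].
#' @return Aggregated probability map(s).
#' @export
aggregatePredictions <- function(pred1, pred2, w = 0.5) {
  stopifnot(w >= 0, w <= 1)
  if (is.list(pred1)) {
    stopifnot(length(pred1) == length(pred2))
    return(lapply(seq_along(pred1), function(i)
      w * pred1[[i]] + (1 - w) * pred2[[i]]))
  }
  stopifnot(identical(dim(pred1), dim(pred2)))
  w * pred1 + (1 - w) * pred2
}

#' Run the full two-stage test-time adaptation
#'
#' Convenience wrapper: Stage 1, Stage 2, and the weighted aggregation.
#'
#' @param model trained source [SegModel-class].
#' @param targetImages list of unlabelled target frames.
#' @param cfg an [adaptConfig()] list.
#' @return list(model, pred1, pred2, final, logs, skipped).
#' @export
cmttAdapt <- function(model, targetImages, cfg = adaptConfig()) {
  s1 <- adaptStage1(model, targetImages, cfg)
  s2 <- adaptStage2(s1$model, targetImages, s1$pred, cfg)
  final <- aggregatePredictions(s1$pred, s2$pred, cfg$aggregationWeight)
  list(model = s2$model, pred1 = s1$pred, pred2 = s2$pred, final = final,
       logs = list(stage1 = s1$log, stage2 = s2$log), skipped = s2$skipped)
}
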