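# End-to-end experiment harness: source training -> test-time adaptation ->
# joint-head training -> online tracking -> metrics, with the ablation
# switchboard (CMTT on/off, Stage 2 on/off, CMC vs Shannon Stage-2 loss,
# SA-ReID vs stacked convolutions).

#' Experiment configuration
#'
#' Bundles every stage's settings and the ablation flags into one
#' reproducible description; the emitted report is a pure function of this
#' configuration (including `seed`).
#'
#' @param sourceScene [SceneConfig-class] of the labelled source domain.
#' @param targetScene [SceneConfig-class] of the target domain (before the
#'   photometric shift); `NULL` skips the adaptation experiment.
#' @param targetShift [ShiftSpec-class] applied to target frames.
#' @param trackScene [SceneConfig-class] of the tracking video; `NULL`
#'   skips the tracking experiment.
#' @param train a [trainConfig()] list.
#' @param adapt an [adaptConfig()] list.
#' @param headEpochs,headLearningRate joint-head training schedule (the
#'   second phase runs at a tenth of the rate).
#' @param focal a [focalConfig()] list.
#' @param weights a [lossWeights()] list.
#' @param assoc an [assocConfig()] list.
#' @param scoreThreshold,nmsThreshold detection thresholds.
#' @param useCmtt run test-time adaptation (FALSE = raw source model).
#' @param useStage2 run Stage 2 (FALSE = Stage 1 only).
#' @param useSaReid use the spatial attention module in the ReID branch.
#' @param seed global seed; all stage seeds derive from it.
#' @return Named list (class "cmttExperiment").
#' @export
experimentConfig <- function(sourceScene = sceneConfig(nCells = 10L,
                               nFrames = 8L, seed = 101L),
                             targetScene = sceneConfig(nCells = 30L,
                               nFrames = 6L, seed = 202L),
                             targetShift = shiftSpec(gamma = 1.6,
                               contrast = 0.6, brightness = 0.08,
                               noiseSigma = 0.05),
                             trackScene = NULL,
                             train = trainConfig(epochs = 60L,
                               learningRate = 1e-3, batchSize = 4L),
                             adapt = adaptConfig(patchSize = 48L,
                               patchOverlap = 16L),
                             headEpochs = c(150L, 80L),
                             headLearningRate = 5e-3,
                             focal = focalConfig(),
                             weights = lossWeights(),
                             assoc = assocConfig(embGate = 12,
                               minScore = 0.6),
                             scoreThreshold = 0.4, nmsThreshold = 0.2,
                             useCmtt = TRUE, useStage2 = TRUE,
                             useSaReid = TRUE, seed = 1L) {
  structure(list(sourceScene = sourceScene, targetScene = targetScene,
                 targetShift = targetShift, trackScene = trackScene,
                 train = train, adapt = adapt, headEpochs = headEpochs,
                 headLearningRate = headLearningRate, focal = focal,
                 weights = weights, assoc = assoc,
                 scoreThreshold = scoreThreshold,
                 nmsThreshold = nmsThreshold, useCmtt = useCmtt,
                 useStage2 = useStage2, useSaReid = useSaReid,
                 seed = as.integer(seed)),
            class = "cmttExperiment")
}

videoBoxes <- function(masksL, withId = TRUE) {
  out <- lapply(seq_along(masksL), function(f) {
    b <- boxesFromMask(masksL[[f]])
    if (!nrow(b)) return(NULL)
    data.frame(frame = f - 1L, id = b$label, x = b$x, y = b$y, w = b$w,
               h = b$h)
  })
  do.call(rbind, out)
}

# instance evaluation splits touching cells by watershed; dense targets
# would otherwise merge neighbours into one component
segMetricsFor <- function(preds, refMasks) {
  predMasks <- lapply(preds, function(p)
    labelInstances(binarizeProb(p), method = "watershed"))
  evaluateAll(predMasks = predMasks, refMasks = refMasks)
}

#' Run one end-to-end experiment
#'
#' Executes, per the configuration flags: source training; test-time
#' adaptation of the segmentation unit on the shifted target video with
#' segmentation metrics (Dice/IOU/AJI) before and after; joint-head
#' training and online tracking on the tracking video with CLEAR and
#' lineage metrics. Fully reproducible from the configuration.
#'
#' @param cfg an [experimentConfig()].
#' @param verbose print stage progress.
#' @return list with `segmentation` (reports: source, noAdapt, stage1,
#'   final and logs), `tracking` (report, track set, lineage), `models`,
#'   and the resolved `config`.
#' @export
runExperiment <- function(cfg, verbose = FALSE) {
  say <- function(...) if (verbose) message(...)
  res <- list(config = cfg)
  say("training source model")
  src <- generateSequence(cfg$sourceScene)
  model <- segModel(seed = cfg$seed)
  tc <- cfg$train; tc$seed <- cfg$seed
  model <- tryCatch(
    trainSource(model, frames(src), masks(src), tc),
    error = function(e) stop("stage train_source failed: ",
                             conditionMessage(e)))
  res$models$source <- model
  if (!is.null(cfg$targetScene)) {
    say("adapting to the target domain")
    tgt <- shiftVideo(generateSequence(cfg$targetScene), cfg$targetShift)
    timgs <- frames(tgt); tmsks <- masks(tgt)
    pred0 <- lapply(timgs, function(im) predictMask(model, im))
    seg <- list(noAdapt = segMetricsFor(pred0, tmsks))
    if (cfg$useCmtt) {
      ac <- cfg$adapt; ac$seed <- cfg$seed + 1L
      s1 <- tryCatch(adaptStage1(model, timgs, ac),
                     error = function(e) stop("stage adapt_stage1 failed: ",
                                              conditionMessage(e)))
      seg$stage1 <- segMetricsFor(s1$pred, tmsks)
      if (cfg$useStage2) {
        s2 <- tryCatch(adaptStage2(s1$model, timgs, s1$pred, ac),
                       error = function(e) stop("stage adapt_stage2 failed: ",
                                                conditionMessage(e)))
        final <- aggregatePredictions(s1$pred, s2$pred,
                                      ac$aggregationWeight)
        seg$final <- segMetricsFor(final, tmsks)
        seg$logs <- list(stage1 = s1$log, stage2 = s2$log)
        res$models$adapted <- s2$model
      } else {
        seg$final <- seg$stage1
        seg$logs <- list(stage1 = s1$log)
        res$models$adapted <- s1$model
      }
    } else {
      seg$final <- seg$noAdapt
    }
    res$segmentation <- seg
  }
  if (!is.null(cfg$trackScene)) {
    say("training the joint head and tracking")
    tv <- generateSequence(cfg$trackScene)
    timgs <- frames(tv); tmsks <- masks(tv)
    gtb <- lapply(tmsks, function(mk) {
      b <- boxesFromMask(mk); b$id <- b$label; b
    })
    nIds <- max(trackTable(tv)$label)
    jm <- jointModel(model, nIds = nIds, useSAM = cfg$useSaReid,
                     seed = cfg$seed + 2L)
    jm <- tryCatch({
      jm <- trainJointHead(jm, timgs, gtb, epochs = cfg$headEpochs[1],
                           learningRate = cfg$headLearningRate,
                           seed = cfg$seed + 3L, focal = cfg$focal,
                           weights = cfg$weights)
      if (length(cfg$headEpochs) > 1L && cfg$headEpochs[2] > 0L)
        jm <- trainJointHead(jm, timgs, gtb, epochs = cfg$headEpochs[2],
                             learningRate = cfg$headLearningRate / 5,
                             seed = cfg$seed + 4L, focal = cfg$focal,
                             weights = cfg$weights)
      jm
    }, error = function(e) stop("stage joint_head failed: ",
                                conditionMessage(e)))
    detList <- lapply(timgs, function(im)
      detectFrame(jm, im, cfg$scoreThreshold, cfg$nmsThreshold))
    ts <- trackDetections(detList, cfg$assoc)
    pt <- trackFrames(ts)
    rt <- videoBoxes(tmsks)
    rep <- evaluateAll(predTracks = pt, refTracks = rt)
    res$tracking <- list(report = rep, trackSet = ts,
                         lineage = buildLineage(ts, cfg$assoc),
                         refTable = trackTable(tv))
    res$models$joint <- jm
  }
  res
}

#' k-fold cross-validation of source training
#'
#' Splits the source frames into k folds; trains on k-1 and scores
#' segmentation Dice/IOU on the held-out fold.
#'
#' @param cfg an [experimentConfig()] (its `sourceScene` provides the
#'   frame pool).
#' @param k number of folds (>= 2).
#' @return list(perFold data.frame, mean, sd).
#' @export
crossValidate <- function(cfg, k = 4L) {
  stopifnot(k >= 2L)
  src <- generateSequence(cfg$sourceScene)
  n <- nFrames(src)
  if (k > n) stop("k exceeds the number of source frames")
  fold <- rep(seq_len(k), length.out = n)
  perFold <- data.frame()
  for (i in seq_len(k)) {
    tr <- which(fold != i); te <- which(fold == i)
    model <- segModel(seed = cfg$seed + i)
    tc <- cfg$train; tc$seed <- cfg$seed + i
    model <- trainSource(model, frames(src)[tr], masks(src)[tr], tc)
    d <- vapply(te, function(j) {
      p <- binarizeProb(predictMask(model, frames(src)[[j]]))
      dice(masks(src)[[j]] > 0, p > 0)
    }, numeric(1))
    j <- vapply(te, function(jj) {
      p <- binarizeProb(predictMask(model, frames(src)[[jj]]))
      iou(masks(src)[[jj]] > 0, p > 0)
    }, numeric(1))
    perFold <- rbind(perFold, data.frame(fold = i, dice = mean(d),
                                         iou = mean(j)))
  }
  list(perFold = perFold,
       mean = c(dice = mean(perFold$dice), iou = mean(perFold$iou)),
       sd = c(dice = stats::sd(perFold$dice), iou = stats::sd(perFold$iou)))
}
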