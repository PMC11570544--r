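# Test-time adaptation objectives: Shannon entropy, batch nuclear-norm
# (BNM), their weighted combination for Stage 1, and the central-metric
# contrastive (CMC) similarity machinery for Stage 2.

probsToResponses <- function(probs) {
  p <- as.vector(probs)
  cbind(p, 1 - p)
}

#' Mean Shannon entropy of per-pixel class distributions
#'
#' `mean over pixels of -sum_c p_c * log(p_c)` (natural log, 0*log0 = 0).
#' Minimized (0) iff every distribution is one-hot; maximized (log C) at
#' uniform.
#'
#' @param probs either a foreground-probability matrix/vector (two-class
#'   form is completed internally) or an n x C matrix of distributions with
#'   rows summing to 1.
#' @return Scalar entropy in nats, >= 0.
#' @examples
#' shannonEntropyLoss(matrix(0.5, 2, 2))  # log(2)
#' @export
shannonEntropyLoss <- function(probs) {
  A <- if (is.matrix(probs) && ncol(probs) >= 2 &&
           max(abs(rowSums(probs) - 1)) < 1e-8) probs
       else probsToResponses(probs)
  if (any(A < 0)) stop("negative probabilities")
  terms <- ifelse(A > 0, A * log(A), 0)
  -sum(terms) / nrow(A)
}

#' Batch nuclear-norm (BNM) loss
#'
#' `-(1/B) * ||A||_*`, the negative nuclear norm (sum of singular values)
#' of the batch response matrix, divided by the number of batch samples.
#' Minimizing it raises prediction discriminability and diversity near the
#' decision boundary.
#'
#' @param responses B x C response matrix (rows = batch samples after
#'   softmax/complement).
#' @return Scalar loss, <= 0.
#' @examples
#' bnmLoss(diag(2))  # -1
#' @export
bnmLoss <- function(responses) {
  if (!all(is.finite(responses))) stop("non-finite entries in responses")
  -sum(svd(responses, nu = 0, nv = 0)$d) / nrow(responses)
}

#' Entire-image adaptation loss (Stage 1)
#'
#' `L_E = L_s + alpha * L_bnm`: Shannon entropy plus alpha times the BNM
#' loss of the batch response matrix.
#'
#' @param probs per-pixel distributions (see [shannonEntropyLoss()]).
#' @param responses batch response matrix (see [bnmLoss()]); defaults to
#'   the two-class response form of `probs`.
#' @param alpha weight of the BNM term (default 0.5).
#' @return Scalar loss.
#' @export
entireImageLoss <- function(probs, responses = NULL, alpha = 0.5) {
  if (alpha < 0) stop("alpha must be >= 0")
  if (is.null(responses)) responses <- probsToResponses(probs)
  shannonEntropyLoss(probs) + alpha * bnmLoss(responses)
}

#' Normalized inverse Euclidean similarity
#'
#' `phi(i, j) = 1 / (1 + ||i - j||^2)` in (0, 1]; pixel features are
#' assumed pre-normalized to [0, 1].
#'
#' @param i,j numeric scalars or equal-length vectors (elementwise).
#' @return Similarity value(s) in (0, 1].
#' @examples
#' phiSimilarity(0.3, 0.3)  # 1
#' phiSimilarity(0, 1)      # 0.5
#' @export
phiSimilarity <- function(i, j) 1 / (1 + (i - j)^2)

#' Background center of a patch (Stage 2)
#'
#' The center delta is the median (default) or mean of the patch pixel
#' values at locations Stage 1 predicted as background. If the patch has no
#' predicted background pixels, the statistic falls back to the
#' whole-frame background value and the fallback is flagged with a warning.
#'
#' @param patch numeric matrix of patch pixel values.
#' @param stage1Mask binary matrix (1 = cell) from the binarized Stage-1
#'   prediction of the same patch.
#' @param mode "median" or "mean".
#' @param globalBackground fallback scalar used when the patch is all cell.
#' @return list(delta, mode, fallback).
#' @export
computeCenter <- function(patch, stage1Mask, mode = c("median", "mean"),
                          globalBackground = NULL) {
  mode <- match.arg(mode)
  stopifnot(identical(dim(patch), dim(stage1Mask)))
  bg <- patch[stage1Mask == 0]
  if (!length(bg)) {
    if (is.null(globalBackground))
      stop("patch has no predicted background and no global fallback")
    warning("patch has no predicted background pixels; ",
            "falling back to the global background statistic")
    return(list(delta = globalBackground, mode = mode, fallback = TRUE))
  }
  d <- if (mode == "median") stats::median(bg) else mean(bg)
  list(delta = d, mode = mode, fallback = FALSE)
}

#' Central-metric contrastive (CMC) loss of one patch
#'
#' Exactly the printed form:
#' `-log( sum_{i in P+} e^{phi(i, delta)} /
#'        (sum_{i in P+} e^{phi(i, delta)} + sum_{i in P-} e^{phi(i, delta)}) )`.
#' P+/P- are the Stage-1 predicted cell/background pixel sets of the patch
#' and delta the background center from [computeCenter()].
#'
#' @param patchPixels numeric vector/matrix of patch pixel values.
#' @param pPlus,pMinus disjoint index vectors into `patchPixels` (cell and
#'   background pixels).
#' @param delta background center.
#' @return Scalar loss >= 0; `NA` with a warning if P+ is empty (patch is
#'   skipped by the adaptation loop).
#' @examples
#' cmcLoss(c(0.2, 0.2, 0.8, 0.8), c(3, 4), c(1, 2), 0.2)
#' @export
cmcLoss <- function(patchPixels, pPlus, pMinus, delta) {
  if (length(intersect(pPlus, pMinus)))
    stop("P+ and P- must be disjoint")
  if (!length(pPlus)) {
    warning("P+ is empty; CMC loss undefined for this patch")
    return(NA_real_)
  }
  sPlus <- sum(exp(phiSimilarity(patchPixels[pPlus], delta)))
  sMinus <- if (length(pMinus))
    sum(exp(phiSimilarity(patchPixels[pMinus], delta))) else 0
  -log(sPlus / (sPlus + sMinus))
}
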