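# Patch tiling with partition-of-unity stitching. Patches are laid on a
# regular grid with the requested overlap (the last row/column is shifted
# so the frame is always fully covered); stitch weights use a raised-cosine
# ramp over the overlap zone and are normalized so that at every frame
# pixel the weights of all covering patches sum to exactly 1.

patchStarts <- function(size, patch, overlap) {
  step <- patch - overlap
  st <- seq(1L, max(1L, size - patch + 1L), by = step)
  if (st[length(st)] + patch - 1L < size) st <- c(st, size - patch + 1L)
  unique(st)
}

cosineProfile <- function(patch, overlap) {
  w <- rep(1, patch)
  if (overlap > 0) {
    ramp <- 0.5 * (1 - cos(pi * (seq_len(overlap) - 0.5) / overlap))
    w[seq_len(overlap)] <- ramp
    w[patch + 1 - seq_len(overlap)] <- ramp
  }
  pmax(w, 1e-3)
}

#' Split a frame into overlapping patches
#'
#' @param image H x W matrix (only its size matters for the grid; the
#'   pixel values are carried along for convenience).
#' @param patchSize patch side length in px (>= 16).
#' @param overlap overlap between neighbouring patches in px
#'   (0 <= overlap < patchSize).
#' @return A patch grid: list with `patches` (list of (row0, col0, h, w),
#'   1-based inclusive origins), `pixels` (list of patch matrices),
#'   `weights` (list of normalized stitch-weight matrices), and the frame
#'   size. At every frame pixel the stitch weights sum to 1.
#' @examples
#' g <- splitPatches(matrix(0, 256, 256), 128, 0)
#' length(g$patches)  # 4
#' @export
splitPatches <- function(image, patchSize, overlap = 0L) {
  H <- nrow(image); W <- ncol(image)
  if (patchSize < 16) stop("patchSize must be >= 16")
  if (overlap >= patchSize) stop("overlap must be smaller than patchSize")
  if (patchSize > H || patchSize > W)
    stop("patchSize exceeds the frame size")
  rs <- patchStarts(H, patchSize, overlap)
  cs <- patchStarts(W, patchSize, overlap)
  prof <- cosineProfile(patchSize, overlap)
  wpatch <- outer(prof, prof)
  total <- matrix(0, H, W)
  patches <- list(); pixels <- list()
  k <- 0L
  for (r0 in rs) for (c0 in cs) {
    k <- k + 1L
    patches[[k]] <- c(row0 = r0, col0 = c0, h = patchSize, w = patchSize)
    pixels[[k]] <- image[r0:(r0 + patchSize - 1L), c0:(c0 + patchSize - 1L)]
    total[r0:(r0 + patchSize - 1L), c0:(c0 + patchSize - 1L)] <-
      total[r0:(r0 + patchSize - 1L), c0:(c0 + patchSize - 1L)] + wpatch
  }
  weights <- lapply(patches, function(p) {
    wpatch / total[p["row0"]:(p["row0"] + p["h"] - 1L),
                   p["col0"]:(p["col0"] + p["w"] - 1L)]
  })
  list(patches = patches, pixels = pixels, weights = weights,
       frameSize = c(H, W), patchSize = patchSize, overlap = overlap)
}

#' Stitch per-patch predictions back into a frame map
#'
#' Weighted average with the grid's partition-of-unity stitch weights;
#' stitching crops of a full-frame map reproduces that map exactly.
#'
#' @param grid a grid from [splitPatches()].
#' @param patchPreds list of patch-sized matrices (one per grid patch).
#' @return H x W matrix.
#' @export
stitchPatches <- function(grid, patchPreds) {
  stopifnot(length(patchPreds) == length(grid$patches))
  out <- matrix(0, grid$frameSize[1], grid$frameSize[2])
  for (k in seq_along(grid$patches)) {
    p <- grid$patches[[k]]
    ri <- p["row0"]:(p["row0"] + p["h"] - 1L)
    ci <- p["col0"]:(p["col0"] + p["w"] - 1L)
    out[ri, ci] <- out[ri, ci] + grid$weights[[k]] * patchPreds[[k]]
  }
  out
}
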