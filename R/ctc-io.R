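# Cell Tracking Challenge style directory I/O (flat layout):
#   tNNN.tif          grayscale frames
#   man_segNNN.tif    16-bit instance segmentation masks
#   man_trackNNN.tif  16-bit tracking masks (same labels as the track table)
#   man_track.txt     rows "label begin end parent"

maskToTiff <- function(mask) {
  if (max(mask) > 65535L) stop("labels exceed 16-bit range")
  mask / 65535
}

tiffToMask <- function(x) {
  m <- round(x * 65535)
  storage.mode(m) <- "integer"
  m
}

#' Write a cell video in CTC layout
#'
#' @param video a [CellVideo-class].
#' @param dir output directory (created if missing).
#' @param digits zero-padded width of the frame index (default 3).
#' @param writeSeg also write `man_segNNN.tif` copies of the masks.
#' @return `dir`, invisibly.
#' @export
writeCTC <- function(video, dir, digits = 3L, writeSeg = TRUE) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  fmt <- paste0("%0", digits, "d")
  for (i in seq_along(video@frames)) {
    id <- sprintf(fmt, i - 1L)
    tiff::writeTIFF(video@frames[[i]], file.path(dir, paste0("t", id, ".tif")),
                    bits.per.sample = 16L)
    tiff::writeTIFF(maskToTiff(video@masks[[i]]),
                    file.path(dir, paste0("man_track", id, ".tif")),
                    bits.per.sample = 16L)
    if (writeSeg)
      tiff::writeTIFF(maskToTiff(video@masks[[i]]),
                      file.path(dir, paste0("man_seg", id, ".tif")),
                      bits.per.sample = 16L)
  }
  utils::write.table(video@trackTable[, c("label", "begin", "end", "parent")],
                     file.path(dir, "man_track.txt"), row.names = FALSE,
                     col.names = FALSE)
  invisible(dir)
}

ctcFrameIndices <- function(dir, prefix) {
  fs <- list.files(dir, pattern = paste0("^", prefix, "[0-9]+\\.tif$"))
  sort(as.integer(sub(paste0("^", prefix, "([0-9]+)\\.tif$"), "\\1", fs)))
}

#' Read a cell video from a CTC-layout directory
#'
#' Frame indices must be contiguous from 0; a gap raises an
#' "inconsistent sequence" error. Missing mask or track-table files yield a
#' video with empty masks/table (frames-only directories are allowed for
#' unannotated target data).
#'
#' @param dir directory written by [writeCTC()] (or equivalent).
#' @return A [CellVideo-class].
#' @export
readCTC <- function(dir) {
  idx <- ctcFrameIndices(dir, "t")
  if (!length(idx)) stop("no tNNN.tif frames in ", dir)
  if (!identical(idx, 0:(length(idx) - 1L)))
    stop("inconsistent sequence: frame indices ", paste(idx, collapse = ","),
         " are not contiguous from 0")
  digits <- nchar(sub("^t([0-9]+)\\.tif$", "\\1",
                      list.files(dir, pattern = "^t[0-9]+\\.tif$")[1]))
  fmt <- paste0("%0", digits, "d")
  framesL <- lapply(idx, function(i)
    tiff::readTIFF(file.path(dir, sprintf(paste0("t", fmt, ".tif"), i))))
  maskFile <- function(i) file.path(dir, sprintf(paste0("man_track", fmt, ".tif"), i))
  if (file.exists(maskFile(0L))) {
    midx <- ctcFrameIndices(dir, "man_track")
    if (!identical(midx, idx))
      stop("inconsistent sequence: mask indices do not match frame indices")
    masksL <- lapply(idx, function(i) tiffToMask(tiff::readTIFF(maskFile(i))))
  } else {
    masksL <- lapply(framesL, function(f) matrix(0L, nrow(f), ncol(f)))
  }
  ttFile <- file.path(dir, "man_track.txt")
  tt <- if (file.exists(ttFile)) {
    d <- utils::read.table(ttFile, col.names = c("label", "begin", "end",
                                                 "parent"))
    d[order(d$label), , drop = FALSE]
  } else {
    data.frame(label = integer(), begin = integer(), end = integer(),
               parent = integer())
  }
  rownames(tt) <- NULL
  cellVideo(framesL, masksL, tt)
}
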