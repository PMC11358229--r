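#' Block-reduced image-motion metric
#'
#' Quantifies the image motion between the first and last frame of a facial
#' expression video: each grayscale frame is divided into non-overlapping
#' square blocks (20 x 20 pixels by default), pixel values are summed
#' within each block to form reduced images, and the motion estimate is
#' the sum of the absolute differences between the two reduced images.
#' The metric is symmetric in frame order and zero exactly when the
#' reduced frames are equal.
#'
#' @param frame1,frame2 equal-size grayscale matrices in `[0, 1]`, or
#'   3-channel arrays (converted with the Rec. 601 luma weights).
#'   Dimensions must be divisible by `block_size`.
#' @param block_size block side length in pixels.
#' @param normalize divide by the number of blocks (a scale that is
#'   comparable across frame sizes)?
#' @return scalar motion estimate (raw block-sum units, or per-block units
#'   when `normalize = TRUE`).
#' @examples
#' f <- matrix(0.5, 200, 200)
#' g <- f; g[1:20, 1:20] <- g[1:20, 1:20] + 0.1
#' image_motion(f, g)   # 0.1 * 400 = 40
#' @export
image_motion <- function(frame1, frame2, block_size = 20L, normalize = FALSE) {
  f1 <- to_gray(frame1); f2 <- to_gray(frame2)
  if (!all(dim(f1) == dim(f2))) stop("frames must have identical dimensions")
  if (any(dim(f1) %% block_size != 0))
    stop("frame dimensions must be divisible by block_size (", block_size, ")")
  r1 <- block_reduce(f1, block_size)
  r2 <- block_reduce(f2, block_size)
  m <- sum(abs(r1 - r2))
  if (normalize) m / length(r1) else m
}

#' @rdname image_motion
#' @param x grayscale matrix.
#' @export
block_reduce <- function(x, block_size = 20L) {
  stopifnot(all(dim(x) %% block_size == 0))
  ri <- rep(seq_len(nrow(x) / block_size), each = block_size)
  ci <- rep(seq_len(ncol(x) / block_size), each = block_size)
  t(rowsum(t(rowsum(x, ri, reorder = FALSE)), ci, reorder = FALSE))
}

to_gray <- function(x) {
  if (length(dim(x)) == 3) {
    0.299 * x[, , 1] + 0.587 * x[, , 2] + 0.114 * x[, , 3]
  } else as.matrix(x)
}
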