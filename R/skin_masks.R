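#' Asymmetric squared segmentation loss
#'
#' The training loss of the skin-detection network,
#' \deqn{E = \sum_{ij} (y_{ij} - \hat y_{ij})^2
#'       \left[\alpha y_{ij} + (1-\alpha)(1-y_{ij})\right],}
#' where \eqn{y} is the ground-truth mask and \eqn{\hat y} the predicted
#' probability map. With \eqn{\alpha < 0.5} false positives
#' (\eqn{\hat y = 1} on \eqn{y = 0}) weigh \eqn{1-\alpha > \alpha}, biasing
#' the segmenter away from including non-skin pixels in the pulse average.
#' At \eqn{\alpha = 0.5} the loss reduces to half the sum of squares.
#'
#' @param pred Numeric matrix of predicted probabilities in [0, 1].
#' @param truth Logical or 0/1 matrix of the same shape.
#' @param alpha Asymmetry weight in [0, 1] (default 0.4).
#' @return Nonnegative scalar.
#' @export
asymmetric_loss <- function(pred, truth, alpha = 0.4) {
  if (!all(dim(pred) == dim(truth))) stop("pred/truth shape mismatch")
  if (alpha < 0 || alpha > 1) stop("alpha must be in [0, 1]")
  y <- as.numeric(truth)
  p <- as.numeric(pred)
  sum((y - p)^2 * (alpha * y + (1 - alpha) * (1 - y)))
}

#' Binarize a skin probability map
#'
#' Pixels with probability at or above the threshold become skin (the tie
#' at exactly the threshold is inclusive).
#'
#' @param map Numeric matrix of probabilities.
#' @param threshold Cut in (0, 1) (default 0.5).
#' @return Logical matrix with attribute `n_skin` (count of TRUE pixels).
#' @export
binarize <- function(map, threshold = 0.5) {
  if (threshold <= 0 || threshold >= 1) stop("threshold must be in (0, 1)")
  mask <- map >= threshold
  attr(mask, "n_skin") <- sum(mask)
  mask
}

#' Number of skin pixels in a mask
#' @param mask Logical matrix.
#' @return Integer count.
#' @export
n_skin <- function(mask) sum(mask)

# Shift a logical matrix by (dr, dc), padding with `fill`.
shift_mask <- function(m, dr, dc, fill = FALSE) {
  out <- matrix(fill, nrow(m), ncol(m))
  r_src <- seq_len(nrow(m)) - dr
  c_src <- seq_len(ncol(m)) - dc
  ok_r <- r_src >= 1 & r_src <= nrow(m)
  ok_c <- c_src >= 1 & c_src <= ncol(m)
  out[ok_r, ok_c] <- m[r_src[ok_r], c_src[ok_c]]
  out
}

#' Morphological erosion / dilation of a binary mask
#'
#' 3 x 3 box (8-neighbour) structuring element, applied `iter` times.
#' Used to emulate segmentation error around the true skin region.
#'
#' @param mask Logical matrix.
#' @param iter Number of passes (0 returns the input unchanged).
#' @return Logical matrix.
#' @export
erode_mask <- function(mask, iter = 1L) {
  for (i in seq_len(iter)) {
    acc <- mask
    for (dr in -1:1) for (dc in -1:1) {
      if (dr == 0 && dc == 0) next
      acc <- acc & shift_mask(mask, dr, dc, fill = FALSE)
    }
    mask <- acc
  }
  mask
}

#' @rdname erode_mask
#' @export
dilate_mask <- function(mask, iter = 1L) {
  for (i in seq_len(iter)) {
    acc <- mask
    for (dr in -1:1) for (dc in -1:1) {
      if (dr == 0 && dc == 0) next
      acc <- acc | shift_mask(mask, dr, dc, fill = FALSE)
    }
    mask <- acc
  }
  mask
}

#' Ground-truth (geometric) mask provider
#'
#' Returns the simulator's exact per-key-frame skin masks, optionally
#' eroded or dilated to emulate segmentation error, so every downstream
#' stage can be exercised independently of network training.
#'
#' @param truth A `ground_truth` from [render_frames()].
#' @param erode,dilate Number of morphological passes applied to every mask
#'   (erosion first if both are given).
#' @return List of logical matrices, one per key frame.
#' @export
geometric_mask_provider <- function(truth, erode = 0L, dilate = 0L) {
  stopifnot(inherits(truth, "ground_truth"))
  lapply(truth$true_masks, function(m) {
    if (erode > 0L) m <- erode_mask(m, erode)
    if (dilate > 0L) m <- dilate_mask(m, dilate)
    m
  })
}
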