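# Evaluation metrics: confusion counts, pixel accuracy, Dice, Jaccard
# (= JSI) and the boundary-F1 contour matching score.

#' Pixel confusion counts
#'
#' @param mask,truth Binary matrices (logical or 0/1) on the same grid;
#'   foreground is `TRUE`/nonzero.
#' @return List with integer counts `TP`, `TN`, `FP`, `FN`.
#' @export
confusion <- function(mask, truth) {
  if (!identical(dim(mask), dim(truth))) {
    stop("shape error: mask and truth grids differ", call. = FALSE)
  }
  m <- mask != 0
  g <- truth != 0
  list(TP = sum(m & g), TN = sum(!m & !g),
       FP = sum(m & !g), FN = sum(!m & g))
}

#' Pixel accuracy
#'
#' `(TP + TN) / (TP + FP + TN + FN)`.
#'
#' @param counts Confusion counts from [confusion()].
#' @return Scalar in `[0, 1]`.
#' @export
accuracy <- function(counts) {
  total <- counts$TP + counts$TN + counts$FP + counts$FN
  if (total <= 0) stop("value error: empty confusion table", call. = FALSE)
  (counts$TP + counts$TN) / total
}

#' Dice overlap index
#'
#' `2 |A n B| / (|A| + |B|)`; two empty masks score 1 by convention.
#'
#' @inheritParams confusion
#' @return Scalar in `[0, 1]`.
#' @export
dice <- function(mask, truth) {
  cc <- confusion(mask, truth)
  denom <- 2 * cc$TP + cc$FP + cc$FN
  if (denom == 0) return(1)
  2 * cc$TP / denom
}

#' Jaccard similarity index
#'
#' `|A n B| / |A u B|`; two empty masks score 1 by convention. Identical to
#' the JSI used for noise-robustness evaluation.
#'
#' @inheritParams confusion
#' @return Scalar in `[0, 1]`.
#' @export
jaccard <- function(mask, truth) {
  cc <- confusion(mask, truth)
  denom <- cc$TP + cc$FP + cc$FN
  if (denom == 0) return(1)
  cc$TP / denom
}

#' Boundary-F1 contour matching score
#'
#' `alpha1` is the fraction of mask-boundary pixels within `distance_tol`
#' (Euclidean, pixels) of the truth boundary, `alpha2` the converse; the
#' score is their harmonic mean `2*alpha1*alpha2 / (alpha1 + alpha2)`
#' (0 when both vanish), so identical masks score 1 and the stated
#' `[0, 1]` range holds.
#'
#' @inheritParams confusion
#' @param distance_tol Positive match distance in pixels.
#' @return Scalar in `[0, 1]`.
#' @export
bf_score <- function(mask, truth, distance_tol = 2) {
  if (!identical(dim(mask), dim(truth))) {
    stop("shape error: mask and truth grids differ", call. = FALSE)
  }
  bm <- which(mask_boundary(mask), arr.ind = TRUE)
  bt <- which(mask_boundary(truth), arr.ind = TRUE)
  if (nrow(bm) == 0 || nrow(bt) == 0) {
    stop("value error: empty boundary", call. = FALSE)
  }
  min_dist <- function(a, b) {
    # nearest-neighbour distance from each row of a to the set b
    d2 <- outer(a[, 1], b[, 1], "-")^2 + outer(a[, 2], b[, 2], "-")^2
    sqrt(apply(d2, 1, min))
  }
  a1 <- mean(min_dist(bm, bt) <= distance_tol)
  a2 <- mean(min_dist(bt, bm) <= distance_tol)
  if (a1 + a2 == 0) return(0)
  2 * a1 * a2 / (a1 + a2)
}

#' Full metrics report
#'
#' @inheritParams bf_score
#' @return List with `accuracy`, `dice`, `jaccard` and `bf_score`, each in
#'   `[0, 1]`.
#' @export
metrics_report <- function(mask, truth, distance_tol = 2) {
  cc <- confusion(mask, truth)
  list(accuracy = accuracy(cc),
       dice = dice(mask, truth),
       jaccard = jaccard(mask, truth),
       bf_score = bf_score(mask, truth, distance_tol))
}
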