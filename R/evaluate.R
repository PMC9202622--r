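#' Confusion counts
#'
#' @param tr_p,tr_n True positives / true negatives.
#' @param fl_p,fl_n False positives / false negatives.
#' @return Object of class `confusion_counts` with the counts plus the
#'   class totals `NP = tr_p + fl_n` and `NN = tr_n + fl_p`.
#' @export
confusion_counts <- function(tr_p, tr_n, fl_p, fl_n) {
  cts <- c(tr_p = tr_p, tr_n = tr_n, fl_p = fl_p, fl_n = fl_n)
  if (any(cts < 0) || any(!is.finite(cts)))
    stop_config("confusion counts must be nonnegative")
  structure(list(tr_p = tr_p, tr_n = tr_n, fl_p = fl_p, fl_n = fl_n,
                 NP = tr_p + fl_n, NN = tr_n + fl_p),
            class = "confusion_counts")
}

#' Accuracy, sensitivity and specificity from confusion counts
#'
#' Accuracy is `(tr_p + tr_n) / (NP + NN)`; sensitivity (recall) is
#' `tr_p / (tr_p + fl_n)`; specificity is `tr_n / (tr_n + fl_p)`. A
#' class-conditional metric whose denominator is zero is returned as
#' `NA` (undefined).
#'
#' @param c A [confusion_counts()].
#' @return Named numeric vector `accuracy`, `sensitivity`, `specificity`.
#' @export
confusion_metrics <- function(c) {
  stopifnot(inherits(c, "confusion_counts"))
  if (c$NP + c$NN <= 0) stop_config("no observations")
  c(accuracy = (c$tr_p + c$tr_n) / (c$NP + c$NN),
    sensitivity = if (c$NP > 0) c$tr_p / c$NP else NA_real_,
    specificity = if (c$NN > 0) c$tr_n / c$NN else NA_real_)
}

#' Revised contrast-to-noise ratio
#'
#' `rCNR = |In_A - In_B| / sigma_n` with `In_A` the mean intensity under
#' the vessel mask, `In_B` under the background mask, and `sigma_n` the
#' image noise level (estimated adaptively when not supplied).
#'
#' @param image Intensity image.
#' @param vessel_mask,background_mask Nonempty binary masks.
#' @param sigma_n Noise standard deviation; `NULL` estimates it with
#'   [estimate_noise_power()].
#' @return Nonnegative scalar.
#' @export
rcnr <- function(image, vessel_mask, background_mask, sigma_n = NULL) {
  check_image(image)
  if (!any(vessel_mask > 0) || !any(background_mask > 0))
    stop_config("both masks must be nonempty")
  sigma_n <- sigma_n %||% estimate_noise_power(image)
  if (sigma_n <= 0) stop_config("degenerate noise level sigma_n = 0")
  abs(mean(image[vessel_mask > 0]) - mean(image[background_mask > 0])) / sigma_n
}

#' Mean squared error
#'
#' @param a,b Numeric vectors or matrices of equal length.
#' @return Mean of squared differences; 0 iff identical.
#' @export
mse <- function(a, b) {
  if (length(a) != length(b)) stop_config("length mismatch")
  mean((as.numeric(a) - as.numeric(b))^2)
}

#' Dice coefficient and Jaccard index of a mask pair
#'
#' `dice = 2|R ∩ Rhat| / (|R| + |Rhat|)`, `jaccard = |R ∩ Rhat| /
#' |R ∪ Rhat|`; the identity `dice = 2 jaccard / (1 + jaccard)` holds.
#' Two empty masks agree perfectly on absence and return `(1, 1)` by
#' convention (flagged via attribute `"both_empty"`).
#'
#' @param reference,predicted Binary matrices of equal shape.
#' @return Named vector `c(dice, jaccard)`.
#' @export
dice_jaccard <- function(reference, predicted) {
  if (!all(dim(reference) == dim(predicted))) stop_config("shape mismatch")
  r <- reference > 0; p <- predicted > 0
  inter <- sum(r & p)
  uni <- sum(r | p)
  if (uni == 0) {
    out <- c(dice = 1, jaccard = 1)
    attr(out, "both_empty") <- TRUE
    return(out)
  }
  c(dice = 2 * inter / (sum(r) + sum(p)), jaccard = inter / uni)
}

# Boundary pixels of a mask: foreground pixels with an 8-neighbour (or
# image border) outside the mask.
mask_boundary <- function(mask) {
  m <- mask > 0
  interior <- m
  for (s in list(c(-1, -1), c(-1, 0), c(-1, 1), c(0, -1),
                 c(0, 1), c(1, -1), c(1, 0), c(1, 1)))
    interior <- interior & shift_mat(m, s[1], s[2])
  which(m & !interior, arr.ind = TRUE)
}

#' Hausdorff distance between two point sets
#'
#' Symmetric Hausdorff distance
#' `max(max_p min_q d(p, q), max_q min_p d(p, q))` with Euclidean
#' `d`. Binary matrices are accepted and reduced to their 8-connectivity
#' boundary pixels first (the point-set formulation is
#' boundary-sensitive).
#'
#' @param p,q Point sets as 2-column coordinate matrices, or binary mask
#'   matrices.
#' @return Nonnegative scalar (pixels).
#' @export
hausdorff <- function(p, q) {
  # a 2-column matrix is a point set; anything else is a mask whose
  # boundary pixels form the set
  as_pts <- function(x) {
    if (is.matrix(x) && ncol(x) == 2L) x else mask_boundary(x)
  }
  p <- as_pts(p); q <- as_pts(q)
  if (is.null(dim(p)) || nrow(p) == 0 || nrow(q) == 0)
    stop_config("both point sets must be nonempty")
  directed <- function(a, b) {
    # max over a of min distance to b, chunked to bound memory
    worst <- 0
    step <- max(1L, floor(2e6 / nrow(b)))
    for (s in seq(1, nrow(a), step)) {
      ii <- s:min(s + step - 1L, nrow(a))
      d2 <- outer(a[ii, 1], b[, 1], "-")^2 + outer(a[ii, 2], b[, 2], "-")^2
      worst <- max(worst, max(apply(d2, 1, min)))
    }
    sqrt(worst)
  }
  max(directed(p, q), directed(q, p))
}

#' Peak signal-to-noise ratio
#'
#' `PSNR = 10 log10(peak^2 / MSE)` in dB; identical images have infinite
#' PSNR and are flagged via attribute `"identical"`.
#'
#' @param reference,test Images of equal shape.
#' @param peak Peak intensity (255 for 8-bit images).
#' @return PSNR in dB.
#' @export
psnr <- function(reference, test, peak = 255) {
  if (!all(dim(reference) == dim(test))) stop_config("shape mismatch")
  if (peak <= 0) stop_config("peak must be positive")
  m <- mse(reference, test)
  if (m == 0) {
    out <- Inf
    attr(out, "identical") <- TRUE
    return(out)
  }
  10 * log10(peak^2 / m)
}

#' ROC curve and AUC
#'
#' True/false positive rates at every distinct score threshold (a
#' monotone staircase from (0,0) to (1,1)) and the trapezoidal AUC,
#' which equals the Mann-Whitney pair-counting statistic.
#'
#' @param scores Numeric scores (higher = more positive).
#' @param labels Binary labels (0/1, logical, or a 2-level factor where
#'   the second level is positive).
#' @return List with `points` (data frame `fpr`, `tpr`, `threshold`) and
#'   `auc`.
#' @export
roc_curve <- function(scores, labels) {
  if (is.factor(labels)) labels <- as.integer(labels) - 1L
  labels <- as.integer(labels > 0)
  if (length(unique(labels)) < 2) stop_config("both classes must be present")
  if (length(scores) != length(labels)) stop_config("length mismatch")
  o <- order(scores, decreasing = TRUE)
  s <- scores[o]; y <- labels[o]
  np <- sum(y); nn <- length(y) - np
  tp <- cumsum(y); fp <- cumsum(1 - y)
  last <- c(diff(s) != 0, TRUE)   # keep one point per distinct score
  pts <- data.frame(fpr = c(0, fp[last] / nn), tpr = c(0, tp[last] / np),
                    threshold = c(Inf, s[last]))
  auc <- sum(diff(pts$fpr) * (pts$tpr[-1] + pts$tpr[-nrow(pts)]) / 2)
  list(points = pts, auc = auc)
}

#' Pixelwise segmentation accuracy
#'
#' Fraction of pixels on which the two masks agree
#' (`(TP + TN) / all pixels`).
#'
#' @param reference,predicted Binary matrices of equal shape.
#' @return Scalar in `[0, 1]`.
#' @export
segmentation_accuracy <- function(reference, predicted) {
  if (!all(dim(reference) == dim(predicted))) stop_config("shape mismatch")
  mean((reference > 0) == (predicted > 0))
}
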