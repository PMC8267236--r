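# Evaluation metrics over the nested tumor regions: pixel confusion counts,
# Dice / precision / sensitivity, symmetric boundary Hausdorff distance, and
# dataset-level region reports.

#' Pixel confusion counts
#'
#' @param pred,truth binary masks (logical or 0/1), same shape.
#' @return list with `tp`, `fp`, `fn`, `tn` pixel counts.
#' @export
confusion_counts <- function(pred, truth) {
  check_same_shape(pred, truth, "pred and truth")
  p <- as.logical(pred); t <- as.logical(truth)
  list(tp = sum(p & t), fp = sum(p & !t), fn = sum(!p & t),
       tn = sum(!p & !t))
}

# Degenerate-denominator convention: a slice where both prediction and truth
# are empty is scored perfect (1) rather than NaN, so tumor-free slices do
# not poison dataset averages.

#' Dice coefficient from confusion counts
#'
#' `2*TP / (2*TP + FP + FN)`; both-empty masks score 1.
#' @param c confusion counts from [confusion_counts()].
#' @return value in `[0, 1]`.
#' @export
dice_coefficient <- function(c) {
  den <- 2 * c$tp + c$fp + c$fn
  if (den == 0) 1 else 2 * c$tp / den
}

#' Precision from confusion counts
#'
#' `TP / (TP + FP)`; scores 1 when nothing is predicted and nothing is true,
#' 0 when something is predicted but nothing is true.
#' @inheritParams dice_coefficient
#' @return value in `[0, 1]`.
#' @export
precision <- function(c) {
  if (c$tp + c$fp == 0) return(if (c$fn == 0) 1 else 0)
  c$tp / (c$tp + c$fp)
}

#' Sensitivity (recall) from confusion counts
#'
#' `TP / (TP + FN)`; scores 1 when nothing is true and nothing predicted,
#' 0 when something is true but nothing predicted hits it.
#' @inheritParams dice_coefficient
#' @return value in `[0, 1]`.
#' @export
sensitivity <- function(c) {
  if (c$tp + c$fn == 0) return(if (c$fp == 0) 1 else 0)
  c$tp / (c$tp + c$fn)
}

#' Boundary pixels of a binary mask
#'
#' A pixel is boundary if it is foreground and at least one of its four
#' axial neighbors is background; pixels on the array edge count their
#' outside neighbors as background.
#'
#' @param mask binary matrix.
#' @return two-column matrix of (row, col) coordinates.
#' @export
mask_boundary <- function(mask) {
  m <- matrix(as.logical(mask), nrow(mask))
  H <- nrow(m); W <- ncol(m)
  pad <- matrix(FALSE, H + 2, W + 2)
  pad[2:(H + 1), 2:(W + 1)] <- m
  inner <- pad[1:H, 2:(W + 1)] & pad[3:(H + 2), 2:(W + 1)] &
    pad[2:(H + 1), 1:W] & pad[2:(H + 1), 3:(W + 2)]
  which(m & !inner, arr.ind = TRUE)
}

directed_hausdorff <- function(a, b) {
  # max over rows of a of the distance to the nearest row of b
  d2 <- outer(a[, 1], b[, 1], "-")^2 + outer(a[, 2], b[, 2], "-")^2
  max(sqrt(apply(d2, 1, min)))
}

#' Symmetric Hausdorff distance between mask boundaries
#'
#' `max(h(A, B), h(B, A))` where `h` is the directed nearest-boundary-point
#' distance in Euclidean pixel units. Two empty masks are at distance 0;
#' if exactly one mask is empty the configured sentinel (default: the image
#' diagonal) is returned.
#'
#' @param pred,truth binary masks, same shape.
#' @param empty_value sentinel for the one-empty case; `NULL` means the
#'   image diagonal.
#' @return non-negative distance in pixels.
#' @export
hausdorff_distance <- function(pred, truth, empty_value = NULL) {
  check_same_shape(pred, truth, "pred and truth")
  pe <- !any(as.logical(pred)); te <- !any(as.logical(truth))
  if (pe && te) return(0)
  if (pe || te) {
    if (is.null(empty_value)) {
      empty_value <- sqrt(sum((dim(as.matrix(pred)) - 1)^2))
    }
    return(empty_value)
  }
  a <- mask_boundary(as.matrix(pred))
  b <- mask_boundary(as.matrix(truth))
  max(directed_hausdorff(a, b), directed_hausdorff(b, a))
}

region_names <- c("WT", "CT", "ET")

slice_region_metrics <- function(pred, truth) {
  out <- matrix(NA_real_, 3, 4,
                dimnames = list(region_names,
                                c("dice", "precision", "sensitivity",
                                  "hausdorff")))
  for (r in region_names) {
    key <- tolower(r)
    cc <- confusion_counts(pred[[key]], truth[[key]])
    out[r, ] <- c(dice_coefficient(cc), precision(cc), sensitivity(cc),
                  hausdorff_distance(pred[[key]], truth[[key]]))
  }
  out
}

#' Evaluate predicted region masks against ground truth
#'
#' Computes Dice, precision, sensitivity and Hausdorff distance per slice
#' for each nested region (WT, CT, ET), averages over the dataset, and adds
#' the cross-region mean of each index.
#'
#' @param preds,truths equal-length lists of region-target lists (elements
#'   `wt`, `ct`, `et`, e.g. from [labels_to_regions()]).
#' @return a `region_report` data.frame with rows WT, CT, ET, Mean and
#'   columns `dice`, `precision`, `sensitivity`, `hausdorff`.
#' @export
evaluate_regions <- function(preds, truths) {
  if (length(preds) != length(truths)) {
    stop("preds (", length(preds), ") and truths (", length(truths),
         ") have different lengths")
  }
  if (length(preds) == 0) stop("empty evaluation set")
  acc <- matrix(0, 3, 4)
  for (i in seq_along(preds)) {
    acc <- acc + slice_region_metrics(preds[[i]], truths[[i]])
  }
  acc <- acc / length(preds)
  rep <- as.data.frame(rbind(acc, Mean = colMeans(acc)))
  rep <- cbind(region = c(region_names, "Mean"), rep)
  rownames(rep) <- NULL
  class(rep) <- c("region_report", "data.frame")
  rep
}

#' Write a region report as CSV
#'
#' @param report a `region_report` from [evaluate_regions()].
#' @param path output CSV path.
#' @return the path, invisibly.
#' @export
write_region_report <- function(report, path) {
  write.csv(report, path, row.names = FALSE)
  invisible(path)
}
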