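# Composite deep-supervision loss: binary cross-entropy, smoothed Dice,
# their weighted combination, and the four-term total over all supervision
# heads.

#' Loss weights
#'
#' @param alpha BCE weight inside the combined BCE+Dice loss (default 0.5).
#' @param lambda1 weight of the encoder (down) and decoder (up) supervision
#'   terms (default 0.4).
#' @param lambda2 weight of the dual-attention bottleneck term
#'   (default 0.2).
#' @param epsilon Dice smoothing factor (default 1e-5).
#' @return a `loss_weights` list.
#' @export
loss_weights <- function(alpha = 0.5, lambda1 = 0.4, lambda2 = 0.2,
                         epsilon = 1e-5) {
  stopifnot(alpha >= 0, lambda1 >= 0, lambda2 >= 0, epsilon > 0)
  structure(list(alpha = alpha, lambda1 = lambda1, lambda2 = lambda2,
                 epsilon = epsilon), class = "loss_weights")
}

check_same_shape <- function(a, b, what = "prediction and target") {
  da <- dim(a); db <- dim(b)
  if (is.null(da)) da <- length(a)
  if (is.null(db)) db <- length(b)
  if (length(da) != length(db) || any(da != db)) {
    stop(what, " shapes differ: ", paste(da, collapse = "x"), " vs ",
         paste(db, collapse = "x"))
  }
}

#' Binary cross-entropy loss
#'
#' Mean binary cross-entropy over all elements, with probabilities clamped
#' to `[clamp, 1 - clamp]` for log safety.
#'
#' @param pred_prob predicted probabilities (any array).
#' @param target binary targets, same shape.
#' @param clamp clamping bound (default 1e-7).
#' @return scalar loss.
#' @export
bce_loss <- function(pred_prob, target, clamp = 1e-7) {
  check_same_shape(pred_prob, target)
  p <- pmin(pmax(pred_prob, clamp), 1 - clamp)
  -mean(target * log(p) + (1 - target) * log(1 - p))
}

#' Smoothed Dice loss
#'
#' One minus the smoothed Dice similarity
#' `2 * sum(T*P) / (sum(T^2) + sum(P^2) + epsilon)`; 0 at perfect overlap,
#' close to 1 for disjoint non-empty masks.
#'
#' @param pred_prob predicted probabilities.
#' @param target binary targets, same shape.
#' @param epsilon smoothing factor.
#' @return scalar loss in `[0, 1]`.
#' @export
dice_loss <- function(pred_prob, target, epsilon = 1e-5) {
  check_same_shape(pred_prob, target)
  1 - 2 * sum(target * pred_prob) /
    (sum(target^2) + sum(pred_prob^2) + epsilon)
}

#' Combined BCE + Dice loss
#'
#' `alpha * BCE + Dice`, the per-head segmentation loss.
#'
#' @inheritParams bce_loss
#' @param weights a [loss_weights()] list supplying `alpha` and `epsilon`.
#' @return scalar loss.
#' @export
combined_loss <- function(pred_prob, target, weights = loss_weights()) {
  weights$alpha * bce_loss(pred_prob, target) +
    dice_loss(pred_prob, target, weights$epsilon)
}

#' Total deep-supervision loss
#'
#' `lambda1 * (L_down + L_up) + lambda2 * L_dual + L_result`, where
#' `L_down`/`L_up` average the combined loss over the four encoder/decoder
#' supervision heads, `L_dual` is the bottleneck head's loss and `L_result`
#' the final head's. Heads in the bundle are logits; the sigmoid is applied
#' here.
#'
#' @param bundle a `supervision_bundle` from [aanet_forward()].
#' @param target binary region target array `H x W x R` (or `x N`) matching
#'   the heads' resolution, e.g. from [regions_to_array()].
#' @param weights a [loss_weights()] list.
#' @return list with `total` and the `l_down`, `l_up`, `l_dual`, `l_result`
#'   breakdown (NA for absent zero-weight terms).
#' @export
total_loss <- function(bundle, target, weights = loss_weights()) {
  head_loss <- function(z) combined_loss(plogis(z), target, weights)
  mean_heads <- function(zs, term, w) {
    zs <- Filter(Negate(is.null), zs)
    if (length(zs) == 0) {
      if (w > 0) stop("no ", term, " heads present but their weight is ", w)
      return(NA_real_)
    }
    mean(vapply(zs, head_loss, 0))
  }
  l_down <- mean_heads(bundle$eds_logits, "down-supervision",
                       weights$lambda1)
  l_up <- mean_heads(bundle$us_logits, "up-supervision", weights$lambda1)
  if (is.null(bundle$daf_logits)) {
    if (weights$lambda2 > 0) {
      stop("no dual-attention head present but lambda2 is ",
           weights$lambda2)
    }
    l_dual <- NA_real_
  } else {
    l_dual <- head_loss(bundle$daf_logits)
  }
  if (is.null(bundle$final_logits)) stop("bundle has no final head")
  l_result <- head_loss(bundle$final_logits)
  z <- function(x) if (is.na(x)) 0 else x
  total <- weights$lambda1 * (z(l_down) + z(l_up)) +
    weights$lambda2 * z(l_dual) + l_result
  list(total = total, l_down = l_down, l_up = l_up, l_dual = l_dual,
       l_result = l_result)
}
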