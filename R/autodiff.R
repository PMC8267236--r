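# Reverse-mode autodiff tape.
#
# Values are plain R arrays laid out H x W x C x N (see kernels.cpp). A tape
# records nodes in topological (creation) order; each non-leaf node carries a
# backward closure returning gradients for its parents. Backprop walks the
# node list in reverse, accumulating into node$grad. Parameter leaves are
# registered by name so a training step can collect a named gradient list.

tape_new <- function() {
  tp <- new.env(parent = emptyenv())
  tp$nodes <- vector("list", 64L)
  tp$n <- 0L
  tp$param_nodes <- list()
  tp
}

node_new <- function(tape, value, parents = list(), backward = NULL) {
  nd <- new.env(parent = emptyenv())
  nd$value <- value
  nd$grad <- NULL
  nd$parents <- parents
  nd$backward <- backward
  tape$n <- tape$n + 1L
  if (tape$n > length(tape$nodes)) {
    tape$nodes <- c(tape$nodes, vector("list", length(tape$nodes)))
  }
  tape$nodes[[tape$n]] <- nd
  nd
}

op_input <- function(tape, value) node_new(tape, value)

# Parameter leaf; one node per name per tape.
op_param <- function(tape, name, value) {
  nd <- tape$param_nodes[[name]]
  if (is.null(nd)) {
    nd <- node_new(tape, value)
    nd$pname <- name
    tape$param_nodes[[name]] <- nd
  }
  nd
}

acc_grad <- function(node, g) {
  if (is.null(node$grad)) node$grad <- g else node$grad <- node$grad + g
}

#' @noRd
backprop <- function(tape, root) {
  root$grad <- 1
  for (i in rev(seq_len(tape$n))) {
    nd <- tape$nodes[[i]]
    if (is.null(nd$grad) || is.null(nd$backward)) next
    gs <- nd$backward(nd)
    for (k in seq_along(nd$parents)) {
      if (!is.null(gs[[k]])) acc_grad(nd$parents[[k]], gs[[k]])
    }
  }
  grads <- lapply(tape$param_nodes, function(nd) {
    if (is.null(nd$grad)) nd$value * 0 else nd$grad
  })
  grads
}

# ---- elementwise and structural ops ----------------------------------------

op_add <- function(tape, a, b) {
  node_new(tape, a$value + b$value, list(a, b),
           function(nd) list(nd$grad, nd$grad))
}

op_relu <- function(tape, x) {
  mask <- x$value > 0
  node_new(tape, x$value * mask, list(x),
           function(nd) list(nd$grad * mask))
}

op_sigmoid <- function(tape, x) {
  s <- 1 / (1 + exp(-x$value))
  node_new(tape, s, list(x),
           function(nd) list(nd$grad * s * (1 - s)))
}

# Concatenate along the channel axis (3rd of H,W,C,N).
op_concat_c <- function(tape, xs) {
  dims <- lapply(xs, function(x) dim(x$value))
  H <- dims[[1]][1]; W <- dims[[1]][2]; N <- dims[[1]][4]
  cs <- vapply(dims, function(d) d[3], 0)
  out <- array(0, c(H, W, sum(cs), N))
  at <- 0L
  for (k in seq_along(xs)) {
    out[, , at + seq_len(cs[k]), ] <- xs[[k]]$value
    at <- at + cs[k]
  }
  node_new(tape, out, xs, function(nd) {
    at <- 0L
    gs <- vector("list", length(xs))
    for (k in seq_along(xs)) {
      gs[[k]] <- nd$grad[, , at + seq_len(cs[k]), , drop = FALSE]
      at <- at + cs[k]
    }
    gs
  })
}

# ---- compiled-layer ops ----------------------------------------------------

op_conv <- function(tape, x, w, b, pad = 0L, dil = 1L) {
  y <- conv2d_fw(x$value, w$value, b$value, pad, dil)
  node_new(tape, y, list(x, w, b), function(nd) {
    g <- conv2d_bw(x$value, w$value, nd$grad, pad, dil)
    list(g$gx, g$gw, g$gb)
  })
}

op_maxpool2 <- function(tape, x) {
  r <- maxpool2_fw(x$value)
  d <- dim(x$value)
  node_new(tape, r$y, list(x), function(nd) {
    list(maxpool2_bw(r$idx, nd$grad, d[1], d[2]))
  })
}

op_upsample2 <- function(tape, x) {
  node_new(tape, upsample2_fw(x$value), list(x), function(nd) {
    list(upsample2_bw(nd$grad))
  })
}

# Repeated factor-2 bilinear upsampling to reach `times` doublings.
op_upsample_to <- function(tape, x, times) {
  nd <- x
  for (i in seq_len(times)) nd <- op_upsample2(tape, nd)
  nd
}

# ---- batch normalization ---------------------------------------------------

# Batch normalization with optional fused ReLU (the conv-BN-ReLU motif).
# gamma/beta are length-C parameter leaves. `running` is an environment with
# $mean/$var updated in training mode and used in eval mode. Statistics and
# gradients are computed in the compiled kernels.
op_bn <- function(tape, x, gamma, beta, running, training,
                  momentum = 0.1, eps = 1e-5, relu = FALSE) {
  C <- dim(x$value)[3]
  r <- bn_relu_fw(x$value, gamma$value, beta$value,
                  if (is.null(running$mean)) numeric(C) else running$mean,
                  if (is.null(running$var)) rep(1, C) else running$var,
                  training, relu, eps)
  if (training) {
    if (is.null(running$mean)) {
      running$mean <- r$mu
      running$var <- r$var
    } else {
      running$mean <- (1 - momentum) * running$mean + momentum * r$mu
      running$var <- (1 - momentum) * running$var + momentum * r$var
    }
  }
  node_new(tape, r$y, list(x, gamma, beta), function(nd) {
    g <- bn_relu_bw(nd$grad, r$y, r$xhat, gamma$value, r$invstd, training,
                    relu)
    list(g$gx, g$ggamma, g$gbeta)
  })
}

# ---- attention heads -------------------------------------------------------

softmax_rows <- function(e) {
  s <- exp(e - apply(e, 1, max))
  s / rowSums(s)
}

softmax_rows_bw <- function(s, ds) {
  s * (ds - rowSums(ds * s))
}

# x as C x P matrix from an H x W x C slab (pixels are columns).
to_cp <- function(x, d) t(matrix(x, nrow = d[1] * d[2]))
from_cp <- function(m, d) array(t(m), c(d[1], d[2], nrow(m)))

# Positional attention (spatial affinity). wa/wb project to a reduced channel
# dimension; wc is the value projection; alpha the learnable residual scale.
# Returns the output node; row-normalized attention maps (one P x P matrix per
# batch element) are stored on the node as $maps.
op_pos_attention <- function(tape, x, wa, ba, wb, bb, wc, bc, alpha) {
  d <- dim(x$value)
  N <- d[4]
  cache <- vector("list", N)
  out <- array(0, d)
  for (n in seq_len(N)) {
    X <- to_cp(x$value[, , , n, drop = FALSE], d)            # C x P
    A <- wa$value %*% X + ba$value                           # C' x P
    B <- wb$value %*% X + bb$value
    V <- wc$value %*% X + bc$value                           # C x P
    E <- crossprod(B, A)                                     # P x P, [j,i]=A_i.B_j
    S <- softmax_rows(E)
    O <- V %*% t(S)                                          # C x P
    Y <- alpha$value[1] * O + X
    out[, , , n] <- from_cp(Y, d)
    cache[[n]] <- list(X = X, A = A, B = B, V = V, S = S, O = O)
  }
  nd <- node_new(tape, out, list(x, wa, ba, wb, bb, wc, bc, alpha),
    function(nd) {
      gX_all <- array(0, d)
      gwa <- wa$value * 0; gba <- ba$value * 0
      gwb <- wb$value * 0; gbb <- bb$value * 0
      gwc <- wc$value * 0; gbc <- bc$value * 0
      galpha <- 0
      for (n in seq_len(N)) {
        cc <- cache[[n]]
        dY <- to_cp(nd$grad[, , , n, drop = FALSE], d)
        galpha <- galpha + sum(dY * cc$O)
        dO <- alpha$value[1] * dY
        dV <- dO %*% cc$S
        dS <- crossprod(dO, cc$V)
        dE <- softmax_rows_bw(cc$S, dS)
        dA <- cc$B %*% dE
        dB <- cc$A %*% t(dE)
        dX <- dY +
          crossprod(wa$value, dA) +
          crossprod(wb$value, dB) +
          crossprod(wc$value, dV)
        gwa <- gwa + dA %*% t(cc$X); gba <- gba + rowSums(dA)
        gwb <- gwb + dB %*% t(cc$X); gbb <- gbb + rowSums(dB)
        gwc <- gwc + dV %*% t(cc$X); gbc <- gbc + rowSums(dV)
        gX_all[, , , n] <- from_cp(dX, d)
      }
      list(gX_all, gwa, gba, gwb, gbb, gwc, gbc, galpha)
    })
  nd$maps <- lapply(cache, `[[`, "S")
  nd
}

# Channel attention: affinities from the raw feature reshape (no convolution),
# beta the learnable residual scale. Attention maps (C x C) stored as $maps.
op_chan_attention <- function(tape, x, beta) {
  d <- dim(x$value)
  N <- d[4]
  cache <- vector("list", N)
  out <- array(0, d)
  for (n in seq_len(N)) {
    X <- to_cp(x$value[, , , n, drop = FALSE], d)  # C x P
    E <- X %*% t(X)                                # C x C, [j,i]=X_j.X_i
    M <- softmax_rows(E)
    O <- M %*% X
    Y <- beta$value[1] * O + X
    out[, , , n] <- from_cp(Y, d)
    cache[[n]] <- list(X = X, M = M, O = O)
  }
  nd <- node_new(tape, out, list(x, beta), function(nd) {
    gX_all <- array(0, d)
    gbeta <- 0
    for (n in seq_len(N)) {
      cc <- cache[[n]]
      dY <- to_cp(nd$grad[, , , n, drop = FALSE], d)
      gbeta <- gbeta + sum(dY * cc$O)
      dO <- beta$value[1] * dY
      dM <- dO %*% t(cc$X)
      dX <- dY + crossprod(cc$M, dO)
      dE <- softmax_rows_bw(cc$M, dM)
      dX <- dX + dE %*% cc$X + crossprod(dE, cc$X)
      gX_all[, , , n] <- from_cp(dX, d)
    }
    list(gX_all, gbeta)
  })
  nd$maps <- lapply(cache, `[[`, "M")
  nd
}

# ---- losses on the tape ----------------------------------------------------

# Composite BCE + Dice segmentation loss from logits. The scalar value is
# alpha_bce * BCE + mean over (channel, sample) of (1 - smoothed Dice).
# Forward and the logit gradient are computed in one compiled pass; BCE and
# Dice component values are stored on the node for logging.
op_seg_loss <- function(tape, z, target, alpha_bce = 0.5, eps = 1e-5,
                        clamp = 1e-7) {
  r <- seg_loss_fwbw(z$value, target, alpha_bce, eps, clamp)
  nd <- node_new(tape, r$value, list(z),
                 function(nd) list(nd$grad * r$dz))
  nd$bce <- r$bce
  nd$dice <- r$dice
  nd
}

# Weighted sum of scalar nodes.
op_wsum <- function(tape, nodes, weights) {
  val <- 0
  for (k in seq_along(nodes)) val <- val + weights[k] * nodes[[k]]$value
  node_new(tape, val, nodes, function(nd) {
    lapply(seq_along(nodes), function(k) weights[k] * nd$grad)
  })
}
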