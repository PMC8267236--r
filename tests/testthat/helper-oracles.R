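# Brute-force oracles and small fixtures shared across test files. The
# oracles are deliberately naive (explicit loops, direct formulas) and
# independent of the package's vectorized/compiled implementations.

rand_feature <- function(H, W, C, seed = 1) {
  set.seed(seed)
  array(rnorm(H * W * C), c(H, W, C))
}

# feature map (H, W, C) -> C x P matrix, pixel p = h + H*(w-1)
cp_matrix <- function(x) {
  d <- dim(x)
  t(matrix(x, d[1] * d[2], d[3]))
}

# positional attention by double loop over pixel pairs
oracle_pos_attention <- function(x, w) {
  X <- cp_matrix(x)
  P <- ncol(X)
  A <- w$wa %*% X + w$ba
  B <- w$wb %*% X + w$bb
  V <- w$wc %*% X + w$bc
  S <- matrix(0, P, P)
  for (j in seq_len(P)) {
    e <- numeric(P)
    for (i in seq_len(P)) e[i] <- exp(sum(A[, i] * B[, j]))
    S[j, ] <- e / sum(e)
  }
  EA <- matrix(0, nrow(X), P)
  for (j in seq_len(P)) {
    acc <- numeric(nrow(X))
    for (i in seq_len(P)) acc <- acc + S[j, i] * V[, i]
    EA[, j] <- w$alpha * acc + X[, j]
  }
  list(ea = array(t(EA), dim(x)), s = S)
}

# channel attention by double loop over channel pairs
oracle_chan_attention <- function(x, beta) {
  X <- cp_matrix(x)
  C <- nrow(X)
  M <- matrix(0, C, C)
  for (j in seq_len(C)) {
    e <- numeric(C)
    for (i in seq_len(C)) e[i] <- exp(sum(X[j, ] * X[i, ]))
    M[j, ] <- e / sum(e)
  }
  CA <- matrix(0, C, ncol(X))
  for (j in seq_len(C)) {
    acc <- numeric(ncol(X))
    for (i in seq_len(C)) acc <- acc + M[j, i] * X[i, ]
    CA[j, ] <- beta * acc + X[j, ]
  }
  list(ca = array(t(CA), dim(x)), m = M)
}

# direct convolution by explicit loops (stride 1)
oracle_conv2d <- function(x, w, b, pad, dil) {
  d <- dim(x); kh <- dim(w)[1]; kw <- dim(w)[2]; cout <- dim(w)[4]
  Ho <- d[1] + 2 * pad - dil * (kh - 1)
  Wo <- d[2] + 2 * pad - dil * (kw - 1)
  y <- array(0, c(Ho, Wo, cout))
  for (o in seq_len(cout)) {
    for (oi in seq_len(Ho)) {
      for (oj in seq_len(Wo)) {
        acc <- b[o]
        for (c in seq_len(d[3])) {
          for (ki in seq_len(kh)) {
            for (kj in seq_len(kw)) {
              ii <- oi - pad + dil * (ki - 1)
              jj <- oj - pad + dil * (kj - 1)
              if (ii >= 1 && ii <= d[1] && jj >= 1 && jj <= d[2]) {
                acc <- acc + x[ii, jj, c] * w[ki, kj, c, o]
              }
            }
          }
        }
        y[oi, oj, o] <- acc
      }
    }
  }
  y
}

# Hausdorff distance by brute force: boundary via per-pixel neighbor
# checks, then a double loop over boundary point pairs
oracle_hausdorff <- function(a, b) {
  boundary_pts <- function(m) {
    pts <- NULL
    for (i in seq_len(nrow(m))) {
      for (j in seq_len(ncol(m))) {
        if (!m[i, j]) next
        nb <- c(
          if (i > 1) m[i - 1, j] else FALSE,
          if (i < nrow(m)) m[i + 1, j] else FALSE,
          if (j > 1) m[i, j - 1] else FALSE,
          if (j < ncol(m)) m[i, j + 1] else FALSE
        )
        if (!all(nb)) pts <- rbind(pts, c(i, j))
      }
    }
    pts
  }
  pa <- boundary_pts(a); pb <- boundary_pts(b)
  directed <- function(p, q) {
    worst <- 0
    for (i in seq_len(nrow(p))) {
      best <- Inf
      for (j in seq_len(nrow(q))) {
        dd <- sqrt(sum((p[i, ] - q[j, ])^2))
        if (dd < best) best <- dd
      }
      if (best > worst) worst <- best
    }
    worst
  }
  max(directed(pa, pb), directed(pb, pa))
}

# tiny network config used across structural tests (32x32 input, base 2)
tiny_config <- function(...) {
  aanet_config(base_channels = 2L, input_size = 32L, ...)
}
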