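# Finite-difference checks of the reverse-mode gradients, layer by layer,
# on tiny tensors. These pin the training machinery: if any layer's
# backward drifts from its forward, optimization results are meaningless.

fd_gradients <- function(build_fn, params, h = 1e-6, probe = 3) {
  ns <- asNamespace("aanet")
  base <- build_fn(params)
  worst <- 0
  for (nm in names(params)) {
    for (i in seq_len(min(length(params[[nm]]), probe))) {
      pp <- params; pp[[nm]][i] <- pp[[nm]][i] + h
      pm <- params; pm[[nm]][i] <- pm[[nm]][i] - h
      num <- (build_fn(pp)$value - build_fn(pm)$value) / (2 * h)
      ana <- base$grads[[nm]][i]
      worst <- max(worst, abs(num - ana) / max(1, abs(num)))
    }
  }
  worst
}

make_builder <- function(x, tgt, body) {
  ns <- asNamespace("aanet")
  function(p) {
    tp <- ns$tape_new()
    P <- function(nm) ns$op_param(tp, nm, p[[nm]])
    xn <- ns$op_input(tp, x)
    loss <- body(ns, tp, P, xn)
    list(value = loss$value, grads = ns$backprop(tp, loss))
  }
}

test_that("conv, fused BN+ReLU, pooling and upsampling gradients match
           finite differences", {
  set.seed(42)
  x <- array(rnorm(6 * 6 * 3 * 2), c(6, 6, 3, 2))
  tgt <- array(rbinom(6 * 6 * 2 * 2, 1, 0.5), c(6, 6, 2, 2))
  params <- list(
    w1 = array(rnorm(3 * 3 * 3 * 4, sd = 0.5), c(3, 3, 3, 4)),
    b1 = rnorm(4), g1 = runif(4, 0.5, 1.5), be1 = rnorm(4),
    w2 = array(rnorm(1 * 1 * 4 * 2, sd = 0.5), c(1, 1, 4, 2)),
    b2 = rnorm(2))
  build <- make_builder(x, tgt, function(ns, tp, P, xn) {
    y <- ns$op_conv(tp, xn, P("w1"), P("b1"), pad = 1L, dil = 1L)
    run <- new.env()
    y <- ns$op_bn(tp, y, P("g1"), P("be1"), run, training = TRUE,
                  relu = TRUE)
    y <- ns$op_maxpool2(tp, y)
    y <- ns$op_upsample2(tp, y)
    z <- ns$op_conv(tp, y, P("w2"), P("b2"), pad = 0L, dil = 1L)
    ns$op_seg_loss(tp, z, tgt)
  })
  expect_lt(fd_gradients(build, params), 1e-5)
})

test_that("dilated convolution and channel-concat gradients match finite
           differences", {
  set.seed(43)
  x <- array(rnorm(6 * 6 * 3 * 2), c(6, 6, 3, 2))
  tgt <- array(rbinom(6 * 6 * 2 * 2, 1, 0.5), c(6, 6, 2, 2))
  params <- list(
    wd = array(rnorm(3 * 3 * 3 * 2, sd = 0.5), c(3, 3, 3, 2)),
    bd = rnorm(2),
    w0 = array(rnorm(1 * 1 * 3 * 2, sd = 0.5), c(1, 1, 3, 2)),
    b0 = rnorm(2),
    wf = array(rnorm(1 * 1 * 4 * 2, sd = 0.5), c(1, 1, 4, 2)),
    bf = rnorm(2))
  build <- make_builder(x, tgt, function(ns, tp, P, xn) {
    a <- ns$op_conv(tp, xn, P("wd"), P("bd"), pad = 2L, dil = 2L)
    b <- ns$op_conv(tp, xn, P("w0"), P("b0"), pad = 0L, dil = 1L)
    y <- ns$op_concat_c(tp, list(a, b))
    z <- ns$op_conv(tp, y, P("wf"), P("bf"), pad = 0L, dil = 1L)
    ns$op_seg_loss(tp, z, tgt)
  })
  expect_lt(fd_gradients(build, params), 1e-5)
})

test_that("attention head gradients match finite differences", {
  set.seed(44)
  x <- array(rnorm(4 * 4 * 4 * 2), c(4, 4, 4, 2))
  tgt <- array(rbinom(4 * 4 * 2 * 2, 1, 0.5), c(4, 4, 2, 2))
  params <- list(
    wa = matrix(rnorm(2 * 4, sd = 0.5), 2), ba = rnorm(2),
    wb = matrix(rnorm(2 * 4, sd = 0.5), 2), bb = rnorm(2),
    wc = matrix(rnorm(4 * 4, sd = 0.5), 4), bc = rnorm(4),
    alpha = 0.7, beta = 0.4,
    wz = array(rnorm(4 * 2, sd = 0.5), c(1, 1, 4, 2)), bz = rnorm(2))
  build <- make_builder(x, tgt, function(ns, tp, P, xn) {
    pa <- ns$op_pos_attention(tp, xn, P("wa"), P("ba"), P("wb"), P("bb"),
                              P("wc"), P("bc"), P("alpha"))
    ca <- ns$op_chan_attention(tp, pa, P("beta"))
    z <- ns$op_conv(tp, ca, P("wz"), P("bz"), pad = 0L, dil = 1L)
    ns$op_seg_loss(tp, z, tgt)
  })
  expect_lt(fd_gradients(build, params), 1e-5)
})

test_that("compiled convolution agrees with the direct-loop oracle", {
  set.seed(45)
  ns <- asNamespace("aanet")
  cases <- list(list(k = 3, pad = 1, dil = 1), list(k = 1, pad = 0, dil = 1),
                list(k = 3, pad = 2, dil = 2), list(k = 3, pad = 6, dil = 6))
  for (cs in cases) {
    x <- rand_feature(9, 9, 3, seed = cs$pad + 10 * cs$dil)
    w <- array(rnorm(cs$k * cs$k * 3 * 2), c(cs$k, cs$k, 3, 2))
    b <- rnorm(2)
    xb <- x; dim(xb) <- c(dim(x), 1L)
    got <- ns$conv2d_fw(xb, w, b, cs$pad, cs$dil)
    want <- oracle_conv2d(x, w, b, cs$pad, cs$dil)
    expect_equal(array(got, dim(want)), want, tolerance = 1e-10)
  }
})
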