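# Architectural contracts: attention normalization and identities, block
# shape algebra, ablation switches, determinism.

test_that("attention maps are row-stochastic for random inputs", {
  set.seed(7)
  for (i in 1:25) {
    C <- sample(2:6, 1); H <- sample(2:5, 1); W <- sample(2:5, 1)
    x <- array(rnorm(H * W * C), c(H, W, C))
    w <- make_pos_attention_weights(C, reduction = 2, alpha = 0.5)
    pa <- positional_attention(x, w)
    expect_equal(rowSums(pa$s), rep(1, H * W), tolerance = 1e-5)
    expect_true(all(pa$s >= 0))
    ca <- channel_attention(x, beta = 0.5)
    expect_equal(rowSums(ca$m), rep(1, C), tolerance = 1e-5)
    expect_true(all(ca$m >= 0))
  }
})

test_that("zero attention scales reduce both heads to the identity", {
  x <- rand_feature(5, 4, 6, seed = 21)
  w <- make_pos_attention_weights(6, alpha = 0)
  expect_equal(positional_attention(x, w)$ea, x, tolerance = 1e-12)
  expect_equal(channel_attention(x, beta = 0)$ca, x, tolerance = 1e-12)
})

test_that("vectorized attention equals the brute-force pair loops", {
  for (seed in 1:4) {
    set.seed(seed)
    C <- sample(2:8, 1); H <- sample(2:6, 1); W <- sample(2:6, 1)
    x <- array(rnorm(H * W * C), c(H, W, C))
    w <- make_pos_attention_weights(C, reduction = 2, alpha = 0.6)
    got <- positional_attention(x, w)
    want <- oracle_pos_attention(x, w)
    expect_equal(got$s, want$s, tolerance = 1e-5)
    expect_equal(got$ea, want$ea, tolerance = 1e-5)
    gotc <- channel_attention(x, beta = 0.3)
    wantc <- oracle_chan_attention(x, 0.3)
    expect_equal(gotc$m, wantc$m, tolerance = 1e-5)
    expect_equal(gotc$ca, wantc$ca, tolerance = 1e-5)
  }
})

test_that("channel attention is equivariant under channel permutation", {
  x <- rand_feature(4, 4, 5, seed = 31)
  perm <- c(3, 5, 1, 4, 2)
  out <- channel_attention(x, beta = 0.8)$ca
  out_p <- channel_attention(x[, , perm], beta = 0.8)$ca
  expect_equal(out_p, out[, , perm], tolerance = 1e-12)
})

test_that("EDS blocks follow the shape contract and halve resolution", {
  set.seed(8)
  w <- make_eds_weights(c_in = 3, c_out = 6)
  x <- rand_feature(16, 16, 3, seed = 9)
  out <- eds_forward(x, w)
  expect_equal(dim(out$h), c(8, 8, 6))
  expect_equal(dim(out$a), c(16, 16, 6))
  expect_error(eds_forward(rand_feature(7, 7, 3), w), "divisible by 2")
  # zeroed parameters: every branch dies, pooled output is exactly zero
  wz <- lapply(w, function(p) p * 0)
  attributes(wz) <- attributes(w)
  outz <- eds_forward(x, wz)
  expect_true(all(outz$h == 0))
})

test_that("EDS arithmetic matches a hand computation on a 2x2 input", {
  # identity-like weights in eval mode: channel 1 of both conv paths
  # passes the input through (up to the BN epsilon scale), so
  # h = maxpool(G2 + R) computed by hand on the 2x2 window
  w <- make_eds_weights(c_in = 1, c_out = 2)
  w[["eds1.c1.w"]][] <- 0; w[["eds1.c1.w"]][2, 2, 1, 1] <- 1
  w[["eds1.c2.w"]][] <- 0; w[["eds1.c2.w"]][2, 2, 1, 1] <- 1
  w[["eds1.res.w"]][] <- 0; w[["eds1.res.w"]][1, 1, 1, 1] <- 1
  for (nm in grep("\\.b$|\\.be$", names(w), value = TRUE)) w[[nm]][] <- 0
  for (nm in grep("\\.g$", names(w), value = TRUE)) w[[nm]][] <- 1
  x <- array(c(1, 2, 3, 4), c(2, 2, 1))
  out <- eds_forward(x, w, training = FALSE)
  s <- 1 / sqrt(1 + 1e-5)  # eval-mode BN with unit running variance
  expect_equal(out$h[1, 1, 1], max(x * s * s + x * s), tolerance = 1e-4)
  expect_equal(out$h[1, 1, 2], 0)
})

test_that("MSC preserves shape and uses the configured dilation branches", {
  w <- make_msc_weights(4)
  a <- rand_feature(10, 10, 4, seed = 12)
  out <- msc_forward(a, w)
  expect_equal(dim(out), dim(a))
  expect_setequal(grep("msc1\\.b", names(w), value = TRUE),
                  c("msc1.b0.w", "msc1.b0.b", "msc1.b6.w", "msc1.b6.b",
                    "msc1.b12.w", "msc1.b12.b", "msc1.b18.w", "msc1.b18.b"))
  # zero input with zero biases: only the fused bias path remains, which
  # is also zero, and ReLU keeps it there
  wz <- w
  for (nm in grep("\\.b$|\\.be$", names(wz), value = TRUE)) wz[[nm]][] <- 0
  expect_true(all(msc_forward(array(0, c(6, 6, 4)), wz) == 0))
})

test_that("DAF variants share the shape contract; DAF1 composes the two
           attention heads", {
  x <- rand_feature(4, 4, 8, seed = 13)
  outs <- lapply(c("DAF1", "DAF2", "DAF3"), function(v) {
    set.seed(20)
    w <- make_daf_weights(8, v, full_size = 16,
                          attention_scale_init = 0.5)
    daf_forward(x, w, v)
  })
  for (o in outs) {
    expect_equal(dim(o$fused), c(4, 4, 8))
    expect_equal(dim(o$aux_logits), c(16, 16, 3))
  }
  set.seed(20)
  w <- make_daf_weights(8, "DAF1", full_size = 16,
                        attention_scale_init = 0.5)
  expect_error(daf_forward(x, w, "DAF2"), "built for DAF1")

  # compositional oracle: recompute DAF1 from the standalone attention ops
  ns <- asNamespace("aanet")
  cbr_eval <- function(xx, pre) {
    xb <- xx; dim(xb) <- c(dim(xx), 1L)
    y <- ns$conv2d_fw(xb, w[[paste0(pre, ".w")]], w[[paste0(pre, ".b")]],
                      1L, 1L)
    C <- dim(y)[3]
    r <- ns$bn_relu_fw(y, w[[paste0(pre, ".g")]], w[[paste0(pre, ".be")]],
                       numeric(C), rep(1, C), FALSE, TRUE, 1e-5)
    array(r$y, dim(r$y)[1:3])
  }
  y2 <- cbr_eval(cbr_eval(x, "daf.c1"), "daf.c2")
  pw <- list(wa = w[["daf.pa.wa"]], ba = w[["daf.pa.ba"]],
             wb = w[["daf.pa.wb"]], bb = w[["daf.pa.bb"]],
             wc = w[["daf.pa.wc"]], bc = w[["daf.pa.bc"]],
             alpha = w[["daf.pa.alpha"]])
  pa <- positional_attention(y2, pw)$ea
  ca <- channel_attention(y2, w[["daf.ca.beta"]])$ca
  summed <- pa + ca
  fuse <- ns$conv2d_fw(array(summed, c(dim(summed), 1)),
                       w[["daf.fuse.w"]], w[["daf.fuse.b"]], 0L, 1L)
  r <- ns$bn_relu_fw(fuse, w[["daf.fuse.g"]], w[["daf.fuse.be"]],
                     numeric(8), rep(1, 8), FALSE, TRUE, 1e-5)
  want <- array(r$y, c(4, 4, 8))
  got <- daf_forward(x, w, "DAF1")$fused
  expect_equal(got, want, tolerance = 1e-10)
})

test_that("US blocks concatenate, fuse and upsample per the shape
           contract", {
  w <- make_us_weights(c_prev = 4, c_skip = 3, c_out = 5)
  prev <- rand_feature(8, 8, 4, seed = 14)
  skip <- rand_feature(8, 8, 3, seed = 15)
  out <- us_forward(prev, skip, w)
  expect_equal(dim(out$up), c(16, 16, 5))
  expect_equal(dim(out$aux_logits), c(8, 8, 3))
  flat <- us_forward(prev, skip, w, upsample_out = FALSE)
  expect_equal(dim(flat$up), c(8, 8, 5))
  expect_error(us_forward(prev, rand_feature(4, 4, 3), w),
               "spatial mismatch")
  wz <- lapply(w, function(p) p * 0)
  attributes(wz) <- attributes(w)
  expect_true(all(us_forward(prev, skip, wz)$up == 0))
})

test_that("the full forward emits all supervision heads at full
           resolution", {
  model <- aanet_model(tiny_config(), seed = 3)
  x <- rand_feature(32, 32, 4, seed = 16)
  b <- aanet_forward(model, x)
  expect_s3_class(b, "supervision_bundle")
  expect_equal(dim(b$final_logits), c(32, 32, 3))
  for (h in b$eds_logits) expect_equal(dim(h), c(32, 32, 3))
  for (h in b$us_logits) expect_equal(dim(h), c(32, 32, 3))
  expect_equal(dim(b$daf_logits), c(32, 32, 3))
  expect_error(aanet_forward(model, rand_feature(16, 16, 4)),
               "does not match")
  # eval-mode determinism
  b2 <- aanet_forward(model, x)
  expect_identical(b$final_logits, b2$final_logits)
})

test_that("ablation switches cover the module on/off and MSC-position
           grid", {
  x <- rand_feature(32, 32, 4, seed = 17)
  configs <- list(
    tiny_config(use_eds = FALSE, use_usl = FALSE, use_daf = FALSE,
                msc_positions = integer(0),
                supervision = list(down = FALSE, up = FALSE, dual = FALSE)),
    tiny_config(use_usl = FALSE, use_daf = FALSE,
                msc_positions = integer(0),
                supervision = list(down = FALSE, up = FALSE, dual = FALSE)),
    tiny_config(use_daf = FALSE, msc_positions = integer(0),
                supervision = list(down = FALSE, up = FALSE, dual = FALSE)),
    tiny_config(msc_positions = integer(0),
                supervision = list(down = FALSE, up = FALSE, dual = TRUE)),
    tiny_config(msc_positions = 1L),
    tiny_config(msc_positions = c(1L, 2L)),
    tiny_config(msc_positions = c(1L, 2L, 3L)),
    tiny_config(daf_variant = "DAF2"),
    tiny_config(daf_variant = "DAF3"))
  for (cfg in configs) {
    model <- aanet_model(cfg, seed = 5)
    b <- aanet_forward(model, x)
    expect_equal(dim(b$final_logits), c(32, 32, 3))
    n_heads <- length(Filter(Negate(is.null), b$eds_logits)) +
      length(Filter(Negate(is.null), b$us_logits)) +
      !is.null(b$daf_logits)
    expect_true(n_heads <= 9)
  }
  full <- aanet_forward(aanet_model(tiny_config(), seed = 5), x)
  expect_equal(length(Filter(Negate(is.null), full$eds_logits)) +
                 length(Filter(Negate(is.null), full$us_logits)) +
                 !is.null(full$daf_logits), 9L)
})
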