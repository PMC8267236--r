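# Network definition: EDS encoder stages, MSC skip connections, DAF
# bottleneck with dual-attention heads, US decoder stages, supervision heads.
#
# Parameters live in a flat named list (e.g. "eds1.c1.w"); batch-norm running
# statistics live in a state environment keyed by the same prefixes. Blocks
# are written against a small context object so the same code serves the full
# network builder and the standalone per-block functions.

#' Network configuration
#'
#' Architectural switches for the segmentation network. The encoder has four
#' stages whose widths double from `base_channels` (U-Net convention); the
#' multi-scale connection uses dilated 3x3 convolutions at `dilation_rates`;
#' the bottleneck dual-attention fusion block comes in three variants, of
#' which `"DAF1"` (sum of the positional and channel attention outputs) is
#' the default. Ablation switches reproduce the module on/off and
#' MSC-position experiments: `use_eds`, `use_usl`, `use_daf` fall back to
#' plain (non-residual, unsupervised) blocks when `FALSE`, and
#' `msc_positions` lists the encoder levels (1 = full resolution) whose skip
#' connection is a multi-scale block rather than an identity.
#'
#' @param base_channels first-stage width; widths double per stage.
#' @param dilation_rates dilation (= padding) rates of the three dilated MSC
#'   branches.
#' @param daf_variant one of `"DAF1"`, `"DAF2"`, `"DAF3"`.
#' @param n_region_channels output channels, one per nested tumor region
#'   (WT, CT, ET).
#' @param attention_scale_init initial value of the learnable attention
#'   residual scales (alpha, beta); 0 starts both heads at exact identity.
#' @param input_channels image channels (4 MRI modalities).
#' @param input_size spatial size of the square input; must be divisible
#'   by 16.
#' @param use_eds,use_usl,use_daf enable the residual/supervised encoder
#'   block, residual decoder block and dual-attention bottleneck.
#' @param msc_positions integer subset of 1:4.
#' @param supervision logical list: compute the `down` (EDS), `up` (US) and
#'   `dual` (DAF) auxiliary heads.
#' @param reduction channel reduction factor of the positional-attention
#'   query/key projections.
#' @return an object of class `aanet_config`.
#' @export
aanet_config <- function(base_channels = 32L,
                         dilation_rates = c(6L, 12L, 18L),
                         daf_variant = c("DAF1", "DAF2", "DAF3"),
                         n_region_channels = 3L,
                         attention_scale_init = 0,
                         input_channels = 4L,
                         input_size = 160L,
                         use_eds = TRUE,
                         use_usl = TRUE,
                         use_daf = TRUE,
                         msc_positions = 1:4,
                         supervision = list(down = TRUE, up = TRUE,
                                            dual = TRUE),
                         reduction = 8L) {
  daf_variant <- match.arg(daf_variant)
  stopifnot(base_channels >= 2, length(dilation_rates) == 3,
            input_size %% 16 == 0,
            all(msc_positions %in% 1:4))
  sup <- modifyList(list(down = TRUE, up = TRUE, dual = TRUE), supervision)
  structure(list(
    base_channels = as.integer(base_channels),
    n_stages = 4L,
    dilation_rates = as.integer(dilation_rates),
    daf_variant = daf_variant,
    n_region_channels = as.integer(n_region_channels),
    attention_scale_init = attention_scale_init,
    input_channels = as.integer(input_channels),
    input_size = as.integer(input_size),
    use_eds = isTRUE(use_eds),
    use_usl = isTRUE(use_usl),
    use_daf = isTRUE(use_daf),
    msc_positions = as.integer(msc_positions),
    supervision = sup,
    reduction = as.integer(reduction)
  ), class = "aanet_config")
}

stage_channels <- function(config) {
  config$base_channels * 2L^(0:(config$n_stages - 1L))
}

# ---- parameter initialization ----------------------------------------------

he_conv <- function(kh, kw, cin, cout) {
  array(rnorm(kh * kw * cin * cout, sd = sqrt(2 / (kh * kw * cin))),
        c(kh, kw, cin, cout))
}

# Region-logit heads start at a low foreground probability
# (sigmoid(-2) ~ 0.12) so early training does not flood the masks with
# positives before the Dice term can shape them.
head_bias_init <- -2

new_param_set <- function() {
  ps <- new.env(parent = emptyenv())
  ps$params <- list()
  ps
}

add_conv <- function(ps, prefix, kh, kw, cin, cout, bn = TRUE) {
  ps$params[[paste0(prefix, ".w")]] <- he_conv(kh, kw, cin, cout)
  bias <- if (grepl("head$", prefix)) rep(head_bias_init, cout)
          else numeric(cout)
  ps$params[[paste0(prefix, ".b")]] <- bias
  if (bn) {
    ps$params[[paste0(prefix, ".g")]] <- rep(1, cout)
    ps$params[[paste0(prefix, ".be")]] <- numeric(cout)
  }
  invisible(ps)
}

init_aanet_params <- function(config) {
  cs <- stage_channels(config)
  nr <- config$n_region_channels
  ps <- new_param_set()
  cin <- config$input_channels
  for (s in 1:4) {
    pre <- paste0("eds", s)
    add_conv(ps, paste0(pre, ".c1"), 3, 3, cin, cs[s])
    add_conv(ps, paste0(pre, ".c2"), 3, 3, cs[s], cs[s])
    if (config$use_eds) {
      add_conv(ps, paste0(pre, ".res"), 1, 1, cin, cs[s])
      add_conv(ps, paste0(pre, ".s1"), 3, 3, cs[s], cs[s] / 2)
      add_conv(ps, paste0(pre, ".s2"), 3, 3, cs[s], cs[s] / 2)
      if (config$supervision$down) {
        add_conv(ps, paste0(pre, ".head"), 1, 1, cs[s], nr, bn = FALSE)
      }
    }
    if (s %in% config$msc_positions) {
      pre <- paste0("msc", s)
      add_conv(ps, paste0(pre, ".b0"), 1, 1, cs[s], cs[s], bn = FALSE)
      for (d in config$dilation_rates) {
        add_conv(ps, paste0(pre, ".b", d), 3, 3, cs[s], cs[s], bn = FALSE)
      }
      add_conv(ps, paste0(pre, ".fuse"), 1, 1, 4 * cs[s], cs[s])
    }
    cin <- cs[s]
  }
  c4 <- cs[4]
  add_conv(ps, "daf.c1", 3, 3, c4, c4)
  add_conv(ps, "daf.c2", 3, 3, c4, c4)
  if (config$use_daf) {
    cr <- max(1L, c4 %/% config$reduction)
    ps$params[["daf.pa.wa"]] <- matrix(rnorm(cr * c4, sd = sqrt(2 / c4)), cr)
    ps$params[["daf.pa.ba"]] <- numeric(cr)
    ps$params[["daf.pa.wb"]] <- matrix(rnorm(cr * c4, sd = sqrt(2 / c4)), cr)
    ps$params[["daf.pa.bb"]] <- numeric(cr)
    ps$params[["daf.pa.wc"]] <- matrix(rnorm(c4 * c4, sd = sqrt(2 / c4)), c4)
    ps$params[["daf.pa.bc"]] <- numeric(c4)
    ps$params[["daf.pa.alpha"]] <- config$attention_scale_init
    ps$params[["daf.ca.beta"]] <- config$attention_scale_init
    nfuse <- switch(config$daf_variant, DAF1 = 1L, DAF2 = 2L, DAF3 = 3L)
    if (config$daf_variant != "DAF1") add_conv(ps, "daf.yp", 1, 1, c4, c4)
    add_conv(ps, "daf.fuse", 1, 1, nfuse * c4, c4)
    if (config$supervision$dual) {
      add_conv(ps, "daf.head", 1, 1, c4, nr, bn = FALSE)
    }
  }
  add_conv(ps, "up0", 1, 1, c4, c4)
  for (s in 4:1) {
    pre <- paste0("us", s)
    cin_us <- 2L * cs[s]
    add_conv(ps, paste0(pre, ".c1"), 3, 3, cin_us, cs[s])
    add_conv(ps, paste0(pre, ".c2"), 3, 3, cs[s], cs[s])
    if (config$use_usl) {
      add_conv(ps, paste0(pre, ".res"), 1, 1, cin_us, cs[s])
      if (config$supervision$up) {
        add_conv(ps, paste0(pre, ".head"), 1, 1, cs[s], nr, bn = FALSE)
      }
    }
    if (s > 1) add_conv(ps, paste0(pre, ".up"), 1, 1, cs[s], cs[s - 1])
  }
  add_conv(ps, "final.head", 1, 1, cs[1], nr, bn = FALSE)
  ps$params
}

#' Create a segmentation model
#'
#' Initializes all trainable parameters (He-normal convolution weights, unit
#' batch-norm scales, zero attention scales) for the given configuration.
#'
#' @param config an [aanet_config()].
#' @param seed integer seed for the weight initialization.
#' @return an object of class `aanet_model` with elements `params` (named
#'   list of arrays), `state` (batch-norm running statistics) and `config`.
#' @export
aanet_model <- function(config = aanet_config(), seed = 1L) {
  set.seed(seed)
  state <- new.env(parent = emptyenv())
  state$bn <- list()
  structure(list(params = init_aanet_params(config), state = state,
                 config = config, seed = as.integer(seed)),
            class = "aanet_model")
}

# ---- block builders (shared by full forward and standalone functions) ------

ctx_new <- function(params, state, config, training) {
  tape <- tape_new()
  ctx <- new.env(parent = emptyenv())
  ctx$tape <- tape
  ctx$params <- params
  ctx$state <- state
  ctx$config <- config
  ctx$training <- training
  ctx$P <- function(name) {
    v <- params[[name]]
    if (is.null(v)) stop("missing parameter: ", name)
    op_param(tape, name, v)
  }
  ctx$bn_env <- function(prefix) {
    e <- state$bn[[prefix]]
    if (is.null(e)) {
      e <- new.env(parent = emptyenv())
      state$bn[[prefix]] <- e
    }
    e
  }
  ctx
}

b_conv <- function(ctx, x, prefix, pad = 0L, dil = 1L) {
  op_conv(ctx$tape, x, ctx$P(paste0(prefix, ".w")),
          ctx$P(paste0(prefix, ".b")), pad, dil)
}

b_cbr <- function(ctx, x, prefix, pad = 0L, dil = 1L) {
  y <- b_conv(ctx, x, prefix, pad, dil)
  op_bn(ctx$tape, y, ctx$P(paste0(prefix, ".g")),
        ctx$P(paste0(prefix, ".be")), ctx$bn_env(prefix), ctx$training,
        relu = TRUE)
}

# EDS encoder stage: residual double convolution, max pooling, and the fused
# supervision feature A built from the low-level (G1) and high-level (G2)
# activations. Returns h (pooled), a (skip/supervision feature) and the
# region-logit head upsampled to full resolution.
b_eds <- function(ctx, x, s) {
  pre <- paste0("eds", s)
  g1 <- b_cbr(ctx, x, paste0(pre, ".c1"), pad = 1L)
  g2 <- b_cbr(ctx, g1, paste0(pre, ".c2"), pad = 1L)
  d <- dim(x$value)
  if (d[1] %% 2 != 0 || d[2] %% 2 != 0) {
    stop("EDS stage ", s, ": spatial dims must be divisible by 2")
  }
  if (ctx$config$use_eds) {
    r <- b_cbr(ctx, x, paste0(pre, ".res"))
    h <- op_maxpool2(ctx$tape, op_add(ctx$tape, g2, r))
    a1 <- b_cbr(ctx, g1, paste0(pre, ".s1"), pad = 1L)
    a2 <- b_cbr(ctx, g2, paste0(pre, ".s2"), pad = 1L)
    a <- op_concat_c(ctx$tape, list(a1, a2))
    head <- NULL
    if (ctx$config$supervision$down) {
      head <- op_upsample_to(ctx$tape, b_conv(ctx, a, paste0(pre, ".head")),
                             s - 1L)
    }
  } else {
    h <- op_maxpool2(ctx$tape, g2)
    a <- g2
    head <- NULL
  }
  list(h = h, a = a, head = head)
}

# MSC skip connection: parallel 1x1 and dilated 3x3 branches (padding equal
# to dilation preserves the spatial size), channel concat, 1x1 fuse.
b_msc <- function(ctx, a, s) {
  pre <- paste0("msc", s)
  branches <- list(b_conv(ctx, a, paste0(pre, ".b0")))
  for (d in ctx$config$dilation_rates) {
    branches <- c(branches,
                  list(b_conv(ctx, a, paste0(pre, ".b", d),
                              pad = as.integer(d), dil = as.integer(d))))
  }
  b_cbr(ctx, op_concat_c(ctx$tape, branches), paste0(pre, ".fuse"))
}

# DAF bottleneck: double 3x3 convolution then the dual-attention heads,
# fused per variant; auxiliary region head at full resolution.
b_daf <- function(ctx, x) {
  y1 <- b_cbr(ctx, x, "daf.c1", pad = 1L)
  y2 <- b_cbr(ctx, y1, "daf.c2", pad = 1L)
  if (!ctx$config$use_daf) {
    return(list(fused = y2, head = NULL, pa = NULL, ca = NULL))
  }
  tp <- ctx$tape
  pa <- op_pos_attention(tp, y2, ctx$P("daf.pa.wa"), ctx$P("daf.pa.ba"),
                         ctx$P("daf.pa.wb"), ctx$P("daf.pa.bb"),
                         ctx$P("daf.pa.wc"), ctx$P("daf.pa.bc"),
                         ctx$P("daf.pa.alpha"))
  ca <- op_chan_attention(tp, y2, ctx$P("daf.ca.beta"))
  fused <- switch(ctx$config$daf_variant,
    DAF1 = b_cbr(ctx, op_add(tp, pa, ca), "daf.fuse"),
    DAF2 = {
      yp <- b_cbr(ctx, y2, "daf.yp")
      b_cbr(ctx, op_concat_c(tp, list(op_add(tp, pa, yp),
                                      op_add(tp, ca, yp))), "daf.fuse")
    },
    DAF3 = {
      yp <- b_cbr(ctx, y2, "daf.yp")
      b_cbr(ctx, op_concat_c(tp, list(op_add(tp, pa, ca),
                                      op_add(tp, pa, yp),
                                      op_add(tp, ca, yp))), "daf.fuse")
    })
  head <- NULL
  if (ctx$config$supervision$dual) {
    times <- as.integer(round(log2(ctx$config$input_size /
                                     dim(x$value)[1])))
    head <- op_upsample_to(ctx$tape, b_conv(ctx, fused, "daf.head"), times)
  }
  list(fused = fused, head = head, pa = pa, ca = ca)
}

# US decoder stage: concat of the previous decoder feature (already at this
# level's resolution) with the skip feature, then the same residual double
# convolution as the encoder; supervision head at full resolution.
b_us <- function(ctx, prev, skip, s) {
  pre <- paste0("us", s)
  dp <- dim(prev$value); dk <- dim(skip$value)
  if (dp[1] != dk[1] || dp[2] != dk[2]) {
    stop("US stage ", s, ": spatial mismatch between decoder (",
         dp[1], "x", dp[2], ") and skip (", dk[1], "x", dk[2], ") features")
  }
  xin <- op_concat_c(ctx$tape, list(prev, skip))
  g1 <- b_cbr(ctx, xin, paste0(pre, ".c1"), pad = 1L)
  g2 <- b_cbr(ctx, g1, paste0(pre, ".c2"), pad = 1L)
  if (ctx$config$use_usl) {
    r <- b_cbr(ctx, xin, paste0(pre, ".res"))
    out <- op_add(ctx$tape, g2, r)
    head <- NULL
    if (ctx$config$supervision$up) {
      head <- op_upsample_to(ctx$tape, b_conv(ctx, out, paste0(pre, ".head")),
                             s - 1L)
    }
  } else {
    out <- g2
    head <- NULL
  }
  list(out = out, head = head)
}

# Full network graph. Returns tape nodes for every head.
build_aanet <- function(ctx, x) {
  cfg <- ctx$config
  eds_heads <- vector("list", 4)
  skips <- vector("list", 4)
  h <- x
  for (s in 1:4) {
    st <- b_eds(ctx, h, s)
    eds_heads[[s]] <- st$head
    skips[[s]] <- if (s %in% cfg$msc_positions) b_msc(ctx, st$a, s) else st$a
    h <- st$h
  }
  daf <- b_daf(ctx, h)
  prev <- b_cbr(ctx, op_upsample2(ctx$tape, daf$fused), "up0")
  us_heads <- vector("list", 4)
  out <- NULL
  for (s in 4:1) {
    us <- b_us(ctx, prev, skips[[s]], s)
    us_heads[[s]] <- us$head
    out <- us$out
    if (s > 1) {
      prev <- b_cbr(ctx, op_upsample2(ctx$tape, out), paste0("us", s, ".up"))
    }
  }
  final <- b_conv(ctx, out, "final.head")
  list(eds = eds_heads, us = us_heads, daf = daf$head, final = final,
       daf_nodes = daf)
}

# ---- public forward --------------------------------------------------------

as_batch <- function(x) {
  if (length(dim(x)) == 3) dim(x) <- c(dim(x), 1L)
  if (length(dim(x)) != 4) stop("expected an H x W x C (x N) array")
  x
}

drop_batch <- function(x, single) if (single) array(x, dim(x)[1:3]) else x

#' Full forward pass
#'
#' Runs the four EDS encoder stages, the MSC skip connections, the DAF
#' bottleneck and the four US decoder stages, returning every
#' deep-supervision head: per-stage EDS and US region logits, the DAF head,
#' and the final head, all at the input resolution. Logits are raw; apply
#' `plogis()`/thresholding or [predict_regions()] for masks.
#'
#' @param model an [aanet_model()].
#' @param image `H x W x C` array (or `H x W x C x N` batch) matching the
#'   configured input shape.
#' @param training logical; use batch statistics (and update running
#'   statistics) in the batch-norm layers.
#' @return a `supervision_bundle`: list with `eds_logits` (list of 4 or
#'   NULLs), `us_logits` (list of 4), `daf_logits`, `final_logits`.
#' @export
aanet_forward <- function(model, image, training = FALSE) {
  image <- as_batch(image)
  d <- dim(image)
  cfg <- model$config
  if (d[1] != cfg$input_size || d[2] != cfg$input_size ||
      d[3] != cfg$input_channels) {
    stop("input shape ", paste(d[1:3], collapse = "x"),
         " does not match configured ", cfg$input_size, "x", cfg$input_size,
         "x", cfg$input_channels)
  }
  single <- d[4] == 1
  ctx <- ctx_new(model$params, model$state, cfg, training)
  g <- build_aanet(ctx, op_input(ctx$tape, image))
  vals <- function(nd) if (is.null(nd)) NULL else drop_batch(nd$value, single)
  structure(list(
    eds_logits = lapply(g$eds, vals),
    us_logits = lapply(g$us, vals),
    daf_logits = vals(g$daf),
    final_logits = vals(g$final)
  ), class = "supervision_bundle")
}

# internal: forward with tape retained, for training
aanet_forward_tape <- function(model, image, training = TRUE) {
  ctx <- ctx_new(model$params, model$state, model$config, training)
  g <- build_aanet(ctx, op_input(ctx$tape, as_batch(image)))
  list(ctx = ctx, graph = g)
}

# ---- standalone block functions (single feature map in, arrays out) --------

run_block <- function(x, params, config, training, fn) {
  x <- as_batch(x)
  state <- new.env(parent = emptyenv())
  state$bn <- list()
  ctx <- ctx_new(params, state, config, training)
  fn(ctx, op_input(ctx$tape, x))
}

default_block_config <- function(...) {
  args <- list(...)
  do.call(aanet_config, modifyList(list(base_channels = 2L, input_size = 16L),
                                   args))
}

#' Standalone EDS encoder block
#'
#' Applies one enhanced down-sampling stage to a feature map: residual
#' double 3x3 convolution (each conv followed by batch norm and ReLU), 2x2
#' max pooling, and the fused supervision feature built from the low- and
#' high-level activations.
#'
#' @param x `H x W x C` input feature map (H, W even).
#' @param weights parameter list from [make_eds_weights()].
#' @param training logical; batch-norm mode.
#' @return list with `h` (pooled output, `H/2 x W/2 x c_out`) and `a`
#'   (supervision/skip feature, `H x W x c_out`).
#' @export
eds_forward <- function(x, weights, training = FALSE) {
  cfg <- attr(weights, "config")
  r <- run_block(x, weights, cfg, training,
                 function(ctx, xn) b_eds(ctx, xn, 1L))
  list(h = drop_batch(r$h$value, TRUE), a = drop_batch(r$a$value, TRUE))
}

#' @rdname eds_forward
#' @param c_in,c_out input and output channel counts.
#' @export
make_eds_weights <- function(c_in, c_out) {
  cfg <- default_block_config(input_channels = as.integer(c_in),
                              supervision = list(down = FALSE, up = FALSE,
                                                 dual = FALSE))
  ps <- new_param_set()
  add_conv(ps, "eds1.c1", 3, 3, c_in, c_out)
  add_conv(ps, "eds1.c2", 3, 3, c_out, c_out)
  add_conv(ps, "eds1.res", 1, 1, c_in, c_out)
  add_conv(ps, "eds1.s1", 3, 3, c_out, max(1L, c_out %/% 2L))
  add_conv(ps, "eds1.s2", 3, 3, c_out, c_out - max(1L, c_out %/% 2L))
  structure(ps$params, config = cfg)
}

#' Standalone multi-scale connection block
#'
#' Fuses an EDS supervision feature through four parallel branches — a 1x1
#' convolution and three 3x3 dilated convolutions with padding equal to the
#' dilation rate (6, 12, 18 by default) — concatenated along channels and
#' projected back to the input width by a 1x1 conv + batch norm + ReLU.
#' Spatial size is preserved.
#'
#' @param a `H x W x C` feature map.
#' @param weights parameter list from [make_msc_weights()].
#' @param training logical; batch-norm mode.
#' @return fused feature map, same shape as `a`.
#' @export
msc_forward <- function(a, weights, training = FALSE) {
  cfg <- attr(weights, "config")
  if (any(dim(as_batch(a))[1:2] <= 0)) stop("non-positive spatial dims")
  r <- run_block(a, weights, cfg, training,
                 function(ctx, xn) b_msc(ctx, xn, 1L))
  drop_batch(r$value, TRUE)
}

#' @rdname msc_forward
#' @param channels feature-map width.
#' @param dilation_rates the three dilation rates.
#' @export
make_msc_weights <- function(channels, dilation_rates = c(6L, 12L, 18L)) {
  cfg <- default_block_config(dilation_rates = dilation_rates)
  ps <- new_param_set()
  add_conv(ps, "msc1.b0", 1, 1, channels, channels, bn = FALSE)
  for (d in dilation_rates) {
    add_conv(ps, paste0("msc1.b", d), 3, 3, channels, channels, bn = FALSE)
  }
  add_conv(ps, "msc1.fuse", 1, 1, 4 * channels, channels)
  structure(ps$params, config = cfg)
}

#' Positional (spatial) attention head
#'
#' Projects the input through 1x1 convolutions to query/key/value maps,
#' forms the position-pair affinity matrix, row-normalizes it by softmax,
#' and returns the value-weighted sum scaled by the learnable `alpha` plus
#' the identity residual. With `alpha = 0` the output equals the input
#' exactly.
#'
#' @param x `H x W x C` feature map.
#' @param weights list from [make_pos_attention_weights()] with elements
#'   `wa`, `ba`, `wb`, `bb` (query/key projections to the reduced width),
#'   `wc`, `bc` (value projection) and `alpha` (scalar residual scale).
#' @return list with `ea` (output feature map, same shape as `x`) and `s`
#'   (the `(H*W) x (H*W)` row-stochastic spatial attention map).
#' @export
positional_attention <- function(x, weights) {
  x <- as_batch(x)
  if (prod(dim(x)[1:2]) == 0) stop("empty spatial extent")
  params <- list(
    "pa.wa" = weights$wa, "pa.ba" = weights$ba,
    "pa.wb" = weights$wb, "pa.bb" = weights$bb,
    "pa.wc" = weights$wc, "pa.bc" = weights$bc,
    "pa.alpha" = weights$alpha)
  state <- new.env(parent = emptyenv()); state$bn <- list()
  ctx <- ctx_new(params, state, NULL, FALSE)
  nd <- op_pos_attention(ctx$tape, op_input(ctx$tape, x),
                         ctx$P("pa.wa"), ctx$P("pa.ba"),
                         ctx$P("pa.wb"), ctx$P("pa.bb"),
                         ctx$P("pa.wc"), ctx$P("pa.bc"), ctx$P("pa.alpha"))
  list(ea = drop_batch(nd$value, TRUE), s = nd$maps[[1]])
}

#' @rdname positional_attention
#' @param channels input width C.
#' @param reduction reduction factor for the query/key width (C/8 by
#'   default).
#' @param alpha initial residual scale.
#' @export
make_pos_attention_weights <- function(channels, reduction = 8L, alpha = 0) {
  cr <- max(1L, channels %/% reduction)
  list(wa = matrix(rnorm(cr * channels, sd = sqrt(2 / channels)), cr),
       ba = numeric(cr),
       wb = matrix(rnorm(cr * channels, sd = sqrt(2 / channels)), cr),
       bb = numeric(cr),
       wc = matrix(rnorm(channels * channels, sd = sqrt(2 / channels)),
                   channels),
       bc = numeric(channels),
       alpha = alpha)
}

#' Channel attention head
#'
#' Computes channel-pair affinities directly from the reshaped feature map
#' (no convolution, preserving raw inter-channel relationships),
#' row-normalizes them by softmax, and returns the channel-weighted sum
#' scaled by the learnable `beta` plus the identity residual. With
#' `beta = 0` the output equals the input exactly.
#'
#' @param x `H x W x C` feature map (C > 0).
#' @param beta scalar residual scale.
#' @return list with `ca` (output feature map) and `m` (the `C x C`
#'   row-stochastic channel attention map).
#' @export
channel_attention <- function(x, beta = 0) {
  x <- as_batch(x)
  if (dim(x)[3] == 0) stop("zero channels")
  params <- list("ca.beta" = beta)
  state <- new.env(parent = emptyenv()); state$bn <- list()
  ctx <- ctx_new(params, state, NULL, FALSE)
  nd <- op_chan_attention(ctx$tape, op_input(ctx$tape, x), ctx$P("ca.beta"))
  list(ca = drop_batch(nd$value, TRUE), m = nd$maps[[1]])
}

#' Standalone dual-attention fusion block
#'
#' Two 3x3 conv+BN+ReLU layers extract high-level semantics, then the
#' positional and channel attention heads re-weight the result. `DAF1`
#' fuses by summing the two attention outputs; `DAF2` adds each attention
#' output to a parallel 1x1-conv branch and concatenates; `DAF3` combines
#' both fusion paths. All variants accept and emit the same shapes.
#'
#' @param x `H x W x C` feature map.
#' @param weights parameter list from [make_daf_weights()] (its variant must
#'   match).
#' @param variant `"DAF1"`, `"DAF2"` or `"DAF3"`.
#' @param training logical; batch-norm mode.
#' @return list with `fused` (`H x W x C`) and `aux_logits` (region logits
#'   upsampled to the configured full resolution).
#' @export
daf_forward <- function(x, weights, variant = c("DAF1", "DAF2", "DAF3"),
                        training = FALSE) {
  variant <- match.arg(variant)
  cfg <- attr(weights, "config")
  if (cfg$daf_variant != variant) {
    stop("weights were built for ", cfg$daf_variant, ", not ", variant)
  }
  r <- run_block(x, weights, cfg, training, function(ctx, xn) b_daf(ctx, xn))
  list(fused = drop_batch(r$fused$value, TRUE),
       aux_logits = if (is.null(r$head)) NULL
                    else drop_batch(r$head$value, TRUE))
}

#' @rdname daf_forward
#' @param channels bottleneck width.
#' @param full_size resolution the auxiliary head is upsampled to; use the
#'   bottleneck size times a power of two.
#' @param n_regions region channels of the auxiliary head.
#' @param reduction positional-attention reduction factor.
#' @param attention_scale_init initial alpha/beta.
#' @export
make_daf_weights <- function(channels, variant = c("DAF1", "DAF2", "DAF3"),
                             full_size = 16L, n_regions = 3L,
                             reduction = 8L, attention_scale_init = 0) {
  variant <- match.arg(variant)
  cfg <- default_block_config(daf_variant = variant,
                              input_size = as.integer(full_size),
                              n_region_channels = as.integer(n_regions),
                              reduction = as.integer(reduction),
                              attention_scale_init = attention_scale_init)
  ps <- new_param_set()
  add_conv(ps, "daf.c1", 3, 3, channels, channels)
  add_conv(ps, "daf.c2", 3, 3, channels, channels)
  cr <- max(1L, channels %/% reduction)
  ps$params[["daf.pa.wa"]] <-
    matrix(rnorm(cr * channels, sd = sqrt(2 / channels)), cr)
  ps$params[["daf.pa.ba"]] <- numeric(cr)
  ps$params[["daf.pa.wb"]] <-
    matrix(rnorm(cr * channels, sd = sqrt(2 / channels)), cr)
  ps$params[["daf.pa.bb"]] <- numeric(cr)
  ps$params[["daf.pa.wc"]] <-
    matrix(rnorm(channels * channels, sd = sqrt(2 / channels)), channels)
  ps$params[["daf.pa.bc"]] <- numeric(channels)
  ps$params[["daf.pa.alpha"]] <- attention_scale_init
  ps$params[["daf.ca.beta"]] <- attention_scale_init
  nfuse <- switch(variant, DAF1 = 1L, DAF2 = 2L, DAF3 = 3L)
  if (variant != "DAF1") add_conv(ps, "daf.yp", 1, 1, channels, channels)
  add_conv(ps, "daf.fuse", 1, 1, nfuse * channels, channels)
  add_conv(ps, "daf.head", 1, 1, channels, n_regions, bn = FALSE)
  structure(ps$params, config = cfg)
}

#' Standalone US decoder block
#'
#' Concatenates the previous decoder feature (already brought to this
#' level's resolution) with the skip feature, applies the residual double
#' convolution of the encoder block with the pooling slot replaced by a 2x
#' bilinear upsampling, and emits the upsampled stage output plus a
#' region-logit supervision head.
#'
#' @param prev decoder feature, `H x W x c_prev`.
#' @param msc_feat skip feature, `H x W x c_skip` (same H, W).
#' @param weights parameter list from [make_us_weights()].
#' @param upsample_out apply the trailing 2x upsampling (the last decoder
#'   stage, already at full resolution, skips it).
#' @param training logical; batch-norm mode.
#' @return list with `up` (`2H x 2W x c_out`, or `H x W x c_out` when
#'   `upsample_out = FALSE`) and `aux_logits`.
#' @export
us_forward <- function(prev, msc_feat, weights, upsample_out = TRUE,
                       training = FALSE) {
  cfg <- attr(weights, "config")
  prev <- as_batch(prev); msc_feat <- as_batch(msc_feat)
  if (!all(dim(prev)[c(1, 2, 4)] == dim(msc_feat)[c(1, 2, 4)])) {
    stop("US block: spatial mismatch between decoder and skip features")
  }
  state <- new.env(parent = emptyenv()); state$bn <- list()
  ctx <- ctx_new(weights, state, cfg, training)
  r <- b_us(ctx, op_input(ctx$tape, prev), op_input(ctx$tape, msc_feat), 1L)
  out <- r$out$value
  if (upsample_out) out <- upsample2_fw(out)
  list(up = drop_batch(out, TRUE),
       aux_logits = if (is.null(r$head)) NULL
                    else drop_batch(r$head$value, TRUE))
}

#' @rdname us_forward
#' @param c_prev,c_skip,c_out channel counts.
#' @param n_regions region channels of the supervision head.
#' @export
make_us_weights <- function(c_prev, c_skip, c_out, n_regions = 3L) {
  cfg <- default_block_config(n_region_channels = as.integer(n_regions))
  ps <- new_param_set()
  cin <- c_prev + c_skip
  add_conv(ps, "us1.c1", 3, 3, cin, c_out)
  add_conv(ps, "us1.c2", 3, 3, c_out, c_out)
  add_conv(ps, "us1.res", 1, 1, cin, c_out)
  add_conv(ps, "us1.head", 1, 1, c_out, n_regions, bn = FALSE)
  structure(ps$params, config = cfg)
}
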