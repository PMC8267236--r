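# Training: Adam over the deep-supervision composite loss, early stopping
# on the monitored Dice, run logging, checkpointing, and prediction.

#' Training configuration
#'
#' Defaults follow the reference setting: Adam with learning rate 3e-4,
#' batch size 16, up to 100 epochs with early-stopping patience 20 on the
#' monitored validation Dice.
#'
#' @param learning_rate Adam step size.
#' @param batch_size samples per optimizer step.
#' @param max_epochs maximum training epochs.
#' @param early_stop_patience epochs without improvement before stopping;
#'   must not exceed `max_epochs`.
#' @param seed seed for data order (model initialization is seeded in
#'   [aanet_model()]).
#' @param loss a [loss_weights()] list.
#' @param net an [aanet_config()]; carries all ablation switches
#'   (per-position MSC, supervision heads, DAF variant).
#' @return a `train_config` list.
#' @export
train_config <- function(learning_rate = 3e-4, batch_size = 16L,
                         max_epochs = 100L, early_stop_patience = 20L,
                         seed = 1L, loss = loss_weights(),
                         net = aanet_config()) {
  stopifnot(batch_size >= 1, max_epochs >= 1)
  if (early_stop_patience > max_epochs) {
    stop("early_stop_patience must not exceed max_epochs")
  }
  structure(list(learning_rate = learning_rate,
                 batch_size = as.integer(batch_size),
                 max_epochs = as.integer(max_epochs),
                 early_stop_patience = as.integer(early_stop_patience),
                 seed = as.integer(seed), loss = loss, net = net),
            class = "train_config")
}

adam_new <- function(params) {
  list(m = lapply(params, function(p) p * 0),
       v = lapply(params, function(p) p * 0),
       t = 0L)
}

adam_step <- function(opt, params, grads, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  opt$t <- opt$t + 1L
  bc1 <- 1 - beta1^opt$t
  bc2 <- 1 - beta2^opt$t
  for (nm in names(grads)) {
    g <- grads[[nm]]
    opt$m[[nm]] <- beta1 * opt$m[[nm]] + (1 - beta1) * g
    opt$v[[nm]] <- beta2 * opt$v[[nm]] + (1 - beta2) * g * g
    params[[nm]] <- params[[nm]] -
      lr * (opt$m[[nm]] / bc1) / (sqrt(opt$v[[nm]] / bc2) + eps)
  }
  list(opt = opt, params = params)
}

samples_to_batch <- function(samples) {
  d <- dim(samples[[1]]$image)
  x <- array(0, c(d[1], d[2], d[3], length(samples)))
  y <- array(0, c(d[1], d[2], 3L, length(samples)))
  for (k in seq_along(samples)) {
    x[, , , k] <- samples[[k]]$image
    y[, , , k] <- regions_to_array(labels_to_regions(samples[[k]]$label))
  }
  list(x = x, y = y)
}

# loss graph over all supervision heads; returns the scalar node and the
# per-term breakdown
build_loss <- function(ctx, graph, target, lw) {
  tp <- ctx$tape
  seg <- function(nd) op_seg_loss(tp, nd, target, lw$alpha, lw$epsilon)
  terms <- list(); coefs <- numeric(0)
  bd <- list(l_down = NA_real_, l_up = NA_real_, l_dual = NA_real_,
             l_result = NA_real_)
  eds <- Filter(Negate(is.null), graph$eds)
  if (length(eds) > 0 && lw$lambda1 > 0) {
    ns <- lapply(eds, seg)
    terms <- c(terms, ns)
    coefs <- c(coefs, rep(lw$lambda1 / length(ns), length(ns)))
    bd$l_down <- mean(vapply(ns, function(n) n$value, 0))
  }
  us <- Filter(Negate(is.null), graph$us)
  if (length(us) > 0 && lw$lambda1 > 0) {
    ns <- lapply(us, seg)
    terms <- c(terms, ns)
    coefs <- c(coefs, rep(lw$lambda1 / length(ns), length(ns)))
    bd$l_up <- mean(vapply(ns, function(n) n$value, 0))
  }
  if (!is.null(graph$daf) && lw$lambda2 > 0) {
    n <- seg(graph$daf)
    terms <- c(terms, list(n))
    coefs <- c(coefs, lw$lambda2)
    bd$l_dual <- n$value
  }
  nf <- seg(graph$final)
  terms <- c(terms, list(nf))
  coefs <- c(coefs, 1)
  bd$l_result <- nf$value
  list(node = op_wsum(tp, terms, coefs), breakdown = bd)
}

batch_dice <- function(final_logits, target, threshold = 0.5) {
  p <- 1 / (1 + exp(-final_logits)) >= threshold
  vapply(1:3, function(r) {
    idx <- slice.index(target, 3) == r
    cc <- confusion_counts(p[idx], target[idx])
    dice_coefficient(cc)
  }, 0)
}

#' Train a segmentation model
#'
#' Minimizes the four-term deep-supervision loss with Adam. After each
#' epoch the monitored Dice (mean over WT/CT/ET on the validation samples,
#' or on the training samples when no validation set is given) is
#' evaluated; the best parameters are kept and training stops once the
#' monitor fails to improve for `early_stop_patience` consecutive epochs.
#' Fully reproducible: (model seed, config seed) determine initialization
#' and data order.
#'
#' @param model an [aanet_model()].
#' @param train_samples list of `slice_sample`s with labels (images already
#'   normalized, e.g. via [normalize_slice()] or [preprocess_case()]).
#' @param val_samples optional validation samples for the early-stop
#'   monitor.
#' @param config a [train_config()].
#' @param verbose print a line per epoch.
#' @return list with `model` (best parameters), `log` (per-epoch
#'   data.frame), `epochs_run`, `best_epoch`, `best_dice`.
#' @export
train_aanet <- function(model, train_samples, val_samples = NULL,
                        config = train_config(), verbose = FALSE) {
  if (length(train_samples) == 0) stop("empty training set")
  stopifnot(inherits(config, "train_config"))
  lw <- config$loss
  set.seed(config$seed)
  opt <- adam_new(model$params)
  n <- length(train_samples)
  best <- list(dice = -Inf, params = model$params,
               bn = bn_state_copy(model$state), epoch = 0L)
  bad <- 0L
  log_rows <- list()

  for (epoch in seq_len(config$max_epochs)) {
    t0 <- proc.time()[["elapsed"]]
    ord <- sample.int(n)
    losses <- c(total = 0, l_down = 0, l_up = 0, l_dual = 0, l_result = 0)
    train_dice <- c(0, 0, 0)
    nb <- 0L
    for (start in seq(1, n, by = config$batch_size)) {
      idx <- ord[start:min(start + config$batch_size - 1L, n)]
      batch <- samples_to_batch(train_samples[idx])
      fw <- aanet_forward_tape(model, batch$x, training = TRUE)
      ls <- build_loss(fw$ctx, fw$graph, batch$y, lw)
      grads <- backprop(fw$ctx$tape, ls$node)
      up <- adam_step(opt, model$params, grads, config$learning_rate)
      opt <- up$opt
      model$params <- up$params
      losses <- losses + c(ls$node$value, ls$breakdown$l_down,
                           ls$breakdown$l_up, ls$breakdown$l_dual,
                           ls$breakdown$l_result)
      train_dice <- train_dice + batch_dice(fw$graph$final$value, batch$y)
      nb <- nb + 1L
    }
    losses <- losses / nb
    # monitor: validation Dice when a validation set exists, otherwise the
    # training-batch Dice already computed during the epoch
    val_dice <- if (is.null(val_samples)) train_dice / nb
                else monitor_dice(model, val_samples)
    elapsed <- proc.time()[["elapsed"]] - t0
    log_rows[[epoch]] <- data.frame(
      epoch = epoch, l_total = losses[1], l_down = losses[2],
      l_up = losses[3], l_dual = losses[4], l_result = losses[5],
      val_dice_wt = val_dice[1], val_dice_ct = val_dice[2],
      val_dice_et = val_dice[3], val_dice_mean = mean(val_dice),
      learning_rate = config$learning_rate, seconds = elapsed)
    if (verbose) {
      message(sprintf("epoch %3d  loss %.4f  dice %.4f", epoch, losses[1],
                      mean(val_dice)))
    }
    if (mean(val_dice) > best$dice) {
      best <- list(dice = mean(val_dice), params = model$params,
                   bn = bn_state_copy(model$state), epoch = epoch)
      bad <- 0L
    } else {
      bad <- bad + 1L
      if (bad >= config$early_stop_patience) break
    }
  }
  model$params <- best$params
  bn_state_restore(model$state, best$bn)
  list(model = model, log = do.call(rbind, log_rows),
       epochs_run = length(log_rows), best_epoch = best$epoch,
       best_dice = best$dice)
}

monitor_dice <- function(model, samples, batch_size = 8L) {
  acc <- c(0, 0, 0)
  nb <- 0L
  for (start in seq(1, length(samples), by = batch_size)) {
    idx <- start:min(start + batch_size - 1L, length(samples))
    batch <- samples_to_batch(samples[idx])
    bundle <- aanet_forward(model, batch$x, training = FALSE)
    acc <- acc + batch_dice(bundle$final_logits, batch$y)
    nb <- nb + 1L
  }
  acc / nb
}

bn_state_copy <- function(state) {
  lapply(state$bn, function(e) list(mean = e$mean, var = e$var))
}

bn_state_restore <- function(state, saved) {
  state$bn <- list()
  for (nm in names(saved)) {
    e <- new.env(parent = emptyenv())
    e$mean <- saved[[nm]]$mean
    e$var <- saved[[nm]]$var
    state$bn[[nm]] <- e
  }
  invisible(state)
}

#' Predict region masks for one image
#'
#' Eval-mode forward pass, sigmoid on the final head, thresholding, and
#' optional nesting repair by intersection (ET within CT within WT).
#'
#' @param model a trained [aanet_model()].
#' @param image `H x W x C` input.
#' @param threshold binarization threshold (0.5).
#' @param repair enforce the region nesting on the predicted masks.
#' @return a `region_targets` list of logical masks.
#' @export
predict_regions <- function(model, image, threshold = 0.5, repair = FALSE) {
  bundle <- aanet_forward(model, image, training = FALSE)
  p <- 1 / (1 + exp(-bundle$final_logits))
  wt <- p[, , 1] >= threshold
  ct <- p[, , 2] >= threshold
  et <- p[, , 3] >= threshold
  if (repair) {
    ct <- ct & wt
    et <- et & ct
  }
  structure(list(wt = wt, ct = ct, et = et), class = "region_targets")
}

#' Evaluate a model on labeled samples
#'
#' @param model a trained [aanet_model()].
#' @param samples list of labeled `slice_sample`s.
#' @param threshold binarization threshold.
#' @param repair nesting repair flag, see [predict_regions()].
#' @return a `region_report`, see [evaluate_regions()].
#' @export
evaluate_model <- function(model, samples, threshold = 0.5,
                           repair = FALSE) {
  preds <- lapply(samples, function(s) {
    predict_regions(model, s$image, threshold, repair)
  })
  truths <- lapply(samples, function(s) labels_to_regions(s$label))
  evaluate_regions(preds, truths)
}

#' Save / load a model checkpoint
#'
#' The checkpoint archives the parameters, batch-norm running statistics,
#' configuration and RNG state in one file.
#'
#' @param model an [aanet_model()].
#' @param path file path (`.rds`).
#' @return `save_checkpoint` returns the path invisibly; `load_checkpoint`
#'   returns the restored `aanet_model`.
#' @export
save_checkpoint <- function(model, path) {
  rng <- if (exists(".Random.seed", globalenv())) {
    get(".Random.seed", globalenv())
  } else {
    NULL
  }
  saveRDS(list(params = model$params, bn = bn_state_copy(model$state),
               config = model$config, seed = model$seed, rng = rng),
          path, compress = "gzip")
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) {
  ck <- readRDS(path)
  state <- new.env(parent = emptyenv())
  state$bn <- list()
  model <- structure(list(params = ck$params, state = state,
                          config = ck$config, seed = ck$seed),
                     class = "aanet_model")
  bn_state_restore(model$state, ck$bn)
  model
}
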