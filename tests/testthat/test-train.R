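# Training mechanics on tiny networks and datasets: seeding, early
# stopping, checkpointing, prediction, and the CLI plumbing.

tiny_samples <- function(n = 4, size = 32L, seed = 5) {
  spec <- phantom_spec(image_size = size, noise_sd = 0.05, seed = seed)
  lapply(generate_dataset(spec, n, seed = seed), normalize_slice)
}

tiny_train_config <- function(...) {
  args <- list(...)
  defaults <- list(batch_size = 4L, max_epochs = 2L,
                   early_stop_patience = 2L, seed = 7L,
                   net = tiny_config())
  do.call(train_config, modifyList(defaults, args))
}

test_that("identical config and seed reproduce epoch-0 losses exactly", {
  samples <- tiny_samples()
  cfg <- tiny_train_config(max_epochs = 1L, early_stop_patience = 1L)
  f1 <- train_aanet(aanet_model(cfg$net, seed = 7), samples, config = cfg)
  f2 <- train_aanet(aanet_model(cfg$net, seed = 7), samples, config = cfg)
  expect_identical(f1$log$l_total, f2$log$l_total)
  expect_identical(f1$model$params, f2$model$params)
})

test_that("a frozen model stops after patience epochs without
           improvement", {
  samples <- tiny_samples()
  cfg <- tiny_train_config(learning_rate = 0, max_epochs = 10L,
                           early_stop_patience = 1L)
  fit <- train_aanet(aanet_model(cfg$net, seed = 7), samples, config = cfg)
  # epoch 1 improves on -Inf; epoch 2 cannot improve on an identical model
  expect_equal(fit$epochs_run, 2L)
  expect_equal(fit$best_epoch, 1L)
  expect_error(tiny_train_config(early_stop_patience = 99L),
               "must not exceed")
})

test_that("a few optimizer steps reduce the training loss", {
  samples <- tiny_samples(n = 4)
  cfg <- tiny_train_config(learning_rate = 3e-4, batch_size = 2L,
                           max_epochs = 6L, early_stop_patience = 6L)
  fit <- train_aanet(aanet_model(cfg$net, seed = 7), samples, config = cfg)
  expect_lt(fit$log$l_total[6], fit$log$l_total[1])
  expect_true(all(diff(fit$log$epoch) == 1))
  expect_true(all(c("l_down", "l_up", "l_dual", "l_result",
                    "val_dice_mean") %in% names(fit$log)))
  # total is the stated combination of the logged terms
  expect_equal(fit$log$l_total,
               0.4 * (fit$log$l_down + fit$log$l_up) +
                 0.2 * fit$log$l_dual + fit$log$l_result,
               tolerance = 1e-7)
})

test_that("checkpoints round-trip the model and predictions exactly", {
  samples <- tiny_samples()
  cfg <- tiny_train_config(max_epochs = 1L, early_stop_patience = 1L)
  fit <- train_aanet(aanet_model(cfg$net, seed = 7), samples, config = cfg)
  f <- withr::local_tempfile(fileext = ".rds")
  save_checkpoint(fit$model, f)
  back <- load_checkpoint(f)
  expect_identical(back$params, fit$model$params)
  p1 <- predict_regions(fit$model, samples[[1]]$image)
  p2 <- predict_regions(back, samples[[1]]$image)
  expect_identical(p1, p2)
  # repaired predictions are always nested
  pr <- predict_regions(back, samples[[1]]$image, repair = TRUE)
  expect_true(all(pr$wt[pr$ct]))
  expect_true(all(pr$ct[pr$et]))
  # evaluating the model against its own predictions is perfect
  own <- lapply(samples, function(s) predict_regions(back, s$image))
  rep <- evaluate_regions(own, own)
  expect_equal(rep$dice, rep(1, 4))
})

test_that("the CLI pipeline runs phantom -> preprocess -> train ->
           evaluate -> predict end to end", {
  dir <- withr::local_tempdir()
  raw <- file.path(dir, "raw"); prep <- file.path(dir, "prep")
  run <- file.path(dir, "run"); outp <- file.path(dir, "pred")
  aanet_cli(c("phantom", paste0("--out_dir=", raw), "--n_cases=2",
              "--size=48", "--slices=3", "--seed=4"))
  expect_length(list.dirs(raw, recursive = FALSE), 2)
  man <- cmd_preprocess(raw, prep, target = c(32L, 32L))
  expect_equal(nrow(man), 6)
  cfg <- tiny_train_config(max_epochs = 1L, early_stop_patience = 1L)
  fit <- cmd_train(cfg, prep, run, val_fraction = 0.5, verbose = FALSE)
  expect_true(file.exists(file.path(run, "checkpoint.rds")))
  expect_true(file.exists(file.path(run, "runlog.csv")))
  rep <- cmd_evaluate(file.path(run, "checkpoint.rds"), prep,
                      out_file = file.path(run, "report.csv"))
  expect_s3_class(rep, "region_report")
  expect_true(file.exists(file.path(run, "report.csv")))
  # determinism of evaluation
  rep2 <- cmd_evaluate(file.path(run, "checkpoint.rds"), prep)
  expect_identical(rep, rep2)
  vol <- cmd_predict(file.path(run, "checkpoint.rds"),
                     list.dirs(raw, recursive = FALSE)[1], outp)
  expect_equal(dim(vol), c(48, 48, 3))
  expect_true(all(unique(as.vector(vol)) %in% c(0L, 1L, 2L, 4L)))
  # the border outside the crop window is zero-padded
  expect_true(all(vol[1:8, , ] == 0))
  expect_true(file.exists(file.path(outp, "phantom_001_pred.nii.gz")))
  expect_error(aanet_cli(c("nonsense")), "unknown subcommand")
  expect_error(aanet_cli(character(0)), "usage")
  # the run directory echoes the full configuration, and the echo reads
  # back as an equivalent train_config
  cfg_path <- file.path(run, "config.json")
  expect_true(file.exists(cfg_path))
  back <- read_train_config(cfg_path)
  expect_equal(back$learning_rate, cfg$learning_rate)
  expect_equal(back$batch_size, cfg$batch_size)
  expect_equal(back$loss$lambda1, cfg$loss$lambda1)
  expect_equal(back$net$base_channels, cfg$net$base_channels)
  expect_equal(back$net$msc_positions, cfg$net$msc_positions)
  expect_equal(back$net$supervision, cfg$net$supervision)
})
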