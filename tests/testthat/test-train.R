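# Training-loop behaviour at miniature scale. Model sizes here are reduced
# (width and depth) to keep the suite fast; equations and defaults are the
# full ones.

tiny_cfg <- function(seed = 1L, epochs = 1L, ...) {
  train_config(epochs = epochs, batch_size = 8L, learning_rate = 0.1,
               loss = loss_config(theta = 0.2),
               model = model_config(encoder_channels = c(4, 4, 8, 8, 16),
                                    blocks = c(1, 1, 1, 1),
                                    cam_reduction_r = 2, ...),
               seed = seed)
}

test_that("training configuration round trips through YAML and JSON", {
  dir <- withr::local_tempdir()
  cfg <- train_config(epochs = 7L, batch_size = 4L, learning_rate = 0.025,
                      loss = loss_config(theta = 0.3, smooth = 0.5),
                      model = model_config(encoder_channels = c(8, 8, 16, 32, 64),
                                           blocks = c(1, 2, 2, 1),
                                           cam_reduction_r = 4,
                                           hddc_rates = c(1, 2, 5),
                                           use_cam = FALSE,
                                           hddc_merge = "concat"),
                      seed = 9L, val_fraction = 0.2)
  for (f in c("cfg.yml", "cfg.json")) {
    p <- file.path(dir, f)
    write_config(cfg, p)
    back <- read_config(p)
    expect_equal(back, cfg)
  }
})

test_that("training is deterministic and rejects bad input", {
  ds <- tiny_train_data(24, size = 64, seed = 31)
  f1 <- train_model(ds$samples, tiny_cfg(seed = 4L))
  f2 <- train_model(ds$samples, tiny_cfg(seed = 4L))
  expect_identical(f1$log, f2$log)
  expect_identical(model_forward(f1$model, ds$samples[[1]]$image),
                   model_forward(f2$model, ds$samples[[1]]$image))
  expect_error(train_model(list(), tiny_cfg()), "empty")
})

test_that("checkpoints round trip with identical evaluation", {
  dir <- withr::local_tempdir()
  ds <- tiny_train_data(12, size = 64, seed = 32)
  fit <- train_model(ds$samples, tiny_cfg(seed = 5L))
  p <- file.path(dir, "ckpt.rds")
  save_checkpoint(fit, p)
  back <- load_checkpoint(p)
  expect_equal(back$config, fit$model$config)
  img <- ds$samples[[2]]$image
  expect_identical(model_forward(back, img), model_forward(fit$model, img))
  m1 <- evaluate_model(fit, ds$samples[1:4])
  m2 <- evaluate_model(back, ds$samples[1:4])
  expect_identical(as.data.frame(m1), as.data.frame(m2))
  # the checkpoint embeds its configuration as JSON for provenance
  expect_true(nchar(readRDS(p)$config_json) > 0)
})

test_that("evaluation is self-consistent and aggregates exactly", {
  ds <- tiny_train_data(6, size = 64, seed = 33)
  m <- build_model(model_config(encoder_channels = c(4, 4, 8, 8, 16),
                                blocks = c(1, 1, 1, 1), cam_reduction_r = 2),
                   seed = 6)
  # evaluating against the model's own predictions is perfect by definition
  self <- lapply(ds$samples, function(s) {
    pm <- binarize(model_forward(m, s$image))
    slice_sample(s$image, pm, s$volume_id, s$slice_index)
  })
  r <- evaluate_model(m, self)
  expect_equal(r$dice, 1)
  expect_equal(c(r$fp, r$fn), c(0L, 0L))
  # report equals detection_metrics applied to the summed per-image counts
  r2 <- evaluate_model(m, ds$samples)
  per <- attr(r2, "per_image")
  agg <- detection_metrics(sum(per$tp), sum(per$fp), sum(per$fn))
  expect_equal(r2$precision, agg$precision)
  expect_equal(r2$recall, agg$recall)
  expect_equal(r2$f1, agg$f1)
})

test_that("predict_mask returns a coherent prob/mask/box bundle", {
  ds <- tiny_train_data(1, size = 64, seed = 34)
  m <- build_model(model_config(encoder_channels = c(4, 4, 8, 8, 16),
                                blocks = c(1, 1, 1, 1), cam_reduction_r = 2),
                   seed = 7)
  pr <- predict_mask(m, ds$samples[[1]]$image, threshold = 0.4)
  expect_equal(dim(pr$prob), c(64, 64))
  expect_identical(pr$mask, binarize(pr$prob, 0.4))
  expect_equal(nrow(pr$boxes), nrow(mask_to_boxes(pr$mask)))
})

test_that("the CLI generates phantom corpora and round-trips configs", {
  dir <- withr::local_tempdir()
  out <- file.path(dir, "corpus")
  expect_message(fracseg_cli(c("phantom", "--n", "3", "--size", "64",
                               "--seed", "2", "--out", out)),
                 "3 phantom slices")
  m <- read_manifest(out)
  expect_equal(nrow(m), 3)
  s <- load_samples(m)
  expect_equal(dim(s[[1]]$image), c(64, 64))
})

test_that("pure cross-entropy underperforms the compound loss (soft check)", {
  # theta = 0 vs theta = 0.2, same seeds/data, median of 3 runs: with <1%
  # foreground, pure CE stays biased to background and rarely crosses the
  # 0.5 threshold within this budget
  ds <- generate_phantom_dataset(160, phantom_spec(image_size = 64), seed = 41)
  dice <- list(ce = c(), mix = c())
  for (seed in 1:3) for (th in c(0, 0.2)) {
    cfg <- train_config(epochs = 4L, batch_size = 16L, learning_rate = 0.1,
                        loss = loss_config(theta = th),
                        model = model_config(encoder_channels = c(16, 16, 32, 64, 128),
                                             blocks = c(1, 1, 1, 1),
                                             cam_reduction_r = 4,
                                             use_hddc = FALSE, use_cam = FALSE),
                        seed = seed)
    fit <- train_model(ds$samples, cfg)
    k <- if (th == 0) "ce" else "mix"
    dice[[k]] <- c(dice[[k]], max(fit$log$val_dice))
  }
  expect_gt(median(dice$mix), median(dice$ce))
})
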