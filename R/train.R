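#' Training configuration
#'
#' Optimizer defaults follow the reference protocol for this task: SGD with
#' momentum 0.9 and weight decay 5e-4, batch size 16, 25 epochs. The
#' learning rate is not part of that protocol and 0.01 is this package's
#' declared default. Validation is split by volume (not by slice) to avoid
#' leakage between neighbouring slices of one scan.
#'
#' @param epochs Number of passes over the training split (>= 1).
#' @param batch_size Slices per gradient step (>= 1).
#' @param learning_rate SGD step size (> 0).
#' @param momentum SGD momentum coefficient.
#' @param weight_decay L2 penalty coefficient.
#' @param loss A [loss_config()].
#' @param model A [model_config()].
#' @param seed Master seed for initialization, splitting and shuffling.
#' @param val_fraction Fraction of volumes held out for validation.
#' @param threshold Binarization cutoff used for validation metrics.
#' @return An object of class `train_config`.
#' @export
train_config <- function(epochs = 25L, batch_size = 16L, learning_rate = 0.01,
                         momentum = 0.9, weight_decay = 5e-4,
                         loss = loss_config(), model = model_config(),
                         seed = 1L, val_fraction = 0.1, threshold = 0.5) {
  stopifnot(epochs >= 1, batch_size >= 1, learning_rate > 0,
            momentum >= 0, momentum < 1, weight_decay >= 0,
            inherits(loss, "loss_config"), inherits(model, "model_config"),
            val_fraction >= 0, val_fraction < 1)
  structure(list(epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size),
                 learning_rate = learning_rate, momentum = momentum,
                 weight_decay = weight_decay, loss = loss, model = model,
                 seed = as.integer(seed), val_fraction = val_fraction,
                 threshold = threshold),
            class = "train_config")
}

.stack_batch <- function(samples, idx) {
  d <- dim(samples[[idx[1]]]$image)
  x <- array(0, c(d[1], d[2], 1L, length(idx)))
  y <- array(0, c(d[1], d[2], 1L, length(idx)))
  for (j in seq_along(idx)) {
    s <- samples[[idx[j]]]
    x[, , 1L, j] <- s$image
    y[, , 1L, j] <- s$mask
  }
  list(x = x, y = y)
}

# One SGD-with-momentum step (PyTorch convention: decay folded into the
# gradient, velocity update v <- mu v + g, parameter step p <- p - lr v).
.sgd_step <- function(params, leaves, vel, lr, mu, wd) {
  for (nm in ls(leaves)) {
    lf <- leaves[[nm]]
    g <- lf$grad
    if (is.null(g)) next
    p <- params[[nm]]
    g <- g + wd * p
    v <- vel[[nm]]
    v <- if (is.null(v)) g else mu * v + g
    vel[[nm]] <- v
    params[[nm]] <- p - lr * v
  }
}

#' Train the segmentation network
#'
#' Minimizes the compound cross-entropy / log-Dice loss by mini-batch SGD
#' over the training split, logs per-epoch train loss and validation
#' Dice/precision/recall/F1, and returns the parameters of the epoch with
#' the best validation Dice. Fully deterministic given the configuration
#' seed and the sample list.
#'
#' @param samples List of [slice_sample()] objects (all the same size), or
#'   a manifest path accepted by [load_samples()].
#' @param config A [train_config()].
#' @param verbose Print one line per epoch.
#' @return An object of class `fracseg_fit`: `model` (best checkpoint),
#'   `log` (per-epoch data frame), `best_epoch`, `config`.
#' @export
train_model <- function(samples, config = train_config(), verbose = FALSE) {
  stopifnot(inherits(config, "train_config"))
  if (is.character(samples)) samples <- load_samples(samples)
  if (!length(samples)) stop("empty training manifest")
  model <- build_model(config$model, seed = config$seed)
  .with_seed(config$seed * 2L + 1L, {
    vols <- vapply(samples, `[[`, "", "volume_id")
    uv <- unique(vols)
    if (length(uv) >= 2L && config$val_fraction > 0) {
      nval <- max(1L, floor(config$val_fraction * length(uv)))
      val_vols <- sample(uv, nval)
      val_idx <- which(vols %in% val_vols)
      tr_idx <- setdiff(seq_along(samples), val_idx)
    } else {
      tr_idx <- seq_along(samples)
      val_idx <- seq_along(samples)
    }
    vel <- new.env(parent = emptyenv())
    log <- NULL
    best <- list(dice = -Inf, epoch = 0L, params = NULL, bn = NULL)
    for (ep in seq_len(config$epochs)) {
      ord <- sample(tr_idx)
      nb <- ceiling(length(ord) / config$batch_size)
      losses <- numeric(nb)
      for (bi in seq_len(nb)) {
        idx <- ord[((bi - 1L) * config$batch_size + 1L):
                     min(bi * config$batch_size, length(ord))]
        batch <- .stack_batch(samples, idx)
        tape <- ag_tape()
        ctx <- new_ctx(tape, model$params, model$bn, training = TRUE)
        xnode <- ag_leaf(tape, batch$x)
        pred <- .net_forward(ctx, xnode, config$model)
        lnode <- ag_compound_loss(tape, pred, batch$y, config$loss)
        if (!is.finite(lnode$value)) {
          stop("non-finite training loss at epoch ", ep, ", batch ", bi)
        }
        ag_backward(tape, lnode)
        .sgd_step(model$params, ctx$leaves, vel, config$learning_rate,
                  config$momentum, config$weight_decay)
        losses[bi] <- lnode$value
      }
      vm <- evaluate_model(model, samples[val_idx],
                           threshold = config$threshold)
      log <- rbind(log, data.frame(epoch = ep, train_loss = mean(losses),
                                   val_dice = vm$dice,
                                   val_precision = vm$precision,
                                   val_recall = vm$recall, val_f1 = vm$f1))
      if (verbose) {
        message(sprintf("epoch %2d  loss %.4f  val dice %.4f  F1 %.4f",
                        ep, mean(losses), vm$dice, vm$f1))
      }
      if (vm$dice > best$dice) {
        best <- list(dice = vm$dice, epoch = ep,
                     params = as.list(model$params), bn = as.list(model$bn))
      }
    }
    for (nm in names(best$params)) model$params[[nm]] <- best$params[[nm]]
    for (nm in names(best$bn)) model$bn[[nm]] <- best$bn[[nm]]
    structure(list(model = model, log = log, best_epoch = best$epoch,
                   config = config),
              class = "fracseg_fit")
  })
}

#' @export
print.fracseg_fit <- function(x, ...) {
  cat("<fracseg_fit> trained", nrow(x$log), "epochs; best epoch",
      x$best_epoch, "\n")
  print(tail(x$log, 3L), row.names = FALSE)
  invisible(x)
}

#' Evaluate a model on labelled slices
#'
#' Runs the full inference chain (forward pass, thresholding, component
#' boxes, greedy matching to ground-truth components) over every sample and
#' aggregates lesion-level TP/FP/FN into precision/recall/F1, plus the
#' pixel Dice computed from intersection/size sums pooled over the whole
#' set (per-image mean Dice is available via `dice_mode`).
#'
#' @param model A `fracseg_model` or `fracseg_fit`.
#' @param samples List of [slice_sample()] objects or a manifest path.
#' @param threshold Binarization cutoff.
#' @param min_area Minimum predicted component area to keep as a detection.
#' @param min_overlap,connectivity,method Passed to [match_to_truth()].
#' @param merge_gap If non-`NULL`, merge predicted boxes with
#'   [merge_boxes()] at this gap before matching.
#' @param dice_mode `"aggregate"` (default) or `"per_image"`.
#' @return A [detection_metrics()] report with `dice` filled in; the
#'   per-image table is attached as attribute `"per_image"`.
#' @export
evaluate_model <- function(model, samples, threshold = 0.5, min_area = 0L,
                           min_overlap = 0, connectivity = 8L,
                           method = "coverage", merge_gap = NULL,
                           dice_mode = c("aggregate", "per_image")) {
  dice_mode <- match.arg(dice_mode)
  if (inherits(model, "fracseg_fit")) model <- model$model
  if (is.character(samples)) samples <- load_samples(samples)
  tp <- fp <- fn <- 0L
  inter <- psum <- tsum <- 0
  rows <- vector("list", length(samples))
  for (i in seq_along(samples)) {
    s <- samples[[i]]
    prob <- model_forward(model, s$image)
    pm <- binarize(prob, threshold)
    boxes <- mask_to_boxes(pm, connectivity, min_area)
    if (!is.null(merge_gap)) boxes <- merge_boxes(boxes, merge_gap)
    mt <- match_to_truth(boxes, s$mask, min_overlap, connectivity, method)
    tp <- tp + mt$tp; fp <- fp + mt$fp; fn <- fn + mt$fn
    ii <- sum(pm * s$mask)
    inter <- inter + ii; psum <- psum + sum(pm); tsum <- tsum + sum(s$mask)
    rows[[i]] <- data.frame(volume_id = s$volume_id,
                            slice_index = s$slice_index,
                            tp = mt$tp, fp = mt$fp, fn = mt$fn,
                            dice = dice_coeff(pm, s$mask, smooth = 1e-8))
  }
  per <- do.call(rbind, rows)
  dice <- if (dice_mode == "aggregate") {
    if (psum + tsum > 0) 2 * inter / (psum + tsum) else 1
  } else {
    mean(per$dice)
  }
  rep_ <- detection_metrics(tp, fp, fn, dice = dice)
  attr(rep_, "per_image") <- per
  rep_
}

#' Segment a single image
#'
#' @param model A `fracseg_model` or `fracseg_fit`.
#' @param image Intensity matrix in \[0, 1\].
#' @param threshold Binarization cutoff.
#' @param min_area Minimum component area kept as a detection.
#' @param merge_gap Optional box-merging gap (see [merge_boxes()]).
#' @return `list(prob, mask, boxes)`.
#' @export
predict_mask <- function(model, image, threshold = 0.5, min_area = 0L,
                         merge_gap = NULL) {
  if (inherits(model, "fracseg_fit")) model <- model$model
  prob <- model_forward(model, image)
  mask <- binarize(prob, threshold)
  boxes <- mask_to_boxes(mask, min_area = min_area)
  if (!is.null(merge_gap)) boxes <- merge_boxes(boxes, merge_gap)
  list(prob = prob, mask = mask, boxes = boxes)
}

#' Save / load a model checkpoint
#'
#' Checkpoints are R native serialization holding the parameter arrays, the
#' batchnorm running statistics, and the model configuration both as an R
#' object and as an embedded JSON string for provenance.
#'
#' @param model A `fracseg_model` or `fracseg_fit`.
#' @param path Destination `.rds` path.
#' @return `path`, invisibly.
#' @export
save_checkpoint <- function(model, path) {
  if (inherits(model, "fracseg_fit")) model <- model$model
  obj <- list(params = as.list(model$params), bn = as.list(model$bn),
              config = model$config, seed = model$seed,
              config_json = as.character(
                jsonlite::toJSON(unclass(model$config), auto_unbox = TRUE)))
  saveRDS(obj, path)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) {
  obj <- readRDS(path)
  params <- list2env(obj$params, new.env(parent = emptyenv()))
  bn <- list2env(obj$bn, new.env(parent = emptyenv()))
  structure(list(config = obj$config, params = params, bn = bn,
                 seed = obj$seed),
            class = "fracseg_model")
}

#' Run the HDDC/CAM ablation grid
#'
#' Trains one model per (use_hddc, use_cam, theta, seed) cell with shared
#' data and per-seed shared initialization/shuffling, evaluating each on
#' its held-out volumes. Rows mirror an ablation table: module flags then
#' Recall / F1 / Precision (plus Dice and parameter count).
#'
#' @param samples Training slices (list of [slice_sample()]).
#' @param config Base [train_config()]; its model flags are overridden per
#'   cell.
#' @param grid Data frame with logical columns `use_hddc`, `use_cam`
#'   (default: the full 2x2 grid).
#' @param thetas Numeric vector of loss mixing weights (default: the
#'   configured theta only).
#' @param seeds Integer vector of training seeds.
#' @param verbose Print progress.
#' @return Data frame, one row per cell and seed.
#' @export
run_ablation <- function(samples, config = train_config(),
                         grid = expand.grid(use_hddc = c(FALSE, TRUE),
                                            use_cam = c(FALSE, TRUE)),
                         thetas = NULL, seeds = NULL, verbose = FALSE) {
  if (is.null(thetas)) thetas <- config$loss$theta
  if (is.null(seeds)) seeds <- config$seed
  out <- NULL
  for (seed in seeds) {
    for (g in seq_len(nrow(grid))) {
      for (th in thetas) {
        cfg <- config
        cfg$seed <- as.integer(seed)
        cfg$model$use_hddc <- grid$use_hddc[g]
        cfg$model$use_cam <- grid$use_cam[g]
        cfg$loss$theta <- th
        fit <- train_model(samples, cfg, verbose = FALSE)
        best <- fit$log[fit$best_epoch, ]
        if (verbose) {
          message(sprintf("hddc=%d cam=%d theta=%.2f seed=%d -> dice %.4f",
                          grid$use_hddc[g], grid$use_cam[g], th, seed,
                          best$val_dice))
        }
        out <- rbind(out, data.frame(
          use_hddc = grid$use_hddc[g], use_cam = grid$use_cam[g],
          theta = th, seed = seed,
          recall = best$val_recall, f1 = best$val_f1,
          precision = best$val_precision, dice = best$val_dice,
          n_params = n_parameters(fit$model)))
      }
    }
  }
  out
}

# --- configuration file round trip ---------------------------------------

.config_as_list <- function(config) {
  l <- unclass(config)
  l$loss <- unclass(l$loss)
  l$model <- unclass(l$model)
  l
}

#' Write / read a training configuration
#'
#' YAML (default, by extension `.yml`/`.yaml`) or JSON. The round trip
#' reproduces identical effective settings.
#'
#' @param config A [train_config()].
#' @param path Destination path.
#' @return `path` invisibly; `read_config()` returns a [train_config()].
#' @export
write_config <- function(config, path) {
  stopifnot(inherits(config, "train_config"))
  l <- .config_as_list(config)
  if (grepl("\\.json$", path)) {
    jsonlite::write_json(l, path, auto_unbox = TRUE, digits = NA)
  } else {
    yaml::write_yaml(l, path)
  }
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  l <- if (grepl("\\.json$", path)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  model <- do.call(model_config, l$model)
  loss <- do.call(loss_config, l$loss)
  rest <- l[setdiff(names(l), c("model", "loss"))]
  do.call(train_config, c(rest, list(model = model, loss = loss)))
}
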