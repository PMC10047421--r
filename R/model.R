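#' Model configuration
#'
#' Hyper-parameters of the residual attention U-net: a ResNet-style encoder
#' (stem + four stages of basic residual blocks), a hybrid dense dilated
#' convolution (HDDC) bottleneck, and a decoder that upsamples by transposed
#' convolution and fuses each skip connection through a coordinate attention
#' module (CAM). Both modules can be ablated independently, which reproduces
#' the plain residual U-net baseline when both are off.
#'
#' @param in_channels Number of input image channels (CT slices: 1).
#' @param n_classes Number of foreground probability maps (binary task: 1).
#' @param encoder_channels Channel widths: stem then the four residual
#'   stages. The default mirrors ResNet34 (64, 64, 128, 256, 512); tests use
#'   reduced widths, which changes capacity but no equations.
#' @param blocks Residual blocks per stage (ResNet34: 3, 4, 6, 3).
#' @param cam_reduction_r Channel compression ratio r of the attention
#'   bottleneck; every skip width divided by r must stay >= 1.
#' @param hddc_rates Dilation-rate cascade of the bottleneck. The default
#'   (1, 3, 5) follows the hybrid-dilated-convolution anti-gridding rule.
#' @param use_hddc,use_cam Ablation switches; with both `FALSE` the model is
#'   the residual U-net baseline.
#' @param hddc_merge How HDDC branch projections are combined: `"sum"`
#'   (superimposed, default) or `"concat"` then jointly projected.
#' @param pad_mode `"pad"` zero-pads inputs whose size is not a multiple of
#'   the total downsampling factor (32 by default) and crops the output
#'   back; `"error"` rejects such inputs.
#' @return An object of class `model_config`.
#' @export
model_config <- function(in_channels = 1L, n_classes = 1L,
                         encoder_channels = c(64L, 64L, 128L, 256L, 512L),
                         blocks = c(3L, 4L, 6L, 3L),
                         cam_reduction_r = 16L,
                         hddc_rates = c(1L, 3L, 5L),
                         use_hddc = TRUE, use_cam = TRUE,
                         hddc_merge = c("sum", "concat"),
                         pad_mode = c("pad", "error")) {
  hddc_merge <- match.arg(hddc_merge)
  pad_mode <- match.arg(pad_mode)
  stopifnot(in_channels >= 1, n_classes >= 1,
            length(encoder_channels) == length(blocks) + 1L,
            all(encoder_channels >= 1), all(blocks >= 1))
  if (cam_reduction_r < 1) stop("cam_reduction_r must be >= 1")
  if (any(hddc_rates < 1) || any(hddc_rates != as.integer(hddc_rates))) {
    stop("hddc_rates must be strictly positive integers")
  }
  if (use_cam && any(encoder_channels %/% cam_reduction_r < 1)) {
    stop("cam_reduction_r too large: some channel count / r < 1")
  }
  structure(list(in_channels = as.integer(in_channels),
                 n_classes = as.integer(n_classes),
                 encoder_channels = as.integer(encoder_channels),
                 blocks = as.integer(blocks),
                 cam_reduction_r = as.integer(cam_reduction_r),
                 hddc_rates = as.integer(hddc_rates),
                 use_hddc = isTRUE(use_hddc),
                 use_cam = isTRUE(use_cam),
                 hddc_merge = hddc_merge,
                 pad_mode = pad_mode),
            class = "model_config")
}

#' Total downsampling factor of the encoder
#' @param config A [model_config()].
#' @return Integer factor (stem and pooling contribute 4, each later stage 2).
#' @export
downsample_factor <- function(config) {
  4L * 2L^(length(config$blocks) - 1L)
}

# Core forward pass: x is a node with value (H, W, C_in, N); returns the
# sigmoid probability node (H, W, n_classes, N).
.net_forward <- function(ctx, x, config) {
  ch <- config$encoder_channels
  e0 <- ag_relu(ctx$tape, nn_bn(ctx, "stem.bn",
        nn_conv(ctx, "stem.conv", x, ch[1], k = 7L, stride = 2L, pad = 3L)))
  h <- ag_maxpool2(ctx$tape, e0)
  skips <- list(e0)
  for (s in seq_along(config$blocks)) {
    stride <- if (s == 1L) 1L else 2L
    for (b in seq_len(config$blocks[s])) {
      h <- residual_block(ctx, sprintf("enc%d.block%d", s, b), h, ch[s + 1L],
                          stride = if (b == 1L) stride else 1L)
    }
    skips[[s + 1L]] <- h
  }
  if (config$use_hddc) {
    h <- hddc_block(ctx, "hddc", h, config$hddc_rates, config$hddc_merge)
  }
  for (s in rev(seq_along(config$blocks))) {
    skip <- skips[[s]]
    up <- nn_deconv2(ctx, sprintf("dec%d.up", s), h, dim(skip$value)[3])
    if (config$use_cam) {
      fused <- cam_block(ctx, sprintf("dec%d.cam", s), skip, up,
                         config$cam_reduction_r)$out
    } else {
      fused <- ag_add(ctx$tape, skip, up)
    }
    h <- nn_cbr(ctx, sprintf("dec%d.refine", s), fused, dim(skip$value)[3])
  }
  h <- nn_deconv2(ctx, "head.up", h, ch[1])
  h <- ag_relu(ctx$tape, nn_bn(ctx, "head.bn", h))
  logits <- nn_conv(ctx, "head.out", h, config$n_classes, 1L, pad = 0L)
  ag_sigmoid(ctx$tape, logits)
}

#' Build a model with seeded random initialization
#'
#' Parameters are created by a shape trace of the forward pass (He-normal
#' convolution weights, unit-gamma batchnorm), so the parameter set is fully
#' determined by the configuration and `seed`.
#'
#' @param config A [model_config()].
#' @param seed Integer seed for the initializer.
#' @return An object of class `fracseg_model`.
#' @export
build_model <- function(config = model_config(), seed = 1L) {
  stopifnot(inherits(config, "model_config"))
  params <- new.env(parent = emptyenv())
  bn <- new.env(parent = emptyenv())
  f <- downsample_factor(config)
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  set.seed(seed)
  ctx <- new_ctx(ag_tape(), params, bn, training = TRUE, allow_init = TRUE)
  # random trace input so batchnorm running statistics start at the scale
  # of real activations (an all-zero trace would leave them degenerate)
  dummy <- ag_leaf(ctx$tape,
                   array(runif(4L * f * f * config$in_channels * 2L),
                         c(2L * f, 2L * f, config$in_channels, 2L)))
  invisible(.net_forward(ctx, dummy, config))
  if (!is.null(old)) assign(".Random.seed", old, globalenv()) else
    rm(".Random.seed", envir = globalenv())
  structure(list(config = config, params = params, bn = bn,
                 seed = as.integer(seed)),
            class = "fracseg_model")
}

#' Number of trainable parameters
#' @param model A `fracseg_model`.
#' @return Integer count of scalar trainable parameters.
#' @export
n_parameters <- function(model) {
  sum(vapply(ls(model$params), function(nm) length(model$params[[nm]]), 1))
}

#' Names of trainable parameter tensors
#' @param model A `fracseg_model`.
#' @return Sorted character vector.
#' @export
parameter_names <- function(model) sort(ls(model$params))

#' @export
print.fracseg_model <- function(x, ...) {
  cfg <- x$config
  cat("<fracseg_model> residual attention U-net\n")
  cat("  encoder channels:", paste(cfg$encoder_channels, collapse = "/"),
      " blocks:", paste(cfg$blocks, collapse = ","), "\n")
  cat("  HDDC:", if (cfg$use_hddc) paste0("rates ", paste(cfg$hddc_rates, collapse = ",")) else "off",
      "  CAM:", if (cfg$use_cam) paste0("r = ", cfg$cam_reduction_r) else "off", "\n")
  cat("  parameters:", format(n_parameters(x), big.mark = ","), "\n")
  invisible(x)
}

# Coerce an image (matrix, HWC array, or HWCN array) to (H, W, C, N).
.as_batch <- function(image, in_channels) {
  d <- dim(image)
  if (is.null(d) || length(d) == 2L) {
    image <- array(image, c(d %||% c(length(image), 1L), 1L, 1L))
  } else if (length(d) == 3L) {
    image <- array(image, c(d, 1L))
  } else if (length(d) != 4L) {
    stop("image must be a matrix or a 3D/4D array")
  }
  if (dim(image)[3] != in_channels) {
    stop("image has ", dim(image)[3], " channels; model expects ", in_channels)
  }
  image
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Run the network on an image
#'
#' Applies the full encoder / bottleneck / attention-decoder network and
#' returns per-pixel foreground probabilities in (0, 1). Inputs whose sides
#' are not multiples of the downsampling factor are zero-padded and the
#' output cropped back (or rejected, per `pad_mode` in the configuration).
#'
#' @param model A `fracseg_model` from [build_model()] or [load_checkpoint()].
#' @param image Matrix (H x W), array (H x W x C), or batch (H x W x C x N)
#'   of intensities, typically in \[0, 1\] after [apply_window()].
#' @param training Use batch statistics and record gradients context
#'   (internal training mode); default `FALSE` uses running statistics.
#' @return Probability map with the same spatial shape (and rank) as the
#'   input.
#' @export
model_forward <- function(model, image, training = FALSE) {
  stopifnot(inherits(model, "fracseg_model"))
  cfg <- model$config
  rank <- length(dim(image) %||% 2L)
  x <- .as_batch(image, cfg$in_channels)
  d <- dim(x)
  f <- downsample_factor(cfg)
  H <- d[1]; W <- d[2]
  Hp <- f * ceiling(H / f); Wp <- f * ceiling(W / f)
  if (Hp != H || Wp != W) {
    if (cfg$pad_mode == "error") {
      stop("input size ", H, "x", W, " is not divisible by ", f)
    }
    xp <- array(0, c(Hp, Wp, d[3], d[4]))
    xp[seq_len(H), seq_len(W), , ] <- x
    x <- xp
  }
  ctx <- new_ctx(NULL, model$params, model$bn, training = training,
                 allow_init = FALSE)
  node <- ag_leaf(NULL, x)
  out <- .net_forward(ctx, node, cfg)$value
  out <- out[seq_len(H), seq_len(W), , , drop = FALSE]
  if (rank == 2L && cfg$n_classes == 1L) dim(out) <- c(H, W)
  else if (rank == 3L) dim(out) <- dim(out)[1:3]
  out
}

#' Directional (coordinate) average pooling
#'
#' Per-channel average pooling with kernels (H, 1) and (1, W): the height
#' profile averages each row over the width, the width profile averages each
#' column over the height.
#'
#' @param x Matrix (H x W) or array (H x W x C).
#' @return `list(h, w)`: `h` is an H x C matrix, `w` a W x C matrix.
#' @export
directional_pool <- function(x) {
  if (is.matrix(x)) dim(x) <- c(dim(x), 1L)
  stopifnot(length(dim(x)) == 3L)
  d <- dim(x)
  h <- apply(x, 3L, rowMeans)
  w <- apply(x, 3L, colMeans)
  list(h = matrix(h, d[1], d[3]), w = matrix(w, d[2], d[3]))
}

.wrap_fm <- function(x) {
  if (is.matrix(x)) dim(x) <- c(dim(x), 1L)
  stopifnot(length(dim(x)) == 3L)
  array(x, c(dim(x), 1L))
}

#' Coordinate attention skip fusion (standalone)
#'
#' Functional form of the attention fusion used at every decoder skip:
#' directional profiles of the two maps are summed, squeezed to C/r
#' channels, split, and expanded into per-height and per-width sigmoid
#' gates that modulate the low-level map before adding the high-level map,
#' `out[i,j,c] = x_l[i,j,c] * f_h[i,c] * f_w[j,c] + x_t[i,j,c]`.
#'
#' @param x_l Low-level (encoder) feature map, H x W matrix or H x W x C.
#' @param x_t High-level (decoder) feature map, same shape.
#' @param r Channel compression ratio (C/r must be >= 1).
#' @param init `"random"` (seeded He init) or `"zero"` (all three 1x1
#'   convolutions frozen at zero, so every gate is exactly sigmoid(0) = 0.5).
#' @param seed Seed for the random initialization.
#' @return `list(output, f_h, f_w)`: the fused map (same shape as input) and
#'   the two gate matrices (H x C and W x C), all entries in (0, 1).
#' @export
cam_fuse <- function(x_l, x_t, r = 16L, init = c("random", "zero"), seed = 1L) {
  init <- match.arg(init)
  if (!identical(dim(x_l), dim(x_t))) {
    stop("cam_fuse: x_l and x_t must have identical shapes")
  }
  orig_dim <- dim(x_l)
  xl <- .wrap_fm(x_l)
  xt <- .wrap_fm(x_t)
  params <- new.env(parent = emptyenv())
  bn <- new.env(parent = emptyenv())
  run <- function() {
    ctx <- new_ctx(ag_tape(), params, bn, training = TRUE, allow_init = TRUE)
    cam_block(ctx, "cam", ag_leaf(ctx$tape, xl), ag_leaf(ctx$tape, xt), r)
  }
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  set.seed(seed)
  res <- run()
  if (init == "zero") {
    for (nm in ls(params)) {
      if (grepl("\\.(squeeze|fh|fw)\\.[wb]$", nm)) params[[nm]][] <- 0
    }
    res <- run()
  }
  if (!is.null(old)) assign(".Random.seed", old, globalenv())
  out <- res$out$value
  dim(out) <- dim(xl)[1:3]
  if (length(orig_dim) == 2L) dim(out) <- orig_dim
  C <- dim(xl)[3]
  list(output = out,
       f_h = matrix(res$fh$value, dim(xl)[1], C),
       f_w = matrix(res$fw$value, dim(xl)[2], C))
}

#' Hybrid dense dilated convolution bottleneck (standalone)
#'
#' Functional form of the bottleneck: a shared cascade of 3x3 dilated
#' convolutions (one per rate, in order) is tapped after every step; each
#' tap and a 1x1 path on the input are projected to the input channel count
#' and superimposed (or concatenated then projected). Spatial size and
#' channel count are always preserved.
#'
#' @param x Feature map, H x W matrix or H x W x C array.
#' @param rates Strictly positive integer dilation rates.
#' @param merge `"sum"` (default) or `"concat"`.
#' @param seed Seed for the random initialization.
#' @return Array with the same shape as `x`.
#' @export
hddc_forward <- function(x, rates = c(1L, 3L, 5L), merge = c("sum", "concat"),
                         seed = 1L) {
  merge <- match.arg(merge)
  if (any(rates < 1)) stop("hddc dilation rates must be >= 1")
  orig_dim <- dim(x)
  xa <- .wrap_fm(x)
  params <- new.env(parent = emptyenv())
  bn <- new.env(parent = emptyenv())
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  set.seed(seed)
  ctx <- new_ctx(ag_tape(), params, bn, training = TRUE, allow_init = TRUE)
  out <- hddc_block(ctx, "hddc", ag_leaf(ctx$tape, xa), as.integer(rates), merge)
  if (!is.null(old)) assign(".Random.seed", old, globalenv())
  v <- out$value
  dim(v) <- dim(xa)[1:3]
  if (length(orig_dim) == 2L) dim(v) <- orig_dim
  v
}

#' Theoretical receptive field of a dilated 3x3 cascade
#'
#' Computed by the standard layer-by-layer recurrence
#' `rf <- rf + (k - 1) * dilation * jump` with stride-1 3x3 layers, so a
#' single rate-d convolution spans `2d + 1` pixels and a cascade with rates
#' `d_1..d_m` spans `1 + 2 * sum(d_i)`.
#'
#' @param x A [model_config()] (uses its `hddc_rates`, the deepest HDDC
#'   branch at the bottleneck) or a numeric vector of dilation rates.
#' @return Receptive field extent in pixels (1 when the bottleneck is
#'   disabled or the cascade is empty).
#' @export
receptive_field <- function(x) {
  rates <- if (inherits(x, "model_config")) {
    if (!x$use_hddc) return(1L)
    x$hddc_rates
  } else {
    x
  }
  if (any(rates < 1)) stop("dilation rates must be >= 1")
  rf <- 1L
  jump <- 1L
  for (d in rates) {
    rf <- rf + 2L * as.integer(d) * jump   # (k - 1) * dilation * jump, k = 3
    jump <- jump * 1L                      # stride 1 throughout
  }
  rf
}
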