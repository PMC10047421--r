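# Parameter-managed layers on top of the autodiff tape.
#
# A forward "context" bundles the tape, the parameter store (name -> array),
# the batchnorm running-statistics store, the per-forward leaf cache, the
# training flag, and whether missing parameters may be lazily initialized
# (only during the seeded build-time trace).

new_ctx <- function(tape, params, bn, training = FALSE, allow_init = FALSE) {
  e <- new.env(parent = emptyenv())
  e$tape <- tape
  e$params <- params
  e$bn <- bn
  e$leaves <- new.env(parent = emptyenv())
  e$training <- training
  e$allow_init <- allow_init
  e
}

getp <- function(ctx, name, init_fn) {
  nd <- ctx$leaves[[name]]
  if (!is.null(nd)) return(nd)
  v <- ctx$params[[name]]
  if (is.null(v)) {
    if (!ctx$allow_init) stop("unknown parameter '", name, "'")
    v <- init_fn()
    ctx$params[[name]] <- v
  }
  nd <- ag_leaf(ctx$tape, v, name)
  ctx$leaves[[name]] <- nd
  nd
}

.he_init <- function(kh, kw, ci, co) {
  array(rnorm(kh * kw * ci * co, sd = sqrt(2 / (kh * kw * ci))),
        c(kh, kw, ci, co))
}

nn_conv <- function(ctx, name, x, co, k = 3L, stride = 1L, dilation = 1L,
                    pad = NULL) {
  ci <- dim(x$value)[3]
  if (is.null(pad)) pad <- dilation * (k - 1L) %/% 2L
  w <- getp(ctx, paste0(name, ".w"), function() .he_init(k, k, ci, co))
  b <- getp(ctx, paste0(name, ".b"), function() numeric(co))
  ag_conv(ctx$tape, x, w, b, stride, dilation, pad)
}

nn_bn <- function(ctx, name, x) {
  c_ <- dim(x$value)[3]
  g <- getp(ctx, paste0(name, ".g"), function() rep(1, c_))
  b <- getp(ctx, paste0(name, ".b"), function() numeric(c_))
  ag_bn(ctx$tape, x, g, b, ctx$bn, name, ctx$training)
}

nn_cbr <- function(ctx, name, x, co, k = 3L, stride = 1L, dilation = 1L) {
  ag_relu(ctx$tape, nn_bn(ctx, paste0(name, ".bn"),
                          nn_conv(ctx, paste0(name, ".conv"), x, co, k,
                                  stride, dilation)))
}

nn_deconv2 <- function(ctx, name, x, co) {
  ci <- dim(x$value)[3]
  w <- getp(ctx, paste0(name, ".w"),
            function() array(rnorm(4L * ci * co, sd = sqrt(2 / (4 * ci))),
                             c(2L, 2L, ci, co)))
  b <- getp(ctx, paste0(name, ".b"), function() numeric(co))
  ag_deconv2(ctx$tape, x, w, b)
}

# ResNet basic block: two 3x3 conv/BN with identity (or projected) shortcut.
residual_block <- function(ctx, name, x, co, stride = 1L) {
  ci <- dim(x$value)[3]
  h <- nn_conv(ctx, paste0(name, ".conv1"), x, co, 3L, stride)
  h <- ag_relu(ctx$tape, nn_bn(ctx, paste0(name, ".bn1"), h))
  h <- nn_conv(ctx, paste0(name, ".conv2"), h, co, 3L, 1L)
  h <- nn_bn(ctx, paste0(name, ".bn2"), h)
  sc <- x
  if (ci != co || stride != 1L) {
    sc <- nn_conv(ctx, paste0(name, ".down.conv"), x, co, 1L, stride, pad = 0L)
    sc <- nn_bn(ctx, paste0(name, ".down.bn"), sc)
  }
  ag_relu(ctx$tape, ag_add(ctx$tape, h, sc))
}

# Hybrid dense dilated convolution bottleneck. A shared cascade of 3x3
# dilated convolutions (one per rate) is tapped after each step; every tap,
# plus a 1x1 path on the input, is brought to the common channel count by a
# 1x1 convolution and the projections are either summed (default) or
# concatenated and jointly projected.
hddc_block <- function(ctx, name, x, rates, merge = c("sum", "concat")) {
  merge <- match.arg(merge)
  if (any(rates < 1)) stop("hddc dilation rates must be >= 1")
  c_ <- dim(x$value)[3]
  b0 <- nn_cbr(ctx, paste0(name, ".b0"), x, c_, k = 1L)
  taps <- list()
  cur <- x
  for (k in seq_along(rates)) {
    cur <- nn_cbr(ctx, paste0(name, ".casc", k), cur, c_, k = 3L,
                  dilation = as.integer(rates[k]))
    taps[[k]] <- nn_conv(ctx, paste0(name, ".proj", k), cur, c_, 1L, pad = 0L)
  }
  if (merge == "sum") {
    out <- b0
    for (t in taps) out <- ag_add(ctx$tape, out, t)
    out
  } else {
    cat_ <- ag_concat3(ctx$tape, c(list(b0), taps))
    nn_conv(ctx, paste0(name, ".merge"), cat_, c_, 1L, pad = 0L)
  }
}

# Coordinate-attention skip fusion. Height/width average-pooled profiles of
# the low-level (encoder) and high-level (decoder) maps are summed per
# direction, concatenated along the spatial axis, squeezed to C/r channels
# through a shared 1x1 conv + BN + ReLU, split, and expanded back to C by
# per-direction 1x1 convs with sigmoid gates. The gates modulate the
# low-level map, which is then added to the high-level map.
cam_block <- function(ctx, name, xl, xt, r) {
  dl <- dim(xl$value)
  if (!identical(dl, dim(xt$value))) {
    stop("cam_fuse: low-level and high-level feature shapes differ")
  }
  c_ <- dl[3]
  cr <- c_ %/% r
  if (cr < 1) stop("cam_fuse: channels/r < 1 (C = ", c_, ", r = ", r, ")")
  H <- dl[1]; W <- dl[2]
  zh <- ag_add(ctx$tape, ag_dirpool_h(ctx$tape, xt), ag_dirpool_h(ctx$tape, xl))
  zw <- ag_add(ctx$tape, ag_dirpool_w(ctx$tape, xt), ag_dirpool_w(ctx$tape, xl))
  zc <- ag_concat1(ctx$tape, zh, zw)                      # (H+W, 1, C, N)
  y <- nn_conv(ctx, paste0(name, ".squeeze"), zc, cr, 1L, pad = 0L)
  y <- ag_relu(ctx$tape, nn_bn(ctx, paste0(name, ".bn"), y))
  yh <- ag_slice1(ctx$tape, y, seq_len(H))
  yw <- ag_slice1(ctx$tape, y, H + seq_len(W))
  fh <- ag_sigmoid(ctx$tape, nn_conv(ctx, paste0(name, ".fh"), yh, c_, 1L, pad = 0L))
  fw <- ag_sigmoid(ctx$tape, nn_conv(ctx, paste0(name, ".fw"), yw, c_, 1L, pad = 0L))
  fw <- ag_t12(ctx$tape, fw)                              # (1, W, C, N)
  gate <- ag_bmul(ctx$tape, fh, fw)                       # (H, W, C, N)
  list(out = ag_add(ctx$tape, ag_mul(ctx$tape, xl, gate), xt),
       fh = fh, fw = fw)
}
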