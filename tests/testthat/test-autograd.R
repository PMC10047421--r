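# Finite-difference gradient checks of every tape primitive. Each check
# builds a tiny graph ending in a weighted sum so the root is scalar, then
# compares the analytic input gradient with central differences.

ag <- function(name) get(name, asNamespace("fracseg"))

check_input_grad <- function(build, x0, tol = 1e-6) {
  # build(tape, xnode) -> output node
  wsum <- NULL
  f <- function(xv) {
    tape <- ag("ag_tape")()
    xn <- ag("ag_leaf")(tape, xv)
    out <- build(tape, xn)
    if (is.null(wsum)) wsum <<- rnorm(length(out$value))
    sum(out$value * wsum)
  }
  f(x0)  # fix the weights
  tape <- ag("ag_tape")()
  xn <- ag("ag_leaf")(tape, x0)
  out <- build(tape, xn)
  root <- ag("ag_node")(tape, sum(out$value * wsum), list(out),
                        function(g) list(array(g * wsum, dim(out$value))))
  ag("ag_backward")(tape, root)
  expect_lt(max(abs(xn$grad - num_grad(f, x0))), tol)
}

test_that("conv, deconv and pooling gradients match finite differences", {
  set.seed(5)
  w <- array(rnorm(3 * 3 * 2 * 3), c(3, 3, 2, 3))
  b <- rnorm(3)
  x0 <- array(rnorm(6 * 8 * 2 * 2), c(6, 8, 2, 2))
  for (cfg in list(c(1, 1, 1), c(2, 1, 1), c(1, 2, 2))) {
    check_input_grad(function(tape, xn) {
      ag("ag_conv")(tape, xn, ag("ag_leaf")(tape, w), ag("ag_leaf")(tape, b),
                    stride = cfg[1], dilation = cfg[2], pad = cfg[3])
    }, x0)
  }
  wd <- array(rnorm(2 * 2 * 2 * 3), c(2, 2, 2, 3))
  bd <- rnorm(3)
  check_input_grad(function(tape, xn) {
    ag("ag_deconv2")(tape, xn, ag("ag_leaf")(tape, wd), ag("ag_leaf")(tape, bd))
  }, x0)
  # keep pooling away from ties so the subgradient is unambiguous
  xp <- array(seq_len(4 * 4 * 2 * 2) / 7, c(4, 4, 2, 2))
  check_input_grad(function(tape, xn) ag("ag_maxpool2")(tape, xn), xp)
})

test_that("conv weight and bias gradients match finite differences", {
  set.seed(6)
  x <- array(rnorm(5 * 5 * 2 * 2), c(5, 5, 2, 2))
  w0 <- array(rnorm(3 * 3 * 2 * 2), c(3, 3, 2, 2))
  b0 <- rnorm(2)
  wsum <- rnorm(5 * 5 * 2 * 2)
  f <- function(wv, bv) {
    y <- fracseg:::.conv_fwd(x, wv, bv, 1L, 1L, 1L)
    sum(y * wsum)
  }
  r <- fracseg:::.conv_bwd(x, w0, array(wsum, c(5, 5, 2, 2)), 1L, 1L, 1L)
  expect_lt(max(abs(r$dw - num_grad(function(wv) f(wv, b0), w0))), 1e-6)
  expect_lt(max(abs(r$db - num_grad(function(bv) f(w0, bv), b0))), 1e-6)
})

test_that("batchnorm, attention pooling and broadcast ops back-propagate", {
  set.seed(7)
  x0 <- array(rnorm(4 * 5 * 3 * 2), c(4, 5, 3, 2))
  gm <- rnorm(3); bt <- rnorm(3)
  check_input_grad(function(tape, xn) {
    st <- new.env(parent = emptyenv())
    ag("ag_bn")(tape, xn, ag("ag_leaf")(tape, gm), ag("ag_leaf")(tape, bt),
                st, "k", training = TRUE)
  }, x0, tol = 1e-5)
  check_input_grad(function(tape, xn) ag("ag_dirpool_h")(tape, xn), x0)
  check_input_grad(function(tape, xn) ag("ag_dirpool_w")(tape, xn), x0)
  check_input_grad(function(tape, xn) ag("ag_sigmoid")(tape, xn), x0)
  other <- array(rnorm(4 * 1 * 3 * 2), c(4, 1, 3, 2))
  check_input_grad(function(tape, xn) {
    ag("ag_bmul")(tape, xn, ag("ag_leaf")(tape, other))
  }, x0)
  check_input_grad(function(tape, xn) {
    z <- ag("ag_concat1")(tape, xn, ag("ag_leaf")(tape, x0))
    ag("ag_slice1")(tape, z, 2:6)
  }, x0)
})

test_that("compound loss gradient matches finite differences", {
  set.seed(8)
  p0 <- array(runif(40, 0.05, 0.95), c(5, 8))
  y <- array(as.numeric(runif(40) < 0.2), c(5, 8))
  cfg <- loss_config(theta = 0.35)
  g <- compound_loss_grad(p0, y, cfg)
  fd <- num_grad(function(p) compound_loss(p, y, cfg), p0)
  expect_lt(max(abs(g - fd)), 1e-6)
})

test_that("a whole-model gradient agrees with finite differences", {
  set.seed(9)
  cfgm <- model_config(encoder_channels = c(4, 4, 6, 8, 8),
                       blocks = c(1, 1, 1, 1), cam_reduction_r = 2,
                       hddc_rates = c(1, 2))
  m <- build_model(cfgm, seed = 7)
  H <- 32
  x <- array(runif(H * H * 2), c(H, H, 1, 2))
  truth <- array(as.numeric(runif(H * H * 2) < 0.1), c(H, H, 1, 2))
  lcfg <- loss_config(theta = 0.3)
  fwd <- function() {
    tape <- ag("ag_tape")()
    ctx <- fracseg:::new_ctx(tape, m$params, m$bn, training = TRUE)
    pr <- fracseg:::.net_forward(ctx, ag("ag_leaf")(tape, x), cfgm)
    list(tape = tape, ctx = ctx,
         loss = fracseg:::ag_compound_loss(tape, pr, truth, lcfg))
  }
  r <- fwd()
  ag("ag_backward")(r$tape, r$loss)
  eps <- 1e-5
  for (nm in c("stem.conv.w", "hddc.casc1.bn.b", "dec3.cam.squeeze.w",
               "dec1.refine.conv.w", "head.out.w", "enc2.block1.down.conv.w")) {
    gvec <- r$ctx$leaves[[nm]]$grad
    expect_false(is.null(gvec))
    i <- which.max(abs(gvec))  # check the most informative coordinate
    pv <- m$params[[nm]]
    m$params[[nm]][i] <- pv[i] + eps
    lp <- fwd()$loss$value
    m$params[[nm]][i] <- pv[i] - eps
    lm <- fwd()$loss$value
    m$params[[nm]][i] <- pv[i]
    fd <- (lp - lm) / (2 * eps)
    # loose tolerance: the loss is only piecewise smooth (ReLU, max-pool),
    # and deep BN shift parameters can move activations across kinks that
    # central differences straddle; per-op checks above are the tight ones
    expect_lt(abs(fd - gvec[i]) / max(abs(fd), 1e-8), 1e-2)
  }
})
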