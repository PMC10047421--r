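# Minimal reverse-mode autodiff over 4D arrays, layout (H, W, C, N).
#
# Nodes are environments carrying a value, the parent nodes, and a backward
# closure mapping the incoming gradient to per-parent gradients. The tape
# records nodes in creation order, which is already a topological order, so
# the backward pass is a single reverse sweep. There is no graph pruning:
# networks here are small enough that simplicity wins.

ag_tape <- function() {
  e <- new.env(parent = emptyenv())
  e$nodes <- vector("list", 256L)
  e$n <- 0L
  e
}

ag_node <- function(tape, value, parents = list(), backfn = NULL, name = NULL) {
  nd <- new.env(parent = emptyenv())
  nd$value <- value
  nd$parents <- parents
  nd$backfn <- backfn
  nd$grad <- NULL
  nd$name <- name
  nd$id <- NA_integer_
  if (!is.null(tape)) {
    tape$n <- tape$n + 1L
    if (tape$n > length(tape$nodes)) {
      length(tape$nodes) <- 2L * length(tape$nodes)
    }
    tape$nodes[[tape$n]] <- nd
    nd$id <- tape$n
  }
  nd
}

ag_leaf <- function(tape, value, name = NULL) ag_node(tape, value, name = name)

ag_backward <- function(tape, root) {
  stopifnot(length(root$value) == 1L)
  root$grad <- 1
  for (i in seq(root$id, 1L)) {
    nd <- tape$nodes[[i]]
    if (is.null(nd$grad) || is.null(nd$backfn)) next
    gs <- nd$backfn(nd$grad)
    for (k in seq_along(nd$parents)) {
      g <- gs[[k]]
      if (is.null(g)) next
      p <- nd$parents[[k]]
      p$grad <- if (is.null(p$grad)) g else p$grad + g
    }
    nd$grad <- NULL  # free intermediate gradients eagerly
  }
  invisible(NULL)
}

# --- broadcasting helpers -------------------------------------------------

# Expand size-1 dimensions of x up to target dims d.
.bc <- function(x, d) {
  dx <- dim(x)
  if (identical(as.integer(dx), as.integer(d))) return(x)
  idx <- lapply(seq_along(d), function(k) {
    if (dx[k] == d[k]) seq_len(d[k]) else rep.int(1L, d[k])
  })
  do.call(`[`, c(list(x), idx, list(drop = FALSE)))
}

# Sum g down to dims d (where d[k] == 1 < dim(g)[k]).
.reduceto <- function(g, d) {
  for (k in seq_along(d)) {
    cur <- dim(g)
    if (d[k] == 1L && cur[k] > 1L) {
      perm <- c(k, setdiff(seq_along(cur), k))
      g <- colSums(aperm(g, perm))
      newd <- cur
      newd[k] <- 1L
      dim(g) <- newd
    }
  }
  g
}

# --- primitive ops --------------------------------------------------------

ag_conv <- function(tape, x, w, b, stride = 1L, dilation = 1L, pad = 0L) {
  v <- .conv_fwd(x$value, w$value, b$value, stride, dilation, pad)
  ag_node(tape, v, list(x, w, b), function(g) {
    r <- .conv_bwd(x$value, w$value, g, stride, dilation, pad)
    list(r$dx, r$dw, r$db)
  })
}

ag_relu <- function(tape, x) {
  m <- x$value > 0
  ag_node(tape, x$value * m, list(x), function(g) list(g * m))
}

ag_sigmoid <- function(tape, x) {
  s <- 1 / (1 + exp(-x$value))
  ag_node(tape, s, list(x), function(g) list(g * s * (1 - s)))
}

ag_add <- function(tape, a, b) {
  ag_node(tape, a$value + b$value, list(a, b), function(g) list(g, g))
}

ag_mul <- function(tape, a, b) {
  ag_node(tape, a$value * b$value, list(a, b),
          function(g) list(g * b$value, g * a$value))
}

ag_scale <- function(tape, x, s) {
  ag_node(tape, x$value * s, list(x), function(g) list(g * s))
}

# Broadcast multiply; either operand may have size-1 dims.
ag_bmul <- function(tape, a, b) {
  d <- pmax(dim(a$value), dim(b$value))
  av <- .bc(a$value, d)
  bv <- .bc(b$value, d)
  da <- dim(a$value)
  db <- dim(b$value)
  ag_node(tape, av * bv, list(a, b), function(g) {
    list(.reduceto(g * bv, da), .reduceto(g * av, db))
  })
}

ag_maxpool2 <- function(tape, x) {
  r <- .maxpool2_fwd(x$value)
  xd <- dim(x$value)
  ag_node(tape, r$y, list(x), function(g) list(.maxpool2_bwd(g, r$idx, xd)))
}

# Transposed convolution, kernel 2, stride 2 (non-overlapping upsampling).
# Implemented in R as a matrix product plus an index scatter.
.deconv_cache <- new.env(parent = emptyenv())

.deconv_idx <- function(H, W, Co) {
  key <- paste(H, W, Co, sep = "x")
  idx <- .deconv_cache[[key]]
  if (is.null(idx)) {
    # T is (H*W, 4*Co) with column index q-1 = a + 2*b + 4*co
    p <- seq_len(H * W) - 1L
    i <- p %% H
    j <- p %/% H
    q <- seq_len(4L * Co) - 1L
    a <- q %% 2L
    b <- (q %/% 2L) %% 2L
    co <- q %/% 4L
    idx <- outer(2L * i, rep(1L, 4L * Co)) +
      outer(rep(1L, H * W), a) +
      2L * H * (outer(2L * j, rep(1L, 4L * Co)) + outer(rep(1L, H * W), b)) +
      4L * H * W * outer(rep(1L, H * W), co) + 1L
    .deconv_cache[[key]] <- idx
  }
  idx
}

ag_deconv2 <- function(tape, x, w, b) {
  xd <- dim(x$value)
  H <- xd[1]; W <- xd[2]; Ci <- xd[3]; N <- xd[4]
  Co <- dim(w$value)[4]
  Wm <- matrix(aperm(w$value, c(3, 1, 2, 4)), nrow = Ci)  # Ci x (4*Co)
  idx <- .deconv_idx(H, W, Co)
  y <- array(0, c(2L * H, 2L * W, Co, N))
  for (n in seq_len(N)) {
    Xn <- matrix(x$value[, , , n, drop = FALSE], nrow = H * W, ncol = Ci)
    Tn <- Xn %*% Wm
    yn <- numeric(4L * H * W * Co)
    yn[as.vector(idx)] <- as.vector(Tn)
    y[, , , n] <- yn + rep(b$value, each = 4L * H * W)
  }
  ag_node(tape, y, list(x, w, b), function(g) {
    dx <- array(0, xd)
    dW <- matrix(0, Ci, 4L * Co)
    db <- numeric(Co)
    for (n in seq_len(N)) {
      gn <- as.vector(g[, , , n, drop = FALSE])
      dTn <- matrix(gn[as.vector(idx)], nrow = H * W, ncol = 4L * Co)
      Xn <- matrix(x$value[, , , n, drop = FALSE], nrow = H * W, ncol = Ci)
      dx[, , , n] <- dTn %*% t(Wm)
      dW <- dW + t(Xn) %*% dTn
      db <- db + colSums(matrix(gn, nrow = 4L * H * W, ncol = Co))
    }
    dw <- aperm(array(dW, c(Ci, 2L, 2L, Co)), c(2, 3, 1, 4))
    list(dx, dw, db)
  })
}

# Batch normalization over (H, W, N) per channel. `state` is an environment
# holding running first/second moments under `key` (used in eval mode).
.chan_mat <- function(x) {
  d <- dim(x)
  matrix(aperm(x, c(1, 2, 4, 3)), ncol = d[3])
}

.chan_unmat <- function(m, d) {
  aperm(array(m, c(d[1], d[2], d[4], d[3])), c(1, 2, 4, 3))
}

ag_bn <- function(tape, x, gamma, beta, state, key, training,
                  momentum = 0.1, eps = 1e-5) {
  d <- dim(x$value)
  xm <- .chan_mat(x$value)
  M <- nrow(xm)
  if (training) {
    mu <- colMeans(xm)
    va <- colMeans(xm * xm) - mu * mu
    va[va < 0] <- 0
    rs <- state[[key]]
    if (is.null(rs)) {
      state[[key]] <- list(mean = mu, var = va)
    } else {
      state[[key]] <- list(mean = (1 - momentum) * rs$mean + momentum * mu,
                           var  = (1 - momentum) * rs$var + momentum * va)
    }
  } else {
    rs <- state[[key]]
    if (is.null(rs)) stop("batchnorm '", key, "' has no running statistics")
    mu <- rs$mean
    va <- rs$var
  }
  sig <- sqrt(va + eps)
  xhat <- sweep(sweep(xm, 2, mu, "-"), 2, sig, "/")
  ym <- sweep(sweep(xhat, 2, gamma$value, "*"), 2, beta$value, "+")
  ag_node(tape, .chan_unmat(ym, d), list(x, gamma, beta), function(g) {
    gm <- .chan_mat(g)
    dgamma <- colSums(gm * xhat)
    dbeta <- colSums(gm)
    dxh <- sweep(gm, 2, gamma$value, "*")
    if (training) {
      t1 <- sweep(dxh, 2, colMeans(dxh), "-")
      t2 <- xhat * rep(colMeans(dxh * xhat), each = M)
      dxm <- sweep(t1 - t2, 2, sig, "/")
    } else {
      dxm <- sweep(dxh, 2, sig, "/")
    }
    list(.chan_unmat(dxm, d), dgamma, dbeta)
  })
}

# Directional average pooling: height profile (H,1,C,N), width profile
# as a column image (W,1,C,N) so 1x1 convolutions apply uniformly.
ag_dirpool_h <- function(tape, x) {
  d <- dim(x$value)
  z <- .reduceto(x$value, c(d[1], 1L, d[3], d[4])) / d[2]
  ag_node(tape, z, list(x), function(g) list(.bc(g, d) / d[2]))
}

ag_dirpool_w <- function(tape, x) {
  d <- dim(x$value)
  z <- .reduceto(x$value, c(1L, d[2], d[3], d[4])) / d[1]
  z <- aperm(z, c(2, 1, 3, 4))
  ag_node(tape, z, list(x), function(g) {
    list(.bc(aperm(g, c(2, 1, 3, 4)), d) / d[1])
  })
}

# Swap the two spatial dims.
ag_t12 <- function(tape, x) {
  ag_node(tape, aperm(x$value, c(2, 1, 3, 4)), list(x),
          function(g) list(aperm(g, c(2, 1, 3, 4))))
}

ag_concat1 <- function(tape, a, b) {
  da <- dim(a$value)
  db <- dim(b$value)
  v <- array(0, c(da[1] + db[1], da[2], da[3], da[4]))
  v[seq_len(da[1]), , , ] <- a$value
  v[da[1] + seq_len(db[1]), , , ] <- b$value
  ag_node(tape, v, list(a, b), function(g) {
    list(g[seq_len(da[1]), , , , drop = FALSE],
         g[da[1] + seq_len(db[1]), , , , drop = FALSE])
  })
}

ag_slice1 <- function(tape, x, rows) {
  d <- dim(x$value)
  ag_node(tape, x$value[rows, , , , drop = FALSE], list(x), function(g) {
    dx <- array(0, d)
    dx[rows, , , ] <- g
    list(dx)
  })
}

ag_concat3 <- function(tape, nodes) {
  ds <- lapply(nodes, function(n) dim(n$value))
  cs <- vapply(ds, function(d) d[3], 1)
  d1 <- ds[[1]]
  v <- array(0, c(d1[1], d1[2], sum(cs), d1[4]))
  off <- 0L
  for (k in seq_along(nodes)) {
    v[, , off + seq_len(cs[k]), ] <- nodes[[k]]$value
    off <- off + cs[k]
  }
  ag_node(tape, v, nodes, function(g) {
    out <- vector("list", length(nodes))
    off <- 0L
    for (k in seq_along(nodes)) {
      out[[k]] <- g[, , off + seq_len(cs[k]), , drop = FALSE]
      off <- off + cs[k]
    }
    out
  })
}
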