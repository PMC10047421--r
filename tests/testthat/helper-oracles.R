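# Brute-force oracles kept deliberately independent of the package
# implementation: queue-based flood fill for component labelling and a
# direct pixel-overlap matcher.

flood_label <- function(mask, connectivity = 8) {
  H <- nrow(mask); W <- ncol(mask)
  lab <- matrix(0L, H, W)
  nbr <- if (connectivity == 8) {
    cbind(c(-1, 1, 0, 0, -1, -1, 1, 1), c(0, 0, -1, 1, -1, 1, -1, 1))
  } else {
    cbind(c(-1, 1, 0, 0), c(0, 0, -1, 1))
  }
  cur <- 0L
  for (j in seq_len(W)) for (i in seq_len(H)) {
    if (mask[i, j] == 0 || lab[i, j] != 0) next
    cur <- cur + 1L
    queue <- list(c(i, j))
    lab[i, j] <- cur
    while (length(queue)) {
      p <- queue[[1]]; queue <- queue[-1]
      for (k in seq_len(nrow(nbr))) {
        qi <- p[1] + nbr[k, 1]; qj <- p[2] + nbr[k, 2]
        if (qi >= 1 && qi <= H && qj >= 1 && qj <= W &&
            mask[qi, qj] != 0 && lab[qi, qj] == 0) {
          lab[qi, qj] <- cur
          queue[[length(queue) + 1L]] <- c(qi, qj)
        }
      }
    }
  }
  lab
}

oracle_boxes <- function(mask, connectivity = 8, min_area = 0) {
  lab <- flood_label(mask, connectivity)
  out <- NULL
  for (k in seq_len(max(lab))) {
    w <- which(lab == k, arr.ind = TRUE)
    if (nrow(w) < min_area) next
    out <- rbind(out, data.frame(
      x_min = min(w[, 2]) - 1L, y_min = min(w[, 1]) - 1L,
      x_max = max(w[, 2]), y_max = max(w[, 1]), area = nrow(w)))
  }
  if (is.null(out)) {
    out <- data.frame(x_min = integer(0), y_min = integer(0),
                      x_max = integer(0), y_max = integer(0),
                      area = integer(0))
  }
  out
}

rand_mask <- function(h, w, p = 0.2) {
  matrix(as.integer(runif(h * w) < p), h, w)
}

# Central finite differences of a scalar function at x (array).
num_grad <- function(f, x, eps = 1e-5) {
  g <- x
  for (i in seq_along(x)) {
    xp <- x; xp[i] <- x[i] + eps
    xm <- x; xm[i] <- x[i] - eps
    g[i] <- (f(xp) - f(xm)) / (2 * eps)
  }
  g
}

tiny_train_data <- function(n = 30, size = 64, seed = 7) {
  generate_phantom_dataset(n, phantom_spec(image_size = size), seed = seed)
}
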