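# Probability maps -> binary masks -> lesion components -> detection boxes.
# Box coordinates are 0-based, half-open on the max side, with x = column
# and y = row (row-major), used consistently across the package.

#' Threshold a probability map
#'
#' @param prob_map Numeric array with values in \[0, 1\].
#' @param threshold Cutoff in (0, 1); pixels `>= threshold` are foreground.
#' @return Integer 0/1 mask of the same shape.
#' @export
binarize <- function(prob_map, threshold = 0.5) {
  stopifnot(threshold > 0, threshold < 1)
  if (any(prob_map < 0 | prob_map > 1)) {
    stop("prob_map must lie in [0, 1]")
  }
  m <- (prob_map >= threshold) + 0L
  dim(m) <- dim(prob_map)
  m
}

#' Label connected components of a binary mask
#'
#' @param mask Binary matrix.
#' @param connectivity 4 or 8 (default 8: thin oblique cracks fragment
#'   under 4-connectivity).
#' @return Integer matrix of component labels (0 = background).
#' @export
label_mask <- function(mask, connectivity = 8L) {
  stopifnot(connectivity %in% c(4L, 8L))
  m <- matrix(as.integer(mask != 0), nrow(mask), ncol(mask))
  .label_components(m, as.integer(connectivity))
}

.box_from_pixels <- function(rows, cols) {
  # rows/cols 1-based; produce 0-based half-open bounds
  c(x_min = min(cols) - 1L, y_min = min(rows) - 1L,
    x_max = max(cols), y_max = max(rows))
}

#' Extract tight bounding boxes of mask components
#'
#' One axis-aligned box per connected component with at least `min_area`
#' pixels.
#'
#' @param mask Binary matrix.
#' @inheritParams label_mask
#' @param min_area Minimum component pixel count to keep.
#' @return Data frame with columns `x_min`, `y_min`, `x_max`, `y_max`
#'   (0-based, max-exclusive), `area` (component pixel count), `matched`.
#' @export
mask_to_boxes <- function(mask, connectivity = 8L, min_area = 0L) {
  stopifnot(min_area >= 0)
  lab <- label_mask(mask, connectivity)
  n <- max(lab)
  out <- data.frame(x_min = integer(0), y_min = integer(0),
                    x_max = integer(0), y_max = integer(0),
                    area = integer(0), matched = logical(0))
  if (n == 0L) return(out)
  for (k in seq_len(n)) {
    w <- which(lab == k, arr.ind = TRUE)
    if (nrow(w) < min_area) next
    b <- .box_from_pixels(w[, 1], w[, 2])
    out <- rbind(out, data.frame(x_min = b[["x_min"]], y_min = b[["y_min"]],
                                 x_max = b[["x_max"]], y_max = b[["y_max"]],
                                 area = nrow(w), matched = FALSE))
  }
  rownames(out) <- NULL
  out
}

#' Merge nearby detection boxes
#'
#' Boxes whose expansions by `gap / 2` on every side intersect are unioned,
#' transitively, so a fracture fragmented into several components can be
#' reported as one detection. `gap = 0` merges only boxes that already
#' overlap. The merged `area` is the sum of the member component areas.
#'
#' @param boxes Data frame as returned by [mask_to_boxes()].
#' @param gap Maximum pixel gap to bridge (>= 0).
#' @return Data frame of merged boxes.
#' @export
merge_boxes <- function(boxes, gap = 0) {
  stopifnot(gap >= 0)
  n <- nrow(boxes)
  if (n <= 1L) return(boxes)
  g <- gap / 2
  # union-find over pairwise intersection of expanded boxes
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  for (i in seq_len(n - 1L)) {
    for (j in seq(i + 1L, n)) {
      xi <- c(boxes$x_min[i] - g, boxes$x_max[i] + g,
              boxes$y_min[i] - g, boxes$y_max[i] + g)
      xj <- c(boxes$x_min[j] - g, boxes$x_max[j] + g,
              boxes$y_min[j] - g, boxes$y_max[j] + g)
      if (xi[1] < xj[2] && xj[1] < xi[2] && xi[3] < xj[4] && xj[3] < xi[4]) {
        ri <- find(i); rj <- find(j)
        if (ri != rj) parent[ri] <- rj
      }
    }
  }
  roots <- vapply(seq_len(n), find, 1L)
  out <- do.call(rbind, lapply(unique(roots), function(r) {
    m <- boxes[roots == r, , drop = FALSE]
    data.frame(x_min = min(m$x_min), y_min = min(m$y_min),
               x_max = max(m$x_max), y_max = max(m$y_max),
               area = sum(m$area), matched = any(m$matched))
  }))
  rownames(out) <- NULL
  out
}

#' Match detection boxes to ground-truth components
#'
#' Each ground-truth component is a connected region of `truth_mask`. A
#' candidate match is a (box, component) pair with positive pixel overlap
#' whose score passes `min_overlap`; matching is greedy one-to-one in order
#' of decreasing overlapping pixel count. Matched components are TP,
#' unmatched components FN, unmatched boxes FP.
#'
#' @param pred_boxes Data frame from [mask_to_boxes()] (possibly merged).
#' @param truth_mask Binary matrix of ground-truth lesion pixels.
#' @param min_overlap Minimum score in \[0, 1\]. With `method =
#'   "coverage"` (default) the score is the fraction of the component's
#'   pixels inside the box and 0 means any positive overlap counts; with
#'   `"iou"` it is intersection over union of the box and the component.
#' @param connectivity Connectivity for the ground-truth components.
#' @param method Matching criterion, `"coverage"` or `"iou"`.
#' @return `list(tp, fp, fn, matched)` where `matched` flags which rows of
#'   `pred_boxes` were matched.
#' @export
match_to_truth <- function(pred_boxes, truth_mask, min_overlap = 0,
                           connectivity = 8L,
                           method = c("coverage", "iou")) {
  method <- match.arg(method)
  stopifnot(min_overlap >= 0, min_overlap <= 1)
  lab <- label_mask(truth_mask, connectivity)
  nc <- max(lab)
  nb <- nrow(pred_boxes)
  if (nc == 0L) {
    return(list(tp = 0L, fp = nb, fn = 0L, matched = rep(FALSE, nb)))
  }
  comp_size <- tabulate(lab[lab > 0], nbins = nc)
  cand <- NULL
  for (b in seq_len(nb)) {
    rows <- (pred_boxes$y_min[b] + 1L):pred_boxes$y_max[b]
    cols <- (pred_boxes$x_min[b] + 1L):pred_boxes$x_max[b]
    sub <- lab[rows, cols, drop = FALSE]
    labs <- sub[sub > 0]
    if (!length(labs)) next
    for (k in unique(labs)) {
      inter <- sum(labs == k)
      score <- if (method == "coverage") {
        inter / comp_size[k]
      } else {
        inter / (length(rows) * length(cols) + comp_size[k] - inter)
      }
      ok <- if (min_overlap == 0) inter > 0 else score >= min_overlap
      if (ok) cand <- rbind(cand, c(b, k, inter))
    }
  }
  box_matched <- rep(FALSE, nb)
  comp_matched <- rep(FALSE, nc)
  if (!is.null(cand)) {
    cand <- cand[order(-cand[, 3]), , drop = FALSE]
    for (i in seq_len(nrow(cand))) {
      b <- cand[i, 1]; k <- cand[i, 2]
      if (!box_matched[b] && !comp_matched[k]) {
        box_matched[b] <- TRUE
        comp_matched[k] <- TRUE
      }
    }
  }
  list(tp = sum(comp_matched), fp = sum(!box_matched), fn = sum(!comp_matched),
       matched = box_matched)
}

#' Export boxes as CSV
#'
#' @param boxes Data frame of boxes.
#' @param image_id Identifier written in the first column.
#' @param path Destination CSV path.
#' @return The path, invisibly.
#' @export
write_boxes_csv <- function(boxes, image_id, path) {
  df <- cbind(image_id = image_id,
              boxes[, c("x_min", "y_min", "x_max", "y_max", "area")])
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Render a truth/prediction overlay
#'
#' Grayscale image with ground-truth component outlines in green and
#' predicted boxes in red, written as an 8-bit PNG (requires the `png`
#' package) or returned as an H x W x 3 array.
#'
#' @param image Intensity matrix in \[0, 1\].
#' @param truth_mask Binary matrix (drawn green).
#' @param pred_boxes Data frame of boxes (drawn red).
#' @param path Optional PNG destination; if `NULL` the RGB array is
#'   returned.
#' @return The RGB array (invisibly if written to file).
#' @export
render_overlay <- function(image, truth_mask = NULL, pred_boxes = NULL,
                           path = NULL) {
  H <- nrow(image); W <- ncol(image)
  rgb <- array(pmin(pmax(image, 0), 1), c(H, W, 3))
  if (!is.null(truth_mask)) {
    edge <- truth_mask != 0
    rgb[, , 1][edge] <- 0; rgb[, , 2][edge] <- 1; rgb[, , 3][edge] <- 0
  }
  if (!is.null(pred_boxes) && nrow(pred_boxes)) {
    for (i in seq_len(nrow(pred_boxes))) {
      r0 <- max(pred_boxes$y_min[i] + 1L, 1L); r1 <- min(pred_boxes$y_max[i], H)
      c0 <- max(pred_boxes$x_min[i] + 1L, 1L); c1 <- min(pred_boxes$x_max[i], W)
      for (ch in 1:3) {
        v <- if (ch == 1) 1 else 0
        rgb[r0, c0:c1, ch] <- v; rgb[r1, c0:c1, ch] <- v
        rgb[r0:r1, c0, ch] <- v; rgb[r0:r1, c1, ch] <- v
      }
    }
  }
  if (!is.null(path)) {
    if (!requireNamespace("png", quietly = TRUE)) {
      stop("the 'png' package is required to write overlays")
    }
    png::writePNG(rgb, path)
    return(invisible(rgb))
  }
  rgb
}
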