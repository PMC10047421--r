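test_that("binarize thresholds with >= convention and is idempotent", {
  expect_equal(sum(binarize(matrix(0, 4, 4))), 0)
  expect_true(all(binarize(matrix(0.5, 3, 3), 0.5) == 1L))
  set.seed(1)
  p <- matrix(runif(64), 8)
  b <- binarize(p, 0.3)
  expect_identical(binarize(b, 0.3), b)
  expect_error(binarize(matrix(1.2)), "\\[0, 1\\]")
  expect_error(binarize(p, 0), "threshold")
})

test_that("mask_to_boxes reproduces the worked examples", {
  expect_equal(nrow(mask_to_boxes(matrix(0L, 8, 8))), 0)
  m <- matrix(0L, 10, 10)
  m[3:5, 6:8] <- 1L   # rows 2-4, cols 5-7 in 0-based coordinates
  b <- mask_to_boxes(m)
  expect_equal(unlist(b[1, c("x_min", "y_min", "x_max", "y_max", "area")]),
               c(x_min = 5, y_min = 2, x_max = 8, y_max = 5, area = 9))
  # diagonal touch merges under 8- but not 4-connectivity
  d <- matrix(0L, 6, 6)
  d[2:3, 2:3] <- 1L
  d[4:5, 4:5] <- 1L
  expect_equal(nrow(mask_to_boxes(d, connectivity = 8)), 1)
  expect_equal(nrow(mask_to_boxes(d, connectivity = 4)), 2)
  # min_area filters small components
  d[1, 6] <- 1L
  expect_equal(nrow(mask_to_boxes(d, connectivity = 4, min_area = 2)), 2)
})

test_that("merge_boxes unions transitively and is idempotent", {
  far <- data.frame(x_min = c(0, 20), y_min = c(0, 20), x_max = c(4, 24),
                    y_max = c(4, 24), area = c(16, 16),
                    matched = c(FALSE, FALSE))
  expect_equal(merge_boxes(far, gap = 0), far)
  near <- data.frame(x_min = c(0, 5), y_min = c(0, 0), x_max = c(4, 9),
                     y_max = c(4, 4), area = c(16, 16),
                     matched = c(FALSE, FALSE))
  mg <- merge_boxes(near, gap = 2)
  expect_equal(nrow(mg), 1)
  expect_equal(unlist(mg[1, c("x_min", "y_min", "x_max", "y_max", "area")]),
               c(x_min = 0, y_min = 0, x_max = 9, y_max = 4, area = 32))
  expect_identical(merge_boxes(mg, gap = 2), mg)
  # gap 0 still merges truly overlapping boxes
  ov <- near
  ov$x_min[2] <- 3
  expect_equal(nrow(merge_boxes(ov, gap = 0)), 1)
  # merging never increases the count; union of extents is covered
  set.seed(2)
  rb <- data.frame(x_min = sample(0:30, 8), y_min = sample(0:30, 8),
                   area = 1, matched = FALSE)
  rb$x_max <- rb$x_min + sample(1:6, 8, replace = TRUE)
  rb$y_max <- rb$y_min + sample(1:6, 8, replace = TRUE)
  rb$area <- (rb$x_max - rb$x_min) * (rb$y_max - rb$y_min)
  mg2 <- merge_boxes(rb, gap = 3)
  expect_lte(nrow(mg2), nrow(rb))
  expect_equal(min(mg2$x_min), min(rb$x_min))
  expect_equal(max(mg2$x_max), max(rb$x_max))
})

test_that("match_to_truth follows the greedy coverage contract", {
  m <- matrix(0L, 12, 12)
  m[2:3, 2:4] <- 1L
  m[8:10, 8:9] <- 1L
  exact <- mask_to_boxes(m)
  r <- match_to_truth(exact, m)
  expect_equal(c(r$tp, r$fp, r$fn), c(2, 0, 0))
  # no predictions: everything is a miss
  none <- mask_to_boxes(matrix(0L, 12, 12))
  r0 <- match_to_truth(none, m)
  expect_equal(c(r0$tp, r0$fp, r0$fn), c(0, 0, 2))
  # half-covering box passes a 0.25 coverage requirement
  half <- data.frame(x_min = 1, y_min = 1, x_max = 4, y_max = 2,
                     area = 3, matched = FALSE)  # covers 3 of 6 pixels
  r5 <- match_to_truth(half, m, min_overlap = 0.25)
  expect_equal(r5$tp, 1)
  expect_equal(r5$fn, 1)
  # same box fails a strict IoU requirement
  riou <- match_to_truth(half, m, min_overlap = 0.9, method = "iou")
  expect_equal(riou$tp, 0)
})

test_that("component extraction and matching agree with the flood-fill oracle", {
  set.seed(33)
  for (i in 1:25) {
    m <- rand_mask(24, 24, p = runif(1, 0.1, 0.45))
    for (conn in c(4L, 8L)) {
      got <- mask_to_boxes(m, conn)
      want <- oracle_boxes(m, conn)
      ord <- function(b) b[order(b$x_min, b$y_min, b$x_max, b$y_max), ,
                           drop = FALSE]
      g <- ord(got[, names(want)]); rownames(g) <- NULL
      w <- ord(want); rownames(w) <- NULL
      expect_equal(g, w)
      # tp + fn always equals the number of truth components
      truth <- rand_mask(24, 24, p = 0.2)
      r <- match_to_truth(got, truth, connectivity = conn)
      expect_equal(r$tp + r$fn, max(flood_label(truth, conn)))
    }
  }
})

test_that("boxes cover every foreground pixel they were extracted from", {
  set.seed(34)
  m <- rand_mask(30, 30, 0.3)
  boxes <- mask_to_boxes(m)
  covered <- matrix(FALSE, 30, 30)
  for (i in seq_len(nrow(boxes))) {
    covered[(boxes$y_min[i] + 1):boxes$y_max[i],
            (boxes$x_min[i] + 1):boxes$x_max[i]] <- TRUE
  }
  expect_true(all(covered[m == 1L]))
})
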