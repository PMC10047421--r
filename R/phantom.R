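# Seeded synthetic rib phantoms: an elliptical ring of bright "rib"
# cross-sections (cortical bone clips to the top of the display window) on
# a noisy soft-tissue background, with a minority of ribs carrying a thin
# dark crack. The mask marks crack pixels only, so foreground occupies far
# less than 1% of the image -- the class imbalance the loss is built for.

.with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv())) {
    get(".Random.seed", globalenv())
  } else NULL
  set.seed(seed)
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, globalenv())
  })
  force(code)
}

#' Construct a validated slice sample
#'
#' @param image Numeric matrix with intensities in \[0, 1\].
#' @param mask Binary matrix of lesion pixels, same shape.
#' @param volume_id Identifier of the source volume.
#' @param slice_index Non-negative integer slice position.
#' @return An object of class `slice_sample`.
#' @export
slice_sample <- function(image, mask, volume_id = "volume", slice_index = 0L) {
  if (!identical(dim(image), dim(mask))) {
    stop("image and mask shapes differ")
  }
  if (any(image < 0 | image > 1)) stop("image intensities must lie in [0, 1]")
  if (!all(mask %in% c(0, 1))) stop("mask must be binary")
  if (slice_index < 0) stop("slice_index must be >= 0")
  structure(list(image = image, mask = matrix(as.integer(mask), nrow(mask)),
                 volume_id = as.character(volume_id),
                 slice_index = as.integer(slice_index)),
            class = "slice_sample")
}

#' Phantom specification
#'
#' States the synthetic world: image geometry, tissue intensity ranges (on
#' the windowed \[0, 1\] scale), fracture prevalence and crack geometry, and
#' the acquisition noise level.
#'
#' @param image_size Side length in pixels.
#' @param n_ribs Fixed count, or a length-2 range sampled per phantom.
#' @param rib_intensity Range of cortical-bone shell intensity; near 1
#'   because +1000 HU bone clips at the top of a width-1000/level-600
#'   window.
#' @param background_intensity Range of the soft-tissue background.
#' @param fracture_probability Per-rib probability of carrying a crack.
#' @param crack_width Crack thickness in pixels (1-3 is realistic for thin
#'   fracture lines).
#' @param crack_intensity Range of the crack gap intensity; soft-tissue-like
#'   density showing through the broken cortical shell.
#' @param noise_sigma Additive Gaussian noise standard deviation.
#' @param seed RNG seed making the phantom fully reproducible.
#' @return An object of class `phantom_spec`.
#' @export
phantom_spec <- function(image_size = 256L, n_ribs = c(10L, 14L),
                         rib_intensity = c(0.92, 1.0),
                         background_intensity = c(0.40, 0.60),
                         fracture_probability = 0.35,
                         crack_width = 2L,
                         crack_intensity = c(0.40, 0.50),
                         noise_sigma = 0.03, seed = 1L) {
  stopifnot(image_size >= 1, all(n_ribs >= 1),
            fracture_probability >= 0, fracture_probability <= 1,
            crack_width >= 1, noise_sigma >= 0)
  rng_ok <- function(r) all(r >= 0) && all(r <= 1)
  if (!rng_ok(rib_intensity) || !rng_ok(background_intensity) ||
      !rng_ok(crack_intensity)) {
    stop("all intensity ranges must lie in [0, 1]")
  }
  structure(list(image_size = as.integer(image_size),
                 n_ribs = as.integer(n_ribs),
                 rib_intensity = rib_intensity,
                 background_intensity = background_intensity,
                 fracture_probability = fracture_probability,
                 crack_width = crack_width,
                 crack_intensity = crack_intensity,
                 noise_sigma = noise_sigma,
                 seed = as.integer(seed)),
            class = "phantom_spec")
}

#' Generate one rib phantom slice
#'
#' Deterministic given `spec$seed`: same spec, bit-identical image and
#' mask. Ribs are ellipses on an elliptical chest-wall ring, oriented along
#' the ring tangent; a fractured rib has a thin dark band through its
#' centre, perpendicular to its long axis, and the mask marks exactly those
#' band pixels (each crack is therefore one connected component).
#'
#' @param spec A [phantom_spec()].
#' @return A [slice_sample()].
#' @export
generate_phantom <- function(spec = phantom_spec()) {
  stopifnot(inherits(spec, "phantom_spec"))
  size <- spec$image_size
  if (size < 24L) stop("image_size too small: ribs would exceed the image")
  .with_seed(spec$seed, {
    cx <- (size + 1) / 2
    cy <- (size + 1) / 2
    rx <- 0.36 * size
    ry <- 0.30 * size
    a <- 0.052 * size          # rib semi-major (along ring tangent)
    b <- 0.030 * size          # rib semi-minor
    n <- if (length(spec$n_ribs) == 2L) {
      sample(spec$n_ribs[1]:spec$n_ribs[2], 1L)
    } else spec$n_ribs[1]
    X <- matrix(rep(seq_len(size), each = size), size)   # column index
    Y <- matrix(rep(seq_len(size), times = size), size)  # row index
    img <- matrix(runif(1, spec$background_intensity[1],
                        spec$background_intensity[2]), size, size)
    mask <- matrix(0L, size, size)
    th <- 2 * pi * (seq_len(n) - 1) / n +
      runif(n, -0.12, 0.12) * 2 * pi / n
    for (k in seq_len(n)) {
      ox <- cx + rx * cos(th[k])
      oy <- cy + ry * sin(th[k])
      phi <- atan2(ry * cos(th[k]), -rx * sin(th[k]))  # ring tangent
      dx <- X - ox
      dy <- Y - oy
      u <- dx * cos(phi) + dy * sin(phi)
      v <- -dx * sin(phi) + dy * cos(phi)
      rib <- (u / a)^2 + (v / b)^2 <= 1
      img[rib] <- runif(1, spec$rib_intensity[1], spec$rib_intensity[2])
      if (runif(1) < spec$fracture_probability) {
        psi <- phi + pi / 2 + runif(1, -0.3, 0.3)  # crack across long axis
        dist <- abs(dx * sin(psi) - dy * cos(psi))
        crack <- rib & dist <= spec$crack_width / 2
        img[crack] <- runif(1, spec$crack_intensity[1],
                            spec$crack_intensity[2])
        mask[crack] <- 1L
      }
    }
    img <- img + rnorm(size * size, 0, spec$noise_sigma)
    img <- pmin(pmax(img, 0), 1)
    dim(img) <- c(size, size)
    slice_sample(img, mask,
                 volume_id = sprintf("phantom_seed%d", spec$seed),
                 slice_index = 0L)
  })
}

#' Generate a phantom corpus
#'
#' Per-sample seeds are derived from `seed` by counter, so any sample can
#' be regenerated in isolation. Slices are grouped ten-per-volume so that
#' by-volume train/validation splitting is meaningful.
#'
#' @param n Number of slices.
#' @param spec Base [phantom_spec()] (its `seed` field is overridden).
#' @param seed Master seed.
#' @return `list(samples, manifest)`: the [slice_sample()] list and a data
#'   frame with `volume_id`, `slice_index`, `n_lesion_pixels`.
#' @export
generate_phantom_dataset <- function(n, spec = phantom_spec(), seed = 1L) {
  stopifnot(n >= 0)
  samples <- vector("list", n)
  for (i in seq_len(n)) {
    si <- spec
    si$seed <- as.integer(seed + i)
    s <- generate_phantom(si)
    s$volume_id <- sprintf("vol%04d", 1L + (i - 1L) %/% 10L)
    s$slice_index <- (i - 1L) %% 10L
    samples[[i]] <- s
  }
  manifest <- data.frame(
    volume_id = vapply(samples, `[[`, "", "volume_id"),
    slice_index = vapply(samples, `[[`, 0L, "slice_index"),
    n_lesion_pixels = vapply(samples, function(s) sum(s$mask), 0L)
  )
  list(samples = samples, manifest = manifest)
}
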