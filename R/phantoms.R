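# Synthetic phantom generator realizing the image formation model
# I(x) = b(x) J(x) + n(x): a two-level true image J from a known shape,
# a multiplicative bias field b, and additive or impulsive noise n, with
# the ground-truth mask and bias recorded for closed-loop evaluation.

# Run expr with a temporary RNG seed, restoring the caller's RNG state.
local_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(),
                      inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}

#' Phantom specification
#'
#' Describes one synthetic test image. Default levels (`fg_level = 0.65`,
#' `bg_level = 0.25`) keep `b(x) * J(x)` inside `[0, 1]` for bias amplitudes
#' up to 0.5, so clipping never flattens the inhomogeneity being studied.
#'
#' @param shape One of `"disk"`, `"two_disks"`, `"fingers_like"`,
#'   `"square"`.
#' @param height,width Grid size in pixels (each at least 8).
#' @param fg_level,bg_level Foreground/background intensities in `[0, 1]`;
#'   must differ.
#' @param bias Bias type: `"none"`, `"linear_ramp"` (columnwise ramp from
#'   `1 - a` to `1 + a`) or `"gaussian_blob"` (`1 + a * G`, peak-normalized
#'   Gaussian at a seed-determined center).
#' @param bias_amplitude Non-negative amplitude `a`; `< 1` for the ramp.
#' @param noise Noise type: `"none"`, `"gaussian"` (zero-mean, variance
#'   `noise_level`, then clipped) or `"salt_pepper"` (a `noise_level`
#'   fraction of pixels set to 0 or 1 equiprobably).
#' @param noise_level Non-negative noise level.
#' @param rng_seed Integer seed making the phantom fully reproducible.
#' @param center Optional `(row, col)` disk/square center override.
#' @param radius Optional disk radius override, pixels.
#' @return A list of class `"phantom_spec"`.
#' @export
phantom_spec <- function(shape = c("disk", "two_disks", "fingers_like",
                                   "square"),
                         height = 128L, width = 128L,
                         fg_level = 0.65, bg_level = 0.25,
                         bias = c("none", "linear_ramp", "gaussian_blob"),
                         bias_amplitude = 0,
                         noise = c("none", "gaussian", "salt_pepper"),
                         noise_level = 0,
                         rng_seed = 1L,
                         center = NULL, radius = NULL) {
  shape <- match.arg(shape)
  bias <- match.arg(bias)
  noise <- match.arg(noise)
  if (height < 8 || width < 8) {
    stop("spec error: grid must be at least 8x8", call. = FALSE)
  }
  if (fg_level == bg_level) {
    stop("spec error: fg_level and bg_level must differ", call. = FALSE)
  }
  if (bias_amplitude < 0) {
    stop("spec error: bias amplitude must be non-negative", call. = FALSE)
  }
  if (noise_level < 0) {
    stop("spec error: noise level must be non-negative", call. = FALSE)
  }
  structure(list(shape = shape, height = as.integer(height),
                 width = as.integer(width),
                 fg_level = fg_level, bg_level = bg_level,
                 bias = bias, bias_amplitude = bias_amplitude,
                 noise = noise, noise_level = noise_level,
                 rng_seed = as.integer(rng_seed),
                 center = center, radius = radius),
            class = "phantom_spec")
}

#' True (bias-free) image and its mask
#'
#' Rasterizes the spec's shape into a two-level image: `fg_level` on the
#' shape, `bg_level` elsewhere.
#'
#' @param spec A [phantom_spec()].
#' @return List with matrix `J` and logical `truth_mask`.
#' @export
make_true_image <- function(spec) {
  h <- spec$height
  w <- spec$width
  rr <- row(matrix(0, h, w))
  cc <- col(matrix(0, h, w))
  disk_at <- function(cr, cl, rad) (rr - cr)^2 + (cc - cl)^2 <= rad^2
  mask <- switch(spec$shape,
    disk = {
      ctr <- if (is.null(spec$center)) c((h + 1) / 2, (w + 1) / 2)
             else spec$center
      rad <- if (is.null(spec$radius)) 0.25 * min(h, w) else spec$radius
      if (rad < 1) stop("spec error: zero-area disk", call. = FALSE)
      disk_at(ctr[1], ctr[2], rad)
    },
    two_disks = {
      rad <- if (is.null(spec$radius)) 0.15 * min(h, w) else spec$radius
      if (rad < 1) stop("spec error: zero-area disk", call. = FALSE)
      disk_at((h + 1) / 2, (w + 1) / 4, rad) |
        disk_at((h + 1) / 2, 3 * (w + 1) / 4, rad)
    },
    square = {
      side <- round(0.5 * min(h, w))
      if (side < 1) stop("spec error: zero-area square", call. = FALSE)
      r0 <- round((h - side) / 2)
      c0 <- round((w - side) / 2)
      rr > r0 & rr <= r0 + side & cc > c0 & cc <= c0 + side
    },
    fingers_like = {
      # four parallel rounded bars separated by 2-px gaps: each bar is the
      # set of pixels within half a bar-width of a vertical segment
      bw <- max(3, round(w / 10))
      gap <- 2L
      total <- 4L * bw + 3L * gap
      c0 <- (w - total) / 2 + bw / 2
      r1 <- 0.22 * h
      r2 <- 0.78 * h
      m <- matrix(FALSE, h, w)
      for (k in 0:3) {
        ck <- c0 + k * (bw + gap)
        rclamp <- pmin(pmax(rr, r1), r2)
        m <- m | ((rr - rclamp)^2 + (cc - ck)^2 <= (bw / 2)^2)
      }
      m
    })
  if (!any(mask) || all(mask)) {
    stop("spec error: degenerate shape geometry", call. = FALSE)
  }
  J <- matrix(spec$bg_level, h, w)
  J[mask] <- spec$fg_level
  list(J = J, truth_mask = mask)
}

#' Ground-truth bias field
#'
#' `"none"` gives a unit field; `"linear_ramp"` runs linearly from
#' `1 - a` on the first column to `1 + a` on the last (requires `a < 1`
#' for positivity); `"gaussian_blob"` is `1 + a * G` with a peak-normalized
#' Gaussian whose center is drawn reproducibly from `rng_seed`.
#'
#' @param spec A [phantom_spec()].
#' @return Strictly positive matrix.
#' @export
make_bias <- function(spec) {
  h <- spec$height
  w <- spec$width
  a <- spec$bias_amplitude
  switch(spec$bias,
    none = matrix(1, h, w),
    linear_ramp = {
      if (a >= 1) {
        stop("spec error: ramp amplitude must be < 1 for positivity",
             call. = FALSE)
      }
      matrix(rep(seq(1 - a, 1 + a, length.out = w), each = h), h, w)
    },
    gaussian_blob = {
      ctr <- local_seed(spec$rng_seed, {
        c(stats::runif(1, 0.25 * h, 0.75 * h),
          stats::runif(1, 0.25 * w, 0.75 * w))
      })
      s <- 0.35 * min(h, w)
      rr <- row(matrix(0, h, w))
      cc <- col(matrix(0, h, w))
      g <- exp(-((rr - ctr[1])^2 + (cc - ctr[2])^2) / (2 * s^2))
      1 + a * g / max(g)
    })
}

#' Add noise to an image
#'
#' `"gaussian"` adds zero-mean noise of variance `level` and clips to
#' `[0, 1]`; `"salt_pepper"` replaces each pixel independently with
#' probability `level` by 0 or 1 (equiprobably). Deterministic in
#' `rng_seed`; the caller's RNG state is untouched.
#'
#' @param image Numeric matrix.
#' @param noise `"none"`, `"gaussian"` or `"salt_pepper"`.
#' @param level Non-negative noise level.
#' @param rng_seed Integer seed.
#' @return Matrix like `image`.
#' @export
add_noise <- function(image, noise = "none", level = 0, rng_seed = 1L) {
  if (level < 0) stop("spec error: negative noise level", call. = FALSE)
  if (noise == "none" || level == 0) return(image)
  n <- length(image)
  switch(noise,
    gaussian = local_seed(rng_seed, {
      out <- image + matrix(stats::rnorm(n, 0, sqrt(level)),
                            nrow(image), ncol(image))
      pmin(pmax(out, 0), 1)
    }),
    salt_pepper = local_seed(rng_seed, {
      hit <- stats::runif(n) < level
      vals <- sample(c(0, 1), sum(hit), replace = TRUE)
      out <- image
      out[hit] <- vals
      out
    }),
    stop(sprintf("spec error: unknown noise type '%s'", noise),
         call. = FALSE))
}

#' Randomized disk phantom specification
#'
#' Draws a disk phantom with random center, radius and contrast polarity,
#' reproducibly from `rng_seed`, for seeding- and segmentation-robustness
#' studies over many geometries. The disk always lies fully inside the
#' grid with a 5-pixel margin.
#'
#' @param rng_seed Integer seed determining geometry and polarity.
#' @param height,width Grid size in pixels.
#' @return A [phantom_spec()].
#' @export
random_disk_spec <- function(rng_seed, height = 128L, width = 128L) {
  local_seed(rng_seed, {
    rad <- stats::runif(1, 12, 0.3 * min(height, width))
    ctr <- c(stats::runif(1, rad + 5, height - rad - 5),
             stats::runif(1, rad + 5, width - rad - 5))
    flip <- stats::runif(1) < 0.5
    phantom_spec(shape = "disk", height = height, width = width,
                 fg_level = if (flip) 0.25 else 0.65,
                 bg_level = if (flip) 0.65 else 0.25,
                 rng_seed = rng_seed, center = ctr, radius = rad)
  })
}

#' Generate a phantom
#'
#' Composes the formation model `I = clip(b * J + n, 0, 1)` and records the
#' ground truth. Bit-identical output for identical specs.
#'
#' @param spec A [phantom_spec()].
#' @return List of class `"phantom"` with `image`, `truth_mask`,
#'   `truth_bias` and `spec`.
#' @export
generate_phantom <- function(spec) {
  tj <- make_true_image(spec)
  b <- make_bias(spec)
  img <- add_noise(b * tj$J, spec$noise, spec$noise_level, spec$rng_seed)
  img <- pmin(pmax(img, 0), 1)
  structure(list(image = img, truth_mask = tj$truth_mask,
                 truth_bias = b, spec = spec),
            class = "phantom")
}
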