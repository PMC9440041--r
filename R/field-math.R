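# Numerical substrate: regularized step/impulse functions, small-kernel
# convolution with replicate padding, finite-difference stencils.
# All fields are plain numeric matrices over one pixel grid (unit spacing,
# 0-based conceptual origin at top-left, row-major).

check_positive_scalar <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x <= 0) {
    stop(sprintf("`%s` must be a single positive finite number", name),
         call. = FALSE)
  }
  invisible(x)
}

check_field <- function(x, name = deparse(substitute(x))) {
  if (!is.matrix(x) || !is.numeric(x)) {
    stop(sprintf("`%s` must be a numeric matrix", name), call. = FALSE)
  }
  invisible(x)
}

#' Regularized Heaviside step
#'
#' Smooth approximation of the unit step used to turn the sign of a level-set
#' field into differentiable region indicators:
#' \deqn{H_\epsilon(\phi) = \frac{1}{2}\left(1 +
#'   \frac{2}{\pi}\arctan(\phi/\epsilon)\right).}
#' `epsilon` controls the width of the transition zone around the zero level
#' set; the output is strictly within (0, 1) and satisfies
#' `heaviside(-phi) == 1 - heaviside(phi)` exactly.
#'
#' @param phi Numeric vector or matrix (a level-set field).
#' @param epsilon Positive transition width, in the units of `phi`.
#' @return Object shaped like `phi` with values in (0, 1).
#' @seealso [dirac()] for the matching impulse (its derivative in `phi`).
#' @export
#' @examples
#' heaviside(0)            # 0.5
#' heaviside(1, epsilon = 1)  # 0.75
heaviside <- function(phi, epsilon = 1) {
  check_positive_scalar(epsilon, "epsilon")
  0.5 * (1 + (2 / pi) * atan(phi / epsilon))
}

#' Regularized Dirac impulse
#'
#' Derivative of [heaviside()] with respect to `phi`:
#' \deqn{\delta_\epsilon(\phi) = \frac{\epsilon}{\pi(\phi^2 + \epsilon^2)},}
#' a Cauchy kernel of unit integral, peaking at \eqn{1/(\pi\epsilon)} on the
#' zero level set. It localizes every contour force to a band around the
#' evolving front.
#'
#' @inheritParams heaviside
#' @return Strictly positive object shaped like `phi`, bounded by
#'   `1 / (pi * epsilon)`.
#' @export
dirac <- function(phi, epsilon = 1) {
  check_positive_scalar(epsilon, "epsilon")
  epsilon / (pi * (phi^2 + epsilon^2))
}

#' Truncated Gaussian kernel
#'
#' Isotropic Gaussian weights on a `(2*radius+1)` square support, renormalized
#' to unit sum. This is the localization kernel \eqn{K_\sigma} of the local
#' fitting model; `radius` should be at least `ceiling(2 * sigma)` so the
#' truncation error is negligible.
#'
#' @param sigma Positive kernel scale in pixels.
#' @param radius Positive integer truncation radius in pixels.
#' @return A `(2*radius+1) x (2*radius+1)` non-negative matrix summing to 1.
#' @export
gaussian_kernel <- function(sigma, radius = ceiling(2 * sigma)) {
  check_positive_scalar(sigma, "sigma")
  if (length(radius) != 1L || !is.finite(radius) || radius < 1) {
    stop("`radius` must be a positive integer", call. = FALSE)
  }
  radius <- as.integer(radius)
  d <- seq.int(-radius, radius)
  k1 <- exp(-d^2 / (2 * sigma^2))
  k <- outer(k1, k1)
  k / sum(k)
}

# Shift a matrix by (dr, dc) with replicate (clamped-index) padding.
shift_rep <- function(x, dr, dc) {
  ri <- pmin.int(pmax.int(seq_len(nrow(x)) + dr, 1L), nrow(x))
  ci <- pmin.int(pmax.int(seq_len(ncol(x)) + dc, 1L), ncol(x))
  x[ri, ci, drop = FALSE]
}

#' 2-D convolution with replicate boundary padding
#'
#' Correlates `x` with an odd-sized kernel, extending the field beyond the
#' grid by edge replication. For the symmetric kernels used throughout the
#' package correlation and convolution coincide.
#'
#' @param x Numeric matrix.
#' @param kernel Odd-dimensioned numeric matrix of weights.
#' @return Matrix of the same dimension as `x`.
#' @export
conv2_rep <- function(x, kernel) {
  check_field(x, "x")
  check_field(kernel, "kernel")
  if (nrow(kernel) %% 2 == 0 || ncol(kernel) %% 2 == 0) {
    stop("`kernel` must have odd dimensions", call. = FALSE)
  }
  rr <- (nrow(kernel) - 1L) %/% 2L
  rc <- (ncol(kernel) - 1L) %/% 2L
  out <- matrix(0, nrow(x), ncol(x))
  for (i in seq.int(-rr, rr)) {
    for (j in seq.int(-rc, rc)) {
      w <- kernel[i + rr + 1L, j + rc + 1L]
      if (w != 0) out <- out + w * shift_rep(x, i, j)
    }
  }
  out
}

#' Gaussian smoothing of a field
#'
#' Separable truncated-Gaussian filter with replicate padding; identical to
#' `conv2_rep(x, gaussian_kernel(sigma, radius))` but linear in the kernel
#' radius. `sigma = 0` returns `x` unchanged.
#'
#' @param x Numeric matrix.
#' @param sigma Non-negative Gaussian scale in pixels.
#' @param radius Truncation radius; defaults to `ceiling(2 * sigma)`.
#' @return Smoothed matrix, same dimension as `x`.
#' @export
gauss_smooth <- function(x, sigma, radius = ceiling(2 * sigma)) {
  check_field(x, "x")
  if (sigma == 0) return(x)
  check_positive_scalar(sigma, "sigma")
  radius <- max(1L, as.integer(radius))
  d <- seq.int(-radius, radius)
  k <- exp(-d^2 / (2 * sigma^2))
  k <- k / sum(k)
  out <- matrix(0, nrow(x), ncol(x))
  for (i in seq_along(d)) out <- out + k[i] * shift_rep(x, d[i], 0L)
  res <- matrix(0, nrow(x), ncol(x))
  for (i in seq_along(d)) res <- res + k[i] * shift_rep(out, 0L, d[i])
  res
}

#' Finite-difference gradient
#'
#' Central differences in the interior, one-sided differences on the first
#' and last row/column. Unit grid spacing.
#'
#' @param f Numeric matrix.
#' @return List with components `dr` (derivative along rows) and `dc`
#'   (derivative along columns), each a matrix like `f`.
#' @export
gradient2 <- function(f) {
  check_field(f, "f")
  nr <- nrow(f)
  nc <- ncol(f)
  if (nr < 2L || nc < 2L) stop("field must be at least 2x2", call. = FALSE)
  dr <- matrix(0, nr, nc)
  dc <- matrix(0, nr, nc)
  if (nr > 2L) dr[2:(nr - 1L), ] <- (f[3:nr, ] - f[1:(nr - 2L), ]) / 2
  dr[1L, ] <- f[2L, ] - f[1L, ]
  dr[nr, ] <- f[nr, ] - f[nr - 1L, ]
  if (nc > 2L) dc[, 2:(nc - 1L)] <- (f[, 3:nc] - f[, 1:(nc - 2L)]) / 2
  dc[, 1L] <- f[, 2L] - f[, 1L]
  dc[, nc] <- f[, nc] - f[, nc - 1L]
  list(dr = dr, dc = dc)
}

#' Finite-difference divergence
#'
#' Divergence of a vector field given by its row and column components,
#' using the same stencils as [gradient2()].
#'
#' @param fr,fc Row and column components (matrices of equal dimension).
#' @return Matrix of the same dimension.
#' @export
divergence2 <- function(fr, fc) {
  gradient2(fr)$dr + gradient2(fc)$dc
}

#' Weighted curvature term
#'
#' Computes \eqn{\mathrm{div}\!\left(w\,\nabla\phi / (|\nabla\phi| +
#' \eta)\right)}, the weighted mean-curvature flow term of the contour length
#' energy. `eta` keeps the normalization defined where the gradient vanishes.
#'
#' @param phi Level-set field (matrix).
#' @param weight Scalar or matrix weight (e.g. the SPF field).
#' @param eta Small positive regularizer added to the gradient magnitude.
#' @return Matrix of the same dimension as `phi`.
#' @export
curvature_divergence <- function(phi, weight = 1, eta = 1e-8) {
  check_positive_scalar(eta, "eta")
  g <- gradient2(phi)
  mag <- sqrt(g$dr^2 + g$dc^2) + eta
  divergence2(weight * g$dr / mag, weight * g$dc / mag)
}

# TRUE where a foreground pixel has a 4-neighbour of the opposite label.
# With border_is_boundary, off-grid pixels count as background, so every
# foreground pixel on the image border is boundary (used by the metrics);
# without it only in-grid adjacency counts (used by level-set seeding).
mask_boundary <- function(mask, border_is_boundary = TRUE) {
  m <- mask != 0
  nr <- nrow(m)
  nc <- ncol(m)
  bg <- !m
  nb <- matrix(FALSE, nr, nc)
  nb[1:(nr - 1L), ] <- nb[1:(nr - 1L), ] | bg[2:nr, ]
  nb[2:nr, ] <- nb[2:nr, ] | bg[1:(nr - 1L), ]
  nb[, 1:(nc - 1L)] <- nb[, 1:(nc - 1L)] | bg[, 2:nc]
  nb[, 2:nc] <- nb[, 2:nc] | bg[, 1:(nc - 1L)]
  if (border_is_boundary) {
    nb[1L, ] <- TRUE
    nb[nr, ] <- TRUE
    nb[, 1L] <- TRUE
    nb[, nc] <- TRUE
  }
  m & nb
}
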