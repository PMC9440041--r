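# Self-initialization: a gradient vector field is scanned with a
# circular-projection (CP) operator that scores how strongly the vectors in
# a window converge toward (or diverge from) its center; strong responses
# mark object interiors and become the seed region for initialize_phi.

#' Circular-projection parameters
#'
#' @param window_z Odd window size `z >= 3`, pixels.
#' @param n_theta Number of projection directions sampled uniformly on
#'   `[0, pi)`; at least 4.
#' @param presmooth_sigma Gaussian presmoothing of the image before the
#'   gradient is taken (0 disables).
#' @param top_fraction Fraction in (0, 1] of the strongest responses kept
#'   as seed candidates.
#' @return A list of class `"cp_params"`.
#' @export
cp_params <- function(window_z = 9L, n_theta = 16L, presmooth_sigma = 2,
                      top_fraction = 0.02) {
  if (window_z < 3 || window_z %% 2 == 0) {
    stop("`window_z` must be an odd integer >= 3", call. = FALSE)
  }
  if (n_theta < 4) stop("`n_theta` must be at least 4", call. = FALSE)
  if (presmooth_sigma < 0) {
    stop("`presmooth_sigma` must be non-negative", call. = FALSE)
  }
  if (top_fraction <= 0 || top_fraction > 1) {
    stop("`top_fraction` must lie in (0, 1]", call. = FALSE)
  }
  structure(list(window_z = as.integer(window_z),
                 n_theta = as.integer(n_theta),
                 presmooth_sigma = presmooth_sigma,
                 top_fraction = top_fraction),
            class = "cp_params")
}

#' Image gradient vector field for seeding
#'
#' The discrete vector field consumed by the circular-projection operator:
#' the gradient of the Gaussian-presmoothed image. Gradient vectors point
#' toward brighter intensities, so they converge onto bright objects and
#' diverge from dark ones.
#'
#' @param image Intensity matrix.
#' @param presmooth_sigma Non-negative Gaussian width in pixels.
#' @return List with matrices `u` (row component) and `v` (column
#'   component).
#' @export
image_vector_field <- function(image, presmooth_sigma = 2) {
  check_field(image, "image")
  sm <- if (presmooth_sigma > 0) {
    gauss_smooth(image, presmooth_sigma)
  } else {
    image
  }
  g <- gradient2(sm)
  list(u = g$dr, v = g$dc)
}

#' Circular projection at one pixel
#'
#' For each sampled direction \eqn{v_R(\theta) = (\cos\theta, \sin\theta)},
#' accumulates the squared scalar projections of the vector field over the
#' window centered at `at`, split by the projection sign: positive
#' projections feed `plus`, negative ones `minus`. The window is clipped at
#' the grid border. Negating the field swaps the two totals.
#'
#' @param field A vector field from [image_vector_field()].
#' @param at Length-2 integer vector `(row, col)`.
#' @param params A [cp_params()] object.
#' @return Named numeric vector `c(plus = P+, minus = P-)`.
#' @export
circular_projection <- function(field, at, params = cp_params()) {
  z2 <- (params$window_z - 1L) %/% 2L
  nr <- nrow(field$u)
  nc <- ncol(field$u)
  rows <- max(1L, at[1] - z2):min(nr, at[1] + z2)
  cols <- max(1L, at[2] - z2):min(nc, at[2] + z2)
  u <- field$u[rows, cols]
  v <- field$v[rows, cols]
  plus <- 0
  minus <- 0
  for (k in seq_len(params$n_theta)) {
    th <- (k - 1) * pi / params$n_theta
    s <- u * cos(th) + v * sin(th)
    plus <- plus + sum(s[s > 0]^2)
    minus <- minus + sum(s[s < 0]^2)
  }
  c(plus = plus, minus = minus)
}

# Converging/diverging response maps over the whole grid. For every window
# offset d != 0 the field at x + d is projected onto the outward unit offset
# d-hat; a negative projection means the vector points back toward x
# (converging), a positive one away (diverging). Squared projections are
# accumulated per pixel; a margin of the window radius is zeroed.
cp_response_maps <- function(field, params = cp_params()) {
  z2 <- (params$window_z - 1L) %/% 2L
  nr <- nrow(field$u)
  nc <- ncol(field$u)
  conv <- matrix(0, nr, nc)
  divg <- matrix(0, nr, nc)
  for (i in seq.int(-z2, z2)) {
    for (j in seq.int(-z2, z2)) {
      if (i == 0L && j == 0L) next
      n <- sqrt(i^2 + j^2)
      s <- shift_rep(field$u, i, j) * (i / n) +
           shift_rep(field$v, i, j) * (j / n)
      conv <- conv + pmin(s, 0)^2
      divg <- divg + pmax(s, 0)^2
    }
  }
  margin <- z2
  zero_border <- function(m) {
    m[seq_len(margin), ] <- 0
    m[nr - seq_len(margin) + 1L, ] <- 0
    m[, seq_len(margin)] <- 0
    m[, nc - seq_len(margin) + 1L] <- 0
    m
  }
  list(converging = zero_border(conv), diverging = zero_border(divg))
}

#' Automatic seed selection by circular projection
#'
#' Computes the converging and diverging response maps of the image's
#' gradient field, keeps whichever polarity responds more strongly (bright
#' objects attract the gradient field, dark objects repel it, so the
#' stronger map sits inside the object either way), thresholds it at the
#' `top_fraction` quantile, and returns the connected-component centroids
#' of the surviving pixels as seed points together with their disc-dilated
#' union as the seed region. Fully deterministic.
#'
#' @param image Non-constant intensity matrix.
#' @param params A [cp_params()] object.
#' @return List with `points` (n x 2 integer matrix of row/col
#'   coordinates) and `region` (logical matrix).
#' @export
select_seeds <- function(image, params = cp_params()) {
  check_field(image, "image")
  if (diff(range(image)) < 1e-12) {
    stop("seeding error: constant image - supply a manual seed region",
         call. = FALSE)
  }
  field <- image_vector_field(image, params$presmooth_sigma)
  maps <- cp_response_maps(field, params)
  ntop <- max(1L, ceiling(params$top_fraction * length(image)))
  top_strength <- function(m) {
    sum(sort(m[m > 0], decreasing = TRUE)[seq_len(min(ntop, sum(m > 0)))],
        na.rm = TRUE)
  }
  chosen <- if (top_strength(maps$converging) >=
                top_strength(maps$diverging)) {
    maps$converging
  } else {
    maps$diverging
  }
  pos <- chosen[chosen > 0]
  if (length(pos) == 0) {
    stop("seeding error: no circular-projection response - supply a manual seed",
         call. = FALSE)
  }
  thr <- stats::quantile(pos, probs = max(0, 1 - ntop / length(pos)),
                         names = FALSE, type = 1)
  cand <- chosen >= thr & chosen > 0
  labels <- EBImage::bwlabel(cand)
  nlab <- max(labels)
  pts <- matrix(0L, nlab, 2L, dimnames = list(NULL, c("row", "col")))
  for (k in seq_len(nlab)) {
    idx <- which(labels == k, arr.ind = TRUE)
    pts[k, ] <- as.integer(round(colMeans(idx)))
  }
  pts <- unique(pts)
  region <- matrix(0, nrow(image), ncol(image))
  region[pts] <- 1
  brush <- EBImage::makeBrush(2L * params$window_z + 1L, shape = "disc")
  region <- EBImage::dilate(region, brush) > 0
  list(points = pts, region = region)
}
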