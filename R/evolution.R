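# Level-set machinery: binary initialization, the gradient-descent update,
# Gaussian regularization of phi, convergence detection and the top-level
# segmentation driver.
#
# Orientation convention, fixed package-wide: inside <=> phi > 0, so
# H(phi) indicates the inside region and c1/m1 are inside means. The area
# (balloon) term enters with +nu * spf * dirac under this convention, the
# corrective direction: it expands the contour where the image lies above
# the global fit and contracts it where below.

#' Evolution parameters
#'
#' Bundles every tunable of the contour evolution with validated defaults.
#' Forces are self-normalizing: the data-fitting terms are divided by the
#' squared intensity range of the image (so their strength is independent
#' of image contrast and commensurate with the already-normalized SPF
#' terms), and the total force field is rescaled to unit maximum before the
#' step is taken. `dt` is therefore the largest per-iteration change of phi
#' anywhere on the grid, and the defaults transfer across inputs without
#' manual tuning.
#'
#' @param mu Non-negative length-term weight (curvature regularization).
#' @param nu Area-term (balloon) weight.
#' @param dt Positive time step of the gradient descent.
#' @param p Positive height of the binary level-set initialization.
#' @param epsilon Heaviside/Dirac width.
#' @param sigma Gaussian kernel scale of the local fitting model, pixels.
#' @param kernel_radius Kernel truncation radius, `>= ceiling(2*sigma)`.
#' @param phi_smooth_sigma Gaussian width applied to phi after each
#'   iteration (0 disables); replaces distance reinitialization.
#' @param hardening Per-iteration multiplicative growth factor of phi
#'   (`>= 1`). Plateaus deepen geometrically, so early iterations behave
#'   quasi-globally (distant mislabeled regions can flip, making the result
#'   independent of the seed position and contrast polarity) while later
#'   iterations are confined to the contour band, which freezes decided
#'   regions and prevents isolated noise pixels from nucleating spurious
#'   components. 1 disables the anneal.
#' @param max_iter Maximum number of iterations.
#' @param tol Convergence threshold on the mask-change fraction.
#' @param window Number of consecutive below-`tol` iterations required.
#' @param spf_mode `"plain"` (default) or `"membership"` (ablation variant).
#' @return A list of class `"evolution_params"`.
#' @export
evolution_params <- function(mu = 1, nu = 1, dt = 1, p = 1,
                             epsilon = 1, sigma = 40,
                             kernel_radius = ceiling(2 * sigma),
                             phi_smooth_sigma = 0.5, hardening = 1.03,
                             max_iter = 300L, tol = 1e-4, window = 3L,
                             spf_mode = c("plain", "membership")) {
  spf_mode <- match.arg(spf_mode)
  if (hardening < 1) stop("`hardening` must be at least 1", call. = FALSE)
  check_positive_scalar(dt, "dt")
  check_positive_scalar(p, "p")
  check_positive_scalar(epsilon, "epsilon")
  check_positive_scalar(sigma, "sigma")
  check_positive_scalar(tol, "tol")
  if (mu < 0) stop("`mu` must be non-negative", call. = FALSE)
  if (phi_smooth_sigma < 0) {
    stop("`phi_smooth_sigma` must be non-negative", call. = FALSE)
  }
  if (max_iter < 1) stop("`max_iter` must be at least 1", call. = FALSE)
  if (window < 1) stop("`window` must be at least 1", call. = FALSE)
  if (kernel_radius < ceiling(2 * sigma)) {
    stop("`kernel_radius` must be at least ceiling(2*sigma)", call. = FALSE)
  }
  structure(list(mu = mu, nu = nu, dt = dt, p = p, epsilon = epsilon,
                 sigma = sigma, kernel_radius = as.integer(kernel_radius),
                 phi_smooth_sigma = phi_smooth_sigma,
                 hardening = hardening,
                 max_iter = as.integer(max_iter), tol = tol,
                 window = as.integer(window), spf_mode = spf_mode),
            class = "evolution_params")
}

#' Binary level-set initialization
#'
#' Builds the initial field from a seed region: `+p` strictly inside the
#' seed, `0` on the seed's inner boundary (seed pixels 4-adjacent, within
#' the grid, to a non-seed pixel), `-p` outside. The inside-positive sign
#' follows the package-wide orientation convention.
#'
#' @param seed_region Logical (or 0/1) matrix; must be neither empty nor
#'   the full grid.
#' @param p Positive plateau height.
#' @return A level-set matrix with values in `{-p, 0, +p}`.
#' @export
initialize_phi <- function(seed_region, p = 1) {
  check_positive_scalar(p, "p")
  seed <- seed_region != 0
  if (!any(seed)) stop("seeding error: seed region is empty", call. = FALSE)
  if (all(seed)) {
    stop("seeding error: seed region covers the full grid", call. = FALSE)
  }
  boundary <- mask_boundary(seed, border_is_boundary = FALSE)
  phi <- matrix(-p, nrow(seed), ncol(seed))
  phi[seed] <- p
  phi[boundary] <- 0
  phi
}

#' Convergence test on the mask-change history
#'
#' TRUE iff the fraction of pixels whose binary label changed stayed below
#' `tol` for the last `window` consecutive iterations.
#'
#' @param history Numeric vector of per-iteration mask-change fractions.
#' @param tol Positive threshold.
#' @param window Required number of consecutive quiet iterations.
#' @return Logical scalar.
#' @export
has_converged <- function(history, tol = 1e-4, window = 3L) {
  if (window < 1) stop("`window` must be at least 1", call. = FALSE)
  if (length(history) < window) return(FALSE)
  all(utils::tail(history, window) < tol)
}

# Fresh evolution state for an initial phi. Local means start as the global
# means with a unit bias field (the local model's first bootstrap).
init_state <- function(image, phi, params) {
  gm <- global_means(image, phi, params$epsilon)
  list(phi = phi,
       bias = matrix(1, nrow(image), ncol(image)),
       means_g = gm,
       means_l = list(m1 = gm$c1, m2 = gm$c2),
       iteration = 0L,
       history = numeric(0),
       converged = FALSE)
}

#' One gradient-descent step of the contour evolution
#'
#' Recomputes, in order, the global means, the bias field (using the
#' previous iteration's local means), the local means, the fitted images
#' and the SPF, then updates
#' \deqn{\phi \leftarrow \phi + dt\,\big[\delta_\epsilon(\phi)(I - I_{bLFI})
#'   (c_1 - c_2) + \delta_\epsilon(\phi)(I - I_{GFI})(m_1 - m_2) +
#'   \mu\,\mathrm{div}(\mathrm{spf}\,\nabla\phi/|\nabla\phi|)\,
#'   \delta_\epsilon(\phi) + \nu\,\mathrm{spf}\,\delta_\epsilon(\phi)\big]}
#' The two data terms are divided by the squared intensity range of the
#' image and the bracketed force field is normalized to unit maximum
#' magnitude (zero if degenerate), so `dt` bounds the per-iteration force
#' contribution anywhere on the grid. After the step `phi` is multiplied
#' by the `hardening` factor (annealed plateau growth) and smoothed with a
#' Gaussian of width `phi_smooth_sigma`.
#'
#' @param image Intensity matrix in `[0, 1]`.
#' @param state Evolution state as produced by [segment_image()] internals
#'   or a previous `evolve_step()` call.
#' @param params An [evolution_params()] object.
#' @return The updated state (fields `phi`, `bias`, `means_g`, `means_l`,
#'   `iteration`, `history`, `converged`).
#' @export
evolve_step <- function(image, state, params = evolution_params()) {
  eps <- params$epsilon
  phi <- state$phi
  mem <- membership_pair(phi, eps)
  gm <- global_means(image, phi, eps)
  b <- bias_field(image, mem, state$means_l, params$sigma,
                  params$kernel_radius)
  lm <- local_means(image, b, mem, params$sigma, params$kernel_radius)
  fit <- fitted_images(gm, lm, b, mem)
  s <- if (params$spf_mode == "membership") {
    spf_with_membership(image, gm, mem)
  } else {
    spf(image, fit$gfi)
  }
  d <- dirac(phi, eps)
  scale2 <- max(diff(range(image))^2, 1e-12)
  force <- d * ((image - fit$blfi) * (gm$c1 - gm$c2) +
                (image - fit$gfi) * (lm$m1 - lm$m2)) / scale2 +
    params$mu * curvature_divergence(phi, s) * d +
    params$nu * s * d
  fmax <- max(abs(force))
  force <- if (fmax > 1e-12) force / fmax else matrix(0, nrow(force),
                                                      ncol(force))
  phi_new <- params$hardening * (phi + params$dt * force)
  if (params$phi_smooth_sigma > 0) {
    phi_new <- gauss_smooth(phi_new, params$phi_smooth_sigma,
                            max(1L, ceiling(2 * params$phi_smooth_sigma)))
  }
  changed <- mean((phi_new > 0) != (phi > 0))
  history <- c(state$history, changed)
  list(phi = phi_new, bias = b, means_g = gm, means_l = lm,
       iteration = state$iteration + 1L, history = history,
       converged = has_converged(history, params$tol, params$window))
}

#' Segment an image with the self-initialized hybrid active contour
#'
#' Top-level driver: obtains a seed region (automatically via
#' [select_seeds()] when none is supplied), initializes the level-set field,
#' iterates [evolve_step()] until the mask settles or `max_iter` is reached,
#' and orients the final binary mask so that the region whose mean intensity
#' deviates most from the global image mean is labeled foreground. This
#' orientation rule makes the result invariant to contrast polarity.
#'
#' @param image Numeric matrix with finite values in `[0, 1]`.
#' @param params An [evolution_params()] object.
#' @param seed_region Optional logical matrix used as the initial contour
#'   interior; when `NULL` the circular-projection seeder runs.
#' @param cp A [cp_params()] object for automatic seeding.
#' @return Object of class `"spf_segmentation"`: a list with `mask`
#'   (logical), `phi_final`, `bias_final`, `iterations_used`, `converged`,
#'   `history` and the parameters used.
#' @export
segment_image <- function(image, params = evolution_params(),
                          seed_region = NULL, cp = cp_params()) {
  check_field(image, "image")
  if (any(!is.finite(image))) {
    stop("input error: image contains non-finite pixels", call. = FALSE)
  }
  if (min(image) < 0 || max(image) > 1) {
    stop("input error: image must be rescaled to [0, 1]", call. = FALSE)
  }
  if (is.null(seed_region)) {
    seed_region <- select_seeds(image, cp)$region
  }
  phi <- initialize_phi(seed_region, params$p)
  state <- init_state(image, phi, params)
  while (state$iteration < params$max_iter && !state$converged) {
    state <- evolve_step(image, state, params)
  }
  mask <- state$phi > 0
  gmean <- mean(image)
  if (any(mask) && !all(mask)) {
    dev_in <- abs(mean(image[mask]) - gmean)
    dev_out <- abs(mean(image[!mask]) - gmean)
    if (dev_out > dev_in) mask <- !mask
  }
  structure(list(mask = mask,
                 phi_final = state$phi,
                 bias_final = state$bias,
                 iterations_used = state$iteration,
                 converged = state$converged,
                 history = state$history,
                 params = params),
            class = "spf_segmentation")
}

#' @export
print.spf_segmentation <- function(x, ...) {
  cat("spf_segmentation:",
      sprintf("%d x %d", nrow(x$mask), ncol(x$mask)),
      "| foreground", sum(x$mask), "px",
      "| iterations", x$iterations_used,
      "| converged", x$converged, "\n")
  invisible(x)
}
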