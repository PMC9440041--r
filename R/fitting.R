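# Data-fitting quantities of the hybrid energy: global region means,
# bias field, bias-corrected local means, fitted images and the signed
# pressure force.

#' Soft region memberships from a level-set field
#'
#' `M1 = heaviside(phi)` indicates the inside region (phi > 0 under the
#' package-wide convention), `M2 = 1 - M1` the outside; they sum to 1
#' elementwise by construction.
#'
#' @inheritParams heaviside
#' @return List with matrices `M1` and `M2`.
#' @export
membership_pair <- function(phi, epsilon = 1) {
  M1 <- heaviside(phi, epsilon)
  list(M1 = M1, M2 = 1 - M1)
}

#' Global region means
#'
#' Heaviside-weighted average intensities of the inside (`c1`) and outside
#' (`c2`) regions of the contour:
#' \deqn{c_1 = \frac{\sum I\,H_\epsilon(\phi)}{\sum H_\epsilon(\phi)},\quad
#'       c_2 = \frac{\sum I\,(1-H_\epsilon(\phi))}{\sum (1-H_\epsilon(\phi))}.}
#'
#' @param image Intensity matrix.
#' @param phi Level-set field on the same grid.
#' @param epsilon Heaviside width.
#' @return List with scalars `c1` (inside mean) and `c2` (outside mean).
#' @export
global_means <- function(image, phi, epsilon = 1) {
  check_field(image, "image")
  stopifnot(identical(dim(image), dim(phi)))
  H <- heaviside(phi, epsilon)
  w1 <- sum(H)
  w2 <- sum(1 - H)
  if (w1 < 1e-6) stop("degenerate region: inside mass vanishes", call. = FALSE)
  if (w2 < 1e-6) stop("degenerate region: outside mass vanishes", call. = FALSE)
  list(c1 = sum(image * H) / w1, c2 = sum(image * (1 - H)) / w2)
}

#' Multiplicative bias field estimate
#'
#' Pointwise ratio of two Gaussian-smoothed fields,
#' \deqn{b = \frac{K_\sigma * \left(I\,(m_1 M_1 + m_2 M_2)\right)}
#'                {K_\sigma * \left(m_1^2 M_1 + m_2^2 M_2\right)},}
#' the closed-form minimizer of the local clustering energy in the bias
#' variable given the memberships and local means. The result varies on the
#' kernel scale and captures the slowly varying intensity corruption.
#'
#' @param image Intensity matrix.
#' @param membership A [membership_pair()].
#' @param means List with local means `m1`, `m2`.
#' @param sigma,kernel_radius Gaussian kernel scale and truncation radius.
#' @return Matrix of bias values (strictly positive for valid inputs).
#' @export
bias_field <- function(image, membership, means, sigma = 3,
                       kernel_radius = ceiling(2 * sigma)) {
  check_field(image, "image")
  num <- gauss_smooth(image * (means$m1 * membership$M1 +
                               means$m2 * membership$M2),
                      sigma, kernel_radius)
  den <- gauss_smooth(means$m1^2 * membership$M1 +
                      means$m2^2 * membership$M2,
                      sigma, kernel_radius)
  if (any(den <= 0)) {
    stop("degenerate fit: bias-field denominator is not strictly positive",
         call. = FALSE)
  }
  num / den
}

#' Bias-corrected local means
#'
#' Scalar per-region intensities of the true (bias-free) image under the
#' local clustering model:
#' \deqn{m_i = \frac{\sum_x [K_\sigma * (I\,b)](x)\, M_i(x)}
#'                  {\sum_x [K_\sigma * (b^2)](x)\, M_i(x)}.}
#' With a unit bias field these reduce to the plain region means.
#'
#' @param image Intensity matrix.
#' @param bias Bias-field matrix.
#' @param membership A [membership_pair()].
#' @inheritParams bias_field
#' @return List with scalars `m1` (inside) and `m2` (outside).
#' @export
local_means <- function(image, bias, membership, sigma = 3,
                        kernel_radius = ceiling(2 * sigma)) {
  check_field(image, "image")
  KIb <- gauss_smooth(image * bias, sigma, kernel_radius)
  Kb2 <- gauss_smooth(bias^2, sigma, kernel_radius)
  den1 <- sum(Kb2 * membership$M1)
  den2 <- sum(Kb2 * membership$M2)
  if (den1 <= 1e-12 || den2 <= 1e-12) {
    stop("degenerate fit: local-mean denominator vanishes", call. = FALSE)
  }
  list(m1 = sum(KIb * membership$M1) / den1,
       m2 = sum(KIb * membership$M2) / den2)
}

#' Fitted images of the hybrid model
#'
#' The global fitted image `gfi = c1*M1 + c2*M2` (piecewise-constant under
#' crisp memberships) and the bias-corrected local fitted image
#' `blfi = b * (m1*M1 + m2*M2)`, which reproduces the observed intensities of
#' an inhomogeneous object when the bias is estimated correctly.
#'
#' @param means_g Global means from [global_means()].
#' @param means_l Local means from [local_means()].
#' @param bias Bias-field matrix.
#' @param membership A [membership_pair()].
#' @return List with matrices `gfi` and `blfi`.
#' @export
fitted_images <- function(means_g, means_l, bias, membership) {
  list(gfi = means_g$c1 * membership$M1 + means_g$c2 * membership$M2,
       blfi = bias * (means_l$m1 * membership$M1 +
                      means_l$m2 * membership$M2))
}

#' Signed pressure force
#'
#' Residual of the global fitted image, normalized by its largest magnitude:
#' \deqn{\mathrm{spf}(I) = \frac{I - I_{\mathrm{GFI}}}
#'                              {\max|I - I_{\mathrm{GFI}}|} \in [-1, 1].}
#' Its sign pushes the contour outward inside the object of interest and
#' inward outside it, acting as a smooth balloon force. A residual that is
#' zero everywhere (the converged state on an exactly fitted image) yields
#' the zero field rather than an undefined ratio.
#'
#' @param image Intensity matrix.
#' @param gfi Global fitted image (matrix on the same grid).
#' @return Matrix with values in `[-1, 1]`.
#' @export
spf <- function(image, gfi) {
  r <- image - gfi
  m <- max(abs(r))
  if (m < 1e-12) return(matrix(0, nrow(image), ncol(image)))
  r / m
}

#' Membership-weighted signed pressure force (ablation variant)
#'
#' Same normalized residual as [spf()], but the fitted image inside the
#' normalization is reweighted by the squared memberships,
#' \eqn{(c_1 M_1^2 + c_2 M_2^2)/(M_1^2 + M_2^2)}, which coincides with the
#' plain global fitted image when the memberships are crisp. Selected via
#' `spf_mode = "membership"` in [evolution_params()]; the default pipeline
#' never calls it.
#'
#' @param image Intensity matrix.
#' @param means_g Global means from [global_means()].
#' @param membership A [membership_pair()].
#' @return Matrix with values in `[-1, 1]`.
#' @export
spf_with_membership <- function(image, means_g, membership) {
  M1 <- membership$M1
  M2 <- membership$M2
  gfi_m <- (means_g$c1 * M1^2 + means_g$c2 * M2^2) / (M1^2 + M2^2)
  spf(image, gfi_m)
}
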