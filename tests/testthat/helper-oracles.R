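# Brute-force oracles, deliberately independent of the package's
# vectorized code paths: plain loops and dense convolutions only.

conv2_oracle <- function(x, kernel) {
  nr <- nrow(x)
  nc <- ncol(x)
  kr <- (nrow(kernel) - 1L) %/% 2L
  kc <- (ncol(kernel) - 1L) %/% 2L
  out <- matrix(0, nr, nc)
  for (r in seq_len(nr)) {
    for (c in seq_len(nc)) {
      acc <- 0
      for (i in -kr:kr) {
        for (j in -kc:kc) {
          rr <- min(max(r + i, 1L), nr)
          cc <- min(max(c + j, 1L), nc)
          acc <- acc + kernel[i + kr + 1L, j + kc + 1L] * x[rr, cc]
        }
      }
      out[r, c] <- acc
    }
  }
  out
}

gaussian_kernel_oracle <- function(sigma, radius) {
  d <- seq.int(-radius, radius)
  k <- exp(-outer(d^2, d^2, "+") / (2 * sigma^2))
  k / sum(k)
}

gradient_oracle <- function(f) {
  nr <- nrow(f)
  nc <- ncol(f)
  dr <- matrix(0, nr, nc)
  dc <- matrix(0, nr, nc)
  for (r in seq_len(nr)) {
    for (c in seq_len(nc)) {
      dr[r, c] <- if (r == 1L) f[2L, c] - f[1L, c]
        else if (r == nr) f[nr, c] - f[nr - 1L, c]
        else (f[r + 1L, c] - f[r - 1L, c]) / 2
      dc[r, c] <- if (c == 1L) f[r, 2L] - f[r, 1L]
        else if (c == nc) f[r, nc] - f[r, nc - 1L]
        else (f[r, c + 1L] - f[r, c - 1L]) / 2
    }
  }
  list(dr = dr, dc = dc)
}

# Straight-line transcription of one full evolution step (the update PDE
# plus the documented normalization, hardening and smoothing), written
# only from loops and dense convolutions.
evolve_step_oracle <- function(image, state, params) {
  eps <- params$epsilon
  phi <- state$phi
  H <- 0.5 * (1 + (2 / pi) * atan(phi / eps))
  M1 <- H
  M2 <- 1 - H
  c1 <- sum(image * H) / sum(H)
  c2 <- sum(image * (1 - H)) / sum(1 - H)
  K <- gaussian_kernel_oracle(params$sigma, params$kernel_radius)
  m1p <- state$means_l$m1
  m2p <- state$means_l$m2
  b <- conv2_oracle(image * (m1p * M1 + m2p * M2), K) /
    conv2_oracle(m1p^2 * M1 + m2p^2 * M2, K)
  KIb <- conv2_oracle(image * b, K)
  Kb2 <- conv2_oracle(b^2, K)
  m1 <- sum(KIb * M1) / sum(Kb2 * M1)
  m2 <- sum(KIb * M2) / sum(Kb2 * M2)
  gfi <- c1 * M1 + c2 * M2
  blfi <- b * (m1 * M1 + m2 * M2)
  resid <- image - gfi
  s <- if (max(abs(resid)) < 1e-12) resid * 0 else resid / max(abs(resid))
  delta <- eps / (pi * (phi^2 + eps^2))
  g <- gradient_oracle(phi)
  mag <- sqrt(g$dr^2 + g$dc^2) + 1e-8
  curv <- gradient_oracle(s * g$dr / mag)$dr +
    gradient_oracle(s * g$dc / mag)$dc
  scale2 <- max(diff(range(image))^2, 1e-12)
  force <- delta * ((image - blfi) * (c1 - c2) +
                    (image - gfi) * (m1 - m2)) / scale2 +
    params$mu * curv * delta + params$nu * s * delta
  fmax <- max(abs(force))
  force <- if (fmax > 1e-12) force / fmax else force * 0
  phi_new <- params$hardening * (phi + params$dt * force)
  if (params$phi_smooth_sigma > 0) {
    ksm <- gaussian_kernel_oracle(params$phi_smooth_sigma,
                                  max(1L,
                                      ceiling(2 * params$phi_smooth_sigma)))
    phi_new <- conv2_oracle(phi_new, ksm)
  }
  phi_new
}

confusion_oracle <- function(mask, truth) {
  tp <- tn <- fp <- fn <- 0L
  for (i in seq_along(mask)) {
    m <- mask[i] != 0
    g <- truth[i] != 0
    if (m && g) tp <- tp + 1L
    else if (!m && !g) tn <- tn + 1L
    else if (m && !g) fp <- fp + 1L
    else fn <- fn + 1L
  }
  list(TP = tp, TN = tn, FP = fp, FN = fn)
}

# boundary pixels: foreground with a 4-neighbour background pixel,
# off-grid treated as background
boundary_oracle <- function(mask) {
  m <- mask != 0
  nr <- nrow(m)
  nc <- ncol(m)
  out <- NULL
  for (r in seq_len(nr)) {
    for (c in seq_len(nc)) {
      if (!m[r, c]) next
      nb_bg <- r == 1L || r == nr || c == 1L || c == nc ||
        !m[r - 1L, c] || !m[r + 1L, c] || !m[r, c - 1L] || !m[r, c + 1L]
      if (nb_bg) out <- rbind(out, c(r, c))
    }
  }
  out
}

bf_oracle <- function(mask, truth, tol) {
  bm <- boundary_oracle(mask)
  bt <- boundary_oracle(truth)
  near <- function(a, b) {
    hits <- 0L
    for (i in seq_len(nrow(a))) {
      dmin <- Inf
      for (j in seq_len(nrow(b))) {
        dd <- sqrt(sum((a[i, ] - b[j, ])^2))
        if (dd < dmin) dmin <- dd
      }
      if (dmin <= tol) hits <- hits + 1L
    }
    hits / nrow(a)
  }
  a1 <- near(bm, bt)
  a2 <- near(bt, bm)
  if (a1 + a2 == 0) 0 else 2 * a1 * a2 / (a1 + a2)
}
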