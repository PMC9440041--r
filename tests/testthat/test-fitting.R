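test_that("memberships from the Heaviside partition to one", {
  set.seed(21)
  phi <- matrix(rnorm(64, sd = 3), 8, 8)
  mem <- membership_pair(phi, 0.8)
  expect_identical(mem$M1 + mem$M2, matrix(1, 8, 8))
  expect_true(all(mem$M1 > 0 & mem$M1 < 1))
})

test_that("global means reduce to region averages", {
  expect_equal(global_means(matrix(0.4, 8, 8), matrix(1, 8, 8)),
               list(c1 = 0.4, c2 = 0.4))
  mask <- disk_mask(16, 16, 8, 8, 5)
  img <- ifelse(mask, 0.8, 0.2)
  gm <- global_means(img, crisp_phi(mask, 1e3))
  expect_lt(abs(gm$c1 - 0.8), 1e-3)
  expect_lt(abs(gm$c2 - 0.2), 1e-3)
  # checkerboard with a half-plane phi against a direct weighted-sum oracle
  img2 <- matrix(rep(c(0.1, 0.9), length.out = 64), 8, 8)
  phi <- matrix(rep(c(1, -1), each = 32), 8, 8)
  gm2 <- global_means(img2, phi, 1)
  H <- 0.5 * (1 + (2 / pi) * atan(phi))
  expect_equal(gm2$c1, sum(img2 * H) / sum(H), tolerance = 1e-12)
  expect_equal(gm2$c2, sum(img2 * (1 - H)) / sum(1 - H), tolerance = 1e-12)
  expect_error(global_means(img2, matrix(1e9, 8, 8)), "degenerate region")
})

test_that("bias field is exact on a self-consistent image and scales linearly", {
  mask <- disk_mask(24, 24, 12, 12, 7)
  mem <- membership_pair(crisp_phi(mask), 1)
  means <- list(m1 = 0.7, m2 = 0.3)
  img <- means$m1 * mem$M1 + means$m2 * mem$M2
  b <- bias_field(img, mem, means, sigma = 2, kernel_radius = 4)
  expect_lt(max(abs(b - 1)), 1e-6)
  b2 <- bias_field(3 * img, mem, means, sigma = 2, kernel_radius = 4)
  expect_equal(b2, 3 * b, tolerance = 1e-12)
})

test_that("bias field and local means match dense convolution oracles", {
  set.seed(22)
  img <- matrix(runif(256, 0.1, 0.9), 16, 16)
  phi <- matrix(rnorm(256), 16, 16)
  mem <- membership_pair(phi, 1)
  means <- list(m1 = 0.65, m2 = 0.3)
  K <- gaussian_kernel_oracle(2, 4)
  b <- bias_field(img, mem, means, sigma = 2, kernel_radius = 4)
  b_or <- conv2_oracle(img * (means$m1 * mem$M1 + means$m2 * mem$M2), K) /
    conv2_oracle(means$m1^2 * mem$M1 + means$m2^2 * mem$M2, K)
  expect_equal(b, b_or, tolerance = 1e-10)
  lm <- local_means(img, b, mem, sigma = 2, kernel_radius = 4)
  KIb <- conv2_oracle(img * b, K)
  Kb2 <- conv2_oracle(b^2, K)
  expect_equal(lm$m1, sum(KIb * mem$M1) / sum(Kb2 * mem$M1),
               tolerance = 1e-10)
  expect_equal(lm$m2, sum(KIb * mem$M2) / sum(Kb2 * mem$M2),
               tolerance = 1e-10)
})

test_that("with unit bias the local model degenerates to the global one", {
  mask <- disk_mask(20, 20, 10, 10, 6)
  img <- ifelse(mask, 0.75, 0.25)
  phi <- crisp_phi(mask, 1e3)
  mem <- membership_pair(phi, 1)
  # exact reduction holds in the narrow-kernel limit (the kernel mixes
  # intensities across the membership boundary otherwise)
  lm <- local_means(img, matrix(1, 20, 20), mem, sigma = 0.1,
                    kernel_radius = 1)
  gm <- global_means(img, phi, 1)
  expect_lt(abs(lm$m1 - gm$c1), 1e-3)
  expect_lt(abs(lm$m2 - gm$c2), 1e-3)
  expect_lt(abs(lm$m1 - 0.75), 1e-3)
  expect_lt(abs(lm$m2 - 0.25), 1e-3)
  # a moderate kernel still lands near the region means
  lm2 <- local_means(img, matrix(1, 20, 20), mem, sigma = 1,
                     kernel_radius = 2)
  expect_lt(abs(lm2$m1 - 0.75), 0.1)
  expect_lt(abs(lm2$m2 - 0.25), 0.1)
  lc <- local_means(matrix(0.4, 8, 8), matrix(1, 8, 8),
                    membership_pair(matrix(1, 8, 8)), 1, 2)
  expect_equal(lc$m1, 0.4, tolerance = 1e-12)
  expect_equal(lc$m2, 0.4, tolerance = 1e-12)
})

test_that("fitted images compose means, bias and memberships elementwise", {
  set.seed(23)
  mem <- membership_pair(matrix(rnorm(36), 6, 6), 1)
  bias <- matrix(runif(36, 0.5, 1.5), 6, 6)
  gmn <- list(c1 = 0.8, c2 = 0.3)
  lmn <- list(m1 = 0.7, m2 = 0.2)
  fit <- fitted_images(gmn, lmn, bias, mem)
  for (i in seq_len(36)) {
    expect_equal(fit$gfi[i], gmn$c1 * mem$M1[i] + gmn$c2 * mem$M2[i])
    expect_equal(fit$blfi[i],
                 bias[i] * (lmn$m1 * mem$M1[i] + lmn$m2 * mem$M2[i]))
  }
  # crisp memberships yield the two-level piecewise-constant local fit
  mask <- disk_mask(12, 12, 6, 6, 4)
  memc <- membership_pair(crisp_phi(mask))
  fitc <- fitted_images(gmn, lmn, matrix(1, 12, 12), memc)
  expect_equal(fitc$blfi, ifelse(mask, lmn$m1, lmn$m2), tolerance = 1e-4)
})

test_that("signed pressure force is the max-normalized residual in [-1, 1]", {
  img <- matrix(0.5, 5, 5)
  expect_identical(spf(img, img), matrix(0, 5, 5))
  toy <- matrix(c(-2, 1, 4), 1, 3)
  expect_equal(spf(toy, matrix(0, 1, 3)), matrix(c(-0.5, 0.25, 1), 1, 3))
  set.seed(24)
  for (i in 1:20) {
    a <- matrix(runif(64), 8, 8)
    g <- matrix(runif(64), 8, 8)
    s <- spf(a, g)
    expect_true(all(s >= -1 & s <= 1))
    expect_equal(max(abs(s)), 1)
  }
})

test_that("membership-weighted SPF agrees with the plain form when crisp", {
  mask <- disk_mask(16, 16, 8, 8, 5)
  img <- ifelse(mask, 0.9, 0.1)
  gmn <- list(c1 = 0.85, c2 = 0.15)
  memc <- membership_pair(crisp_phi(mask))
  gfi <- gmn$c1 * memc$M1 + gmn$c2 * memc$M2
  expect_equal(spf_with_membership(img, gmn, memc), spf(img, gfi),
               tolerance = 1e-12)
  # soft memberships stay within the admissible range
  set.seed(25)
  mems <- membership_pair(matrix(rnorm(64, sd = 0.3), 8, 8), 5)
  s <- spf_with_membership(matrix(runif(64), 8, 8), gmn, mems)
  expect_true(all(s >= -1 & s <= 1))
})
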