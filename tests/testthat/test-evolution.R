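test_that("parameter constructor validates its invariants", {
  expect_s3_class(evolution_params(), "evolution_params")
  expect_error(evolution_params(dt = 0), "dt")
  expect_error(evolution_params(p = -1), "p")
  expect_error(evolution_params(max_iter = 0), "max_iter")
  expect_error(evolution_params(kernel_radius = 1, sigma = 3),
               "kernel_radius")
  expect_error(evolution_params(hardening = 0.9), "hardening")
  expect_error(evolution_params(spf_mode = "bogus"))
})

test_that("binary initialization places the zero set on the seed rim", {
  seed <- matrix(FALSE, 5, 5)
  seed[3, 3] <- TRUE
  phi <- initialize_phi(seed, p = 2)
  expect_equal(phi[3, 3], 0)          # a lone pixel is its own boundary
  expect_equal(sum(phi == -2), 24)    # everything else is outside
  seed2 <- matrix(FALSE, 16, 16)
  seed2[6:11, 6:11] <- TRUE
  phi2 <- initialize_phi(seed2, p = 1.5)
  expect_true(all(phi2[8:9, 8:9] == 1.5))          # 4x4 interior... checked below
  interior <- matrix(FALSE, 16, 16)
  interior[7:10, 7:10] <- TRUE
  rim <- seed2 & !interior
  expect_true(all(phi2[interior] == 1.5))
  expect_true(all(phi2[rim] == 0))
  expect_true(all(phi2[!seed2] == -1.5))
  # inverting the seed swaps the sign on every plateau pixel (the zero
  # ring relocates to the complement's inner rim)
  phi_inv <- initialize_phi(!seed2, p = 1.5)
  plateau <- phi2 != 0 & phi_inv != 0
  expect_true(all(phi_inv[plateau] == -phi2[plateau]))
  expect_error(initialize_phi(matrix(FALSE, 4, 4)), "empty")
  expect_error(initialize_phi(matrix(TRUE, 4, 4)), "full")
})

test_that("convergence requires a full window of quiet iterations", {
  expect_true(has_converged(c(0, 0, 0), tol = 1e-4, window = 3))
  expect_false(has_converged(c(0, 0), tol = 1e-4, window = 3))
  expect_false(has_converged(c(0.1, 0, 0), tol = 1e-4, window = 3))
  expect_true(has_converged(c(0.5, 0.2, 0, 0, 0), tol = 1e-4, window = 3))
  expect_error(has_converged(c(0, 0), window = 0), "window")
})

test_that("an exactly fitted two-level image is a stationary point", {
  mask <- disk_mask(24, 24, 12, 12, 7)
  img <- ifelse(mask, 0.8, 0.2)
  params <- evolution_params(sigma = 3, phi_smooth_sigma = 0,
                             hardening = 1)
  phi <- crisp_phi(mask, 1e6)
  state <- spfcontour:::init_state(img, phi, params)
  out <- evolve_step(img, state, params)
  expect_lt(max(abs(out$phi - phi)), 1e-6)
  expect_equal(out$history, 0)
})

test_that("constant images with zero regularizers leave phi untouched", {
  img <- matrix(0.5, 12, 12)
  params <- evolution_params(mu = 0, nu = 0, sigma = 2,
                             phi_smooth_sigma = 0, hardening = 1)
  phi <- initialize_phi(disk_mask(12, 12, 6, 6, 3))
  state <- spfcontour:::init_state(img, phi, params)
  out <- evolve_step(img, state, params)
  expect_equal(out$phi, phi)
})

test_that("one evolution step equals its term-by-term loop transcription", {
  set.seed(31)
  img <- matrix(runif(256), 16, 16)
  img[1] <- 0                      # pin the intensity range to [0, 1]
  img[256] <- 1
  params <- evolution_params(sigma = 2, kernel_radius = 4,
                             phi_smooth_sigma = 0.7)
  phi <- matrix(rnorm(256, sd = 1.5), 16, 16)
  state <- spfcontour:::init_state(img, phi, params)
  out <- evolve_step(img, state, params)
  expect_equal(out$phi, evolve_step_oracle(img, state, params),
               tolerance = 1e-10)
  # and with smoothing disabled
  params0 <- evolution_params(sigma = 2, kernel_radius = 4,
                              phi_smooth_sigma = 0)
  out0 <- evolve_step(img, state, params0)
  expect_equal(out0$phi, evolve_step_oracle(img, state, params0),
               tolerance = 1e-10)
})

test_that("segmentation recovers a disk phantom from any reasonable seed", {
  ph <- generate_phantom(phantom_spec("disk", height = 64, width = 64))
  seed <- disk_mask(64, 64, 32, 32, 8)
  res <- segment_image(ph$image, seed_region = seed)
  expect_s3_class(res, "spf_segmentation")
  expect_true(res$converged)
  expect_gte(dice(res$mask, ph$truth_mask), 0.98)
  expect_identical(res$mask, res$phi_final > 0)
  expect_length(res$history, res$iterations_used)
})

test_that("contrast polarity does not change the recovered mask", {
  ph <- generate_phantom(phantom_spec("disk", height = 64, width = 64))
  res <- segment_image(ph$image)
  res_inv <- segment_image(1 - ph$image)
  expect_gte(dice(res$mask, res_inv$mask), 0.98)
  expect_gte(dice(res_inv$mask, ph$truth_mask), 0.98)
})

test_that("a constant image with an explicit seed converges immediately", {
  # forces vanish identically; the only label churn is the smoothing of
  # the three-level initial field settling in the first few iterations
  img <- matrix(0.5, 32, 32)
  res <- segment_image(img, seed_region = disk_mask(32, 32, 16, 16, 6))
  expect_true(res$converged)
  expect_true(all(utils::tail(res$history, 3) == 0))
  expect_lte(res$iterations_used, 10)
})

test_that("mask changes settle monotonically near convergence", {
  # a slow run (strong bias) so the final stretch is past the growth phase
  ph <- generate_phantom(phantom_spec("disk", bias = "linear_ramp",
                                      bias_amplitude = 0.5))
  res <- segment_image(ph$image)
  expect_true(res$converged)
  expect_gt(res$iterations_used, 20)
  tail10 <- utils::tail(res$history, 10)
  expect_true(all(diff(tail10) <= 1e-3))
})

test_that("non-finite or out-of-range images are rejected", {
  img <- matrix(0.5, 16, 16)
  img[3, 3] <- NA
  expect_error(segment_image(img), "non-finite")
  expect_error(segment_image(matrix(2, 16, 16)), "rescaled")
})
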