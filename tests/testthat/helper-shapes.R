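# Small geometric helpers shared across test files.

disk_mask <- function(h, w, cr, cc, rad) {
  rr <- row(matrix(0, h, w))
  ccm <- col(matrix(0, h, w))
  (rr - cr)^2 + (ccm - cc)^2 <= rad^2
}

# crisp level-set field: +amp on mask, -amp outside
crisp_phi <- function(mask, amp = 1e6) {
  ifelse(mask, amp, -amp)
}

# the four manual seed configurations used in the initialization study
seed_configurations <- function(h, w) {
  rr <- row(matrix(0, h, w))
  cc <- col(matrix(0, h, w))
  list(
    small_inside = (rr - h / 2)^2 + (cc - w / 2)^2 <= (h / 16)^2,
    large_overlap = (rr - 0.4 * h)^2 + (cc - 0.6 * w)^2 <= (0.23 * h)^2,
    corner_square = rr >= 8 & rr <= 28 & cc >= 8 & cc <= 28,
    two_blobs = ((rr - 0.23 * h)^2 + (cc - 0.7 * w)^2 <= (h / 13)^2) |
      ((rr - 0.78 * h)^2 + (cc - 0.3 * w)^2 <= (h / 13)^2))
}
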