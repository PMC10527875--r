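test_that("foreground intensity statistics match hand computation", {
  s <- full_fg_slice(matrix(c(1, 2, 3, 4), 2, 2))
  st <- intensity_stats(s)
  expect_equal(unname(st), c(2.5, 3, 1.25))

  const <- full_fg_slice(matrix(5, 3, 3))
  expect_equal(unname(intensity_stats(const)), c(5, 0, 0))

  # shift covariance: mean moves by c, range and variance do not
  set.seed(2)
  m <- matrix(runif(64, 10, 50), 8, 8)
  a <- intensity_stats(full_fg_slice(m))
  b <- intensity_stats(full_fg_slice(m + 13.7))
  expect_equal(unname(b["MEAN"] - a["MEAN"]), 13.7)
  expect_equal(b[c("RNG", "VAR")], a[c("RNG", "VAR")])

  empty <- masked(m, matrix(FALSE, 8, 8))
  expect_true(all(is.na(intensity_stats(empty))))
})

test_that("coefficient of variation is correct and scale invariant", {
  s <- full_fg_slice(matrix(c(2, 4), 1 * 2, 1))
  expect_equal(coefficient_of_variation(s), 1 / 3)
  expect_equal(coefficient_of_variation(full_fg_slice(matrix(7, 4, 4))), 0)
  set.seed(3)
  m <- matrix(runif(64, 1, 9), 8, 8)
  expect_equal(coefficient_of_variation(full_fg_slice(m * 11)),
               coefficient_of_variation(full_fg_slice(m)))
  zero_mean <- full_fg_slice(matrix(c(-1, 1), 2, 1))
  expect_true(is.na(coefficient_of_variation(zero_mean)))
})

# Striped background with period 5: every 5x5 window holds each stripe value
# exactly 5 times, so patch mean/SD are known regardless of the random draw.
striped_noise_slice <- function() {
  img <- matrix(0, 20, 20)
  stripes <- c(2, 4, 6, 8, 10)
  for (r in 1:20) img[r, ] <- stripes[(r - 1) %% 5 + 1]
  fg <- matrix(FALSE, 20, 20)
  fg[8:12, 8:12] <- TRUE
  img[fg] <- 20                      # constant foreground block
  masked(img, fg)
}

test_that("SNR1, SNR2 and CNR follow their patch-based definitions", {
  s <- striped_noise_slice()
  # bg_erosion = 0: the raw whole-background formulas
  nm <- noise_metrics(s, seed = 5, bg_erosion = 0)
  sd_b <- sqrt(mean((c(2, 4, 6, 8, 10) - 6)^2))   # population SD of stripes
  expect_equal(unname(nm["SNR1"]), 0 / sd_b)       # constant foreground
  expect_equal(unname(nm["SNR2"]), 20 / sd_b)
  expect_equal(unname(nm["CNR"]), (20 - 6) / sd_b)
})

test_that("PSNR degenerates to the +Inf flag and drops with noise", {
  const <- full_fg_slice(matrix(3, 8, 8))
  expect_identical(unname(noise_metrics(const, seed = 1)["PSNR"]), Inf)

  psnr_at <- function(noise_sd, seed) {
    img <- disk_slice(48, radius = 16, value = 100, noise_sd = noise_sd,
                      seed = seed)
    ms <- detect_foreground(img)
    noise_metrics(ms, seed = seed)["PSNR"]
  }
  sds <- c(1, 4, 12)
  means <- vapply(sds, function(s)
    mean(vapply(1:10, function(seed) psnr_at(s, seed), 0)), 0)
  expect_true(all(diff(means) < 0))
})

test_that("background standoff keeps the boundary skirt out of sigma_B", {
  n <- 40
  ctr <- (n + 1) / 2
  d2 <- outer((seq_len(n) - ctr)^2, (seq_len(n) - ctr)^2, `+`)
  base <- matrix(rep(c(-1, 1), length.out = n * n), n, n) # sd exactly 1
  img <- base
  img[d2 <= 11^2] <- 30                                   # skirt ring
  fg <- d2 <= 8^2
  img[fg] <- 100 + 10 * base[fg]                          # anatomy, sd 10
  s <- masked(img, fg)
  raw <- noise_metrics(s, seed = 1, bg_erosion = 0)
  far <- noise_metrics(s, seed = 1, bg_erosion = 3)
  # the ring inflates the raw estimate and suppresses SNR1
  expect_gt(far[["SNR1"]], 2 * raw[["SNR1"]])
  expect_equal(far[["SNR1"]], 10, tolerance = 1e-12)
})

test_that("zero-variance background disables the dependent features", {
  img <- disk_slice(32, radius = 10, value = 50, noise_sd = 0)
  ms <- detect_foreground(img)
  nm <- noise_metrics(ms, seed = 2)
  expect_true(is.na(nm["SNR1"]))
  expect_true(is.na(nm["SNR2"]))
  expect_true(is.na(nm["CNR"]))
})

test_that("CJV matches its definition and is monotone in sigma_F", {
  mk <- function(f_vals, b_vals) {
    img <- matrix(c(f_vals, b_vals), nrow = 2, byrow = TRUE)
    fg <- rbind(rep(TRUE, length(f_vals)), rep(FALSE, length(b_vals)))
    masked(img, fg)
  }
  # sigma_F = 2, sigma_B = 1, mu_F = 10, mu_B = 0
  s <- mk(c(8, 12), c(-1, 1))
  expect_equal(cjv(s), 0.3)
  expect_equal(cjv(mk(c(10, 10), c(0, 0))), 0)
  spreads <- c(1, 2, 4, 6)
  vals <- vapply(spreads, function(d) cjv(mk(c(10 - d, 10 + d), c(-1, 1))), 0)
  expect_true(all(diff(vals) > 0))
  expect_true(is.na(cjv(mk(c(5, 5), c(5, 5)))))
})

test_that("EFC hits its closed-form extremes and the brute-force oracle", {
  expect_equal(efc(full_fg_slice(matrix(4, 12, 12))), 1.0)
  delta <- matrix(0, 9, 9); delta[3, 7] <- 5
  expect_equal(efc(full_fg_slice(delta)), 0.0)
  expect_true(is.na(efc(full_fg_slice(matrix(0, 8, 8)))))
  for (seed in 1:10) {
    set.seed(seed)
    m <- matrix(runif(64), 8, 8)
    expect_equal(efc(full_fg_slice(m)), oracle_efc(m), tolerance = 1e-12)
  }
})

test_that("ratio features are invariant to global intensity scaling", {
  img <- disk_slice(48, radius = 16, value = 100, noise_sd = 5, seed = 8)
  ms <- detect_foreground(img)
  ms_k <- masked(img * 3.7, ms$fg_mask)
  expect_equal(noise_metrics(ms_k, seed = 1), noise_metrics(ms, seed = 1))
  expect_equal(cjv(ms_k), cjv(ms))
  expect_equal(coefficient_of_variation(ms_k),
               coefficient_of_variation(ms))
  expect_equal(efc(ms_k), efc(ms))
})
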