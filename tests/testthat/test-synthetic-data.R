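test_that("phantom generation is deterministic and obeys its profile", {
  p <- scanner_profile("a", noise_sd = 5)
  v1 <- generate_phantom(p, c(64, 64, 64), seed = 9)
  v2 <- generate_phantom(p, c(64, 64, 64), seed = 9)
  expect_identical(v1$data, v2$data)
  v3 <- generate_phantom(p, c(64, 64, 64), seed = 10)
  expect_false(identical(v1$data, v3$data))

  # background is noise only: sample SD near the configured noise_sd,
  # measured clear of the PSF skirt around the ellipsoid boundary
  n <- 64
  co <- (seq(-1, 1, length.out = n) / 0.9)^2
  r2 <- outer(outer(co, co, `+`), co, `+`)
  far_bg <- r2 > 1.44
  expect_lt(abs(sd(v1$data[far_bg]) - 5) / 5, 0.10)

  # ellipsoid occupancy close to the analytic volume
  semi <- 0.45 * dim(v1$data)
  expect_lt(abs(sum(attr(v1, "fg_mask")) - 4 / 3 * pi * prod(semi)) /
              (4 / 3 * pi * prod(semi)), 0.05)

  expect_error(generate_phantom(p, c(16, 64, 64)), ">= 32")
})

test_that("cohort generation writes files, labels and is reproducible", {
  prof <- list(scanner_profile("ge", noise_sd = 4),
               scanner_profile("siemens", noise_sd = 8),
               scanner_profile("philips", noise_sd = 16))
  dir <- tempfile("sim")
  coh <- generate_multisite_cohort(prof, 10, shape = c(32, 32, 32),
                                   seed = 21, dir = dir)
  expect_length(coh$volumes, 30)
  expect_equal(nrow(coh$labels), 30)
  expect_length(list.files(dir, pattern = "\\.nii\\.gz$"), 30)
  labs <- utils::read.csv(file.path(dir, "labels.csv"))
  expect_equal(sort(names(labs)), c("scan_id", "site"))
  expect_equal(unname(table(labs$site)[c("ge", "philips", "siemens")]),
               c(10L, 10L, 10L), ignore_attr = TRUE)

  coh2 <- generate_multisite_cohort(prof, 10, shape = c(32, 32, 32),
                                    seed = 21)
  expect_identical(coh$volumes[["ge_003"]]$data,
                   coh2$volumes[["ge_003"]]$data)
})

test_that("adding a site leaves existing volumes untouched", {
  p1 <- scanner_profile("s1", noise_sd = 5)
  p2 <- scanner_profile("s2", noise_sd = 9)
  p3 <- scanner_profile("s3", noise_sd = 13)
  a <- generate_multisite_cohort(list(p1, p2), 3, c(32, 32, 32), seed = 30)
  b <- generate_multisite_cohort(list(p1, p2, p3), 3, c(32, 32, 32),
                                 seed = 30)
  for (id in names(a$volumes))
    expect_identical(a$volumes[[id]]$data, b$volumes[[id]]$data)
})

test_that("each profile knob moves its matching feature family", {
  base <- function(site, ...) scanner_profile(site, noise_sd = 4,
                                              contrast_gamma = 1,
                                              smoothing_fwhm = 2, ...)
  site_means <- function(profiles) {
    coh <- generate_multisite_cohort(profiles, 5, c(32, 32, 32), seed = 77)
    tab <- extract_features(coh$volumes, labels = coh$labels, seed = 77)
    list(tab = tab,
         by_site = function(fn) tapply(tab[[fn]], tab$site, mean))
  }

  # noise: quiet vs noisy site -> PSNR drops, SNR1 site means differ > 2x
  res <- site_means(list(base("quiet"),
                         scanner_profile("noisy", noise_sd = 20,
                                         contrast_gamma = 1,
                                         smoothing_fwhm = 2)))
  psnr <- res$by_site("PSNR")
  expect_gt(psnr[["quiet"]], psnr[["noisy"]])
  snr1 <- res$by_site("SNR1")
  expect_gt(max(snr1) / min(snr1), 2)

  # smoothing: stronger PSF -> lower HFR
  res2 <- site_means(list(base("sharp"),
                          scanner_profile("smooth", noise_sd = 4,
                                          contrast_gamma = 1,
                                          smoothing_fwhm = 8)))
  hfr_m <- res2$by_site("HFR")
  expect_gt(hfr_m[["sharp"]], hfr_m[["smooth"]])

  # contrast: a brightening gamma raises the foreground mean (gammas that
  # darken the outer shell below the air/tissue threshold instead flip the
  # segmentation regime, so the knob is probed on the brightening side)
  res3 <- site_means(list(base("lin"),
                          scanner_profile("gamma", noise_sd = 4,
                                          contrast_gamma = 0.6,
                                          smoothing_fwhm = 2)))
  mean_m <- res3$by_site("MEAN")
  expect_gt(abs(mean_m[["lin"]] - mean_m[["gamma"]]),
            0.05 * abs(mean_m[["lin"]]))
})

test_that("strip_background zeroes exactly the non-anatomy voxels", {
  v <- generate_phantom(scanner_profile("s", noise_sd = 6), c(32, 32, 32),
                        seed = 3)
  sv <- strip_background(v)
  mask <- attr(v, "fg_mask")
  expect_true(all(sv$data[!mask] == 0))
  expect_identical(sv$data[mask], v$data[mask])
  plain <- mri_volume(array(1, c(8, 8, 8)))
  expect_error(strip_background(plain), "mask")
})
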