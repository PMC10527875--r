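#' Foreground intensity statistics
#'
#' Mean, range and population variance of the foreground intensities.
#'
#' @param slice A `masked_slice`.
#' @return Named numeric vector `c(MEAN, RNG, VAR)`; all `NA` when the
#'   foreground is empty.
#' @export
intensity_stats <- function(slice) {
  f <- slice$image[slice$fg_mask]
  if (length(f) == 0L)
    return(c(MEAN = NA_real_, RNG = NA_real_, VAR = NA_real_))
  c(MEAN = mean(f), RNG = max(f) - min(f), VAR = pop_var(f))
}

#' Coefficient of variation of the foreground
#'
#' `sigma_F / mu_F` with population standard deviation; `NA` when the
#' foreground mean is zero.
#'
#' @param slice A `masked_slice`.
#' @return Scalar CV or `NA`.
#' @export
coefficient_of_variation <- function(slice) {
  f <- slice$image[slice$fg_mask]
  if (length(f) == 0L || mean(f) == 0) return(NA_real_)
  pop_sd(f) / mean(f)
}

# 5x5 median-filtered version of the slice, the reference image of the PSNR
# convention (exact order statistics, symmetric padding; compiled).
median_reference <- function(image, size = 5L) {
  median_filter_sym(image, (size - 1L) %/% 2L)
}

#' Noise-related features: PSNR, SNR1, SNR2, CNR
#'
#' * `PSNR = 10 log10(max(F)^2 / MSE(F, median5(F)))`, the mean squared error
#'   taken over foreground pixels against the 5x5 median-filtered slice;
#' * `SNR1 = sigma_F / sigma_B`;
#' * `SNR2 = mu_FP / sigma_B`;
#' * `CNR = (mu_FP - mu_BP) / sigma_BP`;
#'
#' where FP and BP are seeded random 5x5 patches of the foreground and
#' background.  Features whose denominator is zero (e.g. the zero background
#' of skull-stripped data) are `NA`; a zero MSE yields `PSNR = +Inf` as an
#' explicit flag.
#'
#' The background statistics (`sigma_B`, the BP patch) are estimated on the
#' background at least `bg_erosion` pixels (Chebyshev) away from any
#' foreground pixel, the usual air-region noise-estimation convention: it
#' keeps the partial-volume / point-spread skirt around the anatomy boundary
#' out of the noise estimate.  Set `bg_erosion = 0` for the raw
#' whole-background definition.
#'
#' @param slice A `masked_slice`.
#' @param seed Integer seed for the patch draws.
#' @param patch_side Patch side length (default 5).
#' @param bg_erosion Background standoff from the foreground, in pixels
#'   (default 3).
#' @return Named numeric vector `c(PSNR, SNR1, SNR2, CNR)`.
#' @export
noise_metrics <- function(slice, seed = 1L, patch_side = 5L,
                          bg_erosion = 3L) {
  out <- c(PSNR = NA_real_, SNR1 = NA_real_, SNR2 = NA_real_, CNR = NA_real_)
  f <- slice$image[slice$fg_mask]
  if (length(f) == 0L) return(out)

  ref <- median_reference(slice$image, patch_side)
  mse <- mean((slice$image[slice$fg_mask] - ref[slice$fg_mask])^2)
  peak <- max(f)
  out["PSNR"] <- if (mse == 0) Inf else 10 * log10(peak^2 / mse)

  bg_far <- slice$bg_mask
  if (bg_erosion > 0)
    bg_far <- bg_far & !dilate_mask(slice$fg_mask, bg_erosion)
  b <- slice$image[bg_far]
  # a noise estimate needs a non-degenerate background: an (eroded)
  # background that is constant except for a few stray pixels — e.g. the
  # zeroed air of skull-stripped data — has IQR 0 and yields no sigma_B
  sd_b <- if (length(b) && bg_nondegenerate(b)) pop_sd(b) else NA_real_
  if (!is.na(sd_b) && sd_b > 0) out["SNR1"] <- pop_sd(f) / sd_b
  else sd_b <- NA_real_

  bslice <- slice
  bslice$bg_mask <- bg_far
  fp <- sample_square_patch(slice, "foreground", patch_side,
                            seed = derive_seed(seed, "fp"))
  bp <- sample_square_patch(bslice, "background", patch_side,
                            seed = derive_seed(seed, "bp"))
  if (!is.null(fp) && !is.na(sd_b))
    out["SNR2"] <- mean(fp$values) / sd_b
  if (!is.null(fp) && !is.null(bp)) {
    bpv <- as.vector(bp$values)
    sd_bp <- pop_sd(bpv)
    if (sd_bp > 0 && bg_nondegenerate(bpv))
      out["CNR"] <- (mean(fp$values) - mean(bp$values)) / sd_bp
  }
  out
}

bg_nondegenerate <- function(b) {
  q <- stats::quantile(b, c(0.25, 0.75), names = FALSE)
  (q[2] - q[1]) > 0
}

#' Coefficient of joint variation
#'
#' `CJV = (sigma_F + sigma_B) / |mu_F - mu_B|`, sensitive to intensity
#' non-uniformity and heavy motion; `NA` when the two region means coincide.
#'
#' @param slice A `masked_slice`.
#' @return Scalar CJV or `NA`.
#' @export
cjv <- function(slice) {
  f <- slice$image[slice$fg_mask]
  b <- slice$image[slice$bg_mask]
  if (length(f) == 0L || length(b) == 0L) return(NA_real_)
  if (mean(f) == mean(b)) return(NA_real_)
  (pop_sd(f) + pop_sd(b)) / abs(mean(f) - mean(b))
}

#' Entropy focus criterion
#'
#' Shannon-entropy sharpness measure over all pixels of the slice:
#' `E = -sum_j (x_j / x_max) ln(x_j / x_max)` with
#' `x_max = sqrt(sum_j x_j^2)` (zero pixels contribute 0), normalized by the
#' entropy of the uniform image, `E_max = sqrt(N) ln(sqrt(N))`, so that a
#' uniform slice scores 1 and a single-pixel impulse scores 0.  Ghosting and
#' motion blur spread intensity and push the score towards 1.
#'
#' @param slice A `masked_slice` (or plain matrix).
#' @return EFC in `[0, 1]`, or `NA` for an all-zero slice.
#' @export
efc <- function(slice) {
  x <- if (inherits(slice, "masked_slice")) slice$image else slice
  x <- abs(as.vector(x))
  xmax <- sqrt(sum(x^2))
  if (xmax == 0) return(NA_real_)
  p <- x / xmax
  p <- p[p > 0]
  e <- -sum(p * log(p))
  n <- length(x)
  e / (sqrt(n) * log(sqrt(n)))
}
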