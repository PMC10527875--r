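# Frequency-domain features.  All three operate on the rectangular slice with
# the background zeroed outside the foreground mask (the FFT needs a full
# grid), via masked_image().

masked_image <- function(slice) {
  if (!inherits(slice, "masked_slice")) return(slice)
  x <- slice$image
  x[!slice$fg_mask] <- 0
  x
}

# Squared distance of every (unshifted) FFT bin from DC, using signed
# frequency coordinates; identical to the distance grid of the centered
# spectrum.
centered_radius2 <- function(nr, nc) {
  fr <- seq_len(nr) - 1L
  fr <- ifelse(fr > nr %/% 2, fr - nr, fr)
  fc <- seq_len(nc) - 1L
  fc <- ifelse(fc > nc %/% 2, fc - nc, fc)
  outer(fr^2, fc^2, `+`)
}

#' Frequency-domain signal-to-noise ratio
#'
#' Centers the 2-D FFT power spectrum and splits it at a radius equal to
#' `signal_radius_fraction` of the maximal distance from DC: power inside the
#' disc is signal, the remainder noise, and
#' `SNRF = 10 log10(P_signal / P_noise)` (dB).  A spectrum with zero
#' out-of-disc power (e.g. a constant slice) yields `+Inf` as an explicit
#' flag.
#'
#' @param slice A `masked_slice` or matrix.
#' @param signal_radius_fraction Fraction of the maximal radius treated as
#'   signal (default 0.25).
#' @return SNRF in dB (possibly `+Inf`).
#' @export
snrf <- function(slice, signal_radius_fraction = 0.25) {
  x <- masked_image(slice)
  stopifnot(signal_radius_fraction > 0, signal_radius_fraction < 1)
  pw <- Mod(stats::fft(x))^2
  r2 <- centered_radius2(nrow(x), ncol(x))
  inside <- r2 <= (signal_radius_fraction^2) * max(r2)
  p_sig <- sum(pw[inside]); p_noise <- sum(pw[!inside])
  if (p_noise == 0) return(Inf)
  10 * log10(p_sig / p_noise)
}

# Mean over all FFT bins of the square root of the amplitude spectrum of
# kernel-filtered x (symmetric padding).
filtered_spectrum_root_mean <- function(x, kernel) {
  y <- conv2_sym(x, kernel)
  amp <- Mod(stats::fft(y))
  mean(sqrt(amp))
}

#' Low-frequency response
#'
#' Convolves the slice with the 3x3 Gaussian low-pass kernel
#' `[[1,2,1],[2,4,2],[1,2,1]]/16` (symmetric padding), then reduces the
#' square-rooted FFT amplitude spectrum of the result to its mean over all
#' bins.
#'
#' @param slice A `masked_slice` or matrix.
#' @return Non-negative LFR score.
#' @export
lfr <- function(slice) {
  filtered_spectrum_root_mean(masked_image(slice), GAUSS3)
}

#' High-frequency response
#'
#' Same reduction as [lfr()] after a 3x3 Laplacian high-pass filter
#' `[[-1,-1,-1],[-1,8,-1],[-1,-1,-1]]`.  Zero for any constant slice (the
#' kernel sums to zero under symmetric padding).
#'
#' @param slice A `masked_slice` or matrix.
#' @return Non-negative HFR score.
#' @export
hfr <- function(slice) {
  filtered_spectrum_root_mean(masked_image(slice), LAPLACE3)
}
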