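# Single-level 2-D discrete wavelet transform with orthonormal filters and
# periodic extension.  Implemented in-package: the transform is applied
# separably (columns then rows), each 1-D step being the circularly wrapped,
# downsampled correlation a[k] = sum_m lo[m] x[(2k + m) mod N].  With an
# orthonormal filter pair this operator has orthonormal rows, so energy is
# conserved exactly on even-sized inputs (Parseval); odd dimensions are
# periodized by repeating the last sample, as is conventional.

# Decomposition low-pass filters (orthonormal; sum = sqrt(2)).
WAVELET_FILTERS <- list(
  haar = c(0.7071067811865476, 0.7071067811865476),
  db2 = c(-0.12940952255092145, 0.22414386804185735,
          0.836516303737469, 0.48296291314469025),
  db4 = c(-0.010597401784997278, 0.032883011666982945,
          0.030841381835986965, -0.18703481171888114,
          -0.02798376941698385, 0.6308807679295904,
          0.7148465705525415, 0.23037781330885523),
  sym4 = c(-0.07576571478927333, -0.02963552764599851,
           0.49761866763201545, 0.8037387518059161,
           0.29785779560527736, -0.09921954357684722,
           -0.012603967262037833, 0.0322231006040427),
  coif1 = c(-0.01565572813546454, -0.0727326195128539,
            0.38486484686420286, 0.8525720202122554,
            0.3378976624578092, -0.0727326195128539)
)

# Quadrature mirror high-pass from the low-pass filter.
qmf_highpass <- function(lo) {
  L <- length(lo)
  rev(lo) * (-1)^(seq_len(L))
}

# One 1-D analysis step along the columns of x (each column is a signal).
dwt_step_cols <- function(x, filt) {
  n <- nrow(x)
  if (n %% 2L == 1L) {
    x <- rbind(x, x[n, , drop = FALSE])   # periodize odd length
    n <- n + 1L
  }
  L <- length(filt)
  half <- n %/% 2L
  out <- matrix(0, half, ncol(x))
  for (m in seq_len(L)) {
    idx <- ((2L * (seq_len(half) - 1L) + (m - 1L)) %% n) + 1L
    out <- out + filt[m] * x[idx, , drop = FALSE]
  }
  out
}

#' Single-level 2-D discrete wavelet transform of a slice
#'
#' Decomposes the (background-zeroed) slice into the four subbands of one
#' level of a separable orthonormal 2-D DWT and returns all coefficients.
#' The first-order Coiflet is the default wavelet; Haar, Daubechies 2/4 and
#' Symlet 4 are also available.
#'
#' @param slice A `masked_slice` or matrix.
#' @param wavelet One of `"coif1"` (default), `"haar"`, `"db2"`, `"db4"`,
#'   `"sym4"`.
#' @return Object of class `wavelet_coefficients`: list with `coefficients`
#'   (all four subbands, flattened), `subbands` (list `LL`, `LH`, `HL`, `HH`)
#'   and `wavelet`.
#' @export
wavelet_decompose <- function(slice, wavelet = "coif1") {
  x <- masked_image(slice)
  lo <- WAVELET_FILTERS[[wavelet]]
  if (is.null(lo)) stop("unknown wavelet '", wavelet, "'; available: ",
                        paste(names(WAVELET_FILTERS), collapse = ", "))
  if (min(dim(x)) < length(lo))
    stop("slice of size ", paste(dim(x), collapse = "x"),
         " is smaller than the '", wavelet, "' filter length ", length(lo))
  hi <- qmf_highpass(lo)
  a_cols <- dwt_step_cols(x, lo)       # low-pass along rows-direction
  d_cols <- dwt_step_cols(x, hi)
  LL <- t(dwt_step_cols(t(a_cols), lo))
  LH <- t(dwt_step_cols(t(a_cols), hi))
  HL <- t(dwt_step_cols(t(d_cols), lo))
  HH <- t(dwt_step_cols(t(d_cols), hi))
  structure(list(
    coefficients = c(LL, LH, HL, HH),
    subbands = list(LL = LL, LH = LH, HL = HL, HH = HH),
    wavelet = wavelet
  ), class = "wavelet_coefficients")
}

coef_vector <- function(coeffs) {
  if (inherits(coeffs, "wavelet_coefficients")) coeffs$coefficients
  else as.numeric(coeffs)
}

#' Wavelet coefficient sparsity
#'
#' Coefficients whose magnitude is at least the mean magnitude are
#' "significant"; WCS is the mean magnitude of the significant set.  An
#' all-zero coefficient set scores 0.
#'
#' @param coeffs A `wavelet_coefficients` object or numeric vector.
#' @return Non-negative WCS score.
#' @export
wcs <- function(coeffs) {
  m <- abs(coef_vector(coeffs))
  stopifnot(length(m) > 0L)
  sig <- m[m >= mean(m)]
  mean(sig)
}

#' Wavelet quality score
#'
#' Sum over coefficients of magnitude times the cosine of the phase.  For the
#' real-valued DWT used here the phase is 0 or pi, so the score reduces to
#' the plain signed sum of the coefficients.
#'
#' @param coeffs A `wavelet_coefficients` object or numeric vector.
#' @return WQS score (any sign).
#' @export
wqs <- function(coeffs) {
  v <- coef_vector(coeffs)
  stopifnot(length(v) > 0L)
  sum(v)
}

#' Wavelet coefficient energy
#'
#' Mean absolute coefficient magnitude over all subbands.
#'
#' @param coeffs A `wavelet_coefficients` object or numeric vector.
#' @return Non-negative WCE score.
#' @export
wce <- function(coeffs) {
  v <- coef_vector(coeffs)
  stopifnot(length(v) > 0L)
  mean(abs(v))
}
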