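#' @keywords internal
#' @useDynLib mrishift, .registration = TRUE
#' @importFrom Rcpp evalCpp
"_PACKAGE"

# Canonical feature order used everywhere a 22-feature vector appears.
FEATURE_NAMES <- c(
  "MEAN", "RNG", "VAR", "CV", "PSNR", "SNR1", "SNR2", "CNR", "CJV", "EFC",
  "SNRF", "LFR", "HFR",
  "WCS", "WQS", "WCE",
  "Contrast", "Dissimilarity", "ASM", "Homogeneity", "Correlation", "Energy"
)

#' Canonical names of the 22 quality features
#'
#' Fixed column order of every feature table produced by the package:
#' ten spatial-domain features, three frequency-domain features, three
#' wavelet-domain features and six GLCM texture features.
#'
#' @return Character vector of length 22.
#' @export
feature_names <- function() FEATURE_NAMES

# Population (N-divisor) standard deviation / variance; NA-safe length-0.
pop_var <- function(x) {
  if (length(x) == 0L) return(NA_real_)
  mean((x - mean(x))^2)
}
pop_sd <- function(x) sqrt(pop_var(x))

# Deterministic 32-bit sub-seed derived from a base seed and string key.
# Polynomial string hash mod a prime below 2^31; keeps derived seeds valid
# R integer seeds whatever the inputs.
derive_seed <- function(seed, ...) {
  key <- paste(vapply(list(...), as.character, character(1)), collapse = "\r")
  h <- as.double(seed) %% 2147483629
  for (ch in utf8ToInt(key)) h <- (h * 131 + ch) %% 2147483629
  as.integer(h)
}

# Evaluate expr with a local RNG state seeded from `seed`, restoring the
# caller's RNG afterwards.
with_seed <- function(seed, expr) {
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    set.seed(NULL)
  }
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  expr
}

# 2-D convolution of matrix x with a small odd-sized kernel, symmetric
# (edge-replicating mirror) padding, implemented as a sum of shifted copies.
conv2_sym <- function(x, kernel) {
  kr <- (nrow(kernel) - 1L) %/% 2L
  kc <- (ncol(kernel) - 1L) %/% 2L
  nr <- nrow(x); nc <- ncol(x)
  ridx <- c(kr:1, 1:nr, nr:(nr - kr + 1L))[seq_len(nr + 2L * kr)]
  if (kr == 0L) ridx <- 1:nr
  cidx <- c(kc:1, 1:nc, nc:(nc - kc + 1L))[seq_len(nc + 2L * kc)]
  if (kc == 0L) cidx <- 1:nc
  xp <- x[ridx, cidx, drop = FALSE]
  out <- matrix(0, nr, nc)
  for (i in seq_len(nrow(kernel))) {
    for (j in seq_len(ncol(kernel))) {
      w <- kernel[i, j]
      if (w != 0) out <- out + w * xp[(i - 1L) + 1:nr, (j - 1L) + 1:nc]
    }
  }
  out
}

GAUSS3 <- matrix(c(1, 2, 1, 2, 4, 2, 1, 2, 1), 3, 3) / 16
LAPLACE3 <- matrix(c(-1, -1, -1, -1, 8, -1, -1, -1, -1), 3, 3)

# Binary dilation of a logical mask by a (2r+1) square box; pixels outside
# the image count as FALSE.
dilate_mask <- function(mask, r) {
  nr <- nrow(mask); nc <- ncol(mask)
  out <- mask
  for (dr in -r:r) {
    rs <- max(1, 1 + dr):min(nr, nr + dr)
    ro <- rs - dr
    for (dc in -r:r) {
      if (dr == 0L && dc == 0L) next
      cs <- max(1, 1 + dc):min(nc, nc + dc)
      co <- cs - dc
      out[rs, cs] <- out[rs, cs] | mask[ro, co]
    }
  }
  out
}

# Missing-value sentinel policy: features whose preconditions fail are NA,
# never NaN; infinities arising from zero-error degenerates keep +Inf as an
# explicit flag at slice level.
sanitize_feature <- function(x) {
  if (length(x) != 1L || is.na(x) || is.nan(x)) NA_real_ else x
}
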