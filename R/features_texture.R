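# GLCM texture features.  No installed R package provides grey-level
# co-occurrence matrices, so counting is implemented here (vectorized over
# offsets) and verified against a brute-force pair-counting oracle in the
# test suite.

#' Quantize foreground intensities to discrete grey levels
#'
#' Linearly rescales the foreground intensity range onto `0 .. levels - 1`;
#' background pixels get `NA` (an ignore label excluded from co-occurrence
#' counting).  A constant foreground maps entirely to level 0.
#'
#' @param slice A `masked_slice` (or matrix, in which case every pixel is
#'   foreground).
#' @param levels Number of grey levels (>= 2, default 64).
#' @return Integer matrix of levels with `NA` outside the foreground.
#' @export
quantize_levels <- function(slice, levels = 64L) {
  stopifnot(levels >= 2L)
  if (!inherits(slice, "masked_slice"))
    slice <- masked_slice(slice, matrix(TRUE, nrow(slice), ncol(slice)))
  f <- slice$image[slice$fg_mask]
  stopifnot(length(f) > 0L)
  lo <- min(f); hi <- max(f)
  q <- matrix(NA_integer_, nrow(slice$image), ncol(slice$image))
  if (hi == lo) {
    q[slice$fg_mask] <- 0L
  } else {
    lev <- floor((slice$image[slice$fg_mask] - lo) / (hi - lo) * levels)
    q[slice$fg_mask] <- as.integer(pmin(lev, levels - 1L))
  }
  q
}

# Cached level-index grids for glcm_properties().
.glcm_grid_cache <- new.env(parent = emptyenv())
glcm_grids <- function(L) {
  key <- as.character(L)
  g <- .glcm_grid_cache[[key]]
  if (is.null(g)) {
    i <- matrix(0:(L - 1L), L, L)
    g <- list(i = i, j = t(i), d = i - t(i))
    .glcm_grid_cache[[key]] <- g
  }
  g
}

# (drow, dcol) steps for the standard four GLCM angles at a given distance.
glcm_offsets <- function(distance, angles = c(0, 45, 90, 135)) {
  lapply(angles, function(a) {
    switch(as.character(a),
           "0" = c(0L, distance),
           "45" = c(-distance, distance),
           "90" = c(-distance, 0L),
           "135" = c(-distance, -distance),
           stop("angle must be one of 0, 45, 90, 135"))
  })
}

#' Grey-level co-occurrence matrix
#'
#' Counts co-occurrences of grey-level pairs at the given pixel offsets,
#' symmetrizes (adds the transpose), normalizes each angle's matrix to sum 1
#' and averages over the angles (default: the four standard angles at
#' distance 1).  Pairs touching the `NA` ignore label are skipped.
#'
#' @param quantized Integer matrix from [quantize_levels()] (`NA` = ignore).
#' @param levels Number of grey levels.
#' @param distance Offset distance in pixels (default 1).
#' @param angles Subset of `c(0, 45, 90, 135)` degrees.
#' @return Object of class `glcm`: list with `matrix` (levels x levels,
#'   symmetric, sums to 1), `levels`, `distance`, `angles`; or `NULL` when no
#'   offset yields a valid pixel pair.
#' @export
compute_glcm <- function(quantized, levels = max(quantized, na.rm = TRUE) + 1L,
                         distance = 1L, angles = c(0, 45, 90, 135)) {
  nr <- nrow(quantized); nc <- ncol(quantized)
  mats <- list()
  for (off in glcm_offsets(distance, angles)) {
    dr <- off[1]; dc <- off[2]
    r1 <- max(1L, 1L - dr):min(nr, nr - dr)
    c1 <- max(1L, 1L - dc):min(nc, nc - dc)
    if (length(r1) == 0L || length(c1) == 0L) next
    a <- quantized[r1, c1, drop = FALSE]
    b <- quantized[r1 + dr, c1 + dc, drop = FALSE]
    keep <- !is.na(a) & !is.na(b)
    if (!any(keep)) next
    idx <- a[keep] * levels + b[keep] + 1L          # row-major cell index
    counts <- tabulate(idx, nbins = levels * levels)
    m <- matrix(counts, levels, levels, byrow = TRUE)
    m <- m + t(m)                                    # symmetrize
    mats[[length(mats) + 1L]] <- m / sum(m)
  }
  if (length(mats) == 0L) return(NULL)
  avg <- Reduce(`+`, mats) / length(mats)
  structure(list(matrix = avg, levels = levels, distance = distance,
                 angles = angles), class = "glcm")
}

#' Haralick-style properties of a GLCM
#'
#' With `P(i, j)` the normalized symmetric co-occurrence matrix and
#' `mu_i, mu_j, sigma_i, sigma_j` its marginal means and SDs:
#' contrast `= sum (i-j)^2 P`, dissimilarity `= sum |i-j| P`,
#' ASM `= sum P^2`, homogeneity `= sum P / (1 + (i-j)^2)`,
#' correlation `= sum (i-mu_i)(j-mu_j) P / (sigma_i sigma_j)` (defined as 1
#' when a marginal SD vanishes: a constant image is perfectly
#' self-correlated), energy `= sqrt(ASM)`.
#'
#' @param glcm A `glcm` object (or plain normalized matrix).
#' @return Named numeric vector
#'   `c(Contrast, Dissimilarity, ASM, Homogeneity, Correlation, Energy)`.
#' @export
glcm_properties <- function(glcm) {
  P <- if (inherits(glcm, "glcm")) glcm$matrix else glcm
  L <- nrow(P)
  g <- glcm_grids(L)
  i <- g$i; j <- g$j; d <- g$d
  asm <- sum(P^2)
  mu_i <- sum(i * P); mu_j <- sum(j * P)
  var_i <- sum((i - mu_i)^2 * P); var_j <- sum((j - mu_j)^2 * P)
  corr <- if (var_i * var_j == 0) 1
          else sum((i - mu_i) * (j - mu_j) * P) / sqrt(var_i * var_j)
  c(Contrast = sum(d^2 * P),
    Dissimilarity = sum(abs(d) * P),
    ASM = asm,
    Homogeneity = sum(P / (1 + d^2)),
    Correlation = corr,
    Energy = sqrt(asm))
}
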