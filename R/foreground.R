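#' Foreground/background segmentation of a slice
#'
#' Segments the anatomy-containing foreground of a 2-D slice from the air
#' background.  The slice is lightly smoothed with a 3x3 Gaussian kernel,
#' thresholded by Otsu's method, morphologically closed (3x3 box), reduced to
#' its largest connected component and hole-filled.  The background mask is
#' the complement, so the two masks partition the slice.
#'
#' Degenerate inputs are handled without error: an all-zero (or
#' all-non-positive) slice yields an empty foreground flagged unusable; an
#' all-constant positive slice yields a foreground covering the whole slice.
#'
#' @param image 2-D numeric matrix of finite intensities.
#' @return An object of class `masked_slice`: list with elements `image`,
#'   `fg_mask`, `bg_mask` (logical matrices) and `usable` (logical flag).
#' @export
detect_foreground <- function(image) {
  stopifnot(is.matrix(image), all(is.finite(image)))
  rng <- range(image)
  if (rng[2] <= 0) {                       # blank slice
    return(masked_slice(image, matrix(FALSE, nrow(image), ncol(image)),
                        usable = FALSE))
  }
  if (rng[1] == rng[2]) {                  # constant bright slice
    return(masked_slice(image, matrix(TRUE, nrow(image), ncol(image))))
  }
  if (mean(image == 0) > 0.2) {
    # a large exact-zero plateau marks zeroed air (skull-stripped or padded
    # data); the anatomical support is then the nonzero set itself
    mask <- image != 0
  } else {
    sm <- conv2_sym(image, GAUSS3)
    u <- (sm - min(sm)) / (max(sm) - min(sm))
    thr <- EBImage::otsu(EBImage::Image(u), range = c(0, 1))
    mask <- u > thr
  }
  if (!any(mask)) {
    return(masked_slice(image, mask, usable = FALSE))
  }
  kern <- EBImage::makeBrush(3, shape = "box")
  mask <- EBImage::closing(mask * 1, kern) > 0
  lab <- EBImage::bwlabel(mask * 1)
  tab <- tabulate(lab[lab > 0])
  mask <- lab == which.max(tab)
  mask <- EBImage::fillHull(mask * 1) > 0
  masked_slice(image, matrix(as.logical(mask), nrow(image), ncol(image)))
}

masked_slice <- function(image, fg_mask, usable = any(fg_mask)) {
  structure(list(image = image, fg_mask = fg_mask, bg_mask = !fg_mask,
                 usable = usable),
            class = "masked_slice")
}

#' @method print masked_slice
#' @export
print.masked_slice <- function(x, ...) {
  cat(sprintf("<masked_slice> %dx%d, foreground %.1f%%%s\n",
              nrow(x$image), ncol(x$image), 100 * mean(x$fg_mask),
              if (x$usable) "" else " (unusable)"))
  invisible(x)
}

# Lower-triangular all-ones matrices, cached by size, so the integral image
# below is two matrix products instead of apply(cumsum) loops.
.ones_cache <- new.env(parent = emptyenv())
tri_ones <- function(n) {
  key <- as.character(n)
  L <- .ones_cache[[key]]
  if (is.null(L)) {
    L <- matrix(0, n, n)
    L[lower.tri(L, diag = TRUE)] <- 1
    .ones_cache[[key]] <- L
  }
  L
}

# Top-left origins (row, col) of side x side windows lying entirely inside
# `mask`, found with an integral image so the window sum test is O(1) per
# origin.
admissible_origins <- function(mask, side) {
  nr <- nrow(mask); nc <- ncol(mask)
  if (nr < side || nc < side) return(matrix(integer(0), 0, 2))
  s <- tri_ones(nr) %*% mask %*% t(tri_ones(nc))  # s[i, j] = sum mask[1:i,1:j]
  S <- matrix(0, nr + 1L, nc + 1L)
  S[-1, -1] <- s
  r0 <- seq_len(nr - side + 1L)
  c0 <- seq_len(nc - side + 1L)
  wsum <- S[r0 + side, c0 + side, drop = FALSE] -
    S[r0, c0 + side, drop = FALSE] - S[r0 + side, c0, drop = FALSE] +
    S[r0, c0, drop = FALSE]
  ok <- which(wsum == side * side, arr.ind = TRUE)
  ok
}

#' Seeded random square patch inside a region mask
#'
#' Draws one side x side patch uniformly at random among all windows lying
#' entirely inside the requested region of the slice.  The draw is fully
#' determined by `seed`.
#'
#' @param slice A `masked_slice` from [detect_foreground()].
#' @param region `"foreground"` or `"background"`.
#' @param side Patch side length in pixels (default 5).
#' @param seed Integer seed controlling the draw.
#' @return List with `values` (side x side matrix) and `origin`
#'   (row, col of the top-left corner), or `NULL` if the region admits no
#'   fully-interior window (patch-unavailable).
#' @export
sample_square_patch <- function(slice, region = c("foreground", "background"),
                                side = 5L, seed = 1L) {
  stopifnot(inherits(slice, "masked_slice"))
  region <- match.arg(region)
  mask <- if (region == "foreground") slice$fg_mask else slice$bg_mask
  origins <- admissible_origins(mask, side)
  if (nrow(origins) == 0L) return(NULL)
  pick <- with_seed(seed, sample.int(nrow(origins), 1L))
  o <- origins[pick, ]
  list(values = slice$image[o[1] + 0:(side - 1L), o[2] + 0:(side - 1L)],
       origin = c(row = unname(o[1]), col = unname(o[2])))
}
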