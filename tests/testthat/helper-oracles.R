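# Independent brute-force oracles used to pin the feature implementations.
# Everything here is written as literal double loops over definitions, on
# purpose: slow, obvious, and sharing no code with the package internals.

# Slice with every pixel foreground (for formula-level tests).
full_fg_slice <- function(mat) {
  mrishift:::masked_slice(mat, matrix(TRUE, nrow(mat), ncol(mat)))
}

# Slice with explicit masks.
masked <- function(mat, fg) mrishift:::masked_slice(mat, fg)

# Disk phantom slice: value inside a centered disk, 0 outside, plus noise.
disk_slice <- function(n = 64, radius = 20, value = 100, noise_sd = 0,
                       seed = 1) {
  ctr <- (n + 1) / 2
  d2 <- outer((seq_len(n) - ctr)^2, (seq_len(n) - ctr)^2, `+`)
  img <- ifelse(d2 <= radius^2, value, 0)
  set.seed(seed)
  img + matrix(rnorm(n * n, 0, noise_sd), n, n)
}

dice <- function(a, b) 2 * sum(a & b) / (sum(a) + sum(b))

# Entropy-focus criterion straight from the definition.
oracle_efc <- function(mat) {
  x <- as.vector(mat)
  xmax <- sqrt(sum(x^2))
  e <- 0
  for (v in x) {
    p <- abs(v) / xmax
    if (p > 0) e <- e - p * log(p)
  }
  n <- length(x)
  e / (sqrt(n) * log(sqrt(n)))
}

# Symmetric-padding convolution by explicit loops.
oracle_conv <- function(mat, kernel) {
  nr <- nrow(mat); nc <- ncol(mat)
  kr <- (nrow(kernel) - 1) / 2; kc <- (ncol(kernel) - 1) / 2
  reflect <- function(i, n) {
    if (i < 1) return(1 - i)
    if (i > n) return(2 * n - i + 1)
    i
  }
  out <- matrix(0, nr, nc)
  for (i in 1:nr) for (j in 1:nc) {
    acc <- 0
    for (a in -kr:kr) for (b in -kc:kc) {
      acc <- acc + kernel[a + kr + 1, b + kc + 1] *
        mat[reflect(i + a, nr), reflect(j + b, nc)]
    }
    out[i, j] <- acc
  }
  out
}

oracle_spectrum_root_mean <- function(mat, kernel) {
  y <- oracle_conv(mat, kernel)
  amp <- Mod(stats::fft(y))
  mean(sqrt(amp))
}

# SNRF partition by explicit per-bin signed-frequency radius.
oracle_snrf <- function(mat, frac) {
  pw <- Mod(stats::fft(mat))^2
  nr <- nrow(mat); nc <- ncol(mat)
  sf <- function(k, n) if (k - 1 > n %/% 2) (k - 1) - n else k - 1
  r2 <- matrix(0, nr, nc)
  for (i in 1:nr) for (j in 1:nc) r2[i, j] <- sf(i, nr)^2 + sf(j, nc)^2
  inside <- r2 <= frac^2 * max(r2)
  10 * log10(sum(pw[inside]) / sum(pw[!inside]))
}

# GLCM by literal pair counting for one (drow, dcol) offset.
oracle_glcm_one <- function(q, levels, drow, dcol) {
  m <- matrix(0, levels, levels)
  nr <- nrow(q); nc <- ncol(q)
  for (i in 1:nr) for (j in 1:nc) {
    i2 <- i + drow; j2 <- j + dcol
    if (i2 < 1 || i2 > nr || j2 < 1 || j2 > nc) next
    a <- q[i, j]; b <- q[i2, j2]
    if (is.na(a) || is.na(b)) next
    m[a + 1, b + 1] <- m[a + 1, b + 1] + 1
  }
  m <- m + t(m)
  if (sum(m) == 0) return(NULL)
  m / sum(m)
}

oracle_glcm <- function(q, levels, distance = 1,
                        angles = c(0, 45, 90, 135)) {
  steps <- list("0" = c(0, distance), "45" = c(-distance, distance),
                "90" = c(-distance, 0), "135" = c(-distance, -distance))
  mats <- list()
  for (a in as.character(angles)) {
    m <- oracle_glcm_one(q, levels, steps[[a]][1], steps[[a]][2])
    if (!is.null(m)) mats[[length(mats) + 1]] <- m
  }
  Reduce(`+`, mats) / length(mats)
}

# Biased squared MMD by explicit kernel sums.
oracle_mmd <- function(a, b, h) {
  k <- function(x, y) exp(-sum((x - y)^2) / (2 * h^2))
  kaa <- 0; kbb <- 0; kab <- 0
  na <- nrow(a); nb <- nrow(b)
  for (i in 1:na) for (j in 1:na) kaa <- kaa + k(a[i, ], a[j, ])
  for (i in 1:nb) for (j in 1:nb) kbb <- kbb + k(b[i, ], b[j, ])
  for (i in 1:na) for (j in 1:nb) kab <- kab + k(a[i, ], b[j, ])
  kaa / na^2 + kbb / nb^2 - 2 * kab / (na * nb)
}

# Gaussian-feature table generator for classifier/MMD tests: two or more
# domains with configurable per-feature mean shifts.
synthetic_feature_table <- function(n_per_domain, shifts, seed = 1) {
  fn <- feature_names()
  set.seed(seed)
  rows <- list()
  for (d in seq_along(shifts)) {
    m <- matrix(rnorm(n_per_domain * length(fn)), n_per_domain)
    m <- sweep(m, 2, shifts[[d]], `+`)
    colnames(m) <- fn
    rows[[d]] <- data.frame(
      scan_id = sprintf("d%d_%03d", d, seq_len(n_per_domain)),
      m, site = sprintf("site%d", d),
      check.names = FALSE, stringsAsFactors = FALSE)
  }
  do.call(rbind, rows)
}

no_shift <- function() rep(0, 22)
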