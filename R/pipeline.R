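#' Extraction configuration
#'
#' Collects every tunable of the per-slice feature computation in one place.
#'
#' @param planes Planes to slice: subset of axial/coronal/sagittal.
#' @param min_fg_fraction Slices whose foreground covers less than this
#'   fraction of pixels are excluded from aggregation (default 0.01).
#' @param patch_side Side of the random foreground/background patches used by
#'   the SNR2/CNR conventions (default 5).
#' @param bg_erosion Standoff (pixels) of the background noise estimate from
#'   the foreground boundary; see [noise_metrics()] (default 3).
#' @param glcm_levels,glcm_distance,glcm_angles GLCM quantization and offset
#'   settings (defaults: 64 levels, distance 1, four angles averaged).
#' @param wavelet Wavelet for the single-level 2-D DWT (default `"coif1"`).
#' @param snrf_radius Fraction of the maximal spectral radius counted as
#'   signal in SNRF (default 0.25).
#' @param slice_step Keep every `slice_step`-th slice per plane (default 1 =
#'   all slices).
#' @return A list of class `extraction_config`.
#' @export
extraction_config <- function(planes = c("axial", "coronal", "sagittal"),
                              min_fg_fraction = 0.01,
                              patch_side = 5L,
                              bg_erosion = 3L,
                              glcm_levels = 64L,
                              glcm_distance = 1L,
                              glcm_angles = c(0, 45, 90, 135),
                              wavelet = "coif1",
                              snrf_radius = 0.25,
                              slice_step = 1L) {
  planes <- match.arg(planes, several.ok = TRUE)
  stopifnot(min_fg_fraction >= 0, min_fg_fraction < 1,
            patch_side >= 2L, bg_erosion >= 0L, glcm_levels >= 2L,
            glcm_distance >= 1L,
            snrf_radius > 0, snrf_radius < 1, slice_step >= 1L)
  structure(list(planes = planes, min_fg_fraction = min_fg_fraction,
                 patch_side = as.integer(patch_side),
                 bg_erosion = as.integer(bg_erosion),
                 glcm_levels = as.integer(glcm_levels),
                 glcm_distance = as.integer(glcm_distance),
                 glcm_angles = glcm_angles,
                 wavelet = wavelet, snrf_radius = snrf_radius,
                 slice_step = as.integer(slice_step)),
            class = "extraction_config")
}

# All 22 features of one already-segmented slice.  `seed` controls the patch
# draws only.
compute_slice_features <- function(ms, config, seed = 1L) {
  out <- stats::setNames(rep(NA_real_, length(FEATURE_NAMES)), FEATURE_NAMES)
  f <- ms$image[ms$fg_mask]

  out[c("MEAN", "RNG", "VAR")] <- intensity_stats(ms)
  out["CV"] <- coefficient_of_variation(ms)
  out[c("PSNR", "SNR1", "SNR2", "CNR")] <-
    noise_metrics(ms, seed = seed, patch_side = config$patch_side,
                  bg_erosion = config$bg_erosion)
  out["CJV"] <- cjv(ms)
  out["EFC"] <- efc(ms)

  out["SNRF"] <- snrf(ms, config$snrf_radius)
  out["LFR"] <- lfr(ms)
  out["HFR"] <- hfr(ms)

  if (min(dim(ms$image)) >= length(WAVELET_FILTERS[[config$wavelet]])) {
    cf <- wavelet_decompose(ms, config$wavelet)
    out["WCS"] <- wcs(cf)
    out["WQS"] <- wqs(cf)
    out["WCE"] <- wce(cf)
  }

  q <- quantize_levels(ms, config$glcm_levels)
  g <- compute_glcm(q, levels = config$glcm_levels,
                    distance = config$glcm_distance,
                    angles = config$glcm_angles)
  if (!is.null(g)) {
    out[c("Contrast", "Dissimilarity", "ASM", "Homogeneity",
          "Correlation", "Energy")] <- glcm_properties(g)
  }
  out
}

#' Compute the 22-feature vector of one scan
#'
#' Slices the volume along the configured planes, segments each slice,
#' retains slices whose foreground covers at least `min_fg_fraction` of the
#' pixels, computes all 22 features per retained slice, and aggregates each
#' feature as the unweighted mean over all retained slices of all planes.
#' Per-slice values that are missing (`NA`) or non-finite flags (`Inf`) are
#' ignored by the mean; a feature missing on every slice stays `NA`.
#'
#' @param volume An [mri_volume].
#' @param config An [extraction_config()].
#' @param seed Integer seed; patch draws are sub-seeded per
#'   (scan, plane, slice) so results are reproducible scan-by-scan.
#' @return Named numeric vector of the 22 features with attributes
#'   `scan_id` and `n_slices` (retained slice count).  Errors if no slice in
#'   any plane is retained.
#' @export
compute_scan_features <- function(volume, config = extraction_config(),
                                  seed = 1L) {
  stopifnot(inherits(volume, "mri_volume"))
  rows <- list()
  for (plane in config$planes) {
    slices <- extract_slices(volume, plane)
    keep <- seq(1L, length(slices), by = config$slice_step)
    for (i in keep) {
      ms <- detect_foreground(slices[[i]])
      if (!ms$usable || mean(ms$fg_mask) < config$min_fg_fraction) next
      sseed <- derive_seed(seed, volume$scan_id, plane, i)
      rows[[length(rows) + 1L]] <- compute_slice_features(ms, config, sseed)
    }
  }
  if (length(rows) == 0L)
    stop("scan '", volume$scan_id, "' rejected: no slice with foreground >= ",
         config$min_fg_fraction * 100, "% of pixels in any plane")
  m <- do.call(rbind, rows)
  agg <- apply(m, 2, function(col) {
    col <- col[is.finite(col)]
    if (length(col) == 0L) NA_real_ else mean(col)
  })
  structure(agg, scan_id = volume$scan_id, n_slices = nrow(m))
}

#' Extract a feature table from a set of scans
#'
#' Runs [compute_scan_features()] over a directory of NIfTI files, a vector
#' of file paths, or a list of [mri_volume] objects, and returns one row per
#' scan: `scan_id`, the 22 features in canonical order, and any label
#' columns merged from `labels` by `scan_id`.
#'
#' @param input Directory containing `.nii`/`.nii.gz` files, character vector
#'   of paths, or list of [mri_volume] objects.
#' @param labels Optional data frame with a `scan_id` column plus label
#'   columns, or path to such a CSV.
#' @param config An [extraction_config()].
#' @param seed Integer seed for the patch randomness.
#' @param verbose Print one line per scan.
#' @return Data frame feature table; provenance (config, seed, package
#'   version) is attached as attribute `provenance`, and a per-scan log of
#'   retained slice counts and missing-feature flags as attribute
#'   `extraction_log`.
#' @export
extract_features <- function(input, labels = NULL,
                             config = extraction_config(), seed = 1L,
                             verbose = FALSE) {
  volumes <- if (is.list(input) && all(vapply(input, inherits, TRUE,
                                              "mri_volume"))) {
    input
  } else {
    paths <- if (length(input) == 1L && dir.exists(input)) {
      sort(list.files(input, pattern = "\\.nii(\\.gz)?$", full.names = TRUE))
    } else as.character(input)
    if (length(paths) == 0L) stop("no NIfTI files found in ", input)
    lapply(paths, read_volume)
  }
  log <- list()
  rows <- lapply(volumes, function(v) {
    if (verbose) message("extracting ", v$scan_id)
    fv <- compute_scan_features(v, config, seed)
    miss <- names(fv)[is.na(fv)]
    log[[v$scan_id]] <<- data.frame(
      scan_id = attr(fv, "scan_id"),
      n_slices = attr(fv, "n_slices"),
      missing_features = paste(miss, collapse = ";"),
      stringsAsFactors = FALSE)
    data.frame(scan_id = attr(fv, "scan_id"), t(fv),
               check.names = FALSE, stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, rows)
  rownames(tab) <- NULL
  if (anyDuplicated(tab$scan_id))
    stop("duplicate scan_id in input: ",
         tab$scan_id[anyDuplicated(tab$scan_id)])
  if (!is.null(labels)) {
    if (is.character(labels)) labels <- utils::read.csv(labels)
    if (!"scan_id" %in% names(labels))
      stop("labels must contain a 'scan_id' column")
    tab <- merge(tab, labels, by = "scan_id", all.x = TRUE, sort = TRUE)
  }
  attr(tab, "provenance") <- list(
    seed = seed, config = unclass(config),
    version = as.character(utils::packageVersion("mrishift")))
  attr(tab, "extraction_log") <- do.call(rbind, c(log, make.row.names = FALSE))
  tab
}

#' Write / read a feature table as CSV
#'
#' The CSV has a header of `scan_id`, the 22 feature columns in canonical
#' order, then any label columns.  Missing values are written as empty cells
#' and read back as `NA`.  A column-permuted CSV is accepted on read (the
#' header is authoritative) and re-emitted in canonical order.
#'
#' @param table Feature table data frame (must contain `scan_id` and the 22
#'   feature columns).
#' @param path CSV path.
#' @return `write_feature_table()`: `path` invisibly;
#'   `read_feature_table()`: the feature table data frame.
#' @export
write_feature_table <- function(table, path) {
  check_feature_columns(table)
  extra <- setdiff(names(table), c("scan_id", FEATURE_NAMES))
  table <- table[, c("scan_id", FEATURE_NAMES, extra), drop = FALSE]
  utils::write.csv(table, path, row.names = FALSE, na = "")
  invisible(path)
}

#' @rdname write_feature_table
#' @export
read_feature_table <- function(path) {
  tab <- utils::read.csv(path, check.names = FALSE, na.strings = c("", "NA"),
                         stringsAsFactors = FALSE)
  check_feature_columns(tab)
  extra <- setdiff(names(tab), c("scan_id", FEATURE_NAMES))
  tab$scan_id <- as.character(tab$scan_id)
  tab[, c("scan_id", FEATURE_NAMES, extra), drop = FALSE]
}

check_feature_columns <- function(tab) {
  missing <- setdiff(c("scan_id", FEATURE_NAMES), names(tab))
  if (length(missing))
    stop("feature table lacks mandatory column(s): ",
         paste(missing, collapse = ", "))
  invisible(TRUE)
}
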