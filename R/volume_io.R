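#' MRI volume container
#'
#' A minimal in-memory representation of a 3-D structural MRI scan: the voxel
#' array in a canonical RAS-like axis order (axis 1 = left-right, axis 2 =
#' posterior-anterior, axis 3 = inferior-superior), the voxel spacing in mm,
#' and a scan identifier.
#'
#' @param data 3-D numeric array, each dimension of length >= 8, all values
#'   finite.
#' @param spacing Positive numeric vector of length 3, voxel sizes in mm.
#' @param scan_id Character scalar identifying the scan.
#' @param source_path Optional path the volume was read from.
#' @return An object of class `mri_volume`.
#' @export
mri_volume <- function(data, spacing = c(1, 1, 1), scan_id = "scan",
                       source_path = NA_character_) {
  if (!is.array(data) || length(dim(data)) != 3L)
    stop("`data` must be a 3-D array, got ", length(dim(data)), " dimension(s)")
  if (any(dim(data) < 8L))
    stop("each volume dimension must be >= 8; got ",
         paste(dim(data), collapse = "x"))
  storage.mode(data) <- "double"
  if (anyNA(data) || any(!is.finite(data)))
    stop("volume intensities must all be finite")
  spacing <- as.double(spacing)
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0))
    stop("`spacing` must be 3 positive voxel sizes (mm)")
  structure(
    list(data = data, spacing = spacing, scan_id = as.character(scan_id),
         source_path = source_path),
    class = "mri_volume"
  )
}

#' @method print mri_volume
#' @export
print.mri_volume <- function(x, ...) {
  cat(sprintf("<mri_volume> %s: %s voxels, spacing %s mm\n", x$scan_id,
              paste(dim(x$data), collapse = "x"),
              paste(format(x$spacing, digits = 3), collapse = "x")))
  invisible(x)
}

#' @method dim mri_volume
#' @export
dim.mri_volume <- function(x) dim(x$data)

#' Read a NIfTI volume in canonical orientation
#'
#' Reads a NIfTI-1 file (optionally gzipped), reorients the voxel array to the
#' RAS axis order when the header carries a usable qform/sform (files without
#' one are taken as already canonical), casts intensities to double and
#' replaces NaN voxels by 0 with a warning.
#'
#' @param path Path to a `.nii` or `.nii.gz` file.
#' @param scan_id Scan identifier; defaults to the file stem.
#' @return An [mri_volume].
#' @export
read_volume <- function(path, scan_id = NULL) {
  if (!file.exists(path)) stop("no such file: ", path)
  img <- tryCatch(RNifti::readNifti(path),
                  error = function(e) stop("cannot read NIfTI file '", path,
                                           "': ", conditionMessage(e)))
  d <- dim(img)
  if (length(d) == 4L && d[4] == 1L) {
    img <- RNifti::asNifti(array(as.array(img), dim = d[1:3]), reference = img)
    d <- dim(img)
  }
  if (length(d) != 3L)
    stop("expected a 3-D volume, got shape ", paste(d, collapse = "x"),
         " in ", path)
  can_orient <- tryCatch({
    xf <- RNifti::xform(img)
    !is.null(attr(xf, "code")) && attr(xf, "code") > 0
  }, error = function(e) FALSE)
  if (can_orient && !identical(RNifti::orientation(img), "RAS"))
    RNifti::orientation(img) <- "RAS"
  arr <- array(as.double(img), dim = dim(img))
  if (anyNA(arr)) {
    warning("NaN voxels replaced by 0 in ", path)
    arr[is.na(arr)] <- 0
  }
  if (is.null(scan_id))
    scan_id <- sub("\\.nii(\\.gz)?$", "", basename(path))
  sp <- RNifti::pixdim(img)[1:3]
  mri_volume(arr, spacing = sp, scan_id = scan_id, source_path = path)
}

#' Write a volume to NIfTI
#'
#' Writes the voxel array with an RAS sform carrying the voxel spacing, so a
#' subsequent [read_volume()] round-trips both data and spacing.
#'
#' @param volume An [mri_volume].
#' @param path Output path (`.nii` or `.nii.gz`).
#' @return `path`, invisibly.
#' @export
write_volume <- function(volume, path) {
  stopifnot(inherits(volume, "mri_volume"))
  img <- RNifti::asNifti(volume$data)
  RNifti::pixdim(img) <- volume$spacing
  xf <- diag(c(volume$spacing, 1))
  RNifti::sform(img) <- structure(xf, code = 2L)
  RNifti::writeNifti(img, path)
  invisible(path)
}

PLANE_AXIS <- c(sagittal = 1L, coronal = 2L, axial = 3L)

#' Extract all 2-D slices of a volume along an anatomical plane
#'
#' In the canonical axis order, axial slices are taken along axis 3, coronal
#' along axis 2 and sagittal along axis 1, in ascending index order.  Slicing
#' happens in voxel space; no resampling to isotropic spacing is performed.
#'
#' @param volume An [mri_volume].
#' @param plane One of `"axial"`, `"coronal"`, `"sagittal"`.
#' @return List of 2-D matrices, one per slice.
#' @export
extract_slices <- function(volume, plane = c("axial", "coronal", "sagittal")) {
  stopifnot(inherits(volume, "mri_volume"))
  plane <- match.arg(plane)
  ax <- PLANE_AXIS[[plane]]
  n <- dim(volume$data)[ax]
  lapply(seq_len(n), function(i) {
    switch(ax,
           volume$data[i, , ],
           volume$data[, i, ],
           volume$data[, , i])
  })
}
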