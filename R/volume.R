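#' 3-D image volume with voxel geometry
#'
#' A `volume_grid` couples a 3-D numeric array (CT in Hounsfield units or PET
#' in SUV) with its voxel spacing in mm and the world coordinate of the first
#' voxel centre. World coordinates are right-handed, in mm; voxel `(i, j, k)`
#' (1-based) has centre `origin + (c(i, j, k) - 1) * spacing`.
#'
#' @param data 3-D numeric array, indexed `[x, y, z]`.
#' @param spacing Voxel size in mm along x, y, z; all positive.
#' @param origin World coordinate (mm) of the centre of voxel `(1, 1, 1)`.
#' @return A `volume_grid` object.
#' @export
volume_grid <- function(data, spacing, origin = c(0, 0, 0)) {
  if (!is.array(data) || length(dim(data)) != 3L)
    stop("`data` must be a 3-D array")
  spacing <- as.numeric(spacing)
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0))
    stop("`spacing` must be three positive voxel sizes in mm")
  origin <- as.numeric(origin)
  if (length(origin) != 3L || any(!is.finite(origin)))
    stop("`origin` must be three finite world coordinates in mm")
  structure(list(data = data, spacing = spacing, origin = origin),
            class = "volume_grid")
}

#' @export
dim.volume_grid <- function(x) dim(x$data)

#' @export
print.volume_grid <- function(x, ...) {
  cat("<volume_grid> ", paste(dim(x$data), collapse = " x "),
      " voxels @ ", paste(format(x$spacing), collapse = " x "), " mm\n",
      "  value range: [", format(min(x$data)), ", ", format(max(x$data)), "]\n",
      sep = "")
  invisible(x)
}

#' Voxel volume in millilitres
#' @param vol A `volume_grid` or `skeleton_voi`.
#' @return Scalar mL per voxel.
#' @export
voxel_volume_ml <- function(vol) prod(vol$spacing) / 1000

# Physical span [low, high] of the volume along each axis (voxel edges).
volume_extent <- function(vol) {
  lo <- vol$origin - vol$spacing / 2
  hi <- vol$origin + (dim(vol$data) - 1) * vol$spacing + vol$spacing / 2
  rbind(lo = lo, hi = hi)
}

#' Read a volume from a NIfTI file
#'
#' Voxel values are taken as stored (HU or SUV); spacing is read from the
#' header `pixdim` and the origin is fixed at the first voxel centre.
#'
#' @param path Path to a `.nii` / `.nii.gz` file.
#' @return A [volume_grid()].
#' @export
read_volume <- function(path) {
  if (!file.exists(path)) stop("volume file not found: ", path)
  img <- RNifti::readNifti(path)
  if (length(dim(img)) != 3L)
    stop("expected a 3-D NIfTI volume in ", path, " (got ",
         length(dim(img)), " dimensions)")
  volume_grid(array(as.numeric(img), dim(img)), RNifti::pixdim(img))
}

#' Write a volume to a NIfTI file
#'
#' @param vol A [volume_grid()].
#' @param path Output path (`.nii` or `.nii.gz`).
#' @return `path`, invisibly.
#' @export
write_volume <- function(vol, path) {
  stopifnot(inherits(vol, "volume_grid"))
  img <- RNifti::asNifti(vol$data)
  RNifti::pixdim(img) <- vol$spacing
  RNifti::writeNifti(img, path)
  invisible(path)
}
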