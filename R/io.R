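#' Read a 3D NIfTI volume
#'
#' Loads intensities, voxel size and the voxel-to-world affine from a
#' NIfTI-1 file. The enhancement model assumes isotropic voxels;
#' anisotropic input is accepted with a warning and the first voxel
#' dimension is used.
#'
#' @param path path to a `.nii` or `.nii.gz` file.
#' @return a native-resolution `volume_grid`.
#' @export
read_volume <- function(path) {
  img <- tryCatch(RNifti::readNifti(path),
                  error = function(e) stop("cannot read NIfTI file '", path,
                                           "': ", conditionMessage(e)))
  d <- dim(img)
  if (length(d) != 3)
    stop("expected a 3D volume, got ", length(d), "D data; ",
         "4D time series are not supported")
  pd <- RNifti::pixdim(img)[1:3]
  if (max(pd) - min(pd) > 1e-4 * max(pd))
    warning("anisotropic voxels (", paste(signif(pd, 4), collapse = " x "),
            " mm); the method assumes isotropic voxels")
  A <- matrix(as.vector(RNifti::xform(img)), 4, 4) # strip RNifti attributes
  volume_grid(array(as.numeric(img), d), voxel_size_mm = pd[1],
              affine = A, level = "low")
}

#' Extract a region of interest around a seed voxel
#'
#' Cuts a `dims`-sized box centred on a seed coordinate, translating the
#' affine so world coordinates are preserved. An out-of-bounds request
#' is an error (no silent clamping).
#'
#' @param vol a `volume_grid`.
#' @param center_vox integer triple: 0-based voxel coordinates of the
#'   ROI centre in `vol`.
#' @param dims ROI dimensions in voxels (default 22 isotropic; scalar
#'   recycled).
#' @return a `volume_grid` covering the ROI, with provenance in
#'   attribute `"roi"`.
#' @export
extract_roi <- function(vol, center_vox, dims = c(22L, 22L, 22L)) {
  .check_volume(vol)
  dims <- as.integer(rep_len(dims, 3))
  center_vox <- as.integer(rep_len(center_vox, 3))
  stopifnot(all(dims >= 3))
  start <- center_vox - dims %/% 2L # 0-based
  end <- start + dims - 1L
  dv <- dim(vol$data)
  if (any(start < 0L) || any(end >= dv))
    stop(sprintf("ROI [%s]..[%s] exceeds image bounds [%s]",
                 paste(start, collapse = ","), paste(end, collapse = ","),
                 paste(dv - 1L, collapse = ",")))
  sub <- vol$data[(start[1] + 1):(end[1] + 1),
                  (start[2] + 1):(end[2] + 1),
                  (start[3] + 1):(end[3] + 1), drop = FALSE]
  A <- vol$affine
  A[, 4] <- vol$affine %*% c(start, 1)
  out <- volume_grid(sub, vol$voxel_size_mm, affine = A, level = "low")
  attr(out, "roi") <- list(center_vox = center_vox, dims = dims,
                           start_vox = start)
  out
}

#' Write an enhanced volume as NIfTI
#'
#' Writes a high-resolution result with halved voxel size and an affine
#' composed of the ROI translation and any residual averaging-grid
#' shift, so the output overlays the source image in world space.
#'
#' @param vol a `volume_grid` (typically the output of [enhance()]).
#' @param path output `.nii` or `.nii.gz` path.
#' @return `path`, invisibly.
#' @export
write_enhanced <- function(vol, path) {
  .check_volume(vol)
  img <- RNifti::asNifti(vol$data)
  RNifti::pixdim(img) <- rep(vol$voxel_size_mm, 3)
  RNifti::sform(img) <- structure(vol$affine, code = 2L)
  RNifti::qform(img) <- structure(vol$affine, code = 2L)
  tryCatch(RNifti::writeNifti(img, path),
           error = function(e) stop("cannot write '", path, "': ",
                                    conditionMessage(e)))
  invisible(path)
}
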