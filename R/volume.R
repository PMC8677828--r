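#' 3D volume with grid geometry
#'
#' Minimal container for a scalar 3D image: the intensity array, the
#' (isotropic) voxel size in mm, and a 4x4 affine mapping 0-based voxel
#' indices to world coordinates (voxel centres). `resolution_level`
#' tracks whether the grid is at native ("low") or doubled ("high")
#' resolution.
#'
#' @param data numeric 3D array.
#' @param voxel_size_mm isotropic voxel edge length, mm.
#' @param affine optional 4x4 voxel-to-world transform; defaults to a
#'   scaled identity placing the centre of voxel (0,0,0) at
#'   `voxel_size_mm / 2` on each axis.
#' @param level `"low"` or `"high"`.
#' @return a `volume_grid` object.
#' @export
volume_grid <- function(data, voxel_size_mm, affine = NULL,
                        level = c("low", "high")) {
  level <- match.arg(level)
  if (length(dim(data)) != 3) stop("data must be a 3D array")
  if (!all(is.finite(data))) stop("volume contains non-finite values")
  stopifnot(is.numeric(voxel_size_mm), voxel_size_mm > 0)
  if (is.null(affine)) {
    affine <- diag(c(rep(voxel_size_mm, 3), 1))
    affine[1:3, 4] <- voxel_size_mm / 2
  }
  stopifnot(identical(dim(affine), c(4L, 4L)))
  structure(list(data = data, voxel_size_mm = voxel_size_mm,
                 affine = affine, resolution_level = level),
            class = "volume_grid")
}

#' @export
print.volume_grid <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("volume_grid: %d x %d x %d voxels @ %g mm (%s resolution)\n",
              d[1], d[2], d[3], x$voxel_size_mm, x$resolution_level))
  cat(sprintf("  intensity range [%.4g, %.4g], origin (%.2f, %.2f, %.2f) mm\n",
              min(x$data), max(x$data),
              x$affine[1, 4], x$affine[2, 4], x$affine[3, 4]))
  invisible(x)
}

#' @export
dim.volume_grid <- function(x) dim(x$data)

.check_volume <- function(vol) {
  if (!inherits(vol, "volume_grid")) stop("expected a volume_grid")
  invisible(vol)
}

## world coordinate of a (0-based) voxel index triple
.voxel_to_world <- function(vol, ijk) {
  as.vector(vol$affine %*% c(ijk, 1))[1:3]
}

## replicate-pad an array by one voxel on every side
.pad_replicate <- function(a) {
  d <- dim(a)
  p <- array(0, d + 2L)
  p[2:(d[1] + 1), 2:(d[2] + 1), 2:(d[3] + 1)] <- a
  p[1, , ] <- p[2, , ]; p[d[1] + 2, , ] <- p[d[1] + 1, , ]
  p[, 1, ] <- p[, 2, ]; p[, d[2] + 2, ] <- p[, d[2] + 1, ]
  p[, , 1] <- p[, , 2]; p[, , d[3] + 2] <- p[, , d[3] + 1]
  p
}

## all 3x3x3 neighbourhoods (edge-replicated at the borders) as a
## 27 x n_voxels matrix, columns in array (column-major) voxel order
.neighborhood_matrix <- function(a) {
  d <- dim(a)
  p <- .pad_replicate(a)
  V <- prod(d)
  NB <- matrix(0, 27, V)
  r <- 1L
  for (dz in 0:2) for (dy in 0:2) for (dx in 0:2) {
    NB[r, ] <- p[dx + seq_len(d[1]), dy + seq_len(d[2]), dz + seq_len(d[3])]
    r <- r + 1L
  }
  NB
}
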