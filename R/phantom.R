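## ---- phantom specification and rasterization ----------------------------

#' Cube phantom specification
#'
#' Parametric description of the synthetic validation object: a cube of
#' uniform intensity on a uniform background inside an isotropic ROI.
#' The default is a 5.6 mm cube (7 voxels at 0.8 mm) with contrast 1,
#' placed with a half-voxel offset on every axis inside a 22x22x22 ROI,
#' so that every face of the cube lies mid-voxel and produces
#' partial-volume voxels.
#'
#' @param side_mm cube edge length, mm.
#' @param offset_vox sub-voxel placement offset per axis, in native
#'   voxels (scalar recycled).
#' @param contrast cube intensity above background.
#' @param background background intensity.
#' @param roi_dims ROI dimensions in voxels.
#' @param voxel_size_mm native isotropic voxel size, mm.
#' @return a `phantom_spec` object.
#' @export
phantom_spec <- function(side_mm = 5.6, offset_vox = c(0.5, 0.5, 0.5),
                         contrast = 1, background = 0,
                         roi_dims = c(22L, 22L, 22L), voxel_size_mm = 0.8) {
  stopifnot(side_mm > 0, voxel_size_mm > 0, contrast != 0,
            length(roi_dims) == 3, all(roi_dims >= 3))
  offset_vox <- rep_len(offset_vox, 3)
  side_vox <- side_mm / voxel_size_mm
  start_vox <- floor((roi_dims - side_vox) / 2) + offset_vox
  if (any(start_vox < 2) || any(start_vox + side_vox > roi_dims - 2))
    stop("cube does not fit inside the ROI with a 2-voxel margin")
  structure(list(side_mm = side_mm, offset_vox = offset_vox,
                 contrast = contrast, background = background,
                 roi_dims = as.integer(roi_dims),
                 voxel_size_mm = voxel_size_mm,
                 side_vox = side_vox, start_vox = start_vox),
            class = "phantom_spec")
}

## exact overlap fractions of interval [start, start+len) with unit cells
## 0..n-1 (all in voxel units)
.axis_fractions <- function(n, start, len) {
  lo <- pmax(0:(n - 1), start)
  hi <- pmin(1:n, start + len)
  pmax(0, hi - lo)
}

#' Rasterize the cube phantom with exact partial volume
#'
#' Every voxel receives `background + contrast * f` where `f` is the
#' exact geometric overlap fraction of the cube with that voxel (a
#' product of per-axis interval overlaps).
#'
#' @param spec a [phantom_spec()].
#' @return a native-resolution `volume_grid`.
#' @export
rasterize_cube <- function(spec) {
  if (!inherits(spec, "phantom_spec")) stop("spec must be a phantom_spec")
  d <- spec$roi_dims
  fx <- .axis_fractions(d[1], spec$start_vox[1], spec$side_vox)
  fy <- .axis_fractions(d[2], spec$start_vox[2], spec$side_vox)
  fz <- .axis_fractions(d[3], spec$start_vox[3], spec$side_vox)
  frac <- outer(outer(fx, fy), fz)
  volume_grid(spec$background + spec$contrast * frac, spec$voxel_size_mm,
              level = "low")
}

## grid descriptor of a volume (or of the nominal 2x high-res grid)
.grid_of <- function(vol) {
  list(dims = dim(vol$data), voxel = vol$voxel_size_mm, affine = vol$affine)
}

.nominal_highres_grid <- function(spec) {
  v <- spec$voxel_size_mm
  A <- diag(c(rep(v / 2, 3), 1))
  A[1:3, 4] <- v / 4
  list(dims = 2L * spec$roi_dims, voxel = v / 2, affine = A)
}

#' Exact cube mask on a high-resolution grid
#'
#' Rasterizes the phantom cube on a given high-resolution grid (by
#' default the nominal doubled grid) and requires the result to be
#' exactly binary, i.e. every cube face must coincide with a voxel
#' boundary of that grid. With the default half-voxel phantom offset the
#' cube is grid-aligned at doubled resolution, so the exact ground truth
#' is representable.
#'
#' @param spec a [phantom_spec()].
#' @param grid a high-resolution `volume_grid` whose grid to use
#'   (e.g. the output of [enhance()], including any recorded shift), or
#'   `NULL` for the nominal doubled grid.
#' @return a `segmentation_mask`.
#' @export
ground_truth_mask <- function(spec, grid = NULL) {
  if (!inherits(spec, "phantom_spec")) stop("spec must be a phantom_spec")
  g <- if (is.null(grid)) .nominal_highres_grid(spec) else .grid_of(grid)
  ## world-space cube bounds
  v <- spec$voxel_size_mm
  lo_mm <- spec$start_vox * v
  hi_mm <- lo_mm + spec$side_mm
  ## voxel j of the target grid covers [origin + (j - 0.5) * s, ...]
  s <- g$voxel
  orig <- g$affine[1:3, 4] # centre of voxel 0
  fr <- lapply(1:3, function(ax) {
    edges0 <- orig[ax] - s / 2 + s * (0:(g$dims[ax] - 1))
    lo <- pmax(edges0, lo_mm[ax])
    hi <- pmin(edges0 + s, hi_mm[ax])
    pmax(0, hi - lo) / s
  })
  frac <- outer(outer(fr[[1]], fr[[2]]), fr[[3]])
  ## snap away floating-point fuzz from world-coordinate arithmetic
  frac[abs(frac) < 1e-9] <- 0
  frac[abs(frac - 1) < 1e-9] <- 1
  if (!all(frac %in% c(0, 1)))
    stop("cube faces do not align with this grid; a finer truth grid is required")
  segmentation_mask(frac == 1, s, affine = g$affine)
}

## ---- noise ---------------------------------------------------------------

#' Add i.i.d. Gaussian noise to a volume
#'
#' @param vol a `volume_grid`.
#' @param sigma noise standard deviation (intensity units; >= 0).
#' @param seed optional RNG seed for a reproducible draw; the caller's
#'   RNG state is left untouched.
#' @return a `volume_grid` with noise added.
#' @export
add_gaussian_noise <- function(vol, sigma, seed = NULL) {
  .check_volume(vol)
  stopifnot(sigma >= 0)
  if (sigma == 0) return(vol)
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()), add = TRUE)
    set.seed(seed)
  }
  vol$data <- vol$data + array(stats::rnorm(length(vol$data), 0, sigma),
                               dim(vol$data))
  vol
}

## ---- masks and metrics ---------------------------------------------------

#' Binary segmentation mask on a stated grid
#'
#' @param mask logical 3D array.
#' @param voxel_size_mm voxel size of the mask grid.
#' @param affine optional 4x4 voxel-to-world transform.
#' @return a `segmentation_mask`.
#' @export
segmentation_mask <- function(mask, voxel_size_mm, affine = NULL) {
  if (length(dim(mask)) != 3) stop("mask must be a 3D array")
  mask <- array(as.logical(mask), dim(mask))
  if (anyNA(mask)) stop("mask contains NA")
  if (is.null(affine)) {
    affine <- diag(c(rep(voxel_size_mm, 3), 1))
    affine[1:3, 4] <- voxel_size_mm / 2
  }
  structure(list(mask = mask, voxel_size_mm = voxel_size_mm, affine = affine),
            class = "segmentation_mask")
}

#' Half-maximum segmentation with largest-component selection
#'
#' Thresholds a volume at `background + 0.5 * contrast`
#' (polarity-aware: intensities beyond the threshold in the direction of
#' the contrast count as foreground) and keeps the largest 26-connected
#' component.
#'
#' @param vol a `volume_grid`.
#' @param background background intensity.
#' @param contrast object intensity relative to background (non-zero).
#' @return a `segmentation_mask` on the volume's grid.
#' @export
segment_halfmax <- function(vol, background = 0, contrast = 1) {
  .check_volume(vol)
  if (contrast == 0) stop("contrast must be non-zero")
  thr <- background + 0.5 * contrast
  fg <- if (contrast > 0) vol$data >= thr else vol$data <= thr
  if (!any(fg)) stop("half-maximum threshold yields an empty foreground")
  lab <- cpp_label_components(fg, dim(fg))
  sizes <- tabulate(lab)
  keep <- which.max(sizes) # ties: first-encountered component
  segmentation_mask(lab == keep, vol$voxel_size_mm, affine = vol$affine)
}

#' Dice similarity coefficient
#'
#' `DSC = 2 * V_shared / (V_a + V_b)` for two masks on the identical
#' grid.
#'
#' @param a,b `segmentation_mask` objects on the same grid.
#' @return scalar in `[0, 1]`.
#' @export
dice_coefficient <- function(a, b) {
  if (!inherits(a, "segmentation_mask") || !inherits(b, "segmentation_mask"))
    stop("dice_coefficient expects segmentation_mask objects")
  if (!identical(dim(a$mask), dim(b$mask)) ||
      !isTRUE(all.equal(a$voxel_size_mm, b$voxel_size_mm)) ||
      max(abs(a$affine - b$affine)) > 1e-6)
    stop("masks are not on the same grid")
  na <- sum(a$mask); nb <- sum(b$mask)
  if (na + nb == 0) return(1)
  2 * sum(a$mask & b$mask) / (na + nb)
}

#' Volume of a segmentation mask
#'
#' @param mask a `segmentation_mask`.
#' @return volume in mm^3 (voxel count times voxel volume).
#' @export
mask_volume <- function(mask) {
  if (!inherits(mask, "segmentation_mask")) stop("expected a segmentation_mask")
  sum(mask$mask) * mask$voxel_size_mm^3
}

## segment an enhanced (or block-replicated) high-res volume and score it
## against the exact cube truth on the same grid
.phantom_metrics <- function(vol_high, spec) {
  seg <- segment_halfmax(vol_high, spec$background, spec$contrast)
  truth <- ground_truth_mask(spec, grid = vol_high)
  vs <- sum(seg$mask & truth$mask) * seg$voxel_size_mm^3
  list(volume_mm3 = mask_volume(seg),
       dsc = dice_coefficient(truth, seg),
       shared_mm3 = vs,
       truth_mm3 = mask_volume(truth))
}

## ---- experiment runners --------------------------------------------------

.spawn_seeds <- function(master, n) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()), add = TRUE)
  set.seed(master)
  sample.int(.Machine$integer.max, n)
}

## shared machinery: for each sigma x replicate, run the iteration trace
## once and score the requested iteration counts (0 = unprocessed,
## block-replicated)
.run_phantom_experiment <- function(lib, sigmas, iterations, replicates,
                                    seed, spec, verbose = FALSE) {
  if (!inherits(lib, "unit_library")) stop("lib must be a unit_library")
  iterations <- sort(unique(as.integer(iterations)))
  stopifnot(all(iterations >= 0), replicates >= 1)
  base <- rasterize_cube(spec)
  grid_runs <- expand.grid(replicate = seq_len(replicates), sigma = sigmas)
  seeds <- .spawn_seeds(seed, nrow(grid_runs))
  rows <- vector("list", 0L)
  for (r in seq_len(nrow(grid_runs))) {
    sg <- grid_runs$sigma[r]
    rep_i <- grid_runs$replicate[r]
    noisy <- add_gaussian_noise(base, sg, seed = seeds[r])
    outs <- list()
    if (0L %in% iterations) outs[["0"]] <- block_replicate(noisy)
    ks <- iterations[iterations >= 1L]
    if (length(ks)) outs <- c(outs, .enhance_trace(noisy, lib, ks))
    for (k in names(outs)) {
      m <- .phantom_metrics(outs[[k]], spec)
      rows[[length(rows) + 1L]] <- data.frame(
        sigma = sg, iterations = as.integer(k), replicate = rep_i,
        seed = seeds[r], volume_mm3 = m$volume_mm3, dsc = m$dsc,
        shared_mm3 = m$shared_mm3)
    }
    if (verbose) message(sprintf("sigma=%g replicate=%d done", sg, rep_i))
  }
  res <- do.call(rbind, rows)
  res[order(res$sigma, res$iterations, res$replicate), , drop = FALSE]
}

.summarize_cells <- function(res) {
  agg <- stats::aggregate(cbind(volume_mm3, dsc) ~ sigma + iterations,
                          data = res, FUN = function(x) c(mean = mean(x), sd = stats::sd(x)))
  data.frame(sigma = agg$sigma, iterations = agg$iterations,
             volume_mean = agg$volume_mm3[, "mean"],
             volume_sd = agg$volume_mm3[, "sd"],
             dsc_mean = agg$dsc[, "mean"], dsc_sd = agg$dsc[, "sd"])
}

#' Noise-sweep phantom experiment
#'
#' For every noise level, iteration count and replicate: rasterize the
#' phantom, add seeded Gaussian noise, enhance, segment at half maximum,
#' and score volume and Dice coefficient against the exact
#' high-resolution cube. Iteration 0 evaluates the unprocessed volume
#' upsampled by block replication onto the same grid.
#'
#' @param lib a `unit_library`.
#' @param sigmas noise standard deviations (contrast units).
#' @param iterations iteration counts to score (0 allowed).
#' @param replicates replicates per noise level.
#' @param seed master seed; per-run seeds are spawned from it and
#'   recorded in the results.
#' @param spec phantom description.
#' @param out_dir optional directory for `results.csv` / `summary.csv`.
#' @param verbose print progress.
#' @return data frame of per-run results, with the per-cell summary
#'   (mean/SD of volume and DSC) as attribute `"summary"`.
#' @export
run_noise_sweep <- function(lib, sigmas = c(1/16, 1/8, 1/4, 1/2, 1),
                            iterations = c(0L, 1L, 3L, 6L), replicates = 5L,
                            seed = 17L, spec = phantom_spec(),
                            out_dir = NULL, verbose = FALSE) {
  res <- .run_phantom_experiment(lib, sigmas, iterations, replicates, seed,
                                 spec, verbose)
  summ <- .summarize_cells(res)
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    utils::write.csv(res, file.path(out_dir, "results.csv"), row.names = FALSE)
    utils::write.csv(summ, file.path(out_dir, "summary.csv"), row.names = FALSE)
  }
  attr(res, "summary") <- summ
  res
}

#' Iteration-convergence phantom experiment
#'
#' Scores the phantom across a grid of iteration counts at high noise
#' levels and summarises how volume and Dice change between successive
#' counts; convergence shows as shrinking successive differences.
#'
#' @inheritParams run_noise_sweep
#' @return data frame of per-run results; attribute `"summary"` holds
#'   per-cell means/SDs and attribute `"deltas"` the successive absolute
#'   changes of the cell means.
#' @export
run_convergence <- function(lib, sigmas = c(0.5, 1),
                            iterations = c(0L, 6L, 12L, 18L, 24L),
                            replicates = 3L, seed = 17L,
                            spec = phantom_spec(), out_dir = NULL,
                            verbose = FALSE) {
  res <- .run_phantom_experiment(lib, sigmas, iterations, replicates, seed,
                                 spec, verbose)
  summ <- .summarize_cells(res)
  deltas <- do.call(rbind, lapply(split(summ, summ$sigma), function(s) {
    s <- s[s$iterations >= 1L, , drop = FALSE]
    s <- s[order(s$iterations), , drop = FALSE]
    if (nrow(s) < 2) return(NULL)
    data.frame(sigma = s$sigma[-1],
               from = s$iterations[-nrow(s)], to = s$iterations[-1],
               d_volume = abs(diff(s$volume_mean)),
               d_dsc = abs(diff(s$dsc_mean)))
  }))
  rownames(deltas) <- NULL
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    utils::write.csv(res, file.path(out_dir, "results.csv"), row.names = FALSE)
    utils::write.csv(summ, file.path(out_dir, "summary.csv"), row.names = FALSE)
    utils::write.csv(deltas, file.path(out_dir, "deltas.csv"), row.names = FALSE)
  }
  attr(res, "summary") <- summ
  attr(res, "deltas") <- deltas
  res
}
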