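#' @useDynLib edgeup, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

## ---- geometry of the template cube --------------------------------------
## High-resolution templates live on a 6x6x6 voxel grid (half the target
## structure's native voxel size). Voxel centres are taken at
## (-2.5, ..., 2.5) per axis so the cube is centred on the origin;
## downsampling collapses non-overlapping 2x2x2 blocks onto a 3x3x3 grid.

.hr_centers <- function() {
  g <- expand.grid(x = 0:5 - 2.5, y = 0:5 - 2.5, z = 0:5 - 2.5)
  as.matrix(g)
}

## low-res block index (1..27) of each of the 216 high-res voxels
.block_index <- function() {
  g <- expand.grid(x = 0:5, y = 0:5, z = 0:5)
  (g$x %/% 2L) + 3L * (g$y %/% 2L) + 9L * (g$z %/% 2L) + 1L
}

## linear indices of the central 2x2x2 block of the 6x6x6 cube
.center_index <- function() {
  g <- expand.grid(x = 0:5, y = 0:5, z = 0:5)
  which(g$x %in% 2:3 & g$y %in% 2:3 & g$z %in% 2:3)
}

#' Quasi-uniform directions on the unit sphere
#'
#' Fibonacci-lattice point set used to sample plane normals when
#' enumerating one-plane templates.
#'
#' @param n number of directions.
#' @return an `n x 3` matrix of unit vectors.
#' @export
fibonacci_sphere <- function(n) {
  stopifnot(is.numeric(n), length(n) == 1, n >= 1)
  i <- seq_len(n) - 0.5
  phi <- acos(1 - 2 * i / n)
  theta <- pi * (1 + sqrt(5)) * i
  cbind(sin(phi) * cos(theta), sin(phi) * sin(theta), cos(phi))
}

#' Principal lattice directions
#'
#' The signed coordinate axes and body diagonals of the voxel lattice
#' (14 unit vectors), optionally extended with the 12 face diagonals.
#' These are the default plane normals for template enumeration: unlike
#' quasi-random sphere samplings they contain the exact axis directions,
#' so the canonical face/edge/vertex prototypes of the polyhedron model
#' are representable.
#'
#' @param face_diagonals also include the 12 face-diagonal directions.
#' @return a matrix of unit row vectors.
#' @export
principal_directions <- function(face_diagonals = FALSE) {
  g <- as.matrix(expand.grid(x = -1:1, y = -1:1, z = -1:1))
  n1 <- rowSums(abs(g))
  keep <- n1 == 1L | n1 == 3L
  if (face_diagonals) keep <- keep | n1 == 2L
  d <- g[keep, , drop = FALSE]
  dimnames(d) <- NULL
  d / sqrt(rowSums(d^2))
}

#' Plane sampling specification
#'
#' Describes the finite set of candidate planes (normal directions and
#' signed offsets along the normal) used to enumerate one-plane edge
#' templates. Normals default to the principal lattice directions;
#' offsets cover the cube's half-diagonal on a uniform grid.
#'
#' @param normals matrix of plane normals (rows); rows are renormalised
#'   to unit length. Defaults to [principal_directions()]. Any custom
#'   set (e.g. [fibonacci_sphere()]) may be supplied.
#' @param offset_spacing offset grid step, in high-resolution voxels.
#' @return an object of class `plane_sampling`.
#' @export
plane_sampling <- function(normals = principal_directions(),
                           offset_spacing = 1) {
  normals <- as.matrix(normals)
  if (ncol(normals) != 3) stop("normals must have 3 columns")
  if (nrow(normals) == 0) stop("empty sampling spec: no plane normals")
  nrm <- sqrt(rowSums(normals^2))
  if (any(nrm == 0)) stop("zero-length normal in sampling spec")
  normals <- normals / nrm
  stopifnot(offset_spacing > 0)
  half_diag <- 3 * sqrt(3)
  offsets <- seq(-half_diag, half_diag, by = offset_spacing)
  structure(list(normals = normals, offsets = offsets,
                 offset_spacing = offset_spacing),
            class = "plane_sampling")
}

## ---- exact pattern keys --------------------------------------------------
## A pattern's canonical key is its 216-bit string in fixed axis order.
## For speed the bits are packed exactly into five doubles (44 bits
## each, exactly representable well inside the 53-bit integer range of a
## double), which sort and compare identically to the bit string;
## `.pattern_chunks` returns the n x 5 numeric key matrix.
.chunk_weights <- function() {
  W <- matrix(0, 216, 5)
  for (c in 1:5) {
    rows <- ((c - 1) * 44 + 1):min(c * 44, 216)
    W[rows, c] <- 2^(seq(43, by = -1, length.out = length(rows)))
  }
  W
}

.pattern_chunks <- function(M) {
  crossprod(M, .chunk_weights()) # n x 5, exact
}

.pattern_keys <- function(M) {
  K <- .pattern_chunks(M)
  paste(K[, 1], K[, 2], K[, 3], K[, 4], K[, 5], sep = "/")
}

.pattern_order <- function(M) {
  K <- .pattern_chunks(M)
  order(K[, 1], K[, 2], K[, 3], K[, 4], K[, 5])
}

## ---- single-unit surface -------------------------------------------------

.as_edge_unit <- function(pattern, n_planes, planes = NULL) {
  structure(list(pattern = array(as.integer(pattern), dim = c(6, 6, 6)),
                 n_planes = as.integer(n_planes), planes = planes),
            class = "edge_unit")
}

.check_unit <- function(u) {
  if (!inherits(u, "edge_unit")) stop("not an edge_unit")
  p <- u$pattern
  if (!all(p %in% c(0L, 1L))) stop("unit pattern must be binary")
  s <- sum(p)
  if (s == 0 || s == length(p)) stop("unit pattern is constant")
  invisible(u)
}

#' Enumerate one-plane edge templates
#'
#' Generates all unique binarized half-space patterns over the 6x6x6
#' template grid for the planes in a [plane_sampling()] spec. A voxel is
#' 1 iff its centre lies in the closed half-space (for a cubic voxel this
#' is exactly the "mean coverage at least 0.5" rule). Constant patterns
#' and duplicates are removed.
#'
#' @param sampling a [plane_sampling()] object.
#' @return a list of `edge_unit` objects with `n_planes = 1`.
#' @export
enumerate_one_plane_units <- function(sampling) {
  if (!inherits(sampling, "plane_sampling")) stop("sampling must be a plane_sampling object")
  em <- .enum_one_plane_matrix(sampling)
  lapply(seq_len(ncol(em$patterns)), function(j) {
    .as_edge_unit(em$patterns[, j], 1L, planes = list(em$planes[[j]]))
  })
}

## matrix-form enumeration used by build_unit_library
.enum_one_plane_matrix <- function(sampling) {
  G <- .hr_centers()
  proj <- G %*% t(sampling$normals) # 216 x n_normals
  cols <- vector("list", ncol(proj))
  planes <- vector("list", ncol(proj))
  for (j in seq_len(ncol(proj))) {
    P <- outer(proj[, j], sampling$offsets, ">=")
    storage.mode(P) <- "integer"
    s <- colSums(P)
    ok <- s > 0L & s < 216L
    cols[[j]] <- P[, ok, drop = FALSE]
    planes[[j]] <- lapply(sampling$offsets[ok], function(o)
      list(normal = sampling$normals[j, ], offset = o))
  }
  M <- do.call(cbind, cols)
  pl <- do.call(c, planes)
  keep <- !duplicated(.pattern_keys(M))
  list(patterns = M[, keep, drop = FALSE], planes = pl[keep])
}

#' Elementwise product of two edge templates
#'
#' Two- and three-plane templates are built as products of lower-order
#' templates; the product of binary half-space patterns is the indicator
#' of their intersection. A constant product (all 0 or all 1) is invalid
#' and returned as `NULL`.
#'
#' @param a,b `edge_unit` objects.
#' @return an `edge_unit` with `n_planes = a$n_planes + b$n_planes`, or
#'   `NULL` if the product is constant.
#' @export
product_unit <- function(a, b) {
  .check_unit(a); .check_unit(b)
  p <- a$pattern * b$pattern
  s <- sum(p)
  if (s == 0 || s == length(p)) return(NULL)
  .as_edge_unit(p, a$n_planes + b$n_planes, planes = c(a$planes, b$planes))
}

#' Population variance of a binary template
#'
#' For a binary pattern with fraction of ones `p` over all 216 elements
#' the population variance is `p * (1 - p)`. Used by the peripheral-edge
#' filter during library construction.
#'
#' @param u an `edge_unit`.
#' @return scalar variance.
#' @export
unit_variance <- function(u) {
  .check_unit(u)
  p <- mean(u$pattern)
  p * (1 - p)
}

#' Downsample a template to fitting resolution
#'
#' Each of the 27 output values is the mean of the corresponding
#' non-overlapping 2x2x2 block of the 6x6x6 pattern, matching the
#' native-resolution grid the templates are fitted on. The template
#' mean and centred sum of squares `sum(E * (E - mean(E)))` needed by
#' the closed-form fit are cached on the result.
#'
#' @param u an `edge_unit`.
#' @return a `lowres_unit`: list with `values` (3x3x3), `mean`,
#'   `centered_ssq`, and the parent unit.
#' @export
downsample_unit <- function(u) {
  .check_unit(u)
  v <- as.vector(rowsum(as.numeric(u$pattern), .block_index())) / 8
  m <- mean(v)
  structure(list(values = array(v, c(3, 3, 3)), mean = m,
                 centered_ssq = sum(v * (v - m)), parent = u),
            class = "lowres_unit")
}

## ---- library construction ------------------------------------------------

#' Configuration for building a template library
#'
#' @param normals plane-normal matrix for one-plane enumeration, or
#'   `NULL` for [principal_directions()] (see the methods vignette for
#'   how the default was chosen).
#' @param offset_spacing plane offset grid step in high-res voxels.
#' @param variance_cutoff minimum population variance for 2- and 3-plane
#'   templates (scalar, or length 2 giving separate 2- and 3-plane
#'   floors); lower-variance templates — edges at the very periphery of
#'   the template cube — are dropped. The defaults 3/16 and 7/64 are the
#'   variances of the centred quarter-cube and octant, so the edge and
#'   vertex prototypes the polyhedron model is built from always
#'   survive; see the methods vignette.
#' @param max_planes maximum planes per template (1, 2 or 3).
#' @return a `library_config` list.
#' @export
library_config <- function(normals = NULL, offset_spacing = 1,
                           variance_cutoff = c(3 / 16, 7 / 64),
                           max_planes = 3L) {
  variance_cutoff <- rep_len(variance_cutoff, 2)
  stopifnot(all(variance_cutoff >= 0), all(variance_cutoff < 0.25),
            max_planes %in% 1:3)
  structure(list(normals = normals, offset_spacing = offset_spacing,
                 variance_cutoff = variance_cutoff,
                 max_planes = as.integer(max_planes),
                 format_version = 1L),
            class = "library_config")
}

#' Build the 1/2/3-plane edge template library
#'
#' Enumerates one-plane half-space templates, forms two-plane templates
#' as products of pairs of one-plane templates and three-plane templates
#' as products of one- and two-plane templates, removes constant
#' patterns, applies the variance filter to 2- and 3-plane templates,
#' deduplicates on the full high-resolution pattern, downsamples every
#' survivor, and orders units deterministically (by number of planes,
#' then by the canonical 216-bit pattern key).
#'
#' @param config a [library_config()].
#' @param verbose print per-level counts while building.
#' @return a `unit_library`: high-res patterns (216 x n), per-unit plane
#'   counts, low-res template matrix (27 x n) with cached fit statistics,
#'   central 2x2x2 blocks (8 x n), counts by plane number, and the
#'   generating config.
#' @export
build_unit_library <- function(config = library_config(), verbose = FALSE) {
  if (!inherits(config, "library_config")) stop("config must be a library_config")
  normals <- if (is.null(config$normals)) principal_directions() else config$normals
  sampling <- plane_sampling(normals, config$offset_spacing)
  vc2 <- config$variance_cutoff[1]
  vc3 <- config$variance_cutoff[2]
  M1 <- .enum_one_plane_matrix(sampling)$patterns
  n1 <- ncol(M1)
  if (n1 == 0) stop("library generation produced no one-plane units")
  if (verbose) message("one-plane units: ", n1)

  M2 <- NULL
  M3 <- NULL
  if (config$max_planes >= 2L) {
    ## a product's fraction of ones cannot exceed either factor's, so
    ## only factors with variance-feasible p can contribute survivors;
    ## this pruning is exact, it removes no admissible product
    p1 <- colSums(M1) / 216
    F12 <- M1[, p1 >= .p_floor(vc2), drop = FALSE]
    keys1 <- .pattern_keys(M1)
    M2 <- .product_level(F12, F12, vc2, exclude = keys1, pairs = "upper")
    if (verbose) message("two-plane units: ", ncol(M2))
    if (config$max_planes >= 3L && ncol(M2) > 0) {
      F13 <- M1[, p1 >= .p_floor(vc3), drop = FALSE]
      M3 <- .product_level(F13, M2, vc3,
                           exclude = c(keys1, .pattern_keys(M2)),
                           pairs = "all")
      if (verbose) message("three-plane units: ", ncol(M3))
    }
  }

  counts <- c(`1` = n1, `2` = if (is.null(M2)) 0L else ncol(M2),
              `3` = if (is.null(M3)) 0L else ncol(M3))
  M <- cbind(M1, M2, M3)
  np <- rep(1:3, counts)
  ## canonical deterministic ordering within each plane level
  ord <- unlist(lapply(1:3, function(k) {
    w <- which(np == k)
    w[.pattern_order(M[, w, drop = FALSE])]
  }), use.names = FALSE)
  M <- M[, ord, drop = FALSE]
  np <- np[ord]
  .finalize_library(M, np, counts, config)
}

## smallest fraction of ones compatible with a variance floor
.p_floor <- function(vc) (1 - sqrt(1 - 4 * vc)) / 2

## products of every column of A with columns of B; constant patterns and
## patterns below the variance cutoff dropped; dedup against `exclude`
## keys and within the level. pairs = "upper" restricts to unordered
## pairs of distinct columns when A and B are the same matrix.
.product_level <- function(A, B, vcut, exclude, pairs = c("all", "upper")) {
  pairs <- match.arg(pairs)
  seen <- new.env(hash = TRUE, parent = emptyenv())
  for (k in exclude) assign(k, TRUE, envir = seen)
  out <- vector("list", 0L)
  nA <- ncol(A)
  for (a in seq_len(nA)) {
    Bcols <- if (pairs == "upper") {
      if (a >= ncol(B)) break
      B[, (a + 1):ncol(B), drop = FALSE]
    } else B
    P <- Bcols * A[, a]
    s <- colSums(P)
    p <- s / 216
    keep <- s > 0L & (p * (1 - p)) >= vcut
    if (!any(keep)) next
    P <- P[, keep, drop = FALSE]
    kk <- .pattern_keys(P)
    fresh <- !duplicated(kk)
    fresh[fresh] <- !vapply(kk[fresh], exists, logical(1),
                            envir = seen, inherits = FALSE)
    if (!any(fresh)) next
    P <- P[, fresh, drop = FALSE]
    for (k in kk[fresh]) assign(k, TRUE, envir = seen)
    out[[length(out) + 1L]] <- P
  }
  if (!length(out)) {
    m <- matrix(0L, 216, 0)
  } else {
    m <- do.call(cbind, out)
  }
  m
}

.finalize_library <- function(M, np, counts, config) {
  storage.mode(M) <- "integer"
  bi <- .block_index()
  E <- rowsum(M + 0, bi) / 8 # 27 x n low-res values
  Em <- colMeans(E)
  Ec <- sweep(E, 2, Em)
  SEE <- colSums(E * Ec)
  structure(list(patterns = M, n_planes = as.integer(np),
                 lowres = E, lowres_mean = Em, lowres_centered = Ec,
                 lowres_cssq = SEE, center = M[.center_index(), , drop = FALSE],
                 counts_by_nplanes = counts, config = config),
            class = "unit_library")
}

#' @export
print.unit_library <- function(x, ...) {
  cat("Edge template library:", ncol(x$patterns), "units",
      sprintf("(1-plane %d, 2-plane %d, 3-plane %d)\n",
              x$counts_by_nplanes[1], x$counts_by_nplanes[2],
              x$counts_by_nplanes[3]))
  cat("  normals:", if (is.null(x$config$normals)) "principal directions"
      else paste(nrow(x$config$normals), "explicit"),
      "| offset spacing:", x$config$offset_spacing,
      "| variance cutoffs:", paste(signif(x$config$variance_cutoff, 4),
                                   collapse = "/"), "\n")
  invisible(x)
}

#' Number of units in a library
#' @param lib a `unit_library`.
#' @return integer count.
#' @export
library_size <- function(lib) ncol(lib$patterns)

## ---- persistence ---------------------------------------------------------

#' Save / load a template library
#'
#' Libraries are persisted as JSON with the binary patterns packed to
#' base64; the generating configuration and a format version travel with
#' the file, and the round trip is exact (cached statistics are
#' recomputed deterministically from the patterns).
#'
#' @param lib a `unit_library`.
#' @param path file path (conventionally `.json`).
#' @return `load_unit_library` returns the restored `unit_library`.
#' @export
save_unit_library <- function(lib, path) {
  if (!inherits(lib, "unit_library")) stop("lib must be a unit_library")
  bits <- as.logical(lib$patterns)
  payload <- list(
    format = "edgeup-unit-library",
    version = lib$config$format_version,
    n_units = ncol(lib$patterns),
    n_planes = lib$n_planes,
    counts_by_nplanes = as.integer(lib$counts_by_nplanes),
    config = lib$config[c("offset_spacing", "variance_cutoff", "max_planes")],
    normals = if (is.null(lib$config$normals)) NULL else
      as.vector(lib$config$normals),
    patterns = jsonlite::base64_enc(packBits(bits, type = "raw"))
  )
  writeLines(jsonlite::toJSON(payload, auto_unbox = TRUE, digits = NA), path)
  invisible(path)
}

#' @rdname save_unit_library
#' @export
load_unit_library <- function(path) {
  payload <- tryCatch(jsonlite::fromJSON(path),
                      error = function(e) stop("corrupt or unreadable library file: ",
                                               conditionMessage(e)))
  if (!identical(payload$format, "edgeup-unit-library"))
    stop("not an edgeup unit library file")
  if (!identical(as.integer(payload$version), 1L))
    stop("unsupported library format version: ", payload$version)
  n <- as.integer(payload$n_units)
  raw <- jsonlite::base64_dec(payload$patterns)
  bits <- as.integer(rawToBits(raw))
  if (length(bits) < 216L * n) stop("corrupt library file: truncated pattern data")
  M <- matrix(bits[seq_len(216L * n)], nrow = 216L)
  np <- as.integer(payload$n_planes)
  if (length(np) != n) stop("corrupt library file: plane-count mismatch")
  cfg <- library_config(
    normals = if (is.null(payload$normals)) NULL else
      matrix(payload$normals, ncol = 3),
    offset_spacing = payload$config$offset_spacing,
    variance_cutoff = payload$config$variance_cutoff,
    max_planes = payload$config$max_planes
  )
  counts <- as.integer(payload$counts_by_nplanes)
  if (!identical(as.integer(tabulate(np, 3L)), counts))
    stop("corrupt library file: counts do not match plane labels")
  names(counts) <- as.character(1:3)
  .finalize_library(M, np, counts, cfg)
}
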