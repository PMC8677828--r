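## shared fixtures, built once per test session

.eu_cache <- new.env(parent = emptyenv())

eu_memo <- function(key, fn) {
  if (!exists(key, envir = .eu_cache)) assign(key, fn(), envir = .eu_cache)
  get(key, envir = .eu_cache)
}

## full default library (principal directions, default cutoffs)
eu_default_lib <- function() eu_memo("default", function() build_unit_library())

## axis-only normals, half-voxel offsets: small library with a fully
## enumerable structure, used for brute-force oracles
eu_axis_normals <- function() {
  rbind(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0), c(0, -1, 0),
        c(0, 0, 1), c(0, 0, -1))
}

eu_axis_lib <- function() eu_memo("axis", function() {
  build_unit_library(library_config(normals = eu_axis_normals(),
                                    offset_spacing = 0.5))
})

## deterministic 50-unit sub-library for fit-layer oracle tests
eu_sub_lib <- function(n = 50) {
  lib <- eu_default_lib()
  idx <- seq(1, library_size(lib), length.out = n)
  idx <- unique(as.integer(round(idx)))
  edgeup:::.finalize_library(lib$patterns[, idx, drop = FALSE],
                             lib$n_planes[idx],
                             tabulate(lib$n_planes[idx], 3L),
                             lib$config)
}

## results of the desk-scale noise sweep (shared by several tests)
eu_sweep <- function() eu_memo("sweep", function() {
  run_noise_sweep(eu_default_lib(), sigmas = c(1/16, 1/8, 1/4, 1/2, 1),
                  iterations = c(0L, 6L), replicates = 5L, seed = 17L)
})

## one edge_unit built from a 6x6x6 binary array
eu_unit <- function(pattern, n_planes = 1L) {
  edgeup:::.as_edge_unit(pattern, n_planes)
}

## reference (brute force) fit of a neighbourhood against every library
## unit: minimal SSR, ties to the lowest index
eu_brute_best <- function(I, lib) {
  n <- library_size(lib)
  ssr <- K <- B <- numeric(n)
  for (j in seq_len(n)) {
    f <- fit_unit(I, lib$lowres[, j])
    ssr[j] <- f$SSR; K[j] <- f$K; B[j] <- f$B
  }
  j <- which.min(ssr) # first minimum = lowest index
  list(unit_index = j, K = K[j], B = B[j], SSR = ssr[j])
}
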