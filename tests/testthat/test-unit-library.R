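test_that("one-plane enumeration matches the exhaustive axis-aligned oracle", {
  ## oracle: along one axis the only half-space patterns are "top k" /
  ## "bottom k" layer stacks, k = 1..5 (constants excluded); over the six
  ## signed axis normals that is 10 distinct patterns per axis, 30 total
  oracle <- list()
  for (ax in 1:3) for (dir in c(1, -1)) for (k in 1:5) {
    idx <- expand.grid(x = 0:5, y = 0:5, z = 0:5)[[ax]]
    on <- if (dir == 1) idx >= (6 - k) else idx <= (k - 1)
    oracle[[length(oracle) + 1]] <- paste(as.integer(on), collapse = "")
  }
  oracle <- unique(unlist(oracle))
  expect_length(oracle, 30)

  units <- enumerate_one_plane_units(
    plane_sampling(normals = eu_axis_normals(), offset_spacing = 0.5))
  got <- vapply(units, function(u) paste(as.integer(u$pattern), collapse = ""),
                character(1))
  expect_setequal(got, oracle)
})

test_that("a centre plane yields the half-on pattern with variance 1/4", {
  units <- enumerate_one_plane_units(
    plane_sampling(normals = matrix(c(0, 0, 1), 1), offset_spacing = 0.5))
  ## find the pattern with equal halves
  ps <- vapply(units, function(u) mean(u$pattern), numeric(1))
  u <- units[[which(ps == 0.5)[1]]]
  expect_equal(sum(u$pattern[, , 1:3]), 0)  # bottom three layers off
  expect_equal(sum(u$pattern[, , 4:6]), 108)
  expect_equal(unit_variance(u), 0.25)
})

test_that("planes outside the cube produce no units", {
  ## offsets far beyond the half-diagonal give constant patterns only
  s <- plane_sampling(normals = matrix(c(0, 0, 1), 1), offset_spacing = 0.5)
  s$offsets <- c(-100, 100)
  expect_length(enumerate_one_plane_units(s), 0)
})

test_that("product_unit follows binary-product algebra", {
  z <- eu_unit(array(rep(rep(c(1L, 0L), c(3, 3)), each = 36), c(6, 6, 6)))
  ## idempotence: a * a keeps the pattern
  expect_equal(product_unit(z, z)$pattern, z$pattern)
  expect_equal(product_unit(z, z)$n_planes, 2L)
  ## disjoint half-spaces: constant zero product is dropped
  zc <- eu_unit(1L - z$pattern)
  expect_null(product_unit(z, zc))
  ## orthogonal centre planes: quarter-cube slab, p = 1/4
  g <- expand.grid(x = 0:5, y = 0:5, z = 0:5)
  uy <- eu_unit(array(as.integer(g$y >= 3), c(6, 6, 6)))
  uz <- eu_unit(array(as.integer(g$z >= 3), c(6, 6, 6)))
  q <- product_unit(uy, uz)
  expect_equal(mean(q$pattern), 0.25)
  expect_equal(q$pattern, array(as.integer(g$y >= 3 & g$z >= 3), c(6, 6, 6)))
  expect_equal(unit_variance(q), 0.1875)
})

test_that("population variance is p(1-p) over the 216 voxels", {
  g <- expand.grid(x = 0:5, y = 0:5, z = 0:5)
  u <- eu_unit(array(as.integer(g$x >= 3 & g$y >= 3), c(6, 6, 6)), 2L)
  expect_equal(mean(u$pattern), 54 / 216)
  expect_equal(unit_variance(u), 0.25 * 0.75)
})

test_that("downsampling is block-mean with exact conservation", {
  g <- expand.grid(x = 0:5, y = 0:5, z = 0:5)
  ## block-aligned plane (between layers 1 and 2): boundaries coincide
  ## with the downsampling blocks -> strictly binary result
  u <- eu_unit(array(as.integer(g$z >= 2), c(6, 6, 6)))
  d <- downsample_unit(u)
  expect_true(all(d$values %in% c(0, 1)))
  expect_identical(mean(d$values), mean(u$pattern))
  ## mid-block (centre) plane: the middle layer is exactly one half
  u2 <- eu_unit(array(as.integer(g$z >= 3), c(6, 6, 6)))
  d2 <- downsample_unit(u2)
  expect_equal(unique(as.vector(d2$values[, , 2])), 0.5)
  expect_equal(as.vector(d2$values[1, 1, ]), c(0, 0.5, 1))
  expect_identical(mean(d2$values), mean(u2$pattern))
  ## cached statistics
  expect_equal(d2$mean, mean(d2$values))
  expect_equal(d2$centered_ssq, sum(d2$values * (d2$values - mean(d2$values))))
  expect_gt(d2$centered_ssq, 0)
})

test_that("library construction is deterministic, deduplicated and filtered", {
  cfg <- library_config(normals = eu_axis_normals(), offset_spacing = 0.5)
  lib1 <- build_unit_library(cfg)
  lib2 <- build_unit_library(cfg)
  expect_identical(lib1$patterns, lib2$patterns)
  expect_identical(lib1$n_planes, lib2$n_planes)
  expect_identical(lib1$counts_by_nplanes, lib2$counts_by_nplanes)
  ## no duplicate high-resolution patterns
  expect_false(any(duplicated(edgeup:::.pattern_keys(lib1$patterns))))
  ## no constant units, and variance floors hold for 2-/3-plane units
  p <- colSums(lib1$patterns) / 216
  expect_true(all(p > 0 & p < 1))
  v <- p * (1 - p)
  expect_true(all(v[lib1$n_planes == 2] >= cfg$variance_cutoff[1]))
  expect_true(all(v[lib1$n_planes == 3] >= cfg$variance_cutoff[2]))
  ## ordering: plane counts non-decreasing, canonical key order within
  expect_true(all(diff(lib1$n_planes) >= 0))
})

test_that("denser offset sampling never loses one-plane patterns", {
  counts <- vapply(c(1, 0.5, 0.25), function(sp) {
    length(enumerate_one_plane_units(
      plane_sampling(normals = eu_axis_normals(), offset_spacing = sp)))
  }, numeric(1))
  expect_true(all(diff(counts) >= 0))
  ## axis patterns are exhausted already at half-voxel spacing
  expect_equal(counts[2], counts[3])
})

test_that("unit counts per plane level are reported (reference 109/768/34048)", {
  lib <- eu_default_lib()
  counts <- lib$counts_by_nplanes
  ## the enumeration convention of the reference counts is unspecified;
  ## counts are logged for comparison, not asserted
  cat(sprintf("\n  library counts [1/2/3-plane]: %d/%d/%d (reference 109/768/34048)\n",
              counts[1], counts[2], counts[3]))
  expect_true(all(counts > 0))
  expect_identical(as.integer(tabulate(lib$n_planes, 3)), as.integer(counts))
})

test_that("library save/load round-trips exactly and rejects corrupt files", {
  lib <- eu_axis_lib()
  path <- tempfile(fileext = ".json")
  save_unit_library(lib, path)
  back <- load_unit_library(path)
  expect_identical(back$patterns, lib$patterns)
  expect_identical(back$n_planes, lib$n_planes)
  expect_identical(back$lowres, lib$lowres)
  expect_identical(back$lowres_cssq, lib$lowres_cssq) # full precision
  expect_identical(back$center, lib$center)
  expect_equal(back$config$normals, lib$config$normals)
  expect_equal(back$config$variance_cutoff, lib$config$variance_cutoff)

  ## truncation must be an explicit error, not a silent partial library
  txt <- readLines(path)
  writeLines(substr(paste(txt, collapse = ""), 1, 200), path)
  expect_error(load_unit_library(path), "corrupt|truncated|unexpected")

  ## wrong format
  writeLines('{"format": "something-else"}', path)
  expect_error(load_unit_library(path), "not an edgeup")
})
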