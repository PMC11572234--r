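test_that("NIfTI masks round-trip with geometry and binarize correctly", {
  arr <- array(0, dim = c(6, 5, 4))
  arr[2, 2, 2] <- 0.2
  arr[3, 3, 3] <- 0.7
  arr[4, 4, 4] <- 1
  attr(arr, "pixdim") <- c(0.86, 0.86, 3)
  img <- RNifti::asNifti(arr)
  path <- tempfile(fileext = ".nii.gz")
  RNifti::writeNifti(img, path)

  m <- read_mask(path, threshold = 0.5)
  expect_equal(m$geometry$dims, c(6L, 5L, 4L))
  expect_equal(m$geometry$spacing, c(0.86, 0.86, 3), tolerance = 1e-6)
  # probabilistic map: only the 0.7 and 1.0 voxels survive threshold 0.5
  expect_equal(n_voxels(m), 2L)
  expect_true(m$data[3, 3, 3] && m$data[4, 4, 4])
  expect_false(m$data[2, 2, 2])

  # hard 0/1 volume passes through unchanged at the default threshold
  m0 <- read_mask(path, threshold = 0)
  expect_equal(n_voxels(m0), 3L)

  # derived mask written with the source header is bit-compatible
  out <- tempfile(fileext = ".nii.gz")
  write_mask(m, out)
  m2 <- read_mask(out)
  expect_equal(m2$data, m$data)
  expect_equal(m2$geometry$spacing, m$geometry$spacing, tolerance = 1e-6)

  expect_error(read_mask(tempfile(fileext = ".nii")), "cannot read")
  arr4 <- array(0, dim = c(4, 4, 4, 2))
  p4 <- tempfile(fileext = ".nii.gz")
  RNifti::writeNifti(RNifti::asNifti(arr4), p4)
  expect_error(read_mask(p4), "3D")
})

test_that("mask volume follows voxel count times physical voxel volume", {
  g <- vol_geom(c(12, 12, 12), c(0.86, 0.86, 3))
  vox <- as.matrix(expand.grid(1:10, 1:10, 1))      # 100 voxels
  m <- mask_from_voxels(vox, c(12, 12, 12), c(0.86, 0.86, 3))
  expect_equal(mask_volume_ml(m), 100 * 0.86 * 0.86 * 3 / 1000,
               tolerance = 1e-12)
  expect_equal(mask_volume_ml(m), 0.22188, tolerance = 1e-9)

  empty <- binary_mask(array(FALSE, c(12, 12, 12)), g)
  expect_equal(mask_volume_ml(empty), 0)

  cube <- mask_from_voxels(as.matrix(expand.grid(1:10, 1:10, 1:10)),
                           c(12, 12, 12), c(1, 1, 1))
  expect_equal(mask_volume_ml(cube), 1)

  # additivity over disjoint masks
  set.seed(1)
  a <- array(runif(12^3) < 0.2, c(12, 12, 12))
  b <- array(runif(12^3) < 0.2, c(12, 12, 12)) & !a
  expect_equal(mask_volume_ml(binary_mask(a | b, g)),
               mask_volume_ml(binary_mask(a, g)) +
                 mask_volume_ml(binary_mask(b, g)))

  # invariance under axis permutation with matching spacing permutation
  gp <- vol_geom(c(12, 12, 12), c(3, 0.86, 0.86))
  mp <- binary_mask(aperm(m$data, c(3, 1, 2)), gp)
  expect_equal(mask_volume_ml(mp), mask_volume_ml(m))
})

test_that("connected components match a flood-fill oracle and adjacency rules", {
  dims <- c(8, 8, 8)
  face <- mask_from_voxels(rbind(c(2, 2, 2), c(3, 2, 2)), dims)
  expect_equal(connected_components(face, 6)$n, 1L)

  corner <- mask_from_voxels(rbind(c(2, 2, 2), c(3, 3, 3)), dims)
  expect_equal(connected_components(corner, 6)$n, 2L)
  expect_equal(connected_components(corner, 26)$n, 1L)

  expect_error(connected_components(face, 18), "connectivity")

  for (conn in c(6, 26)) {
    set.seed(42 + conn)
    m <- binary_mask(array(runif(16^3) < 0.3, c(16, 16, 16)),
                     vol_geom(c(16, 16, 16)))
    cc <- connected_components(m, conn)
    oracle <- flood_fill_oracle(m, conn)
    mine <- cc$labels[which(m$data)]
    expect_equal(cc$n, max(oracle))
    expect_true(same_partition(mine, oracle))
    # every true voxel has exactly one positive label
    expect_true(all(mine >= 1L))
    expect_equal(sum(cc$labels > 0), n_voxels(m))
  }
})

test_that("distance field is exact under anisotropic spacing", {
  dims <- c(9, 9, 9)
  m <- mask_from_voxels(rbind(c(5, 5, 5)), dims, c(1, 1, 3))
  d <- distance_field(m)
  expect_equal(d$values[5, 5, 5], 0)
  expect_equal(d$values[5, 5, 6], 3)        # one step along the 3 mm axis
  expect_equal(d$values[6, 6, 5], sqrt(2))  # in-plane diagonal at 1 mm
  expect_true(all(d$values >= 0))

  set.seed(7)
  r <- binary_mask(array(runif(12^3) < 0.04, c(12, 12, 12)),
                   vol_geom(c(12, 12, 12), c(0.86, 0.86, 3)))
  if (n_voxels(r) == 0) r$data[3, 4, 5] <- TRUE
  bf <- brute_force_distance(r)
  co <- as.matrix(expand.grid(1:12, 1:12, 1:12))
  expect_lt(max(abs(bf - distance_field(r)$values[co])), 1e-9)

  empty <- binary_mask(array(FALSE, dims), vol_geom(dims))
  expect_error(distance_field(empty), "empty")
})

test_that("geometry constructors validate their invariants", {
  expect_error(vol_geom(c(4, 4), c(1, 1, 1)), "dims")
  expect_error(vol_geom(c(4, 4, 4), c(1, -1, 1)), "spacing")
  expect_error(vol_geom(c(4, 4, 4), c(1, Inf, 1)), "spacing")
  expect_error(binary_mask(array(TRUE, c(3, 3)), vol_geom(c(3, 3, 3))), "3D")
  expect_error(binary_mask(array(NA, c(3, 3, 3)), vol_geom(c(3, 3, 3))),
               "binary")
  g1 <- vol_geom(c(4, 4, 4), c(1, 1, 2))
  g2 <- vol_geom(c(4, 4, 4), c(1, 1, 2.5))
  expect_true(geom_compatible(g1, g1))
  expect_false(geom_compatible(g1, g2))
})
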