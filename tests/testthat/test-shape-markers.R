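test_that("convex hull metrics are exact for cuboids and dominate the body", {
  for (dims in list(c(10, 6, 4), c(5, 5, 5), c(12, 3, 7))) {
    cub <- cuboid_mask(dims[1], dims[2], dims[3])
    h <- convex_hull_metrics(cub)
    a <- dims[1]; b <- dims[2]; c_ <- dims[3]
    expect_equal(h$volume, a * b * c_, tolerance = 1e-10)
    expect_equal(h$area, 2 * (a * b + b * c_ + c_ * a), tolerance = 1e-10)
    expect_equal(solidity(list(V = a * b * c_, V_H = h$volume)), 1)
  }
  # physical spacing scales hull volume and area correctly
  cub <- cuboid_mask(10, 6, 4, spacing = c(0.86, 0.86, 3))
  h <- convex_hull_metrics(cub)
  expect_equal(h$volume, (10 * 0.86) * (6 * 0.86) * (4 * 3), tolerance = 1e-9)

  # two separated voxels: hull spans the gap
  two <- mask_from_voxels(rbind(c(2, 2, 2), c(8, 6, 5)), c(10, 10, 10))
  h2 <- convex_hull_metrics(two)
  expect_gt(h2$volume, 2)

  # hull dominance on irregular lesions
  for (s in 1:5) {
    les <- make_lesion(vol_geom(c(48, 48, 48)), c(23, 23, 23), c(7, 6, 5),
                       kappa = 0.7, seed = s)
    m <- component_shape_metrics(les, markers = "none")
    expect_gte(m$V_H, m$V)
  }
})

test_that("corner-point hull of a digitized ball matches the frozen oracle", {
  # Frozen from an independent Qhull (scipy.spatial.ConvexHull) run on the
  # identical corner point set: V_H / ((4/3) pi 10^3) = 1.1763938,
  # S_H / (4 pi 10^2) = 1.1215028. The excess over the analytic ball is the
  # digitization staircase, not an implementation artifact.
  h <- convex_hull_metrics(ball_mask(10))
  expect_equal(h$volume / (4 / 3 * pi * 1000), 1.1763938, tolerance = 1e-6)
  expect_equal(h$area / (4 * pi * 100), 1.1215028, tolerance = 1e-6)
})

test_that("isosurface area tracks smooth bodies and bounds single voxels", {
  ball <- ball_mask(10)
  s <- surface_area(ball)
  expect_lt(abs(s - 4 * pi * 100) / (4 * pi * 100), 0.03)

  one <- mask_from_voxels(rbind(c(3, 3, 3)), c(5, 5, 5))
  s1 <- surface_area(one)
  expect_gt(s1, 0)
  expect_lte(s1, 6)

  # doubling the physical spacing quadruples the area
  one2 <- mask_from_voxels(rbind(c(3, 3, 3)), c(5, 5, 5), c(2, 2, 2))
  expect_equal(surface_area(one2), 4 * s1, tolerance = 1e-9)
  ball2 <- binary_mask(ball$data, vol_geom(ball$geometry$dims, c(2, 2, 2)))
  expect_equal(surface_area(ball2), 4 * s, tolerance = 1e-9)

  # voxel-face counting overestimates the smooth sphere by about 3/2
  expect_equal(surface_area(ball, method = "voxel_faces") / (4 * pi * 100),
               1.5, tolerance = 0.05)
})

test_that("convexity and solidity fall for irregular bodies", {
  ball <- ball_mask(10)
  mb <- component_shape_metrics(ball, markers = "none")
  cvx_ball <- convexity(mb)

  # radial grooves carved into the ball: the lesion surface grows while its
  # hull stays put, so convexity and solidity drop strictly below the ball
  ctr <- c(14, 14, 14)
  co <- as.matrix(expand.grid(1:27, 1:27, 1:27))
  dent <- array(sqrt(colSums((t(co) - ctr)^2)) <= 10, c(27, 27, 27))
  for (dir in list(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0), c(0, -1, 0),
                   c(0, 0, 1), c(0, 0, -1), c(1, 1, 0), c(1, -1, 0),
                   c(-1, 1, 0), c(-1, -1, 0), c(0, 1, 1), c(0, 1, -1))) {
    dn <- dir / sqrt(sum(dir^2))
    for (t in seq(5.5, 10.5, by = 0.5)) {
      p <- round(ctr + dn * t)
      for (a in -1:1) for (b in -1:1) for (cc in -1:1)
        if (abs(a) + abs(b) + abs(cc) <= 2) {
          q <- pmin(pmax(p + c(a, b, cc), 1), 27)
          dent[q[1], q[2], q[3]] <- FALSE
        }
    }
  }
  sp <- binary_mask(dent, vol_geom(c(27, 27, 27)))
  ms <- component_shape_metrics(sp, markers = "none")
  expect_lt(convexity(ms), cvx_ball)
  expect_lt(solidity(ms), solidity(mb))
  # same ordering along the generator's irregularity axis at fixed extent
  g64 <- vol_geom(c(64, 64, 64))
  k0 <- make_lesion(g64, c(31, 31, 31), c(9, 7, 6), 0, 1, growth = 0)
  k6 <- make_lesion(g64, c(31, 31, 31), c(9, 7, 6), 0.6, 1, growth = 0)
  expect_lt(convexity(component_shape_metrics(k6, markers = "none")),
            convexity(component_shape_metrics(k0, markers = "none")))

  # drilled notch lowers solidity below 1 on a cuboid
  cub <- cuboid_mask(10, 8, 6)
  notched <- cub
  notched$data[7:9, 5:8, 5:7] <- FALSE
  expect_lt(solidity(component_shape_metrics(notched, markers = "none")), 1)
})

test_that("concavity index combines the convexity and solidity deficits", {
  expect_equal(concavity_index(1, 1), 1)
  expect_equal(concavity_index(1.03, 0.19), (2 - 1.03) + (1 - 0.19))
  expect_equal(concavity_index(1.03, 0.19), 1.78, tolerance = 1e-12)
  # strictly increasing as either ratio decreases
  expect_gt(concavity_index(0.9, 0.5), concavity_index(1.0, 0.5))
  expect_gt(concavity_index(0.9, 0.4), concavity_index(0.9, 0.5))
  # strategy slot accepts a custom formula
  expect_equal(concavity_index(0.8, 0.5, formula = function(cvx, sol) cvx * sol),
               0.4)
  expect_error(concavity_index(1, 1, formula = "no_such"), "unknown")
})

test_that("box-counting dimension hits the closed forms exactly", {
  cube <- cuboid_mask(8, 8, 8)
  expect_equal(fractal_dimension(cube), 3, tolerance = 1e-9)
  expect_equal(fractal_dimension(cuboid_mask(16, 16, 16)), 3, tolerance = 1e-9)
  plane <- cuboid_mask(32, 32, 1)
  expect_equal(fractal_dimension(plane), 2, tolerance = 1e-9)
  line <- cuboid_mask(64, 1, 1)
  expect_equal(fractal_dimension(line), 1, tolerance = 1e-9)

  # invariant to padding with empty space
  small <- mask_from_voxels(as.matrix(expand.grid(2:9, 2:9, 2:9)), c(12, 12, 12))
  big <- mask_from_voxels(as.matrix(expand.grid(2:9, 2:9, 2:9)), c(40, 40, 40))
  expect_equal(fractal_dimension(small), fractal_dimension(big))

  expect_error(fractal_dimension(mask_from_voxels(rbind(c(2, 2, 2)),
                                                  c(5, 5, 5))), "scales")
})

test_that("eccentricity separates balls from rods and respects symmetry", {
  expect_lt(eccentricity(ball_mask(10)), 0.2)

  rod <- mask_from_voxels(cbind(3, 3, 3:52), c(5, 5, 56))
  expect_gt(eccentricity(rod), 0.99)
  expect_lt(eccentricity(rod), 1)

  # invariant under axis permutation of the coordinate frame
  rod_x <- mask_from_voxels(cbind(3:52, 3, 3), c(56, 5, 5))
  expect_equal(eccentricity(rod_x), eccentricity(rod), tolerance = 1e-12)

  # single voxel on an isotropic grid is defined as 0
  expect_equal(eccentricity(mask_from_voxels(rbind(c(3, 3, 3)), c(5, 5, 5))), 0)
})

test_that("all five markers are invariant to uniform physical rescaling", {
  les <- make_lesion(vol_geom(c(48, 48, 48)), c(23, 23, 23), c(7, 6, 5),
                     kappa = 0.5, seed = 9)
  les2 <- binary_mask(les$data, vol_geom(c(48, 48, 48), c(2.5, 2.5, 2.5)))
  m1 <- component_shape_metrics(les)
  m2 <- component_shape_metrics(les2)
  for (f in c("solidity", "convexity", "concavity_index",
              "fractal_dimension", "eccentricity"))
    expect_equal(m2[[f]], m1[[f]], tolerance = 1e-6)
})

test_that("participant markers average per type and handle absent types", {
  g <- vol_geom(c(60, 20, 20))
  mk_comp <- function(id, vox, type) {
    comp <- wmhshape:::new_lesion_component(id, vox, g)
    comp$type <- type
    comp
  }
  rod_short <- cbind(2:21, 5L, 5L)   # 20-voxel line
  rod_long <- cbind(2:41, 12L, 12L)  # 40-voxel line
  blob <- as.matrix(expand.grid(45:52, 5:12, 5:12))
  comps <- list(mk_comp(1, rod_short, "deep"), mk_comp(2, rod_long, "deep"),
                mk_comp(3, blob, "confluent"))
  typed <- merge_pv_confluent(comps)
  pm <- participant_markers(typed)
  expect_equal(pm$n_deep, 2L)
  expect_equal(pm$n_pvc, 1L)
  # unweighted mean of the two deep-lesion marker values
  expect_equal(pm$fd_deep,
               mean(c(fractal_dimension(comps[[1]]),
                      fractal_dimension(comps[[2]]))))
  expect_equal(pm$eccentricity,
               mean(c(eccentricity(comps[[1]]), eccentricity(comps[[2]]))))
  expect_false(is.na(pm$solidity))

  # no deep components: deep markers missing, PV/confluent still produced
  pm2 <- participant_markers(merge_pv_confluent(comps[3]))
  expect_true(is.na(pm2$eccentricity) && is.na(pm2$fd_deep))
  expect_false(is.na(pm2$solidity))

  # single-voxel lesions are skipped and counted
  tiny <- mk_comp(4, rbind(c(55L, 18L, 18L)), "deep")
  pm3 <- participant_markers(merge_pv_confluent(list(comps[[1]], tiny)))
  expect_equal(pm3$n_skipped, 1L)
  expect_equal(pm3$n_deep, 1L)
})
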