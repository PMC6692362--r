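test_that("straight tube geometry: tau = 1, surface and radius near analytic", {
  gt <- straight_tube_gt(r = 5, len = 200, dom = c(220, 40, 40))
  vol <- voxelize(gt)
  sk <- skeletonize(vol)
  seg <- segment_geometry(vol, build_graph(sk), sk)
  expect_equal(nrow(seg), 1)
  # axis-aligned path has no lattice overshoot
  expect_lte(seg$tortuosity, 1.08)
  expect_gte(seg$tortuosity, 1)
  expect_equal(seg$surface_um2, 2 * pi * 5 * 200, tolerance = 0.15)
  # radius within 0.6 voxel units of truth (r = 4 voxels here)
  expect_lt(abs(seg$radius_um - 5) / 1.25, 0.6)
})

test_that("quarter-arc tortuosity approaches the analytic arc/chord ratio", {
  th <- seq(0, pi / 2, length.out = 80)
  poly <- cbind(20 + 150 * sin(th), 20 + 150 * (1 - cos(th)), 40)
  gt <- straight_tube_gt(r = 4, len = 100, dom = c(200, 200, 80))
  gt$nodes$x <- poly[c(1, 80), 1]; gt$nodes$y <- poly[c(1, 80), 2]
  gt$nodes$z <- c(40, 40)
  gt$edges$radius_um <- 4
  gt$polylines[[1]] <- poly
  vol <- voxelize(gt)
  sk <- skeletonize(vol)
  seg <- segment_geometry(vol, build_graph(sk), sk)
  # analytic (pi/2)/sqrt(2) = 1.1107, plus bounded lattice-path overshoot
  expect_gte(seg$tortuosity, 1.10)
  expect_lte(seg$tortuosity, 1.1107 * 1.08)
})

test_that("tortuosity >= 1 for every segment with d > 0 across phantom fixtures", {
  for (mode in c("healthy_like", "tumor_like")) {
    gt <- generate_network(phantom_spec(mode = mode, seed = 5))
    tau <- gt$edges$tortuosity
    expect_true(all(tau[is.finite(tau)] >= 1 - 1e-9))
  }
  gt <- generate_network(phantom_spec(domain_size_um = c(600, 600, 300),
                                      mode = "custom", tree_levels = 3,
                                      radius_range_um = c(7, 10), seed = 2))
  vol <- voxelize(gt)
  sk <- skeletonize(vol)
  seg <- segment_geometry(vol, build_graph(sk), sk)
  expect_true(all(seg$tortuosity[is.finite(seg$tortuosity)] >= 1 - 1e-9))
})

test_that("tile statistics: saturated, empty, and single-cylinder boxes", {
  # solid all-foreground box
  solid <- binary_volume(array(TRUE, c(20, 20, 20)), c(25, 25, 25))
  ts <- tile_stats(solid, box_um = 500)
  expect_equal(nrow(ts), 1)
  expect_equal(ts$fVV, 1)
  # empty box
  empty <- binary_volume(array(FALSE, c(20, 20, 20)), c(25, 25, 25))
  te <- tile_stats(empty, box_um = 500)
  expect_equal(te$fVV, 0)
  expect_equal(te$MVD, 0)
  # one 500 um box containing a spanning cylinder of radius 10
  gt <- straight_tube_gt(r = 10, len = 500, dom = c(500, 500, 500),
                         sp = c(5, 5, 5))
  gt$polylines[[1]] <- rbind(c(0, 250, 250), c(500, 250, 250))
  gt$nodes$x <- c(0, 500); gt$nodes$y <- 250; gt$nodes$z <- 250
  vol <- voxelize(gt)
  tc <- tile_stats(vol, box_um = 500)
  expect_equal(tc$fVV, pi * 100 * 500 / 500^3, tolerance = 0.15)
  # box smaller than 2 voxels fails
  expect_error(tile_stats(solid, box_um = 30), "2 voxels")
  # MVD counts each segment once, via its centerline median voxel
  sk <- skeletonize(vol)
  vg <- build_graph(sk)
  tm <- tile_stats(vol, vg, box_um = 500)
  expect_equal(sum(tm$MVD * 0.125), 1)   # one segment in 0.125 mm^3 boxes
})

test_that("global densities scale as expected and reject empty masks", {
  # one 1 mm tube in 1 mm^3 -> rho_L = 1 mm^-2
  gt <- straight_tube_gt(r = 10, len = 1000, dom = c(1000, 1000, 1000),
                         sp = c(10, 10, 10))
  gt$polylines[[1]] <- rbind(c(0, 500, 500), c(1000, 500, 500))
  gt$nodes$x <- c(0, 1000); gt$nodes$y <- 500; gt$nodes$z <- 500
  vol <- voxelize(gt)
  sk <- skeletonize(vol)
  vg <- build_graph(sk)
  seg <- segment_geometry(vol, vg, sk)
  dens <- global_densities(vol, vg, seg)
  expect_equal(dens$tissue_volume_mm3, 1)
  expect_equal(dens$rho_L, 1, tolerance = 0.05)
  expect_equal(dens$MVD_global, 1)
  # doubling the (mask) volume halves the densities
  half <- region_mask(array(rep(c(TRUE, FALSE), each = 50 * 100 * 100),
                            c(100, 100, 100)))
  dh <- global_densities(vol, vg, seg, mask = half)
  expect_equal(dh$rho_L, 2 * dens$rho_L, tolerance = 1e-6)
  allf <- region_mask(array(FALSE, c(100, 100, 100)))
  expect_error(global_densities(vol, vg, seg, mask = allf), "zero")
})

test_that("fVV and densities are invariant under axis permutation", {
  gt <- generate_network(phantom_spec(domain_size_um = c(600, 600, 300),
                                      mode = "custom", tree_levels = 2,
                                      radius_range_um = c(7, 10), seed = 3))
  vol <- voxelize(gt, spacing_um = c(4, 4, 4))
  f1 <- sum(vol$grid) / length(vol$grid)
  volp <- binary_volume(aperm(vol$grid, c(2, 3, 1)), c(4, 4, 4))
  f2 <- sum(volp$grid) / length(volp$grid)
  expect_equal(f1, f2)
})

test_that("shrinkage scaling reproduces the printed factors and round-trips", {
  # in-vivo 4 um diameter shrinks to 4 * 0.6^(1/3) = 3.37 um after clearing
  expect_equal(4 * 0.6^(1 / 3), 3.37, tolerance = 2e-3)
  expect_equal(0.6^(-1 / 3), 1.186, tolerance = 1e-3)
  seg <- data.frame(edge_id = 1, length_um = 100, separation_um = 90,
                    tortuosity = 100 / 90, radius_um = 1.6865,
                    surface_um2 = 1000)
  up <- scale_to_in_vivo(seg, 0.40)
  expect_equal(up$radius_um * 2, 4, tolerance = 1e-3)   # cleared 3.37 -> in vivo 4
  expect_equal(up$length_um / seg$length_um, 0.6^(-1 / 3))
  expect_equal(up$surface_um2 / seg$surface_um2, 0.6^(-2 / 3))
  # s = 0 is the identity; round-trip with the inverse shrinkage recovers input
  expect_identical(scale_to_in_vivo(seg, 0), seg)
  back <- scale_to_in_vivo(up, -0.4 / 0.6)
  expect_equal(back, seg, tolerance = 1e-12)
  expect_error(scale_to_in_vivo(seg, 1))
  # density summary scaling
  ds <- structure(list(fVV_global = 0.1, MVD_global = 1000, rho_L = 980,
                       rho_A = 25, tissue_volume_mm3 = 10),
                  class = "density_summary")
  us <- scale_to_in_vivo(ds, 0.40)
  expect_equal(us$rho_L, 980 * 0.6^(2 / 3))
  expect_equal(us$rho_A, 25 * 0.6^(1 / 3))
  expect_equal(us$tissue_volume_mm3, 10 / 0.6)
  expect_equal(us$fVV_global, 0.1)
})

test_that("geometry summaries: directed deviations and tau quantiles", {
  segs <- data.frame(edge_id = 1:4, length_um = c(10, 10, 10, 10),
                     separation_um = 10, tortuosity = c(1, 1, 1.2, 2),
                     radius_um = 4, surface_um2 = 100)
  sm <- summarize_geometry(segs)
  tau <- sm[sm$quantity == "tortuosity", ]
  expect_equal(tau$median, 1.1)    # mean of the middle pair
  expect_equal(tau$q95, 1.88)      # linear interpolation between order stats
  # constant values have zero directed deviations
  r <- sm[sm$quantity == "radius_um", ]
  expect_equal(r$dev_plus, 0)
  expect_equal(r$dev_minus, 0)
  # reported mean is the arithmetic sample mean
  set.seed(2)
  lr <- exp(rnorm(500, log(4.9), 0.5))
  segs2 <- data.frame(edge_id = seq_along(lr), length_um = 10,
                      separation_um = 10, tortuosity = 1, radius_um = lr,
                      surface_um2 = 100)
  sm2 <- summarize_geometry(segs2)
  expect_equal(sm2[sm2$quantity == "radius_um", "mean"], mean(lr))
})
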