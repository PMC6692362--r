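test_that("phantom_spec validates its invariants", {
  expect_error(phantom_spec(domain_size_um = c(-1, 10, 10)))
  expect_error(phantom_spec(endpoint_fraction_target = 1.5))
  expect_error(phantom_spec(domain_size_um = c(1e5, 1e5, 1e5)), "max_voxels")
  expect_error(generate_network(
    phantom_spec(domain_size_um = c(60, 60, 60), mode = "healthy_like")),
    "infeasible")
})

test_that("a custom tree with 3 bifurcation levels has consistent combinatorics", {
  # a rooted tree with a trunk and 3 full bifurcation levels: 7 degree-3
  # junctions, 9 endpoints (8 leaves + root tip), 15 edges; degree sum 30
  gt <- generate_network(phantom_spec(mode = "custom", tree_levels = 3, seed = 1))
  expect_equal(nrow(gt$nodes), 16)
  expect_equal(nrow(gt$edges), 15)
  expect_equal(sum(gt$nodes$degree == 1), 9)
  expect_equal(sum(gt$nodes$degree == 3), 7)
  expect_equal(sum(gt$nodes$degree), 2 * nrow(gt$edges))
})

test_that("presets hit their endpoint fractions and are deterministic", {
  gh <- generate_network(phantom_spec(mode = "healthy_like", seed = 1))
  expect_equal(mean(gh$nodes$degree == 1), 0.11, tolerance = 0.05 / 0.11)
  gt <- generate_network(phantom_spec(mode = "tumor_like", seed = 1))
  ept <- mean(gt$nodes$degree == 1)
  expect_gte(ept, 0.20); expect_lte(ept, 0.30)
  gh2 <- generate_network(phantom_spec(mode = "healthy_like", seed = 1))
  expect_identical(gh$nodes, gh2$nodes)
  expect_identical(gh$edges, gh2$edges)
  gh3 <- generate_network(phantom_spec(mode = "healthy_like", seed = 2))
  expect_false(identical(gh$edges, gh3$edges))
})

test_that("healthy-like phantoms reproduce their generative length density", {
  spec <- phantom_spec(mode = "healthy_like", seed = 3)
  gt <- generate_network(spec)
  rho <- sum(gt$edges$length_um) * 1e-3 / prod(spec$domain_size_um * 1e-3)
  expect_equal(rho, spec$capillary_mesh_density, tolerance = 0.10)
})

test_that("voxelize matches the analytic cylinder volume and handles edge cases", {
  gt <- straight_tube_gt(r = 5, len = 500)
  vol <- voxelize(gt)
  analytic <- pi * 5^2 * 500 / prod(vol$spacing_um)
  expect_equal(sum(vol$grid), analytic, tolerance = 0.15)
  # every true centerline voxel is foreground
  mid <- dim(vol$grid)[2:3] / 2
  axis_vox <- vol$grid[ceiling(10 / 1.25):floor(510 / 1.25),
                       ceiling(mid[1]), ceiling(mid[2])]
  expect_true(all(axis_vox))

  # empty ground truth -> all-background volume
  empty <- gt; empty$edges <- gt$edges[0, ]; empty$polylines <- list()
  expect_equal(sum(voxelize(empty)$grid), 0)

  # two disjoint tubes -> exactly 2 components (26-connectivity)
  two <- straight_tube_gt(r = 4, len = 100, dom = c(120, 120, 120),
                          sp = c(2, 2, 2))
  two$nodes <- rbind(two$nodes,
                     data.frame(id = 3:4, x = c(10, 110), y = 90, z = 90,
                                degree = 1L))
  two$edges <- rbind(two$edges,
                     data.frame(id = 2L, node_a = 3L, node_b = 4L,
                                radius_um = 4, length_um = 100, tortuosity = 1))
  two$polylines[[2]] <- rbind(c(10, 90, 90), c(110, 90, 90))
  expect_equal(n_components(voxelize(two), 26), 2)

  # sub-resolvability tubes are flagged with a warning
  thin <- straight_tube_gt(r = 0.5, len = 100, dom = c(120, 40, 40),
                           sp = c(2, 2, 2))
  expect_warning(voxelize(thin), "resolvability")
})

test_that("corrupt adds the stated artefacts and all-zero noise is the identity", {
  gt <- straight_tube_gt(r = 6, len = 150, sp = c(1.5, 1.5, 1.5))
  vol <- voxelize(gt)
  expect_identical(corrupt(vol, noise_spec())$grid, vol$grid)

  # 10 disjoint specks -> component count increases by exactly 10
  noisy <- corrupt(vol, noise_spec(speck_count = 10, speck_radius_um = 2,
                                   seed = 2))
  expect_equal(n_components(noisy), n_components(vol) + 10)

  # one carved hole -> one enclosed background cavity
  holed <- corrupt(vol, noise_spec(hole_count = 1, seed = 2))
  refilled <- fill_holes(holed)
  expect_equal(sum(refilled$grid) - sum(holed$grid), 1)
  expect_identical(refilled$grid, vol$grid)

  # deterministic given the seed
  n1 <- corrupt(vol, noise_spec(speck_count = 5, boundary_fuzz_prob = 0.05,
                                seed = 7))
  n2 <- corrupt(vol, noise_spec(speck_count = 5, boundary_fuzz_prob = 0.05,
                                seed = 7))
  expect_identical(n1$grid, n2$grid)
})

test_that("G(n,m) generator: exact sizes, saturated case, determinism", {
  g <- generate_er_graph(5, 10, seed = 1)   # complete K5
  expect_equal(igraph::ecount(g), 10)
  cc <- clustering_coefficients(g)
  expect_equal(cc$mean_c, 1)
  expect_equal(mean(igraph::degree(g)), 4)
  expect_error(generate_er_graph(5, 11))
  g1 <- generate_er_graph(200, 400, seed = 3)
  g2 <- generate_er_graph(200, 400, seed = 3)
  expect_identical(igraph::as_edgelist(g1), igraph::as_edgelist(g2))
  # mean degree is 2m/n exactly
  expect_equal(mean(igraph::degree(g1)), 2 * 400 / 200)
})

test_that("ER degree distribution is Poisson(2m/n) by chi-square", {
  n <- 50000; m <- 78250    # mean degree 3.13
  g <- generate_er_graph(n, m, seed = 4)
  k <- igraph::degree(g)
  lam <- 2 * m / n
  kmax <- 10
  obs <- tabulate(pmin(k, kmax) + 1L, kmax + 1L)
  pr <- dpois(0:(kmax - 1), lam)
  pr <- c(pr, 1 - sum(pr))
  chi <- sum((obs - n * pr)^2 / (n * pr))
  # df = 11 bins - 1; alpha = 0.01
  expect_lt(chi, qchisq(0.99, kmax))
})

test_that("hierarchical model is deterministic with analytic hub clustering", {
  g1 <- generate_hierarchical_graph(2)
  g2 <- generate_hierarchical_graph(2)
  expect_identical(igraph::as_edgelist(g1), igraph::as_edgelist(g2))
  expect_equal(igraph::vcount(g1), 25)
  g <- generate_hierarchical_graph(3)
  deg <- igraph::degree(g)
  hub <- which.max(deg)
  nb <- as.integer(igraph::neighbors(g, hub))
  e_i <- igraph::ecount(igraph::induced_subgraph(g, nb))   # triangle count
  expect_equal(clustering_coefficients(g)$ci[hub],
               2 * e_i / (deg[hub] * (deg[hub] - 1)))
})

test_that("configuration-model generator preserves its drawn degree sequence", {
  g1 <- generate_powerlaw_graph(5000, 2.5, seed = 6)
  g2 <- generate_powerlaw_graph(5000, 2.5, seed = 6)
  expect_identical(igraph::degree(g1), igraph::degree(g2))
  expect_true(all(igraph::degree(g1) >= 3))
  expect_error(generate_powerlaw_graph(50, 2.5))
  expect_error(generate_powerlaw_graph(5000, 0.9))
})
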