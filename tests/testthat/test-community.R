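test_that("modularity matches brute-force double-sum evaluation", {
  g <- two_clique_graph()
  memb <- rep(1:2, each = 5)
  # two K5 cliques with one bridge: Q = 2*(10/21 - (21/42)^2) = 0.452381
  expect_equal(modularity_q(g, memb), 2 * (10 / 21 - (21 / 42)^2),
               tolerance = 1e-12)
  # one community -> 0; singletons -> -sum k_i^2/(2m)^2 = -178/1764
  expect_equal(modularity_q(g, rep(1, 10)), 0, tolerance = 1e-12)
  expect_equal(modularity_q(g, 1:10), -178 / 1764, tolerance = 1e-12)
  expect_equal(modularity_q(g, memb), bf_modularity(g, memb), tolerance = 1e-12)

  # random weighted graphs with self-loops, <= 50 nodes
  for (seed in 1:3) {
    set.seed(seed)
    n <- sample(10:50, 1)
    el <- cbind(sample(n, 3 * n, TRUE), sample(n, 3 * n, TRUE))
    g2 <- igraph::make_graph(t(el), n = n, directed = FALSE)
    w <- runif(igraph::ecount(g2), 0.5, 2)
    memb2 <- sample(4, n, TRUE)
    expect_equal(modularity_q(g2, memb2, weights = w),
                 bf_modularity(g2, memb2, weights = w), tolerance = 1e-12)
  }
  # empty edge set: undefined, flagged
  expect_warning(q0 <- modularity_q(igraph::make_empty_graph(3, directed = FALSE),
                                    rep(1, 3)))
  expect_true(is.na(q0))
})

test_that("Louvain finds the verified global optimum on the bridge-clique fixture", {
  g <- two_clique_graph()
  # exhaustive bipartition check: 0.452381 is the best two-community split
  best <- -Inf
  for (code in 0:(2^9 - 1)) {
    memb <- c(1, as.integer(intToBits(code))[1:9] + 1)
    best <- max(best, modularity_q(g, memb))
  }
  expect_equal(best, 0.452381, tolerance = 1e-6)
  p <- louvain_unfold(g, seed = 1)
  expect_equal(p$q_final, best, tolerance = 1e-9)
  expect_equal(p$n_c, 2)
  expect_true(all(table(p$final, rep(1:2, each = 5)) %in% c(0, 5)))
})

test_that("Louvain on the clique ring attains the brute-force clique-partition Q", {
  g <- clique_ring_graph(16)
  memb <- rep(1:16, each = 5)
  qref <- bf_modularity(g, memb)
  p <- louvain_unfold(g, seed = 2)
  expect_equal(p$q_final, qref, tolerance = 0.02 / qref)
  # Q non-decreasing across levels, final at least the one-community value 0
  expect_true(all(diff(p$q_levels) >= -1e-12))
  expect_gte(p$q_final, 0)
})

test_that("Louvain recovers a planted bipartition exactly", {
  set.seed(9)
  n <- 100
  blk <- function(off) {
    ut <- utils::combn(n, 2)
    as.vector(ut[, runif(ncol(ut)) < 0.5]) + off
  }
  grid <- expand.grid(a = 1:n, b = (n + 1):(2 * n))
  cross <- as.matrix(grid[runif(nrow(grid)) < 0.01, ])
  g <- igraph::make_graph(c(blk(0), blk(n), as.vector(t(cross))),
                          directed = FALSE)
  p <- louvain_unfold(g, seed = 4)
  truth <- rep(1:2, each = n)
  expect_equal(p$n_c, 2)
  tab <- table(p$final, truth)
  expect_true(all(rowSums(tab > 0) == 1))
  # no community spans disconnected halves
  g2 <- igraph::disjoint_union(igraph::make_full_graph(6),
                               igraph::make_full_graph(6))
  p2 <- louvain_unfold(g2, seed = 1)
  expect_true(all(table(p2$final, rep(1:2, each = 6)) %in% c(0, 6)))
})

test_that("community structure bookkeeping identities hold", {
  g <- two_clique_graph()
  memb <- rep(1:2, each = 5)
  pos <- cbind(c(rep(0, 5), rep(100, 5)), 0, 0)
  cs <- community_structure(g, memb, pos)
  expect_equal(cs$n, c(5, 5))
  expect_equal(cs$e, c(10, 10))
  expect_equal(cs$P, c(1, 1))
  expect_equal(cs$k_c, 2 * cs$e + cs$P)
  expect_equal(cs$e_over_P, c(10, 10))
  # sum n_j = N_n; sum e_j + N_ice = N_e
  expect_equal(sum(cs$n), igraph::vcount(g))
  expect_equal(sum(cs$e) + sum(cs$P) / 2, igraph::ecount(g))
  # two nodes at (0,0,0), (2,0,0): centroid (1,0,0), R = 1
  g3 <- igraph::make_graph(c(1, 2), directed = FALSE)
  cs3 <- community_structure(g3, c(1, 1), rbind(c(0, 0, 0), c(2, 0, 0)))
  expect_equal(c(cs3$cx, cs3$cy, cs3$cz), c(1, 0, 0))
  expect_equal(cs3$R, 1)
  # community with e=10, P=5 has k_c = 25
  expect_equal(2 * 10 + 5, 25)
})

test_that("isolated small communities are filtered by the stated rule", {
  tab <- data.frame(community = 1:4, n = c(50, 3, 30, 4),
                    e = c(60, 3, 35, 5), P = c(4, 0, 2, 0))
  kept <- filter_isolated_communities(tab, min_edges = 20)
  # disconnected triangle-like community (e=3, P=0) removed; the P>0 small one kept
  expect_equal(kept$community, c(1, 3))
  expect_equal(attr(kept, "n_removed"), 2)
  # connected small community retained; min_edges = 0 is the identity
  tab2 <- data.frame(community = 1:2, n = c(5, 50), e = c(5, 60), P = c(2, 2))
  expect_equal(nrow(filter_isolated_communities(tab2, 20)), 2)
  expect_equal(nrow(filter_isolated_communities(tab, 0)), 4)
})

test_that("meta-network construction and handshake identities", {
  g <- two_clique_graph()
  memb <- rep(1:2, each = 5)
  mn <- build_meta_network(g, memb, tissue_volume_mm3 = 0.5)
  expect_equal(igraph::vcount(mn$graph), 2)
  expect_equal(igraph::ecount(mn$graph), 1)
  expect_equal(igraph::E(mn$graph)$weight, 1)
  expect_equal(mn$n_ice, 1)
  expect_equal(mn$rho_c, 4)
  expect_equal(mn$rho_ice, 2)
  # 3 communities pairwise linked by 2 segments: triangle, weights 2, N_ice 6
  gm <- igraph::make_graph(c(1, 2, 3, 4, 5, 6, 2, 3, 2, 3, 4, 5, 4, 5, 6, 1, 6, 1),
                           directed = FALSE)
  mn3 <- build_meta_network(gm, c(1, 1, 2, 2, 3, 3))
  expect_equal(igraph::ecount(mn3$graph), 3)
  expect_equal(igraph::E(mn3$graph)$weight, rep(2, 3))
  expect_equal(mn3$n_ice, 6)
  # handshake: sum P_j = 2 * sum of meta-edge weights
  cs <- community_structure(gm, c(1, 1, 2, 2, 3, 3))
  expect_equal(sum(cs$P), 2 * sum(igraph::E(mn3$graph)$weight))
  mt <- meta_topology(mn3)
  expect_equal(mt$C_c, 1)
  expect_equal(mt$L_c, 1)
  expect_equal(mt$D_c, 1)
})

test_that("meta path-of-three fixture and the degree histogram", {
  # A - B - C: L_c = 4/3, D_c = 2
  gm <- igraph::make_graph(c(1, 2, 2, 3, 3, 4, 4, 5, 5, 6), directed = FALSE)
  memb <- c(1, 1, 2, 2, 3, 3)
  mn <- build_meta_network(gm, memb)
  mt <- meta_topology(mn)
  expect_equal(mt$L_c, 4 / 3)
  expect_equal(mt$D_c, 2)
  expect_equal(sum(mt$k_c_hist$count), 3)
  expect_equal(mt$k_cu, setNames(c(1, 2, 1), NULL), ignore_attr = TRUE)
})

test_that("isolation exponent: exact recovery, flat case, annotation", {
  e <- round(10^seq(0.5, 3, length.out = 30))
  comm <- data.frame(community = seq_along(e), n = e, e = e,
                     P = round(3 * e^0.99))
  fit <- fit_isolation_exponent(comm)
  expect_equal(fit$xi, 0.99, tolerance = 0.015)
  expect_equal(fit$interpretation, "weak community structure")
  flat <- data.frame(community = 1:20, n = 10, e = round(10^seq(1, 3, length.out = 20)),
                     P = 7)
  expect_equal(fit_isolation_exponent(flat)$xi, 0, tolerance = 1e-9)
  tiny <- comm[1:3, ]
  expect_true(fit_isolation_exponent(tiny)$flagged)
})

test_that("assortativity: star and ring fixtures plus estimator recovery", {
  # family of hub-leaf pairs wired on the inverse relation k_c1 = C/k_c:
  # both endpoints of every pair sit on y = C/x, so kappa = -1 exactly
  npair <- 15
  hub_kc <- 10^seq(1, 2.5, length.out = npair)
  leaf_kc <- 10^3.5 / hub_kc
  edges <- as.vector(rbind(seq_len(npair), npair + seq_len(npair)))
  pairs <- igraph::make_graph(edges, n = 2 * npair, directed = FALSE)
  comm <- data.frame(community = seq_len(2 * npair), n = 5,
                     e = 1, P = 1, k_c = c(hub_kc, leaf_kc))
  mn <- structure(list(graph = pairs, communities = comm, n_ice = npair),
                  class = "meta_network")
  fa <- fit_assortativity(mn)
  expect_equal(fa$kappa, -1, tolerance = 1e-6)
  # degree-regular ring: all k_c equal -> kappa = 0 by convention, flagged
  ring <- igraph::make_ring(12)
  commr <- data.frame(community = 1:12, n = 5, e = 6, P = 2, k_c = 14)
  mnr <- structure(list(graph = ring, communities = commr, n_ice = 12),
                   class = "meta_network")
  far <- fit_assortativity(mnr)
  expect_equal(far$kappa, 0)
  expect_true(far$flagged)
  # meta-star: the robust fit treats the single hub as an outlier against the
  # flat leaf cloud; the plain neighbor-degree values still show the inverse
  # relation directly
  star <- igraph::make_star(13, mode = "undirected")
  kcs <- c(400, round(10^seq(0.5, 1.5, length.out = 12)))
  comms <- data.frame(community = 1:13, n = 5, e = pmax(1, (kcs - 2) %/% 2),
                      P = 2, k_c = kcs)
  mns <- structure(list(graph = star, communities = comms, n_ice = 12),
                   class = "meta_network")
  fas <- fit_assortativity(mns)
  expect_equal(fas$knn[2:13], rep(400, 12))      # leaves all see the hub
  expect_lt(fas$knn[1], 40)                      # hub sees the small leaves
  # the robust log-log estimator recovers a 0.5 exponent exactly on synthetic
  # neighbor-degree relations (an undirected wiring cannot realize y = x^0.5
  # at every node simultaneously, so the estimator is validated directly)
  kcs <- 10^seq(0.5, 3, length.out = 40)
  est <- vasculotopo:::robust_loglog_fit(kcs, 2.5 * kcs^0.5)
  expect_equal(est$slope, 0.5, tolerance = 0.05 / 0.5)
})

test_that("path length vs separation bins connected pairs exhaustively", {
  gm <- igraph::make_graph(c(1, 2, 2, 3, 3, 4, 4, 5, 5, 6), directed = FALSE)
  memb <- c(1, 1, 2, 2, 3, 3)
  mn <- build_meta_network(gm, memb)
  igraph::V(mn$graph)$x <- c(0, 100, 200)
  igraph::V(mn$graph)$y <- 0
  igraph::V(mn$graph)$z <- 0
  lc <- path_length_vs_separation(mn, delta_um = 50)
  # pairs: (A,B) 100 um 1 hop, (B,C) 100 um 1 hop, (A,C) 200 um 2 hops
  expect_equal(sum(lc$n_pairs), 3)
  expect_equal(lc$mean_L[lc$bin_lo == 100], 1)
  expect_equal(lc$mean_L[lc$bin_lo == 200], 2)
  # two adjacent communities 120 um apart land in the [100, 150) bin with L = 1
  g2 <- igraph::make_graph(c(1, 2, 2, 3, 3, 4), directed = FALSE)
  mn2 <- build_meta_network(g2, c(1, 1, 2, 2))
  igraph::V(mn2$graph)$x <- c(0, 120); igraph::V(mn2$graph)$y <- 0
  igraph::V(mn2$graph)$z <- 0
  lc2 <- path_length_vs_separation(mn2, delta_um = 50)
  expect_equal(lc2$bin_lo, 100)
  expect_equal(lc2$mean_L, 1)
  expect_equal(lc2$n_pairs, 1)
})

test_that("healthy-like phantoms form larger communities than tumor-like ones", {
  res <- lapply(c("healthy_like", "tumor_like"), function(mode) {
    gt <- generate_network(phantom_spec(mode = mode, seed = 12))
    g <- gt_as_igraph(gt)
    p <- louvain_unfold(g, seed = 1)
    cs <- filter_isolated_communities(community_structure(g, p$final), 20)
    c(n = mean(cs$n), e = mean(cs$e), R = mean(cs$R))
  })
  expect_gt(res[[1]]["n"], res[[2]]["n"])
  expect_gt(res[[1]]["e"], res[[2]]["e"])
  expect_gt(res[[1]]["R"], res[[2]]["R"])
})
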