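# fixtures and independent oracles used across the suite

# digital solid cylinder along x in a box, via a hand-built ground truth
straight_tube_gt <- function(r = 5, len = 500, dom = c(len + 20, 8 * r, 8 * r),
                             sp = c(1.25, 1.25, 1.25)) {
  spec <- phantom_spec(domain_size_um = dom, voxel_spacing_um = sp,
                       mode = "custom", seed = 1)
  mid <- dom[2:3] / 2
  poly <- rbind(c(10, mid[1], mid[2]), c(10 + len, mid[1], mid[2]))
  gt <- list(nodes = data.frame(id = 1:2, x = poly[, 1], y = poly[, 2],
                                z = poly[, 3]),
             edges = data.frame(id = 1L, node_a = 1L, node_b = 2L,
                                radius_um = r),
             polylines = list(poly), spec = spec)
  class(gt) <- "ground_truth_graph"
  gt$nodes$degree <- c(1L, 1L)
  gt$edges$length_um <- len
  gt$edges$tortuosity <- 1
  gt
}

# two K5 cliques joined by one bridge edge (nodes 1..5 and 6..10, bridge 1-6)
two_clique_graph <- function() {
  k5 <- function(off) as.vector(utils::combn(5, 2)) + off
  igraph::make_graph(c(k5(0), k5(5), 1, 6), directed = FALSE)
}

# ring of n_c K5 cliques, consecutive cliques joined by one edge
clique_ring_graph <- function(n_c = 16) {
  k5 <- function(off) as.vector(utils::combn(5, 2)) + off
  edges <- unlist(lapply(0:(n_c - 1), function(i) k5(i * 5)))
  for (i in 0:(n_c - 1))
    edges <- c(edges, i * 5 + 5, ((i + 1) %% n_c) * 5 + 1)
  igraph::make_graph(edges, directed = FALSE)
}

# brute-force double-sum modularity, A_ii = 2 x self-loop weight
bf_modularity <- function(g, memb, weights = NULL) {
  n <- igraph::vcount(g)
  if (is.null(weights)) weights <- rep(1, igraph::ecount(g))
  A <- matrix(0, n, n)
  el <- igraph::ends(g, igraph::E(g), names = FALSE)
  for (i in seq_len(nrow(el))) {
    a <- el[i, 1]; b <- el[i, 2]
    if (a == b) A[a, a] <- A[a, a] + 2 * weights[i]
    else { A[a, b] <- A[a, b] + weights[i]; A[b, a] <- A[b, a] + weights[i] }
  }
  m <- sum(A) / 2
  k <- rowSums(A)
  s <- 0
  for (i in 1:n) for (j in 1:n)
    if (memb[i] == memb[j]) s <- s + A[i, j] - k[i] * k[j] / (2 * m)
  s / (2 * m)
}

# Floyd-Warshall all-pairs hop distances
fw_distances <- function(g) {
  n <- igraph::vcount(g)
  d <- matrix(Inf, n, n); diag(d) <- 0
  el <- igraph::ends(g, igraph::E(g), names = FALSE)
  for (i in seq_len(nrow(el))) {
    d[el[i, 1], el[i, 2]] <- 1; d[el[i, 2], el[i, 1]] <- 1
  }
  for (k in 1:n) for (i in 1:n) {
    nd <- d[i, k] + d[k, ]
    upd <- nd < d[i, ]
    d[i, upd] <- nd[upd]
  }
  d
}

# rank-based Kruskal-Wallis H without tie correction (tie-free inputs only)
kw_brute <- function(groups) {
  values <- unlist(groups)
  n <- length(values)
  r <- rank(values)
  rs <- split(r, rep(seq_along(groups), lengths(groups)))
  12 / (n * (n + 1)) * sum(vapply(rs, function(x) sum(x)^2 / length(x), 0)) -
    3 * (n + 1)
}

# preprocessing chain used by the recovery suite
preprocess_chain <- function(vol) {
  remove_specks(fill_holes(smooth_and_rebinarize(vol, 1)), 6)
}

degree_multiset <- function(g) sort(as.integer(igraph::degree(g)))

n_components <- function(vol, connectivity = 6L) {
  g <- if (inherits(vol, "binary_volume")) vol$grid else vol
  max(vasculotopo:::cc_label_cpp(g, dim(g), as.integer(connectivity)))
}
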