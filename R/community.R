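#' Modularity of a partition
#'
#' Exact evaluation of the weighted modularity
#' Q = (1/2m) sum_ij (A_ij - k_i k_j / 2m) delta(c_i, c_j),
#' with the usual diagonal convention A_ii = twice the self-loop weight, so
#' that k_i counts self-loops twice and sum_i k_i = 2m.
#'
#' @param graph igraph or package graph classes
#' @param membership integer community assignment for every node
#' @param weights edge weights (default: the `weight` attribute, else 1)
#' @return scalar Q in [-1, 1]
#' @export
modularity_q <- function(graph, membership, weights = NULL) {
  g <- as_igraph(graph)
  n <- igraph::vcount(g)
  if (length(membership) != n) stop("every node must be assigned a community")
  if (is.null(weights)) {
    weights <- if ("weight" %in% igraph::edge_attr_names(g))
      igraph::E(g)$weight else rep(1, igraph::ecount(g))
  }
  m <- sum(weights)
  if (m == 0) { warning("graph has no edge weight; Q undefined"); return(NA_real_) }
  el <- igraph::ends(g, igraph::E(g), names = FALSE)
  memb <- as.integer(factor(membership))
  # intra-community term: each edge (loop or not) contributes 2w when both
  # endpoints share a community, matching A_ii = 2w for self-loops
  intra <- sum(2 * weights[memb[el[, 1]] == memb[el[, 2]]])
  k <- numeric(n)   # weighted degrees, loops twice
  acc <- rowsum(c(weights, weights), c(el[, 1], el[, 2]))
  k[as.integer(rownames(acc))] <- acc
  kc <- rowsum(k, memb)
  intra / (2 * m) - sum((kc / (2 * m))^2)
}

#' Louvain community unfolding
#'
#' Multi-level modularity maximization: nodes start in singleton communities,
#' are greedily moved to neighboring communities while Q increases, and the
#' graph is then contracted to a weighted meta-graph of communities on which
#' the procedure recurses, yielding one assignment per level with
#' non-decreasing modularity. The sweep order is randomized; the best of
#' `restarts` seeded runs (by final Q) is returned with all its levels.
#'
#' @param graph igraph or package graph classes
#' @param seed base RNG seed; restart r uses `seed + r - 1`
#' @param weights optional edge weights for the base graph (default unit)
#' @param restarts number of independent runs (default 5)
#' @return object of class `community_partition`: `levels` (list of
#'   assignments), `q_levels`, `final`, `q_final`, `n_c`
#' @export
louvain_unfold <- function(graph, seed = 1, weights = NULL, restarts = 5) {
  g <- as_igraph(graph)
  if (igraph::ecount(g) == 0) stop("community unfolding requires at least one edge")
  best <- NULL
  for (r in seq_len(restarts)) {
    cl <- with_seed(seed + r - 1,
                    igraph::cluster_louvain(g, weights = weights))
    q <- max(cl$modularity)
    if (is.null(best) || q > best$q) best <- list(cl = cl, q = q)
  }
  cl <- best$cl
  levels <- lapply(seq_len(nrow(cl$memberships)), function(i)
    as.integer(cl$memberships[i, ]))
  final <- as.integer(igraph::membership(cl))
  structure(list(levels = levels,
                 q_levels = as.numeric(cl$modularity),
                 final = final,
                 q_final = modularity_q(g, final, weights = weights),
                 n_c = length(unique(final))),
            class = "community_partition")
}

#' @export
print.community_partition <- function(x, ...) {
  cat(sprintf("community_partition: %d levels, final Q = %.4f, N_c = %d\n",
              length(x$levels), x$q_final, x$n_c))
  invisible(x)
}

#' Per-community structural statistics
#'
#' For every community j: node count `n`, internal edge count `e`, perimeter
#' `P` (edges to other communities), node centroid, spatial extent `R` (mean
#' distance of member nodes to the centroid), community degree
#' `k_c = 2e + P`, and the supply ratio `e/P`.
#'
#' @param graph igraph or package graph classes
#' @param membership community assignment (e.g. `partition$final`)
#' @param positions n x 3 matrix of node positions in um; defaults to vertex
#'   attributes `x`, `y`, `z`
#' @return data.frame, one row per community
#' @export
community_structure <- function(graph, membership, positions = NULL) {
  g <- as_igraph(graph)
  n <- igraph::vcount(g)
  if (is.null(positions)) {
    va <- igraph::vertex_attr_names(g)
    if (all(c("x", "y", "z") %in% va))
      positions <- cbind(igraph::V(g)$x, igraph::V(g)$y, igraph::V(g)$z)
  }
  memb <- as.integer(factor(membership))
  nc <- max(memb)
  el <- igraph::ends(g, igraph::E(g), names = FALSE)
  ca <- memb[el[, 1]]; cb <- memb[el[, 2]]
  e_in <- tabulate(ca[ca == cb], nc)
  perim <- tabulate(c(ca[ca != cb], cb[ca != cb]), nc)
  nj <- tabulate(memb, nc)
  out <- data.frame(community = seq_len(nc), n = nj, e = e_in, P = perim,
                    k_c = 2 * e_in + perim,
                    e_over_P = ifelse(perim > 0, e_in / perim, NA_real_))
  if (!is.null(positions)) {
    cx <- rowsum(positions[, 1], memb) / nj
    cy <- rowsum(positions[, 2], memb) / nj
    cz <- rowsum(positions[, 3], memb) / nj
    dev <- sqrt((positions[, 1] - cx[memb])^2 + (positions[, 2] - cy[memb])^2 +
                  (positions[, 3] - cz[memb])^2)
    out$cx <- as.numeric(cx); out$cy <- as.numeric(cy); out$cz <- as.numeric(cz)
    out$R <- as.numeric(rowsum(dev, memb) / nj)
  }
  out
}

#' Drop isolated small communities
#'
#' Communities that are disconnected from the rest of the network (P = 0)
#' and contain fewer than `min_edges` internal edges are removed from
#' subsequent statistics, suppressing boundary effects.
#'
#' @param communities data.frame from [community_structure]
#' @param min_edges threshold (default 20); 0 is the identity
#' @return filtered data.frame; attribute `n_removed` records the count
#' @export
filter_isolated_communities <- function(communities, min_edges = 20) {
  drop <- communities$P == 0 & communities$e < min_edges
  structure(communities[!drop, , drop = FALSE], n_removed = sum(drop))
}

#' Build the community meta-network
#'
#' Communities become meta-nodes located at their centroids; every community
#' pair linked by at least one vessel segment receives one meta-edge whose
#' weight is the number of crossing segments.
#'
#' @param graph igraph or package graph classes
#' @param membership community assignment
#' @param communities optional (possibly filtered) table from
#'   [community_structure]; defaults to the full table
#' @param tissue_volume_mm3 optional analyzed volume for the densities
#'   `rho_c` (communities/mm^3) and `rho_ice` (intercommunity edges/mm^3)
#' @return object of class `meta_network`: weighted igraph `graph` (vertex
#'   attribute `community` maps back), `communities`, `n_ice`, densities
#' @export
build_meta_network <- function(graph, membership, communities = NULL,
                               tissue_volume_mm3 = NULL) {
  g <- as_igraph(graph)
  memb <- as.integer(factor(membership))
  if (is.null(communities)) communities <- community_structure(g, memb)
  keep <- communities$community
  el <- igraph::ends(g, igraph::E(g), names = FALSE)
  ca <- memb[el[, 1]]; cb <- memb[el[, 2]]
  cross <- ca != cb & ca %in% keep & cb %in% keep
  a <- pmin(ca[cross], cb[cross]); b <- pmax(ca[cross], cb[cross])
  idx <- match(a, keep); jdx <- match(b, keep)
  key <- paste(idx, jdx)
  w <- as.integer(table(key))
  pairs <- do.call(rbind, strsplit(names(table(key)), " "))
  mg <- igraph::make_graph(rbind(as.integer(pairs[, 1]), as.integer(pairs[, 2])),
                           n = length(keep), directed = FALSE)
  igraph::E(mg)$weight <- w
  igraph::V(mg)$community <- keep
  igraph::V(mg)$k_c <- communities$k_c
  if (!is.null(communities$cx)) {
    igraph::V(mg)$x <- communities$cx
    igraph::V(mg)$y <- communities$cy
    igraph::V(mg)$z <- communities$cz
  }
  n_ice <- sum(w)
  structure(list(graph = mg, communities = communities, n_ice = n_ice,
                 rho_c = if (is.null(tissue_volume_mm3)) NA_real_ else
                   length(keep) / tissue_volume_mm3,
                 rho_ice = if (is.null(tissue_volume_mm3)) NA_real_ else
                   n_ice / tissue_volume_mm3),
            class = "meta_network")
}

#' @export
print.meta_network <- function(x, ...) {
  cat(sprintf("meta_network: %d communities, %d meta-edges, N_ice = %d\n",
              igraph::vcount(x$graph), igraph::ecount(x$graph), x$n_ice))
  invisible(x)
}

#' Meta-network topology
#'
#' Clustering coefficient `C_c`, characteristic path length `L_c` and
#' diameter `D_c` of the unweighted simple meta-graph, a log-binned frequency
#' distribution of the community degree `k_c = 2e + P` (10 bins per decade),
#' and the unique-neighbor counts `k_cu`.
#'
#' @param meta a `meta_network`
#' @return list with `C_c`, `L_c`, `D_c`, `k_cu` (per community),
#'   `k_cu_mean`, and `k_c_hist`
#' @export
meta_topology <- function(meta) {
  stopifnot(inherits(meta, "meta_network"))
  mg <- igraph::simplify(meta$graph, remove.multiple = TRUE, remove.loops = TRUE)
  if (igraph::vcount(mg) < 2) stop("meta-network needs at least 2 communities")
  ci <- igraph::transitivity(mg, type = "local", isolates = "zero")
  ci[is.nan(ci)] <- 0
  sp <- shortest_path_stats(mg, exact_threshold = igraph::vcount(mg))
  kc <- meta$communities$k_c
  pos <- pmax(kc, 1)
  lb <- floor(log10(pos) * 10) / 10
  tab <- table(lb)
  hist <- data.frame(bin_center = 10^(as.numeric(names(tab)) + 0.05),
                     count = as.integer(tab))
  list(C_c = mean(ci), L_c = sp$L, D_c = sp$D,
       k_cu = igraph::degree(mg), k_cu_mean = mean(igraph::degree(mg)),
       k_c_hist = hist)
}

#' Community isolation exponent xi
#'
#' Robust power-law fit P ~ e^xi over individual communities with e > 0 and
#' P > 0; xi between 2/3 and 1 indicates weak community structure, lower
#' values stronger isolation (annotation only).
#'
#' @param communities data.frame from [community_structure]
#' @return list with `xi`, `scale`, `r_squared`, `n_support`, `flagged`,
#'   `interpretation`
#' @export
fit_isolation_exponent <- function(communities) {
  sub <- communities[communities$e > 0 & communities$P > 0, ]
  if (nrow(sub) < 5)
    return(list(xi = NA_real_, scale = NA_real_, r_squared = NA_real_,
                n_support = nrow(sub), flagged = TRUE,
                interpretation = NA_character_))
  fit <- robust_loglog_fit(sub$e, sub$P)
  xi <- fit$slope
  interp <- if (is.na(xi)) NA_character_
  else if (xi >= 2 / 3 && xi <= 1) "weak community structure"
  else if (xi < 2 / 3) "strongly isolated communities"
  else "perimeter grows superlinearly with size"
  list(xi = xi, scale = fit$scale, r_squared = fit$r_squared,
       n_support = fit$n, flagged = fit$flagged, interpretation = interp)
}

#' Meta-network assortativity exponent kappa
#'
#' For each community, the mean community degree of its unique (unweighted)
#' meta-neighbors, <k_c1>, is regressed against its own k_c with a robust
#' power-law fit <k_c1>(k_c) ~ k_c^kappa.
#'
#' @param meta a `meta_network`
#' @param weighted if `TRUE`, neighbor averaging weights by meta-edge weight
#' @return list with `kappa`, `knn` (per-community <k_c1>), fit diagnostics
#' @export
fit_assortativity <- function(meta, weighted = FALSE) {
  stopifnot(inherits(meta, "meta_network"))
  mg <- igraph::simplify(meta$graph, remove.multiple = FALSE, remove.loops = TRUE)
  nv <- igraph::vcount(mg)
  if (nv < 5)
    return(list(kappa = NA_real_, knn = rep(NA_real_, nv), flagged = TRUE))
  kc <- meta$communities$k_c
  el <- igraph::ends(mg, igraph::E(mg), names = FALSE)
  w <- if (weighted) igraph::E(mg)$weight else rep(1, nrow(el))
  if (!weighted) {
    # unique neighbors only
    key <- paste(pmin(el[, 1], el[, 2]), pmax(el[, 1], el[, 2]))
    first <- !duplicated(key)
    el <- el[first, , drop = FALSE]; w <- w[first]
  }
  num <- numeric(nv); den <- numeric(nv)
  for (i in seq_len(nrow(el))) {
    a <- el[i, 1]; b <- el[i, 2]
    num[a] <- num[a] + w[i] * kc[b]; den[a] <- den[a] + w[i]
    num[b] <- num[b] + w[i] * kc[a]; den[b] <- den[b] + w[i]
  }
  knn <- ifelse(den > 0, num / den, NA_real_)
  if (length(unique(kc[den > 0])) < 2) {
    # degree-regular meta-network: no degree relation to fit
    return(list(kappa = 0, knn = knn, scale = NA_real_, r_squared = NA_real_,
                n_support = sum(den > 0), flagged = TRUE))
  }
  fit <- robust_loglog_fit(kc[den > 0], knn[den > 0])
  list(kappa = fit$slope, knn = knn, scale = fit$scale,
       r_squared = fit$r_squared, n_support = fit$n, flagged = fit$flagged)
}

#' Meta path length versus physical separation
#'
#' Every connected community pair contributes its geodesic hop count and its
#' centroid separation Delta; pairs are binned by Delta with width
#' `delta_um` and summarized as per-bin mean L_c and pair count.
#'
#' @param meta a `meta_network` with centroid positions
#' @param delta_um bin width in um (default 50)
#' @return data.frame with `bin_lo`, `bin_hi`, `mean_L`, `n_pairs`
#' @export
path_length_vs_separation <- function(meta, delta_um = 50) {
  stopifnot(inherits(meta, "meta_network"))
  mg <- meta$graph
  if (is.null(igraph::V(mg)$x)) stop("meta-network has no centroid positions")
  dm <- igraph::distances(mg, weights = NA)
  nv <- igraph::vcount(mg)
  pos <- cbind(igraph::V(mg)$x, igraph::V(mg)$y, igraph::V(mg)$z)
  ut <- upper.tri(dm)
  hops <- dm[ut]
  sep <- as.matrix(stats::dist(pos))[ut]
  ok <- is.finite(hops)
  hops <- hops[ok]; sep <- sep[ok]
  if (!length(hops))
    return(data.frame(bin_lo = numeric(), bin_hi = numeric(),
                      mean_L = numeric(), n_pairs = integer()))
  bin <- floor(sep / delta_um)
  agg <- rowsum(cbind(hops, 1), bin)
  bins <- as.numeric(rownames(agg))
  data.frame(bin_lo = bins * delta_um, bin_hi = (bins + 1) * delta_um,
             mean_L = agg[, 1] / agg[, 2], n_pairs = as.integer(agg[, 2]))
}
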