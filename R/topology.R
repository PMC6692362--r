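as_igraph <- function(x) {
  if (inherits(x, "vascular_graph")) x$graph
  else if (inherits(x, "ground_truth_graph")) gt_as_igraph(x)
  else x
}

#' Degree distribution P(k)
#'
#' Relative frequencies of node degrees; self-loops count twice.
#'
#' @param graph igraph, [vascular_graph] or `ground_truth_graph`
#' @return data.frame with columns `k` and `p` (sums to 1), observed degrees only
#' @export
degree_distribution_pk <- function(graph) {
  g <- as_igraph(graph)
  stopifnot(igraph::vcount(g) >= 1)
  k <- igraph::degree(g, loops = TRUE)
  tab <- table(k)
  data.frame(k = as.integer(names(tab)), p = as.numeric(tab) / length(k))
}

#' Degree exponent from a log-log least-squares fit
#'
#' Fits `log10 P(k) ~ log10 k` over observed degrees `k >= k_min` (no
#' zero-count bins) and returns `gamma` = minus the slope, as used for
#' scale-free classification P(k) ~ k^-gamma.
#'
#' @param pk data.frame from [degree_distribution_pk] (or a graph)
#' @param k_min smallest degree entering the fit (default 5)
#' @return list with `gamma`, `r_squared`, `n_support`, `flagged`
#' @export
fit_degree_exponent <- function(pk, k_min = 5) {
  if (!is.data.frame(pk)) pk <- degree_distribution_pk(pk)
  sub <- pk[pk$k >= k_min & pk$p > 0, ]
  if (nrow(sub) < 3)
    return(list(gamma = NA_real_, r_squared = NA_real_,
                n_support = nrow(sub), flagged = TRUE))
  fit <- lm(log10(p) ~ log10(k), data = sub)
  r2 <- suppressWarnings(summary(fit)$r.squared)   # exact laws fit perfectly
  list(gamma = -unname(coef(fit)[2]),
       r_squared = r2,
       n_support = nrow(sub), flagged = FALSE)
}

#' Local clustering coefficients
#'
#' C_i = 2 E_i / (k_i (k_i - 1)) on the simple-graph reduction (parallel
#' edges collapsed, self-loops dropped). Nodes with fewer than two distinct
#' neighbors have C_i = 0 and are included in the mean; the mean excluding
#' them is also reported.
#'
#' @param graph igraph or package graph classes
#' @return list with `ci` (per node), `mean_c`, `mean_c_k2` (k >= 2 only),
#'   and `k` (multigraph degrees, loops twice)
#' @export
clustering_coefficients <- function(graph) {
  g <- as_igraph(graph)
  gs <- igraph::simplify(g, remove.multiple = TRUE, remove.loops = TRUE)
  ci <- igraph::transitivity(gs, type = "local", isolates = "zero")
  ci[is.nan(ci)] <- 0
  ks <- igraph::degree(gs)
  list(ci = ci, mean_c = mean(ci),
       mean_c_k2 = if (any(ks >= 2)) mean(ci[ks >= 2]) else NA_real_,
       k = igraph::degree(g, loops = TRUE))
}

#' Hierarchical scaling exponent beta
#'
#' Robust (IRLS, bisquare) fit of `log10 C_i ~ log10 k_i` over individual
#' nodes with `C_i > 0` and `k_i >= k_min`; hierarchical networks scale as
#' C(k) ~ k^-beta.
#'
#' @param ci per-node clustering coefficients (or a graph, in which case
#'   `k` is ignored)
#' @param k per-node degrees
#' @param k_min smallest degree entering the fit (default 3)
#' @param aggregate `"none"` fits over individual nodes (the choice for
#'   empirical point clouds); `"degree"` fits the per-degree mean C(k) with
#'   one point per distinct degree, the estimator of the C(k) relation itself
#'   (appropriate for deterministic models, whose node counts are heavily
#'   skewed towards the smallest degrees)
#' @return list with `beta`, `scale`, `r_squared`, `n_support`, `flagged`
#' @export
fit_hierarchical_exponent <- function(ci, k = NULL, k_min = 3,
                                      aggregate = c("none", "degree")) {
  aggregate <- match.arg(aggregate)
  if (!is.numeric(ci)) {
    cc <- clustering_coefficients(ci)
    ci <- cc$ci; k <- cc$k
  }
  sel <- ci > 0 & k >= k_min
  x <- k[sel]; y <- ci[sel]
  if (aggregate == "degree" && length(x)) {
    y <- as.numeric(tapply(y, x, mean))
    x <- sort(unique(x))
  }
  fit <- robust_loglog_fit(x, y)
  # when almost no node has a closed neighbor pair (e.g. sparse random
  # graphs), the C_i > 0 subset is a quantization artefact, not structure
  support_fraction <- if (any(k >= k_min)) mean(ci[k >= k_min] > 0) else 0
  list(beta = -fit$slope, scale = fit$scale, r_squared = fit$r_squared,
       n_support = fit$n, support_fraction = support_fraction,
       flagged = fit$flagged || support_fraction < 0.05)
}

#' Characteristic path length and diameter
#'
#' Unweighted geodesics within connected components, averaged over all
#' ordered reachable pairs. Exact breadth-first search from every node when
#' the graph has at most `exact_threshold` nodes; otherwise geodesics from
#' `n_sources` uniformly sampled source nodes (the diameter is then a lower
#' bound and the estimate is flagged approximate).
#'
#' @param graph igraph or package graph classes
#' @param exact_threshold node count up to which all-pairs BFS is used
#' @param n_sources number of BFS sources when sampling
#' @param seed RNG seed for source sampling
#' @return list with `L`, `D`, `exact`, `n_sources`
#' @export
shortest_path_stats <- function(graph, exact_threshold = 5000, n_sources = 1000,
                                seed = 1) {
  g <- as_igraph(graph)
  n <- igraph::vcount(g)
  if (n < 2) return(list(L = NA_real_, D = NA_real_, exact = TRUE, n_sources = n))
  exact <- n <= exact_threshold
  src <- if (exact) igraph::V(g) else
    with_seed(seed, sample.int(n, min(n_sources, n)))
  dm <- igraph::distances(g, v = src, weights = NA)
  vals <- dm[is.finite(dm) & dm > 0]
  list(L = mean(vals), D = max(vals), exact = exact, n_sources = length(src))
}

#' Full topology summary of a vascular network
#'
#' @param graph igraph or package graph classes
#' @param k_min_gamma,k_min_beta fit supports for the degree and hierarchical
#'   exponents
#' @param ... passed to [shortest_path_stats]
#' @return list of class `topology_summary`
#' @export
topology_summary <- function(graph, k_min_gamma = 5, k_min_beta = 3, ...) {
  g <- as_igraph(graph)
  k <- igraph::degree(g, loops = TRUE)
  pk <- degree_distribution_pk(g)
  cc <- clustering_coefficients(g)
  sp <- shortest_path_stats(g, ...)
  structure(list(
    n_nodes = igraph::vcount(g), n_edges = igraph::ecount(g),
    k_mean = mean(k), k_max = max(k),
    endpoint_fraction = mean(k == 1),
    pk = pk,
    gamma = fit_degree_exponent(pk, k_min = k_min_gamma),
    C = cc$mean_c, C_k2 = cc$mean_c_k2, ci = cc$ci,
    beta = fit_hierarchical_exponent(cc$ci, cc$k, k_min = k_min_beta),
    L = sp$L, D = sp$D, path_exact = sp$exact
  ), class = "topology_summary")
}

#' @export
print.topology_summary <- function(x, ...) {
  cat(sprintf("topology_summary: N_n %d, N_e %d, k_mean %.3f, k_max %d\n",
              x$n_nodes, x$n_edges, x$k_mean, x$k_max))
  cat(sprintf("  gamma %.3f (R2 %.2f), C %.4g, beta %.3f, L %.3f, D %g%s\n",
              x$gamma$gamma, x$gamma$r_squared, x$C, x$beta$beta, x$L, x$D,
              if (x$path_exact) "" else " (sampled)"))
  invisible(x)
}

#' Erdos-Renyi baseline ensemble
#'
#' Replicate G(n, m) graphs summarized by mean degree, maximum degree and
#' mean clustering coefficient, as a null model for vascular networks of the
#' same size.
#'
#' @param n,m node and edge counts
#' @param replicates ensemble size (default 12)
#' @param seed base seed; replicate i uses `seed + i - 1`
#' @return list with per-replicate data.frame and `mean`/`sd` rows
#' @export
er_baseline <- function(n, m, replicates = 12, seed = 1) {
  per <- lapply(seq_len(replicates), function(i) {
    g <- generate_er_graph(n, m, seed = seed + i - 1)
    k <- igraph::degree(g)
    ci <- igraph::transitivity(g, type = "local", isolates = "zero")
    ci[is.nan(ci)] <- 0
    data.frame(replicate = i, k_mean = mean(k), k_max = max(k), C = mean(ci))
  })
  tab <- do.call(rbind, per)
  list(replicates = tab,
       mean = colMeans(tab[, -1]),
       sd = apply(tab[, -1], 2, sd))
}
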