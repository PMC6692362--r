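#!/usr/bin/env Rscript
# Graph-topological quantification: degree distributions with gamma fits,
# clustering with the hierarchical beta fit, path lengths, against matched
# Erdos-Renyi baselines (including one ensemble at the published size).

library(vasculotopo)
dir.create("results", showWarnings = FALSE)

rows <- list()
for (mode in c("healthy_like", "tumor_like")) {
  for (s in 1:6) {
    g <- gt_as_igraph(generate_network(phantom_spec(mode = mode, seed = s +
                                                      ifelse(mode == "tumor_like", 50, 0))))
    ts <- topology_summary(g, seed = 1)
    rows[[length(rows) + 1]] <- data.frame(
      group = mode, seed = s, n_nodes = ts$n_nodes, n_edges = ts$n_edges,
      k_mean = ts$k_mean, k_max = ts$k_max,
      endpoint_fraction = ts$endpoint_fraction,
      gamma = ts$gamma$gamma, C = ts$C, beta = ts$beta$beta,
      L = ts$L, D = ts$D)
  }
}
tab <- do.call(rbind, rows)
write.csv(tab, "results/table2_topology_cohorts.csv", row.names = FALSE)
print(aggregate(tab[, -(1:2)], list(group = tab$group), mean), digits = 3)

message("Erdos-Renyi ensemble at the published mean size (n = 358k, m = 561k) ...")
eb <- er_baseline(358000, 561000, replicates = 12, seed = 1)
er <- data.frame(quantity = c("k_mean", "k_max", "C"),
                 mean = eb$mean, sd = eb$sd)
write.csv(er, "results/table2_er_baseline.csv", row.names = FALSE)
print(er, digits = 3)
message("random graphs cluster near k_mean/N_e ~ 1e-5; vascular phantoms sit ",
        "orders of magnitude above, with tumor-like networks the most clustered")

# modularity of a sparse random graph, for contrast with vascular values
ger <- generate_er_graph(20000, 31300, seed = 3)
per <- louvain_unfold(ger, seed = 1)
message(sprintf("Louvain on sparse G(n,m): Q = %.3f over %d communities — ",
                per$q_final, per$n_c),
        "substantially positive, as expected for sparse random graphs")
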