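#' Tagged skeleton
#'
#' One-voxel-wide centerline volume with every voxel tagged by its number of
#' foreground 26-neighbors: endpoints (< 2 neighbors), slab voxels (exactly
#' 2), junctions (> 2).
#'
#' @param tags integer 3D array: 0 background, 1 endpoint, 2 slab, 3 junction
#' @param spacing_um voxel spacing
#' @param origin_um physical origin
#' @return object of class `tagged_skeleton`
#' @export
tagged_skeleton <- function(tags, spacing_um = c(3.25, 3.25, 5),
                            origin_um = c(0, 0, 0)) {
  structure(list(tags = tags, spacing_um = as.numeric(spacing_um),
                 origin_um = as.numeric(origin_um)),
            class = "tagged_skeleton")
}

#' @export
print.tagged_skeleton <- function(x, ...) {
  tab <- tabulate(x$tags[x$tags > 0], 3L)
  cat(sprintf("tagged_skeleton: %d endpoints, %d slab, %d junction voxels\n",
              tab[1], tab[2], tab[3]))
  invisible(x)
}

#' Skeletonize a binary volume
#'
#' Topology-preserving medial-axis thinning to a one-voxel-wide, 26-connected
#' centerline (sequential simple-point peeling with directional subiterations
#' and curve-endpoint preservation), followed by neighbor-count tagging.
#' The thinned object has the same number of connected components and the
#' same Euler characteristic as the input.
#'
#' @param vol a [binary_volume]
#' @return a [tagged_skeleton]
#' @export
skeletonize <- function(vol) {
  stopifnot(inherits(vol, "binary_volume"))
  sk <- thin_cpp(vol$grid, dim(vol$grid))
  tag_skeleton(sk, vol$spacing_um, vol$origin_um)
}

#' Tag an existing one-voxel-wide skeleton
#'
#' @param skel logical 3D array of skeleton voxels
#' @param spacing_um,origin_um geometry of the grid
#' @return a [tagged_skeleton]
#' @export
tag_skeleton <- function(skel, spacing_um = c(3.25, 3.25, 5),
                         origin_um = c(0, 0, 0)) {
  cnt <- count_nbrs26_cpp(skel, dim(skel))
  tags <- integer(length(skel))
  tags[skel & cnt < 2L] <- 1L
  tags[skel & cnt == 2L] <- 2L
  tags[skel & cnt > 2L] <- 3L
  dim(tags) <- dim(skel)
  tagged_skeleton(tags, spacing_um, origin_um)
}

#' Vascular graph
#'
#' Undirected spatial multigraph of branch/end nodes connected by vessel
#' segments. Wraps an igraph object (vertex attributes `x`, `y`, `z` in um
#' and `kind`) together with per-edge ordered centerline voxel paths.
#'
#' @param graph igraph object
#' @param paths list (one entry per edge, igraph edge order) of integer
#'   matrices of voxel coordinates `[x, y, z]`
#' @param spacing_um,origin_um,dims grid geometry
#' @return object of class `vascular_graph`
#' @export
vascular_graph <- function(graph, paths, spacing_um = c(3.25, 3.25, 5),
                           origin_um = c(0, 0, 0), dims = NULL) {
  structure(list(graph = graph, paths = paths,
                 spacing_um = as.numeric(spacing_um),
                 origin_um = as.numeric(origin_um), dims = dims),
            class = "vascular_graph")
}

#' @export
print.vascular_graph <- function(x, ...) {
  cat(sprintf("vascular_graph: %d nodes, %d edges\n",
              igraph::vcount(x$graph), igraph::ecount(x$graph)))
  invisible(x)
}

node_positions <- function(vg) {
  g <- vg$graph
  cbind(x = igraph::V(g)$x, y = igraph::V(g)$y, z = igraph::V(g)$z)
}

vox_center_um <- function(coords, spacing, origin) {
  sweep(sweep(coords - 0.5, 2, spacing, "*"), 2, origin, "+")
}

#' Build the vascular graph from a tagged skeleton
#'
#' 26-connected clusters of junction voxels merge into single branch nodes
#' (position: cluster centroid in um); endpoint voxels become end nodes; each
#' maximal slab-voxel path between node clusters becomes one edge carrying
#' its ordered centerline. Multi-edges and self-loops are retained, as are
#' degree-2 nodes produced by tagging; isolated single voxels are dropped.
#' Pure cycles without any junction are anchored at their lexicographically
#' smallest voxel as a degree-2 node with a self-loop.
#'
#' @param skel a [tagged_skeleton]
#' @return a [vascular_graph]
#' @export
build_graph <- function(skel) {
  stopifnot(inherits(skel, "tagged_skeleton"))
  tags <- skel$tags
  d <- dim(tags)
  fgidx <- which(tags > 0L)
  nfg <- length(fgidx)
  empty <- function() {
    g <- igraph::make_empty_graph(0, directed = FALSE)
    vascular_graph(g, list(), skel$spacing_um, skel$origin_um, d)
  }
  if (nfg == 0L) return(empty())

  ord_of <- integer(prod(d))
  ord_of[fgidx] <- seq_len(nfg)
  coords <- arrayInd(fgidx, d)
  tagv <- as.integer(tags[fgidx])

  # 26-neighborhood voxel adjacency (each unordered pair once)
  offs <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
  offs <- offs[rowSums(abs(offs)) > 0, , drop = FALSE]
  offs <- offs[offs[, 3] > 0 | (offs[, 3] == 0 & (offs[, 2] > 0 |
                (offs[, 2] == 0 & offs[, 1] > 0))), , drop = FALSE]
  pa <- integer(0); pb <- integer(0)
  for (r in seq_len(nrow(offs))) {
    o <- offs[r, ]
    nx <- coords[, 1] + o[1]; ny <- coords[, 2] + o[2]; nz <- coords[, 3] + o[3]
    ok <- nx >= 1 & nx <= d[1] & ny >= 1 & ny <= d[2] & nz >= 1 & nz <= d[3]
    if (!any(ok)) next
    nlin <- fgidx[ok] + o[1] + d[1] * o[2] + d[1] * d[2] * o[3]
    hit <- ord_of[nlin] > 0L
    pa <- c(pa, which(ok)[hit])
    pb <- c(pb, ord_of[nlin[hit]])
  }

  # adjacency list over skeleton voxels
  adj <- split(c(pb, pa), factor(c(pa, pb), levels = seq_len(nfg)))

  # node voxels: junction clusters (26-adjacency transitive closure) + endpoints
  node_id <- integer(nfg)
  n_nodes <- 0L
  jmask <- tagv == 3L
  if (any(jmask)) {
    jp <- jmask[pa] & jmask[pb]
    gj <- igraph::make_graph(rbind(match(pa[jp], which(jmask)),
                                   match(pb[jp], which(jmask))),
                             n = sum(jmask), directed = FALSE)
    comp <- igraph::components(gj)$membership
    node_id[jmask] <- comp
    n_nodes <- max(comp)
  }
  emask <- tagv == 1L & lengths(adj) >= 1L  # isolated voxels dropped
  if (any(emask)) {
    node_id[emask] <- n_nodes + seq_len(sum(emask))
    n_nodes <- n_nodes + sum(emask)
  }

  edges_a <- integer(0); edges_b <- integer(0)
  paths <- list()
  add_edge <- function(a, b, path_ord) {
    edges_a <<- c(edges_a, a); edges_b <<- c(edges_b, b)
    paths[[length(paths) + 1L]] <<- coords[path_ord, , drop = FALSE]
  }

  visited <- logical(nfg)   # slab voxels claimed by a traced chain
  node_vox <- which(node_id > 0L)
  for (v in node_vox) {
    for (u in adj[[v]]) {
      if (node_id[u] > 0L) {
        # direct node-node adjacency; skip intra-cluster pairs, dedupe by order
        if (node_id[u] != node_id[v] && v < u) add_edge(node_id[v], node_id[u], c(v, u))
      } else if (!visited[u]) {
        path <- c(v, u)
        visited[u] <- TRUE
        prev <- v; cur <- u
        repeat {
          nbrs <- adj[[cur]]
          nxt <- nbrs[nbrs != prev]
          if (length(nxt) == 0L) break            # dangling slab chain end
          nxt <- nxt[1L]
          path <- c(path, nxt)
          if (node_id[nxt] > 0L) break
          visited[nxt] <- TRUE
          prev <- cur; cur <- nxt
        }
        tail_id <- node_id[path[length(path)]]
        if (tail_id > 0L) add_edge(node_id[v], tail_id, path)
        else add_edge(node_id[v], node_id[v], path)  # defensive: open chain
      }
    }
  }

  # pure cycles: slab components never reached from any node voxel
  left <- which(tagv == 2L & !visited)
  if (length(left)) {
    lset <- logical(nfg); lset[left] <- TRUE
    for (anchor in left[order(fgidx[left])]) {
      if (visited[anchor]) next
      n_nodes <- n_nodes + 1L
      node_id[anchor] <- n_nodes
      visited[anchor] <- TRUE
      nbrs <- adj[[anchor]]
      path <- anchor
      prev <- anchor; cur <- nbrs[1L]
      while (cur != anchor) {
        path <- c(path, cur)
        visited[cur] <- TRUE
        nxt <- adj[[cur]][adj[[cur]] != prev][1L]
        prev <- cur; cur <- nxt
      }
      add_edge(n_nodes, n_nodes, c(path, anchor))
    }
  }

  if (n_nodes == 0L) return(empty())

  # node positions: centroid of member voxels
  memb <- which(node_id > 0L)
  pos_um <- vox_center_um(coords, skel$spacing_um, skel$origin_um)
  px <- rowsum(pos_um[memb, 1], node_id[memb])
  py <- rowsum(pos_um[memb, 2], node_id[memb])
  pz <- rowsum(pos_um[memb, 3], node_id[memb])
  nm <- tabulate(node_id[memb], n_nodes)
  kind <- rep("branch", n_nodes)
  kind[sort(unique(node_id[emask]))] <- "end"

  g <- igraph::make_graph(rbind(edges_a, edges_b), n = n_nodes, directed = FALSE)
  igraph::V(g)$x <- as.numeric(px / nm)
  igraph::V(g)$y <- as.numeric(py / nm)
  igraph::V(g)$z <- as.numeric(pz / nm)
  igraph::V(g)$kind <- kind
  igraph::V(g)$n_voxels <- nm
  vascular_graph(g, paths, skel$spacing_um, skel$origin_um, d)
}

#' Node density
#'
#' @param vgraph a [vascular_graph] (or igraph)
#' @param tissue_volume_mm3 analyzed (shrunken) tissue volume in mm^3
#' @return nodes per mm^3
#' @export
node_density <- function(vgraph, tissue_volume_mm3) {
  stopifnot(tissue_volume_mm3 > 0)
  g <- if (inherits(vgraph, "vascular_graph")) vgraph$graph else vgraph
  igraph::vcount(g) / tissue_volume_mm3
}
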