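#' Phantom specification
#'
#' Generative parameters for synthetic vascular networks. The
#' `healthy_like` preset emulates hierarchical arterio-venous trees feeding a
#' dense, lattice-like capillary mesh, calibrated to a vessel length density
#' of about 980 mm/mm^3 and an endpoint (degree-1) fraction of about 0.11.
#' The `tumor_like` preset fragments the same mesh (random edge deletion),
#' inserts terminal stubs up to an endpoint fraction of about 0.22, adds
#' short cross-links that create local vessel loops (raising clustering), and
#' increases segment tortuosity. `custom` builds a single deterministic
#' bifurcating tree, useful as an exact combinatorial oracle.
#'
#' @param domain_size_um physical extent, um (3-vector)
#' @param voxel_spacing_um voxel pitch for voxelization (default the
#'   anisotropic 3.25 x 3.25 x 5 um grid)
#' @param mode `"healthy_like"`, `"tumor_like"` or `"custom"`
#' @param n_seed_trees number of arterio-venous seed trees
#' @param capillary_mesh_density target vessel length per volume, mm/mm^3
#' @param radius_range_um (capillary radius, trunk radius) in um
#' @param endpoint_fraction_target target fraction of degree-1 nodes;
#'   `NULL` uses the preset (0.11 healthy-like, 0.22 tumor-like)
#' @param tortuosity_amplitude dimensionless bow amplitude of segment
#'   centerlines; `NULL` uses the preset (0.15 healthy-like, 0.5 tumor-like)
#' @param tree_levels bifurcation levels for `custom` trees
#' @param noise a [noise_spec] or `NULL`
#' @param seed integer RNG seed
#' @param max_voxels memory guard for the implied voxel grid
#' @return object of class `phantom_spec`
#' @export
phantom_spec <- function(domain_size_um = c(600, 600, 300),
                         voxel_spacing_um = c(3.25, 3.25, 5),
                         mode = c("healthy_like", "tumor_like", "custom"),
                         n_seed_trees = 2,
                         capillary_mesh_density = 980,
                         radius_range_um = c(3, 12),
                         endpoint_fraction_target = NULL,
                         tortuosity_amplitude = NULL,
                         tree_levels = 3,
                         noise = NULL,
                         seed = 1,
                         max_voxels = 4e7) {
  mode <- match.arg(mode)
  stopifnot(all(domain_size_um > 0), all(voxel_spacing_um > 0),
            n_seed_trees >= 0, capillary_mesh_density > 0,
            length(radius_range_um) == 2, all(radius_range_um > 0),
            tree_levels >= 1)
  if (is.null(endpoint_fraction_target))
    endpoint_fraction_target <- switch(mode, healthy_like = 0.11,
                                       tumor_like = 0.22, custom = NA_real_)
  if (!is.na(endpoint_fraction_target) &&
      (endpoint_fraction_target < 0 || endpoint_fraction_target > 1))
    stop("endpoint_fraction_target must be in [0, 1]")
  if (is.null(tortuosity_amplitude))
    tortuosity_amplitude <- switch(mode, healthy_like = 0.15,
                                   tumor_like = 0.5, custom = 0)
  stopifnot(tortuosity_amplitude >= 0)
  nvox <- prod(ceiling(domain_size_um / voxel_spacing_um))
  if (nvox > max_voxels)
    stop(sprintf("implied grid of %.3g voxels exceeds max_voxels = %.3g",
                 nvox, max_voxels))
  structure(list(domain_size_um = as.numeric(domain_size_um),
                 voxel_spacing_um = as.numeric(voxel_spacing_um),
                 mode = mode, n_seed_trees = n_seed_trees,
                 capillary_mesh_density = capillary_mesh_density,
                 radius_range_um = as.numeric(radius_range_um),
                 endpoint_fraction_target = endpoint_fraction_target,
                 tortuosity_amplitude = tortuosity_amplitude,
                 tree_levels = tree_levels, noise = noise, seed = seed),
            class = "phantom_spec")
}

#' Noise specification for volume corruption
#'
#' @param speck_count number of isolated small foreground components to add
#' @param speck_radius_um radius of each speck (must stay below the 6 um
#'   cleanup sphere for [remove_specks] to undo it)
#' @param hole_count number of single-voxel interior cavities to carve
#' @param boundary_fuzz_prob per-surface-voxel flip probability
#' @param seed RNG seed
#' @return object of class `noise_spec`
#' @export
noise_spec <- function(speck_count = 0, speck_radius_um = 3, hole_count = 0,
                       boundary_fuzz_prob = 0, seed = 1) {
  stopifnot(speck_count >= 0, hole_count >= 0,
            boundary_fuzz_prob >= 0, boundary_fuzz_prob <= 1)
  structure(list(speck_count = speck_count, speck_radius_um = speck_radius_um,
                 hole_count = hole_count,
                 boundary_fuzz_prob = boundary_fuzz_prob, seed = seed),
            class = "noise_spec")
}

polyline_length <- function(m) {
  if (nrow(m) < 2) return(0)
  sum(sqrt(rowSums((m[-1, , drop = FALSE] - m[-nrow(m), , drop = FALSE])^2)))
}

# unit vectors spanning the plane perpendicular to v
perp_basis <- function(v) {
  v <- v / sqrt(sum(v^2))
  a <- if (abs(v[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  u <- a - sum(a * v) * v
  u <- u / sqrt(sum(u^2))
  w <- c(v[2] * u[3] - v[3] * u[2], v[3] * u[1] - v[1] * u[3],
         v[1] * u[2] - v[2] * u[1])
  list(u = u, w = w)
}

# sinusoidal-bow polyline from p0 to p1 with peak displacement
# amplitude/2 * chord, in a random perpendicular direction
make_polyline <- function(p0, p1, amplitude, step_um = 10) {
  chord <- sqrt(sum((p1 - p0)^2))
  if (chord == 0) return(rbind(p0, p1))
  n <- max(2L, ceiling(chord / step_um))
  t <- seq(0, 1, length.out = n + 1L)
  base <- outer(1 - t, p0) + outer(t, p1)
  if (amplitude <= 0) return(base)
  pb <- perp_basis(p1 - p0)
  phi <- runif(1, 0, 2 * pi)
  dirv <- cos(phi) * pb$u + sin(phi) * pb$w
  h <- 0.5 * amplitude * chord
  base + outer(h * sin(pi * t), dirv)
}

gt_new <- function(spec) {
  list(nodes = data.frame(id = integer(), x = numeric(), y = numeric(),
                          z = numeric()),
       edges = data.frame(id = integer(), node_a = integer(),
                          node_b = integer(), radius_um = numeric()),
       polylines = list(), spec = spec)
}

gt_add_node <- function(gt, pos) {
  id <- nrow(gt$nodes) + 1L
  gt$nodes[id, ] <- c(id, pos)
  gt
}

gt_add_edge <- function(gt, a, b, radius, polyline = NULL, amplitude = 0) {
  pa <- as.numeric(gt$nodes[a, c("x", "y", "z")])
  pb <- as.numeric(gt$nodes[b, c("x", "y", "z")])
  if (is.null(polyline)) polyline <- make_polyline(pa, pb, amplitude)
  id <- nrow(gt$edges) + 1L
  gt$edges[id, ] <- list(id, a, b, radius)
  gt$polylines[[id]] <- polyline
  gt
}

gt_degrees <- function(gt) {
  tabulate(c(gt$edges$node_a, gt$edges$node_b), nrow(gt$nodes))
}

gt_finalize <- function(gt) {
  deg <- gt_degrees(gt)
  keep <- which(deg > 0L)
  remap <- integer(nrow(gt$nodes)); remap[keep] <- seq_along(keep)
  gt$nodes <- gt$nodes[keep, , drop = FALSE]
  gt$nodes$id <- seq_along(keep)
  gt$edges$node_a <- remap[gt$edges$node_a]
  gt$edges$node_b <- remap[gt$edges$node_b]
  gt$edges$id <- seq_len(nrow(gt$edges))
  rownames(gt$nodes) <- rownames(gt$edges) <- NULL
  gt$nodes$degree <- gt_degrees(gt)
  gt$edges$length_um <- vapply(gt$polylines, polyline_length, 0)
  d <- sqrt(rowSums((as.matrix(gt$nodes[gt$edges$node_a, c("x", "y", "z")]) -
                     as.matrix(gt$nodes[gt$edges$node_b, c("x", "y", "z")]))^2))
  gt$edges$tortuosity <- ifelse(d > 0, gt$edges$length_um / d, NA_real_)
  class(gt) <- "ground_truth_graph"
  gt
}

#' @export
print.ground_truth_graph <- function(x, ...) {
  cat(sprintf("ground_truth_graph: %d nodes, %d edges, endpoint fraction %.3f\n",
              nrow(x$nodes), nrow(x$edges), mean(x$nodes$degree == 1)))
  invisible(x)
}

#' Ground truth as an igraph object
#'
#' Vertex attributes `x`, `y`, `z` carry node positions in um.
#' @param gt a `ground_truth_graph`
#' @return igraph object
#' @export
gt_as_igraph <- function(gt) {
  g <- igraph::make_graph(rbind(gt$edges$node_a, gt$edges$node_b),
                          n = nrow(gt$nodes), directed = FALSE)
  igraph::V(g)$x <- gt$nodes$x
  igraph::V(g)$y <- gt$nodes$y
  igraph::V(g)$z <- gt$nodes$z
  g
}

# deterministic-geometry bifurcating tree grown along +x, alternating split
# planes; returns updated gt and ids of leaf nodes
grow_tree <- function(gt, root_pos, levels, r0, seg_len, amplitude, dir0 = c(1, 0, 0),
                      r_min = 0) {
  gt <- gt_add_node(gt, root_pos)
  root <- nrow(gt$nodes)
  tips <- list(list(node = root, pos = root_pos, dir = dir0, r = r0,
                    len = seg_len))
  # trunk
  leaves <- integer(0)
  for (lev in seq_len(levels + 1L)) {
    newtips <- list()
    for (tp in tips) {
      endp <- tp$pos + tp$dir * tp$len
      gt <- gt_add_node(gt, endp)
      nid <- nrow(gt$nodes)
      gt <- gt_add_edge(gt, tp$node, nid, tp$r, amplitude = amplitude)
      if (lev > levels) { leaves <- c(leaves, nid); next }
      # split into two children in the plane alternating with level
      pb <- perp_basis(tp$dir)
      axis <- if (lev %% 2 == 1) pb$u else pb$w
      ang <- pi / 5
      for (s in c(-1, 1)) {
        cd <- cos(ang) * tp$dir + s * sin(ang) * axis
        cd <- cd / sqrt(sum(cd^2))
        newtips[[length(newtips) + 1L]] <-
          list(node = nid, pos = endp, dir = cd,
               r = max(tp$r * 2^(-1 / 3), r_min),   # Murray taper, capillary floor
               len = tp$len * 0.72)
      }
    }
    if (lev <= levels) tips <- newtips
  }
  list(gt = gt, root = root, leaves = leaves)
}

#' Generate a synthetic vascular network with known topology
#'
#' Deterministic given `spec$seed`. See [phantom_spec] for the generative
#' model behind each mode.
#'
#' @param spec a [phantom_spec]
#' @return a `ground_truth_graph` with nodes (positions in um, true degree),
#'   edges (centerline polylines, radii, lengths, tortuosities)
#' @export
generate_network <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  with_seed(spec$seed, {
    if (spec$mode == "custom") generate_custom_tree(spec)
    else generate_mesh_network(spec)
  })
}

generate_custom_tree <- function(spec) {
  L <- spec$domain_size_um
  gt <- gt_new(spec)
  seg0 <- min(L) * 0.22
  res <- grow_tree(gt, c(0.08 * L[1], L[2] / 2, L[3] / 2),
                   levels = spec$tree_levels, r0 = spec$radius_range_um[2],
                   seg_len = seg0, amplitude = spec$tortuosity_amplitude,
                   r_min = spec$radius_range_um[1])
  gt_finalize(res$gt)
}

generate_mesh_network <- function(spec) {
  L <- spec$domain_size_um
  rho <- spec$capillary_mesh_density            # mm / mm^3
  p_keep <- 0.55
  a_mm <- sqrt(2.6 * p_keep / rho)              # lattice pitch from density
  a <- a_mm * 1000
  if (a < 3 * max(spec$voxel_spacing_um))
    stop("infeasible capillary_mesh_density: lattice pitch below voxel resolvability")
  nl <- floor(L / a)
  if (any(nl < 2))
    stop("infeasible capillary_mesh_density for domain size: fewer than 2 lattice cells along an axis")

  # jittered lattice nodes
  gpts <- as.matrix(expand.grid(x = seq_len(nl[1]), y = seq_len(nl[2]),
                                z = seq_len(nl[3])))
  off <- (L - nl * a) / 2
  pos <- sweep((gpts - 0.5) * a, 2, off, "+") +
    matrix(runif(length(gpts), -0.2 * a, 0.2 * a), ncol = 3)
  gt <- gt_new(spec)
  gt$nodes <- data.frame(id = seq_len(nrow(pos)), x = pos[, 1], y = pos[, 2],
                         z = pos[, 3])
  nid <- array(seq_len(nrow(gpts)), nl)

  # candidate lattice edges (+x, +y, +z), sampled to hit the target length
  cand_a <- integer(0); cand_b <- integer(0)
  if (nl[1] > 1) { cand_a <- c(cand_a, nid[-nl[1], , ]); cand_b <- c(cand_b, nid[-1, , ]) }
  if (nl[2] > 1) { cand_a <- c(cand_a, nid[, -nl[2], ]); cand_b <- c(cand_b, nid[, -1, ]) }
  if (nl[3] > 1) { cand_a <- c(cand_a, nid[, , -nl[3]]); cand_b <- c(cand_b, nid[, , -1]) }
  target_len <- rho * prod(L / 1000) * 1000     # um
  p_eff <- target_len / (a * length(cand_a))
  if (p_eff > 1)
    stop("infeasible capillary_mesh_density for domain size: lattice cannot supply the requested length")
  sel <- runif(length(cand_a)) < p_eff
  rmin <- spec$radius_range_um[1]
  for (i in which(sel))
    gt <- gt_add_edge(gt, cand_a[i], cand_b[i], rmin,
                      amplitude = spec$tortuosity_amplitude)

  # arterio-venous seed trees entering from the top face, leaves tied into the mesh
  if (spec$n_seed_trees > 0) {
    for (tix in seq_len(spec$n_seed_trees)) {
      root <- c(runif(1, 0.2, 0.8) * L[1], runif(1, 0.2, 0.8) * L[2], 0.02 * L[3])
      res <- grow_tree(gt, root, levels = 2, r0 = spec$radius_range_um[2],
                       seg_len = 0.25 * L[3], amplitude = spec$tortuosity_amplitude,
                       dir0 = c(0, 0, 1), r_min = spec$radius_range_um[1])
      gt <- res$gt
      for (lf in res$leaves) {
        lp <- as.numeric(gt$nodes[lf, c("x", "y", "z")])
        dd <- (pos[, 1] - lp[1])^2 + (pos[, 2] - lp[2])^2 + (pos[, 3] - lp[3])^2
        gt <- gt_add_edge(gt, lf, which.min(dd), rmin,
                          amplitude = spec$tortuosity_amplitude)
      }
    }
  }

  if (spec$mode == "tumor_like") {
    # fragmentation: random deletion of about a third of all segments,
    # emulating occlusion and regression
    ne <- nrow(gt$edges)
    drop <- sample.int(ne, round(0.35 * ne))
    gt$edges <- gt$edges[-drop, , drop = FALSE]
    gt$polylines <- gt$polylines[-drop]
  }
  # local vessel loops: cross-links between two neighbors of a node; sparse
  # in healthy capillary beds, abundant under angiogenic remodeling
  tri_rate <- if (spec$mode == "tumor_like") 0.10 else 0.02
  deg <- gt_degrees(gt)
  adj <- split(c(gt$edges$node_b, gt$edges$node_a),
               factor(c(gt$edges$node_a, gt$edges$node_b),
                      levels = seq_len(nrow(gt$nodes))))
  hubs <- which(deg >= 2)
  n_tri <- round(tri_rate * nrow(gt$nodes))
  if (length(hubs) > 0 && n_tri > 0) {
    pick <- sample(hubs, min(n_tri, length(hubs)))
    for (h in pick) {
      nb <- unique(adj[[h]])
      if (length(nb) < 2) next
      ab <- sample(nb, 2)
      gt <- gt_add_edge(gt, ab[1], ab[2], rmin,
                        amplitude = spec$tortuosity_amplitude)
    }
  }

  # calibrate the endpoint fraction by inserting terminal stubs
  target <- spec$endpoint_fraction_target
  if (!is.na(target)) {
    deg <- gt_degrees(gt)
    live <- deg > 0
    for (iter in seq_len(20000)) {
      frac <- sum(deg == 1 & live) / sum(live)
      if (frac >= target) break
      h <- sample(which(deg >= 2), 1)
      hp <- as.numeric(gt$nodes[h, c("x", "y", "z")])
      dirv <- rnorm(3); dirv <- dirv / sqrt(sum(dirv^2))
      sp <- pmin(pmax(hp + dirv * 0.35 * a, 2), L - 2)
      gt <- gt_add_node(gt, sp)
      gt <- gt_add_edge(gt, h, nrow(gt$nodes), rmin,
                        amplitude = spec$tortuosity_amplitude)
      deg <- c(deg, 0L)
      deg[h] <- deg[h] + 1L
      deg[length(deg)] <- 1L
      live <- c(live, TRUE)
    }
  }
  gt_finalize(gt)
}

#' Voxelize a ground-truth network onto an anisotropic grid
#'
#' Marks every voxel whose center lies within the (radius-interpolated)
#' capsule around each centerline polyline segment; overlapping tubes union.
#' Segments with radius below half the largest spacing component are below
#' the resolvability guard: they are still drawn but flagged with a warning.
#'
#' @param gt a `ground_truth_graph`
#' @param spacing_um voxel spacing (default from the spec)
#' @return a [binary_volume]; attribute `flagged_segments` lists edges below
#'   the resolvability guard
#' @export
voxelize <- function(gt, spacing_um = NULL) {
  stopifnot(inherits(gt, "ground_truth_graph"))
  if (is.null(spacing_um)) spacing_um <- gt$spec$voxel_spacing_um
  L <- gt$spec$domain_size_um
  dims <- pmax(ceiling(L / spacing_um), 1)
  grid <- array(FALSE, dims)
  guard <- max(spacing_um) / 2
  flagged <- which(gt$edges$radius_um < guard)
  if (length(flagged))
    warning(sprintf("%d segment(s) thinner than the resolvability guard (%.2f um)",
                    length(flagged), guard))
  if (nrow(gt$edges) == 0)
    return(structure(binary_volume(grid, spacing_um), flagged_segments = integer(0)))

  cx <- (seq_len(dims[1]) - 0.5) * spacing_um[1]
  cy <- (seq_len(dims[2]) - 0.5) * spacing_um[2]
  cz <- (seq_len(dims[3]) - 0.5) * spacing_um[3]
  for (e in seq_len(nrow(gt$edges))) {
    pl <- gt$polylines[[e]]
    r <- gt$edges$radius_um[e]
    for (s in seq_len(nrow(pl) - 1L)) {
      p0 <- pl[s, ]; p1 <- pl[s + 1L, ]
      lo <- pmin(p0, p1) - r - 0.5 * spacing_um
      hi <- pmax(p0, p1) + r + 0.5 * spacing_um
      i0 <- pmax(1, floor(lo / spacing_um + 0.5)); i1 <- pmin(dims, ceiling(hi / spacing_um + 0.5))
      if (any(i0 > i1)) next
      ix <- i0[1]:i1[1]; iy <- i0[2]:i1[2]; iz <- i0[3]:i1[3]
      nxs <- length(ix); nys <- length(iy); nzs <- length(iz)
      px <- rep(cx[ix], times = nys * nzs)
      py <- rep(rep(cy[iy], each = nxs), times = nzs)
      pz <- rep(cz[iz], each = nxs * nys)
      v <- p1 - p0
      vv <- sum(v^2)
      capsule_d2 <- function(qx, qy, qz) {
        if (vv == 0) return((qx - p0[1])^2 + (qy - p0[2])^2 + (qz - p0[3])^2)
        t <- ((qx - p0[1]) * v[1] + (qy - p0[2]) * v[2] + (qz - p0[3]) * v[3]) / vv
        t <- pmin(pmax(t, 0), 1)
        (qx - (p0[1] + t * v[1]))^2 + (qy - (p0[2] + t * v[2]))^2 +
          (qz - (p0[3] + t * v[3]))^2
      }
      # center rule guarantees centerline voxels; the 3x3x3 subsample
      # majority approximates >= 50% voxel coverage for near-unbiased volume
      inside <- capsule_d2(px, py, pz) <= r^2
      cover <- integer(length(px))
      sub <- c(-1 / 3, 0, 1 / 3)
      for (sx in sub) for (sy in sub) for (sz in sub)
        cover <- cover + (capsule_d2(px + sx * spacing_um[1],
                                     py + sy * spacing_um[2],
                                     pz + sz * spacing_um[3]) <= r^2)
      inside <- inside | cover >= 14L
      if (any(inside)) {
        sub <- grid[ix, iy, iz]
        sub[inside] <- TRUE
        grid[ix, iy, iz] <- sub
      }
    }
  }
  structure(binary_volume(grid, spacing_um), flagged_segments = flagged)
}

#' Corrupt a binary volume with segmentation-like artefacts
#'
#' Adds isolated specks (small foreground balls placed clear of existing
#' foreground), carves single-voxel interior cavities ("hollow" vessels), and
#' flips surface voxels with a stated probability. Deterministic given
#' `noise$seed`; an all-zero spec is the identity.
#'
#' @param vol a [binary_volume]
#' @param noise a [noise_spec]
#' @return a [binary_volume]
#' @export
corrupt <- function(vol, noise) {
  stopifnot(inherits(vol, "binary_volume"), inherits(noise, "noise_spec"))
  if (noise$speck_count == 0 && noise$hole_count == 0 &&
      noise$boundary_fuzz_prob == 0) return(vol)
  with_seed(noise$seed, {
    g <- vol$grid
    d <- dim(g)
    sp <- vol$spacing_um

    if (noise$boundary_fuzz_prob > 0) {
      surf <- which(boundary_layer(g))
      flip <- surf[runif(length(surf)) < noise$boundary_fuzz_prob]
      g[flip] <- FALSE
    }

    if (noise$hole_count > 0) {
      # interior voxels: full 3x3x3 neighborhood foreground
      cnt <- count_nbrs26_cpp(g, d)
      interior <- which(g & cnt == 26L)
      if (length(interior)) {
        carve <- sample(interior, min(noise$hole_count, length(interior)))
        g[carve] <- FALSE
      }
    }

    if (noise$speck_count > 0) {
      rvox <- ceiling(noise$speck_radius_um / sp)
      placed <- 0L
      for (att in seq_len(noise$speck_count * 200)) {
        if (placed >= noise$speck_count) break
        c0 <- c(sample.int(d[1], 1), sample.int(d[2], 1), sample.int(d[3], 1))
        i0 <- pmax(1, c0 - rvox - 1L); i1 <- pmin(d, c0 + rvox + 1L)
        box <- g[i0[1]:i1[1], i0[2]:i1[2], i0[3]:i1[3]]
        if (any(box)) next   # keep specks disjoint from everything
        ix <- i0[1]:i1[1]; iy <- i0[2]:i1[2]; iz <- i0[3]:i1[3]
        dx2 <- ((ix - c0[1]) * sp[1])^2
        dy2 <- ((iy - c0[2]) * sp[2])^2
        dz2 <- ((iz - c0[3]) * sp[3])^2
        ball <- outer(outer(dx2, dy2, "+"), dz2, "+") <= noise$speck_radius_um^2
        sub <- g[ix, iy, iz]
        sub[ball] <- TRUE
        g[ix, iy, iz] <- sub
        placed <- placed + 1L
      }
      if (placed < noise$speck_count)
        warning(sprintf("placed only %d of %d specks", placed, noise$speck_count))
    }

    out <- vol
    out$grid <- g
    out
  })
}

#' Erdos-Renyi G(n, m) random graph
#'
#' Simple undirected graph with exactly `n` nodes and `m` distinct edges,
#' uniform over edge sets.
#'
#' @param n,m node and edge counts; `m <= n(n-1)/2`
#' @param seed RNG seed
#' @return igraph object
#' @export
generate_er_graph <- function(n, m, seed = 1) {
  if (m > n * (n - 1) / 2) stop("m exceeds the number of possible edges")
  with_seed(seed, igraph::sample_gnm(n, m))
}

#' Deterministic hierarchical (Ravasz-type) network
#'
#' Starts from a 5-clique and iteratively replicates the module four times,
#' wiring the peripheral nodes of the replicas to the central hub. Its node
#' clustering scales as C(k) ~ 1/k, making it an oracle for hierarchical
#' exponent fits with beta near 1.
#'
#' @param levels number of construction levels (>= 2); the graph has
#'   `5^levels` nodes
#' @return igraph object
#' @export
generate_hierarchical_graph <- function(levels) {
  stopifnot(levels >= 2)
  # level 1: K5 with hub 1, peripheral nodes 2..5
  el <- t(utils::combn(5L, 2L))
  periph <- 2:5
  nn <- 5L
  for (t_ in seq_len(levels - 1L)) {
    base_el <- el
    base_periph <- periph
    new_el <- base_el
    new_periph <- integer(0)
    for (i in 1:4) {
      off <- i * nn
      new_el <- rbind(new_el, base_el + off)
      new_periph <- c(new_periph, base_periph + off)
    }
    new_el <- rbind(new_el, cbind(1L, new_periph))
    el <- new_el
    periph <- new_periph
    nn <- nn * 5L
  }
  igraph::make_graph(t(el), n = nn, directed = FALSE)
}

#' Configuration-model graph with power-law degrees
#'
#' Degrees are sampled from a truncated discrete power law
#' P(k) ~ k^-gamma on `k_min .. k_max` (default structural cutoff
#' sqrt(n)); the configuration model preserves the drawn degree sequence
#' exactly (multi-edges and loops permitted).
#'
#' @param n number of nodes (>= 100)
#' @param gamma power-law exponent (> 1)
#' @param seed RNG seed
#' @param k_min,k_max degree support of the truncated power law
#' @return igraph object
#' @export
generate_powerlaw_graph <- function(n, gamma, seed = 1, k_min = 3,
                                    k_max = floor(sqrt(n))) {
  stopifnot(gamma > 1, n >= 100, k_min >= 1, k_max > k_min)
  with_seed(seed, {
    ks <- k_min:k_max
    pr <- ks^(-gamma)
    deg <- sample(ks, n, replace = TRUE, prob = pr / sum(pr))
    if (sum(deg) %% 2 == 1) deg[which.max(deg)] <- deg[which.max(deg)] + 1L
    igraph::sample_degseq(deg, method = "configuration")
  })
}
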