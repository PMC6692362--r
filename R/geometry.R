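#' Euclidean distance transform of a binary volume
#'
#' Physical (anisotropic) distance from each foreground voxel center to the
#' nearest background voxel center, in um; 0 on background.
#'
#' @param vol a [binary_volume]
#' @return numeric 3D array
#' @export
distance_transform <- function(vol) {
  stopifnot(inherits(vol, "binary_volume"))
  d2 <- edt_sq_cpp(vol$grid, dim(vol$grid), vol$spacing_um)
  dim(d2) <- dim(vol$grid)
  sqrt(d2)
}

edge_polyline_um <- function(vg, e) {
  pts <- vox_center_um(vg$paths[[e]], vg$spacing_um, vg$origin_um)
  ends <- igraph::ends(vg$graph, e)
  pa <- as.numeric(c(igraph::V(vg$graph)$x[ends[1]], igraph::V(vg$graph)$y[ends[1]],
                     igraph::V(vg$graph)$z[ends[1]]))
  pb <- as.numeric(c(igraph::V(vg$graph)$x[ends[2]], igraph::V(vg$graph)$y[ends[2]],
                     igraph::V(vg$graph)$z[ends[2]]))
  # extend the voxel path to the node positions (cluster centroids) so that
  # arc length and endpoint separation refer to the same endpoints
  if (sum((pts[1, ] - pa)^2) > sum((pts[1, ] - pb)^2)) { tmp <- pa; pa <- pb; pb <- tmp }
  rbind(pa, pts, pb)
}

#' Per-segment vessel geometry
#'
#' For every edge of the vascular graph: true centerline length `l` (sum of
#' physical step lengths, extended to the node positions), Euclidean endpoint
#' separation `d`, tortuosity `tau = l/d` (undefined for self-loops, which
#' are excluded from tortuosity statistics), mean radius `r_um` from the
#' distance transform sampled along slab voxels (junction voxels are
#' excluded: their distance values conflate adjoining vessels), and lateral
#' surface area `A = sum 2 pi r_i dl_i`.
#'
#' @param vol the [binary_volume] the graph was extracted from
#' @param vgraph a [vascular_graph]
#' @param skel optionally the [tagged_skeleton], used to exclude junction
#'   voxels from radius profiles
#' @return data.frame with one row per edge: `edge_id`, `length_um`,
#'   `separation_um`, `tortuosity`, `radius_um`, `surface_um2`
#' @export
segment_geometry <- function(vol, vgraph, skel = NULL) {
  stopifnot(inherits(vol, "binary_volume"), inherits(vgraph, "vascular_graph"))
  ne <- igraph::ecount(vgraph$graph)
  if (ne == 0)
    return(data.frame(edge_id = integer(), length_um = numeric(),
                      separation_um = numeric(), tortuosity = numeric(),
                      radius_um = numeric(), surface_um2 = numeric()))
  edt <- distance_transform(vol)
  d <- dim(vol$grid)
  tags <- if (!is.null(skel)) skel$tags else NULL

  out <- lapply(seq_len(ne), function(e) {
    pl <- edge_polyline_um(vgraph, e)
    steps <- sqrt(rowSums((pl[-1, , drop = FALSE] - pl[-nrow(pl), , drop = FALSE])^2))
    l <- sum(steps)
    dsep <- sqrt(sum((pl[1, ] - pl[nrow(pl), ])^2))
    tau <- if (dsep > 1e-9) l / dsep else NA_real_

    vox <- vgraph$paths[[e]]
    lin <- vox[, 1] + d[1] * (vox[, 2] - 1L) + d[1] * d[2] * (vox[, 3] - 1L)
    prof <- edt[lin]
    slab <- if (!is.null(tags)) tags[lin] == 2L else rep(TRUE, length(lin))
    r_pts <- prof
    if (any(slab) && any(!slab)) {
      # replace junction-voxel values by the nearest slab value along the path
      idx <- seq_along(prof)
      r_pts[!slab] <- prof[slab][vapply(idx[!slab], function(i)
        which.min(abs(idx[slab] - i)), 1L)]
    }
    rbar <- mean(if (any(slab)) prof[slab] else prof)
    # radii at polyline points (node-extension points take the adjacent value)
    rr <- c(r_pts[1], r_pts, r_pts[length(r_pts)])
    area <- sum(2 * pi * (rr[-1] + rr[-length(rr)]) / 2 * steps)
    c(l, dsep, tau, rbar, area)
  })
  m <- do.call(rbind, out)
  data.frame(edge_id = seq_len(ne), length_um = m[, 1], separation_um = m[, 2],
             tortuosity = m[, 3], radius_um = m[, 4], surface_um2 = m[, 5])
}

#' Tiling-box statistics: fractional vessel volume and microvascular density
#'
#' The volume is tiled with cubes of `box_um` (default 500 um, isotropic in
#' physical units). Per box: `fVV` = foreground voxels / in-mask voxels, and
#' `MVD` = number of vessel segments whose centerline median voxel falls in
#' the box, per mm^3 of in-mask volume. Boxes with mask coverage below 50%
#' are excluded.
#'
#' @param vol a [binary_volume]
#' @param vgraph a [vascular_graph] (or `NULL`: fVV only)
#' @param mask optional [region_mask]
#' @param box_um box side length; must span at least 2 voxels per axis
#' @return data.frame per retained box: `bx`, `by`, `bz`, `fVV`, `MVD`,
#'   `coverage`
#' @export
tile_stats <- function(vol, vgraph = NULL, mask = NULL, box_um = 500) {
  stopifnot(inherits(vol, "binary_volume"))
  if (any(box_um / vol$spacing_um < 2))
    stop("box_um must span at least 2 voxels along every axis")
  d <- dim(vol$grid)
  sp <- vol$spacing_um
  bx <- pmin(floor((seq_len(d[1]) - 0.5) * sp[1] / box_um), ceiling(d[1] * sp[1] / box_um) - 1)
  by <- pmin(floor((seq_len(d[2]) - 0.5) * sp[2] / box_um), ceiling(d[2] * sp[2] / box_um) - 1)
  bz <- pmin(floor((seq_len(d[3]) - 0.5) * sp[3] / box_um), ceiling(d[3] * sp[3] / box_um) - 1)
  nbx <- max(bx) + 1L; nby <- max(by) + 1L
  key <- rep(bx, times = d[2] * d[3]) +
    nbx * rep(rep(by, each = d[1]), times = d[3]) +
    nbx * nby * rep(bz, each = d[1] * d[2])
  nkeys <- nbx * nby * (max(bz) + 1L)
  if (is.null(mask)) {
    n_in <- tabulate(key + 1L, nkeys)
    n_fg <- tabulate(key[as.vector(vol$grid)] + 1L, nkeys)
  } else {
    minm <- as.vector(mask$grid)
    n_in <- tabulate(key[minm] + 1L, nkeys)
    n_fg <- tabulate(key[minm & as.vector(vol$grid)] + 1L, nkeys)
  }
  voxv <- voxel_volume_um3(vol)
  coverage <- n_in * voxv / box_um^3

  mvd_count <- rep(0L, nkeys)
  if (!is.null(vgraph) && igraph::ecount(vgraph$graph) > 0) {
    mid <- t(vapply(vgraph$paths, function(p) p[ceiling(nrow(p) / 2), ], c(1, 1, 1)))
    mkey <- pmin(floor((mid[, 1] - 0.5) * sp[1] / box_um), nbx - 1L) +
      nbx * pmin(floor((mid[, 2] - 0.5) * sp[2] / box_um), nby - 1L) +
      nbx * nby * pmin(floor((mid[, 3] - 0.5) * sp[3] / box_um), max(bz))
    mvd_count <- tabulate(mkey + 1L, nkeys)
  }

  keep <- which(n_in > 0 & coverage >= 0.5)
  k0 <- keep - 1L
  data.frame(bx = k0 %% nbx, by = (k0 %/% nbx) %% nby, bz = k0 %/% (nbx * nby),
             fVV = n_fg[keep] / n_in[keep],
             MVD = mvd_count[keep] / (n_in[keep] * voxv * 1e-9),
             coverage = coverage[keep])
}

#' Global tissue densities
#'
#' @param vol a [binary_volume]
#' @param vgraph a [vascular_graph]
#' @param segments output of [segment_geometry]
#' @param mask optional [region_mask]
#' @return a `density_summary`: `fVV_global`, `MVD_global` (segments/mm^3),
#'   `rho_L` (mm/mm^3), `rho_A` (mm^2/mm^3), `tissue_volume_mm3`
#' @export
global_densities <- function(vol, vgraph, segments, mask = NULL) {
  stopifnot(inherits(vol, "binary_volume"))
  inmask <- if (is.null(mask)) rep(TRUE, length(vol$grid)) else as.vector(mask$grid)
  v_mm3 <- sum(inmask) * voxel_volume_um3(vol) * 1e-9
  if (v_mm3 <= 0) stop("mask volume is zero")
  structure(list(
    fVV_global = sum(vol$grid & inmask) / sum(inmask),
    MVD_global = nrow(segments) / v_mm3,
    rho_L = sum(segments$length_um) * 1e-3 / v_mm3,
    rho_A = sum(segments$surface_um2) * 1e-6 / v_mm3,
    tissue_volume_mm3 = v_mm3
  ), class = "density_summary")
}

#' @export
print.density_summary <- function(x, ...) {
  cat(sprintf("density_summary: fVV %.4f, MVD %.3g /mm^3, rho_L %.3g mm^-2, rho_A %.3g mm^-1, V %.4g mm^3\n",
              x$fVV_global, x$MVD_global, x$rho_L, x$rho_A, x$tissue_volume_mm3))
  invisible(x)
}

#' Rescale cleared-tissue measurements to in-vivo scale
#'
#' Optical clearing shrinks tissue isotropically by a volume fraction `s`
#' (typically up to 0.40), i.e. lengths and radii carry a factor
#' (1-s)^(1/3) ~ 0.84. This op multiplies lengths and radii by
#' (1-s)^(-1/3), areas by (1-s)^(-2/3) and volumes by (1-s)^(-1); densities
#' are divided accordingly. Tortuosity and fVV are scale-invariant.
#'
#' @param x a `density_summary` or a [segment_geometry] data.frame
#' @param shrinkage_fraction volume shrinkage `s` in `[0, 1)` (default 0.40)
#' @return object of the same type at in-vivo scale
#' @export
scale_to_in_vivo <- function(x, shrinkage_fraction = 0.40) {
  s <- shrinkage_fraction
  if (s >= 1) stop("shrinkage_fraction must be < 1")
  f <- (1 - s)^(-1 / 3)   # linear magnification back to in vivo
  if (inherits(x, "density_summary")) {
    x$rho_L <- x$rho_L / f^2          # length * f / (volume * f^3)
    x$rho_A <- x$rho_A / f            # area * f^2 / volume * f^3
    x$MVD_global <- x$MVD_global / f^3
    x$tissue_volume_mm3 <- x$tissue_volume_mm3 * f^3
    return(x)
  }
  if (is.data.frame(x)) {
    for (cn in intersect(c("length_um", "separation_um", "radius_um"), names(x)))
      x[[cn]] <- x[[cn]] * f
    if ("surface_um2" %in% names(x)) x$surface_um2 <- x$surface_um2 * f^2
    return(x)
  }
  stop("unsupported type")
}

#' Summary table of segment geometry
#'
#' Radius, length and surface area are near-log-normal: reported as the
#' arithmetic mean with the mean deviation above and below it (the average
#' directed deviations). Tortuosity is near-exponential (shifted, tau >= 1):
#' reported as median and empirical 95% quantile (linear interpolation
#' between order statistics).
#'
#' @param segments output of [segment_geometry]
#' @return data.frame of summary statistics
#' @export
summarize_geometry <- function(segments) {
  stopifnot(nrow(segments) >= 1)
  dirdev <- function(x) {
    x <- x[is.finite(x)]
    m <- mean(x)
    up <- x[x > m] - m
    dn <- m - x[x < m]
    c(mean = m, dev_plus = if (length(up)) mean(up) else 0,
      dev_minus = if (length(dn)) mean(dn) else 0)
  }
  r <- dirdev(segments$radius_um)
  l <- dirdev(segments$length_um)
  a <- dirdev(segments$surface_um2)
  tau <- segments$tortuosity[is.finite(segments$tortuosity)]
  data.frame(
    quantity = c("radius_um", "length_um", "surface_um2", "tortuosity"),
    mean = c(r[1], l[1], a[1], NA),
    dev_plus = c(r[2], l[2], a[2], NA),
    dev_minus = c(r[3], l[3], a[3], NA),
    median = c(NA, NA, NA, if (length(tau)) median(tau) else NA),
    q95 = c(NA, NA, NA,
            if (length(tau)) quantile(tau, 0.95, names = FALSE, type = 7) else NA),
    n = nrow(segments)
  )
}
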