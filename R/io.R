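#' Write a binary volume as multi-page TIFF
#'
#' One 8-bit page per z-slice, foreground 255, rows = y, columns = x.
#'
#' @param vol a [binary_volume]
#' @param path output file
#' @return invisibly, `path`
#' @export
write_volume_tiff <- function(vol, path) {
  stopifnot(inherits(vol, "binary_volume"))
  pages <- lapply(seq_len(dim(vol$grid)[3]),
                  function(k) t(vol$grid[, , k]) * 1.0)
  tiff::writeTIFF(pages, path, bits.per.sample = 8L)
  invisible(path)
}

#' Read a multi-page TIFF into a binary volume
#'
#' Nonzero intensity becomes foreground; use [threshold_volume] for
#' grayscale stacks requiring a real threshold.
#'
#' @param path TIFF file
#' @param spacing_um voxel spacing to attach
#' @return a [binary_volume]
#' @export
read_volume_tiff <- function(path, spacing_um = c(3.25, 3.25, 5)) {
  pages <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  d <- dim(pages[[1]])
  grid <- array(FALSE, c(d[2], d[1], length(pages)))
  for (k in seq_along(pages)) grid[, , k] <- t(pages[[k]]) > 0
  binary_volume(grid, spacing_um)
}

#' Export a vascular graph as GraphML plus CSV tables
#'
#' Writes `graph.graphml` (node attributes x, y, z, kind; edge attributes
#' length_um, radius_um, tortuosity when segment geometry is supplied) and
#' `nodes.csv` / `edges.csv`.
#'
#' @param vgraph a [vascular_graph]
#' @param dir output directory (created if needed)
#' @param segments optional [segment_geometry] table
#' @return invisibly, the directory
#' @export
export_graph <- function(vgraph, dir, segments = NULL) {
  stopifnot(inherits(vgraph, "vascular_graph"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  g <- vgraph$graph
  if (!is.null(segments)) {
    igraph::E(g)$length_um <- segments$length_um
    igraph::E(g)$radius_um <- segments$radius_um
    igraph::E(g)$tortuosity <- segments$tortuosity
  }
  igraph::write_graph(g, file.path(dir, "graph.graphml"), format = "graphml")
  nodes <- data.frame(id = seq_len(igraph::vcount(g)),
                      x = igraph::V(g)$x, y = igraph::V(g)$y,
                      z = igraph::V(g)$z, kind = igraph::V(g)$kind,
                      degree = igraph::degree(g, loops = TRUE))
  el <- igraph::ends(g, igraph::E(g), names = FALSE)
  edges <- data.frame(id = seq_len(igraph::ecount(g)),
                      node_a = el[, 1], node_b = el[, 2])
  if (!is.null(segments)) edges <- cbind(edges, segments[, -1])
  write.csv(nodes, file.path(dir, "nodes.csv"), row.names = FALSE)
  write.csv(edges, file.path(dir, "edges.csv"), row.names = FALSE)
  invisible(dir)
}

#' Export a ground-truth phantom network
#'
#' GraphML with positions plus a CSV edge table (lengths, radii,
#' tortuosities).
#'
#' @param gt a `ground_truth_graph`
#' @param dir output directory
#' @return invisibly, the directory
#' @export
export_ground_truth <- function(gt, dir) {
  stopifnot(inherits(gt, "ground_truth_graph"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  g <- gt_as_igraph(gt)
  igraph::E(g)$length_um <- gt$edges$length_um
  igraph::E(g)$radius_um <- gt$edges$radius_um
  igraph::write_graph(g, file.path(dir, "ground_truth.graphml"),
                      format = "graphml")
  write.csv(gt$edges, file.path(dir, "ground_truth_edges.csv"),
            row.names = FALSE)
  invisible(dir)
}
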