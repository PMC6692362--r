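#' Binary vessel volume
#'
#' A 3D boolean voxel grid with physical spacing, the substrate of all
#' image-side operations. Arrays are indexed `[x, y, z]`; `spacing_um` gives
#' the voxel pitch along each axis in micrometers. The default spacing is the
#' anisotropic light-sheet grid (3.25 x 3.25 um in plane, 5 um between
#' slices).
#'
#' @param grid 3D logical (or coercible) array
#' @param spacing_um length-3 positive numeric, micrometers per voxel
#' @param origin_um physical position of the corner of voxel (1,1,1)
#' @return an object of class `binary_volume`
#' @export
binary_volume <- function(grid, spacing_um = c(3.25, 3.25, 5),
                          origin_um = c(0, 0, 0)) {
  if (length(dim(grid)) != 3L) stop("grid must be a 3D array")
  if (length(spacing_um) != 3L || any(spacing_um <= 0))
    stop("spacing_um must be 3 positive numbers")
  storage.mode(grid) <- "logical"
  structure(list(grid = grid, spacing_um = as.numeric(spacing_um),
                 origin_um = as.numeric(origin_um)),
            class = "binary_volume")
}

#' @export
print.binary_volume <- function(x, ...) {
  d <- dim(x$grid)
  cat(sprintf("binary_volume %d x %d x %d voxels, spacing %.3g x %.3g x %.3g um, %d foreground\n",
              d[1], d[2], d[3], x$spacing_um[1], x$spacing_um[2], x$spacing_um[3],
              sum(x$grid)))
  invisible(x)
}

#' Region mask
#'
#' Boolean mask congruent with a [binary_volume], restricting analysis to a
#' tissue region (tumor, core, control) or excluding artefacts.
#'
#' @param grid 3D logical array
#' @param label one of `"tumor"`, `"core"`, `"control"`, `"exclude"`
#' @return object of class `region_mask`
#' @export
region_mask <- function(grid, label = c("control", "tumor", "core", "exclude")) {
  label <- match.arg(label)
  if (length(dim(grid)) != 3L) stop("mask grid must be a 3D array")
  storage.mode(grid) <- "logical"
  structure(list(grid = grid, label = label), class = "region_mask")
}

voxel_volume_um3 <- function(vol) prod(vol$spacing_um)

#' Gaussian smoothing followed by re-binarization
#'
#' Blurs the 0/1 field with an isotropic Gaussian of standard deviation
#' `sigma_vox` in voxel units (despite anisotropic physical spacing, matching
#' common practice for segmented stacks) and thresholds at half of the
#' maximum smoothed value over the volume. Removes single-voxel surface
#' roughness while preserving bulk shape; `sigma_vox = 0` is the identity.
#'
#' @param vol a [binary_volume]
#' @param sigma_vox standard deviation in voxels (default 1)
#' @return a [binary_volume]
#' @export
smooth_and_rebinarize <- function(vol, sigma_vox = 1) {
  stopifnot(inherits(vol, "binary_volume"), sigma_vox >= 0)
  if (sigma_vox == 0) return(vol)
  a <- array(as.numeric(vol$grid), dim(vol$grid))
  k <- gauss_kernel(sigma_vox)
  for (ax in 1:3) a <- conv_axis(a, k, ax)
  thr <- 0.5 * max(a)
  out <- vol
  out$grid <- a >= thr & thr > 0
  out
}

#' Fill enclosed cavities
#'
#' Background components (6-connectivity) not connected to the volume border
#' become foreground, solidifying "hollow" vessels left by segmentation.
#' Idempotent; foreground count is non-decreasing.
#'
#' @param vol a [binary_volume]
#' @return a [binary_volume]
#' @export
fill_holes <- function(vol) {
  stopifnot(inherits(vol, "binary_volume"))
  g <- vol$grid
  d <- dim(g)
  labs <- cc_label_cpp(!g, dim(g), 6L)
  dim(labs) <- d
  border <- unique(c(labs[1, , ], labs[d[1], , ], labs[, 1, ], labs[, d[2], ],
                     labs[, , 1], labs[, , d[3]]))
  border <- border[border > 0]
  out <- vol
  out$grid <- g | !(labs %in% c(0L, border))
  dim(out$grid) <- d
  out
}

#' Remove isolated specks
#'
#' Deletes connected components whose physical volume is below that of a
#' sphere with radius `min_radius_um` (default 6 um, i.e. 904.78 um^3; at
#' 3.25 x 3.25 x 5 um spacing components of 17 voxels or fewer are removed).
#'
#' @param vol a [binary_volume]
#' @param min_radius_um sphere radius defining the volume threshold
#' @param connectivity 6, 18 or 26 (default 6)
#' @return a [binary_volume]
#' @export
remove_specks <- function(vol, min_radius_um = 6, connectivity = 6) {
  stopifnot(inherits(vol, "binary_volume"), min_radius_um >= 0,
            connectivity %in% c(6, 18, 26))
  if (min_radius_um == 0) return(vol)
  thr_um3 <- 4 / 3 * pi * min_radius_um^3
  labs <- cc_label_cpp(vol$grid, dim(vol$grid), as.integer(connectivity))
  if (max(labs) == 0L) return(vol)
  sizes <- tabulate(labs)
  small <- which(sizes * voxel_volume_um3(vol) < thr_um3)
  out <- vol
  out$grid <- vol$grid & !(labs %in% small)
  dim(out$grid) <- dim(vol$grid)
  out
}

# foreground voxels with at least one 6-neighbor (or volume face) in background
boundary_layer <- function(g) {
  d <- dim(g)
  b <- array(FALSE, d)
  shifted_bg <- function(ax, o) {
    s <- array(TRUE, d)   # outside counts as background
    n <- d[ax]
    to <- max(1L, 1L + o):min(n, n + o)
    from <- to - o
    if (ax == 1L) s[to, , ] <- !g[from, , ]
    else if (ax == 2L) s[, to, ] <- !g[, from, ]
    else s[, , to] <- !g[, , from]
    s
  }
  for (ax in 1:3) for (o in c(-1L, 1L)) b <- b | shifted_bg(ax, o)
  g & b
}

#' Circumferential thinning
#'
#' Removes one morphological surface layer (foreground voxels with a
#' 6-connected background neighbor, the volume border counting as
#' background), keeping every skeleton voxel, to compensate over-segmentation
#' from fluorescent overexposure. The skeleton, and hence the network
#' topology, is untouched.
#'
#' @param vol a [binary_volume]
#' @param skeleton a [tagged_skeleton] or logical array of skeleton voxels;
#'   must be a subset of the foreground
#' @return a [binary_volume]
#' @export
circumferential_thinning <- function(vol, skeleton) {
  stopifnot(inherits(vol, "binary_volume"))
  sk <- if (inherits(skeleton, "tagged_skeleton")) skeleton$tags > 0L else skeleton
  if (!identical(dim(sk), dim(vol$grid))) stop("skeleton shape mismatch")
  if (any(sk & !vol$grid)) stop("skeleton voxel outside volume foreground")
  out <- vol
  out$grid <- (vol$grid & !boundary_layer(vol$grid)) | sk
  out
}

#' Restrict a volume to a region mask
#'
#' @param vol a [binary_volume]
#' @param mask a [region_mask] congruent with `vol`
#' @return a [binary_volume] with attribute `mask_voxels` (in-mask voxel count)
#' @export
apply_mask <- function(vol, mask) {
  stopifnot(inherits(vol, "binary_volume"), inherits(mask, "region_mask"))
  if (!identical(dim(mask$grid), dim(vol$grid))) stop("mask shape mismatch")
  out <- vol
  out$grid <- vol$grid & mask$grid
  attr(out, "mask_voxels") <- sum(mask$grid)
  out
}

#' Threshold a grayscale stack to a binary volume
#'
#' Plain global threshold for grayscale input; a deterministic stand-in for
#' interactive segmentation, not equivalent to it.
#'
#' @param arr 3D numeric array
#' @param spacing_um voxel spacing
#' @param threshold absolute intensity threshold; if `NULL`, use `percentile`
#' @param percentile quantile of nonzero intensities used when `threshold` is
#'   `NULL` (default 0.5)
#' @return a [binary_volume]
#' @export
threshold_volume <- function(arr, spacing_um = c(3.25, 3.25, 5),
                             threshold = NULL, percentile = 0.5) {
  if (is.null(threshold)) threshold <- quantile(arr[arr > 0], percentile, names = FALSE)
  binary_volume(arr >= threshold, spacing_um)
}
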