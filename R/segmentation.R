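#' Segmentation configuration
#'
#' Settings for turning a CBCT-like volume into a surface model. The
#' 1600 HU default threshold separates mineralised tooth tissue from
#' background and pulp; thresholding is strict (`value > threshold`), so
#' voxels exactly at the threshold are background.
#'
#' @param hu_threshold segmentation threshold in HU (default 1600).
#' @param fill_canals fill internal cavities (pulp canals) before
#'   surfacing (default TRUE).
#' @param keep_largest_component keep only the largest connected
#'   foreground component, suppressing noise speckle (default TRUE).
#' @param closing_radius_voxels radius of the ball used to seal
#'   near-open canals during cavity filling (default 3).
#' @param smooth_sigma_voxels Gaussian smoothing (in voxels) applied to
#'   the binary mask before isosurface extraction. Sub-voxel
#'   anti-aliasing: it removes the staircase bias of a surface extracted
#'   from raw {0,1} data while staying on the thresholded-mask route.
#'   Set 0 for the raw blocky surface.
#' @param step_size grid subsampling factor for surfacing (>= 1).
#' @return A list of class `segmentation_config`.
#' @export
segmentation_config <- function(hu_threshold = 1600, fill_canals = TRUE,
                                keep_largest_component = TRUE,
                                closing_radius_voxels = 3L,
                                smooth_sigma_voxels = 0.8,
                                step_size = 1L) {
  stopifnot(is.finite(hu_threshold), step_size >= 1,
            closing_radius_voxels >= 0, smooth_sigma_voxels >= 0)
  structure(list(hu_threshold = hu_threshold, fill_canals = fill_canals,
                 keep_largest_component = keep_largest_component,
                 closing_radius_voxels = as.integer(closing_radius_voxels),
                 smooth_sigma_voxels = smooth_sigma_voxels,
                 step_size = as.integer(step_size)),
            class = "segmentation_config")
}

#' Threshold a volume into a binary mask
#'
#' Foreground is `value > hu_threshold`, strictly: voxels exactly at the
#' threshold stay background.
#' @param vol a [voxel_volume()].
#' @param cfg a [segmentation_config()].
#' @return A [binary_mask()] with the same grid geometry.
#' @export
threshold_volume <- function(vol, cfg = segmentation_config()) {
  binary_mask(vol$values > cfg$hu_threshold, vol$spacing, vol$origin)
}

#' Fill internal cavities (pulp canals) of a binary mask
#'
#' Two-step hole filling. Step 1: background voxels 6-connected to the
#' grid boundary are "outside"; any remaining background voxel is an
#' enclosed cavity and becomes foreground. Step 2: to catch canals that
#' open at the root apex through a narrow channel, the mask is closed
#' with a digital ball (radius `closing_radius_voxels`); cavities
#' enclosed by the closed mask are then filled in the original. Only
#' cavity voxels are added; the closing itself is never written to the
#' output, so the outer surface is untouched. The output is always a
#' superset of the input, and the operation is idempotent.
#'
#' @param mask a [binary_mask()].
#' @param closing_radius_voxels ball radius in voxels for the sealing
#'   step (0 disables step 2).
#' @return The filled [binary_mask()].
#' @export
fill_internal_cavities <- function(mask, closing_radius_voxels = 3L) {
  dims <- dim(mask$values)
  fill_enclosed <- function(m) {
    reached <- .cpp_background_reach(m, dims)
    m | (!m & !reached)
  }
  m <- fill_enclosed(as.vector(mask$values))
  if (closing_radius_voxels > 0) {
    closed <- .cpp_ball_morph(.cpp_ball_morph(m, dims,
                                              closing_radius_voxels, TRUE),
                              dims, closing_radius_voxels, FALSE)
    reached_closed <- .cpp_background_reach(closed, dims)
    m <- m | (!m & !reached_closed)
    m <- fill_enclosed(m)
  }
  binary_mask(array(m, dims), mask$spacing, mask$origin)
}

#' Keep only the largest connected foreground component
#'
#' Components use 26-connectivity; ties are broken in favour of the
#' component whose seed voxel has the lowest linear index.
#' @param mask a [binary_mask()] with at least one foreground voxel.
#' @return A [binary_mask()] containing one component.
#' @export
largest_component <- function(mask) {
  if (!any(mask$values)) stop("no foreground voxels in mask")
  keep <- .cpp_largest_component(as.vector(mask$values), dim(mask$values))
  binary_mask(array(keep, dim(mask$values)), mask$spacing, mask$origin)
}

#' Extract the surface of a binary mask
#'
#' Isosurface at level 0.5 of the {0,1} mask field (optionally Gaussian
#' smoothed by `smooth_sigma_voxels` for sub-voxel anti-aliasing).
#' Vertex coordinates are physical mm. The result is closed when the
#' foreground does not touch the grid boundary; touching foreground is
#' an error because the surface would be clipped open.
#'
#' @param mask a [binary_mask()].
#' @param smooth_sigma_voxels Gaussian sigma in voxels (0 = raw mask).
#' @return A closed [surface_mesh()].
#' @export
extract_surface <- function(mask, smooth_sigma_voxels = 0.8) {
  dims <- dim(mask$values)
  if (!any(mask$values)) stop("no foreground voxels in mask")
  if (any(mask$values[c(1, dims[1]), , ]) ||
      any(mask$values[, c(1, dims[2]), ]) ||
      any(mask$values[, , c(1, dims[3])]))
    stop("foreground touches the grid boundary; surface would be clipped")
  f <- as.numeric(mask$values)
  if (smooth_sigma_voxels > 0)
    f <- .cpp_gauss_blur3(f, dims, rep(smooth_sigma_voxels, 3))
  mesh <- isosurface(array(f, dims), 0.5, spacing = mask$spacing,
                     origin = mask$origin)
  if (nrow(mesh$triangles) == 0)
    stop("no surface extracted (foreground too small for the smoothing used)")
  mesh
}

#' Segment a CBCT-like volume into a surface model
#'
#' End-to-end reconstruction: threshold at `hu_threshold` (strict >),
#' fill internal cavities (root canals), keep the largest connected
#' component, and extract the iso-0.5 surface of the (anti-aliased)
#' binary mask. The returned mesh is the CBCT reconstruction model.
#'
#' @param vol a [voxel_volume()].
#' @param cfg a [segmentation_config()].
#' @return A closed [surface_mesh()].
#' @export
segment_volume <- function(vol, cfg = segmentation_config()) {
  mask <- threshold_volume(vol, cfg)
  if (isTRUE(cfg$fill_canals))
    mask <- fill_internal_cavities(mask, cfg$closing_radius_voxels)
  if (isTRUE(cfg$keep_largest_component))
    mask <- largest_component(mask)
  extract_surface(mask, cfg$smooth_sigma_voxels)
}
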