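#' Parametric tooth phantom specification
#'
#' Describes a synthetic tooth used as ground truth throughout the
#' pipeline: a superellipsoid crown blended with one or more tapered
#' round-cone roots, each optionally carrying a cylindrical pulp canal.
#' Single-rooted kinds (premolar, canine) have exactly one root; the
#' molar has two diverging roots so a furcation saddle exists between
#' them. The shape parameters are fixed per kind so that two phantoms of
#' the same kind are geometrically identical; the seed only feeds the
#' stochastic operations applied downstream (voxel noise, milling noise).
#'
#' @param tooth_kind `"premolar"`, `"canine"` or `"molar"`.
#' @param seed integer seed recorded in the spec and used by downstream
#'   stochastic operations.
#' @return A list of class `phantom_spec` with fields `tooth_kind`,
#'   `crown_half_axes` (mm), `crown_exponent`, `feature_spheres`
#'   (cusp/ridge bulges blended into the crown), `root_specs` (per root:
#'   `base_offset`, `apex_offset` (mm, relative to crown centre), `length`,
#'   `base_radius`, `tip_radius`), `canal_radius` (mm per root),
#'   `blend_k` (mm) and `seed`.
#' @export
phantom_spec <- function(tooth_kind = c("premolar", "canine", "molar"),
                         seed = 1L) {
  tooth_kind <- match.arg(tooth_kind)
  root <- function(base, apex, r1, r2)
    list(base_offset = base, apex_offset = apex,
         length = sqrt(sum((apex - base)^2)),
         base_radius = r1, tip_radius = r2)
  # feature spheres model cusps and ridge bulges; besides realism they
  # break rotational near-symmetry so surface registration is well posed
  spec <- switch(tooth_kind,
    premolar = list(
      crown_half_axes = c(4.2, 3.2, 4.0), crown_exponent = 2.5,
      feature_spheres = list(
        list(center = c(1.8, 0.8, 3.2), radius = 1.8),    # buccal cusp
        list(center = c(-1.6, -0.6, 2.9), radius = 1.5)), # lingual cusp
      root_specs = list(root(c(0, 0, -2.5), c(0.8, 0.4, -14.0), 3.2, 1.0)),
      canal_radius = 0.5),
    canine = list(
      crown_half_axes = c(3.8, 3.0, 4.6), crown_exponent = 2.5,
      feature_spheres = list(
        list(center = c(0.6, 0.8, 4.2), radius = 1.7),    # cusp tip
        list(center = c(0, 2.0, 1.0), radius = 2.2)),     # labial ridge
      root_specs = list(root(c(0, 0, -2.5), c(0.6, 0.8, -15.0), 3.0, 0.7)),
      canal_radius = 0.5),
    molar = list(
      crown_half_axes = c(5.2, 4.8, 4.0), crown_exponent = 2.5,
      feature_spheres = list(
        list(center = c(2.6, 2.2, 3.4), radius = 1.8)),   # mesiobuccal cusp
      root_specs = list(
        root(c(-2.6, 0, -2.5), c(-6.3, 0, -11.5), 2.0, 0.8),
        root(c(2.6, 0, -2.5), c(6.3, 0.6, -11.5), 2.0, 0.8)),
      canal_radius = 0.5))
  spec$tooth_kind <- tooth_kind
  spec$blend_k <- 0.8
  spec$seed <- as.integer(seed)
  for (r in spec$root_specs) {
    stopifnot(r$length > 0, r$base_radius > 0, r$tip_radius > 0,
              r$tip_radius < r$base_radius)
  }
  n_roots <- length(spec$root_specs)
  if (tooth_kind %in% c("premolar", "canine")) stopifnot(n_roots == 1L)
  if (tooth_kind == "molar") stopifnot(n_roots >= 2L)
  structure(spec, class = "phantom_spec")
}

# signed pseudo-distance of a superellipsoid |x/a|^e + |y/b|^e + |z/c|^e = 1
sd_superellipsoid <- function(px, py, pz, half, e) {
  r <- (abs(px / half[1])^e + abs(py / half[2])^e +
          abs(pz / half[3])^e)^(1 / e)
  (r - 1) * min(half)
}

# exact signed distance of a round cone (sphere-swept tapered segment)
# from a (radius r1) to b (radius r2)
sd_round_cone <- function(px, py, pz, a, b, r1, r2) {
  bax <- b[1] - a[1]; bay <- b[2] - a[2]; baz <- b[3] - a[3]
  l2 <- bax^2 + bay^2 + baz^2
  rr <- r1 - r2
  a2 <- l2 - rr^2
  il2 <- 1 / l2
  pax <- px - a[1]; pay <- py - a[2]; paz <- pz - a[3]
  y <- pax * bax + pay * bay + paz * baz
  z <- y - l2
  x2 <- (pax * l2 - bax * y)^2 + (pay * l2 - bay * y)^2 +
    (paz * l2 - baz * y)^2
  y2 <- y^2 * l2
  z2 <- z^2 * l2
  k <- sign(rr) * rr^2 * x2
  out <- (sqrt(x2 * a2 * il2) + y * rr) * il2 - r1
  hi <- sign(z) * a2 * z2 > k
  lo <- sign(y) * a2 * y2 < k
  out[hi] <- (sqrt(x2[hi] + z2[hi]) * il2 - r2)
  out[lo] <- (sqrt(x2[lo] + y2[lo]) * il2 - r1)
  out
}

# polynomial smooth union of two signed distance fields
smin <- function(d1, d2, k) {
  h <- pmin(pmax(0.5 + 0.5 * (d2 - d1) / k, 0), 1)
  d2 * (1 - h) + d1 * h - k * h * (1 - h)
}

# signed distance field of the whole tooth at given points (inside < 0)
phantom_sdf <- function(spec, px, py, pz) {
  d <- sd_superellipsoid(px, py, pz, spec$crown_half_axes,
                         spec$crown_exponent)
  for (fs in spec$feature_spheres) {
    ds <- sqrt((px - fs$center[1])^2 + (py - fs$center[2])^2 +
                 (pz - fs$center[3])^2) - fs$radius
    d <- smin(d, ds, spec$blend_k)
  }
  for (r in spec$root_specs) {
    dr <- sd_round_cone(px, py, pz, r$base_offset, r$apex_offset,
                        r$base_radius, r$tip_radius)
    d <- smin(d, dr, spec$blend_k)
  }
  d
}

#' Pulp-canal centre lines of a phantom
#'
#' One segment per root, running from just below the crown centre to
#' 1.5 mm short of the root apex, so the carved canal stays enclosed by
#' hard tissue.
#' @param spec a [phantom_spec()].
#' @return A list of segments with fields `from`, `to` (mm) and `radius`.
#' @export
canal_paths <- function(spec) {
  lapply(spec$root_specs, function(r) {
    u <- (r$apex_offset - r$base_offset) / r$length
    list(from = r$base_offset + c(0, 0, 0.5),
         to = r$apex_offset - 1.5 * u,
         radius = spec$canal_radius)
  })
}

#' Generate a ground-truth tooth phantom
#'
#' Evaluates the parametric signed-distance field of the requested tooth
#' kind on a fine grid and extracts the zero isosurface, yielding a
#' closed, outward-oriented triangle mesh. Bit-identical for identical
#' `(tooth_kind, seed)`; the geometry itself does not depend on the seed.
#'
#' @param tooth_kind `"premolar"`, `"canine"` or `"molar"`.
#' @param seed integer, recorded in the spec for downstream noise stages.
#' @param resolution grid step of the ground-truth surface, mm. The
#'   default 0.15 mm is finer than the 0.2 mm CBCT voxel so that
#'   ground-truth discretisation is a small fraction of the voxel error
#'   budget.
#' @return A list with elements `spec` ([phantom_spec()]) and `mesh`
#'   (closed [surface_mesh()]).
#' @export
make_phantom <- function(tooth_kind, seed = 1L, resolution = 0.15) {
  spec <- phantom_spec(tooth_kind, seed)
  # bounding box over crown and root spheres, with margin
  lo <- -spec$crown_half_axes
  hi <- spec$crown_half_axes
  for (fs in spec$feature_spheres) {
    lo <- pmin(lo, fs$center - fs$radius)
    hi <- pmax(hi, fs$center + fs$radius)
  }
  for (r in spec$root_specs) {
    lo <- pmin(lo, r$base_offset - r$base_radius, r$apex_offset - r$tip_radius)
    hi <- pmax(hi, r$base_offset + r$base_radius, r$apex_offset + r$tip_radius)
  }
  lo <- lo - 4 * resolution
  hi <- hi + 4 * resolution
  dims <- pmax(4L, as.integer(ceiling((hi - lo) / resolution)) + 1L)
  ax <- lapply(1:3, function(a) lo[a] + (seq_len(dims[a]) - 1) * resolution)
  px <- rep(ax[[1]], times = dims[2] * dims[3])
  py <- rep(rep(ax[[2]], each = dims[1]), times = dims[3])
  pz <- rep(ax[[3]], each = dims[1] * dims[2])
  f <- -phantom_sdf(spec, px, py, pz)   # inside > 0
  mesh <- isosurface(array(f, dims), 0, spacing = rep(resolution, 3),
                     origin = lo)
  list(spec = spec, mesh = mesh)
}

#' Voxelize a closed mesh into a CBCT-like volume
#'
#' Voxel centres inside the mesh receive `hu_hard_tissue`, except within
#' the cylindrical pulp-canal channels (`canal_paths`, radius per root)
#' which receive `hu_canal`; outside voxels receive `hu_background`.
#' Partial-volume averaging is emulated by a Gaussian blur of physical
#' width `blur_sigma` and detector noise by additive Gaussian noise of
#' standard deviation `noise_sd` (seeded, reproducible). The grid is
#' padded so the surface never touches the volume boundary.
#'
#' @param mesh a closed [surface_mesh()].
#' @param spacing isotropic voxel size in mm (default 0.2 mm).
#' @param hu_hard_tissue,hu_canal,hu_background HU values for mineralised
#'   tissue, pulp canal and surrounding air/soft tissue. Defaults 2000 /
#'   300 / 0 straddle the 1600 HU segmentation threshold with
#'   dentin-like contrast.
#' @param blur_sigma Gaussian blur sigma in mm (0 = no blur).
#' @param noise_sd additive Gaussian noise sd in HU (0 = no noise).
#' @param canals list of canal path segments (`from`, `to`, `radius`),
#'   e.g. from [phantom_spec()] via the internal canal layout; NULL for
#'   none.
#' @param seed integer seed for the noise draw.
#' @param pad_voxels background padding on every side (>= 5 recommended
#'   so isosurfacing never clips the tooth).
#' @return A [voxel_volume()].
#' @export
voxelize <- function(mesh, spacing = 0.2, hu_hard_tissue = 2000,
                     hu_canal = 300, hu_background = 0, blur_sigma = 0,
                     noise_sd = 0, canals = NULL, seed = 1L,
                     pad_voxels = 6L) {
  stopifnot(spacing > 0, blur_sigma >= 0, noise_sd >= 0)
  if (!(hu_hard_tissue > 1600 && 1600 > hu_background))
    stop("hu_hard_tissue must exceed 1600 HU and hu_background lie below it")
  if (!mesh_is_closed(mesh))
    stop("mesh must be closed (watertight) for an inside test to be defined")
  bb_lo <- apply(mesh$vertices, 2, min)
  bb_hi <- apply(mesh$vertices, 2, max)
  origin <- bb_lo - pad_voxels * spacing
  dims <- as.integer(ceiling((bb_hi - origin) / spacing)) + 1L + pad_voxels
  inside <- .cpp_voxelize_inside(mesh$vertices, mesh$triangles,
                                 dims[1], dims[2], dims[3],
                                 rep(spacing, 3), origin)
  vals <- rep(hu_background, length(inside))
  vals[inside] <- hu_hard_tissue
  if (!is.null(canals) && length(canals) > 0) {
    ax <- lapply(1:3, function(a) origin[a] + (seq_len(dims[a]) - 1) * spacing)
    px <- rep(ax[[1]], times = dims[2] * dims[3])
    py <- rep(rep(ax[[2]], each = dims[1]), times = dims[3])
    pz <- rep(ax[[3]], each = dims[1] * dims[2])
    for (cp in canals) {
      d <- point_segment_distance(px, py, pz, cp$from, cp$to)
      vals[inside & d <= cp$radius] <- hu_canal
    }
  }
  if (blur_sigma > 0)
    vals <- .cpp_gauss_blur3(vals, dims, rep(blur_sigma / spacing, 3))
  if (noise_sd > 0)
    vals <- vals + with_local_seed(seed, rnorm(length(vals), 0, noise_sd))
  voxel_volume(array(vals, dims), rep(spacing, 3), origin)
}

# distance from points to a 3-D segment
point_segment_distance <- function(px, py, pz, a, b) {
  ab <- b - a
  l2 <- sum(ab^2)
  t <- ((px - a[1]) * ab[1] + (py - a[2]) * ab[2] + (pz - a[3]) * ab[3]) / l2
  t <- pmin(pmax(t, 0), 1)
  sqrt((px - a[1] - t * ab[1])^2 + (py - a[2] - t * ab[2])^2 +
         (pz - a[3] - t * ab[3])^2)
}

#' Apply a localized smooth bump (or dent) to a mesh
#'
#' Vertices within `radius` of `center` move along their outward normals
#' by `amplitude * w(d)` where `w` is a cosine taper with `w(0) = 1` and
#' `w(radius) = 0`. Negative amplitudes create dents. Vertices outside
#' the support are bit-identical to the input. This emulates localized
#' reproduction errors such as a mis-imaged root tip, a furcation defect
#' or a chipped filling patch.
#'
#' @param mesh a [surface_mesh()] (closed, outward-oriented).
#' @param center length-3 bump centre, mm.
#' @param radius support radius, mm (> 0).
#' @param amplitude peak displacement, mm (may be negative).
#' @return The deformed [surface_mesh()].
#' @export
deform_bump <- function(mesh, center, radius, amplitude) {
  stopifnot(radius > 0)
  if (amplitude == 0) return(mesh)
  d <- sqrt(colSums((t(mesh$vertices) - center)^2))
  sel <- d < radius
  if (!any(sel)) return(mesh)
  n <- vertex_normals(mesh)
  w <- 0.5 * (1 + cos(pi * d[sel] / radius))
  mesh$vertices[sel, ] <- mesh$vertices[sel, , drop = FALSE] +
    n[sel, , drop = FALSE] * (amplitude * w)
  mesh
}

#' Simulate a milled replica of a surface
#'
#' Adds seeded i.i.d. zero-mean Gaussian displacement along each vertex
#' normal (milling error), then a light Taubin smoothing pass to keep
#' the perturbed surface manifold, mimicking the low-pass character of a
#' rotary tool. With `milling_noise_sd = 0` the input is returned
#' unchanged.
#'
#' @param mesh a [surface_mesh()].
#' @param milling_noise_sd standard deviation of the normal displacement, mm.
#' @param seed integer seed.
#' @param smooth_iterations Taubin passes applied after the noise
#'   (0 disables smoothing; useful when the raw displacement statistics
#'   are of interest).
#' @return The perturbed [surface_mesh()].
#' @export
simulate_replica <- function(mesh, milling_noise_sd = 0.05, seed = 1L,
                             smooth_iterations = 2L) {
  stopifnot(milling_noise_sd >= 0)
  if (milling_noise_sd == 0) return(mesh)
  n <- vertex_normals(mesh)
  disp <- with_local_seed(seed,
                          rnorm(nrow(mesh$vertices), 0, milling_noise_sd))
  mesh$vertices <- mesh$vertices + n * disp
  if (smooth_iterations > 0)
    mesh <- smooth_mesh(mesh, iterations = smooth_iterations)
  mesh
}
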