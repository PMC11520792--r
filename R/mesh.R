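#' Triangulated surface mesh
#'
#' Light-weight container for a triangle mesh in physical units (mm):
#' an `n x 3` vertex coordinate matrix and an `m x 3` matrix of 1-based
#' vertex indices. Meshes produced by the phantom generator and the
#' segmentation pipeline are closed (watertight) and wound so triangle
#' normals point outward.
#'
#' @param vertices numeric matrix, one vertex per row (x, y, z in mm).
#' @param triangles integer matrix, one triangle per row, 1-based indices.
#' @return An object of class `surface_mesh`.
#' @export
surface_mesh <- function(vertices, triangles) {
  vertices <- as.matrix(vertices)
  storage.mode(vertices) <- "double"
  triangles <- as.matrix(triangles)
  storage.mode(triangles) <- "integer"
  if (ncol(vertices) != 3L) stop("vertices must have 3 columns")
  if (ncol(triangles) != 3L) stop("triangles must have 3 columns")
  if (!all(is.finite(vertices))) stop("vertex coordinates must be finite")
  if (nrow(triangles) > 0) {
    rng <- range(triangles)
    if (rng[1] < 1L || rng[2] > nrow(vertices))
      stop("triangle indices out of range")
  }
  structure(list(vertices = vertices, triangles = triangles),
            class = "surface_mesh")
}

#' @export
print.surface_mesh <- function(x, ...) {
  cat(sprintf("surface_mesh: %d vertices, %d triangles\n",
              nrow(x$vertices), nrow(x$triangles)))
  bb <- apply(x$vertices, 2, range)
  cat(sprintf("  bbox [%.2f, %.2f] x [%.2f, %.2f] x [%.2f, %.2f] mm\n",
              bb[1, 1], bb[2, 1], bb[1, 2], bb[2, 2], bb[1, 3], bb[2, 3]))
  invisible(x)
}

# corner coordinate matrices of all triangles
tri_corners <- function(mesh) {
  list(a = mesh$vertices[mesh$triangles[, 1], , drop = FALSE],
       b = mesh$vertices[mesh$triangles[, 2], , drop = FALSE],
       c = mesh$vertices[mesh$triangles[, 3], , drop = FALSE])
}

row_cross <- function(u, v) {
  cbind(u[, 2] * v[, 3] - u[, 3] * v[, 2],
        u[, 3] * v[, 1] - u[, 1] * v[, 3],
        u[, 1] * v[, 2] - u[, 2] * v[, 1])
}

#' Total surface area of a mesh (mm^2)
#' @param mesh a [surface_mesh()].
#' @return Numeric scalar, the sum of triangle areas.
#' @export
mesh_area <- function(mesh) {
  co <- tri_corners(mesh)
  cr <- row_cross(co$b - co$a, co$c - co$a)
  sum(0.5 * sqrt(rowSums(cr^2)))
}

#' Enclosed volume of a closed mesh (mm^3)
#'
#' Signed volume by the divergence theorem; positive when triangle
#' winding gives outward normals.
#' @param mesh a closed [surface_mesh()].
#' @param signed if `FALSE` (default) the absolute value is returned.
#' @return Numeric scalar in mm^3.
#' @export
mesh_volume <- function(mesh, signed = FALSE) {
  co <- tri_corners(mesh)
  v <- sum(rowSums(row_cross(co$a, co$b) * co$c)) / 6
  if (signed) v else abs(v)
}

# multiplicity of each undirected edge; used for closedness / Euler checks
mesh_edge_counts <- function(mesh) {
  tr <- mesh$triangles
  e <- rbind(tr[, c(1, 2)], tr[, c(2, 3)], tr[, c(3, 1)])
  nv <- nrow(mesh$vertices)
  key <- pmin(e[, 1], e[, 2]) * (nv + 1) + pmax(e[, 1], e[, 2])
  u <- unique(key)
  tabulate(match(key, u), nbins = length(u))
}

#' Is a mesh closed (watertight)?
#'
#' Every undirected edge must be shared by exactly two triangles.
#' @param mesh a [surface_mesh()].
#' @return Logical scalar.
#' @export
mesh_is_closed <- function(mesh) {
  if (nrow(mesh$triangles) == 0) return(FALSE)
  all(mesh_edge_counts(mesh) == 2L)
}

#' Euler characteristic V - E + F
#'
#' For a closed orientable surface of genus g this equals 2 - 2g per
#' shell; a single genus-0 shell (sphere topology) gives 2.
#' @param mesh a [surface_mesh()].
#' @return Integer scalar.
#' @export
euler_characteristic <- function(mesh) {
  used <- sort(unique(as.vector(mesh$triangles)))
  v <- length(used)
  e <- length(mesh_edge_counts(mesh))
  f <- nrow(mesh$triangles)
  as.integer(v - e + f)
}

#' Number of connected surface shells
#'
#' Counts connected components of the triangle graph (triangles joined
#' through shared vertices). A solid with an internal cavity surfaces as
#' two shells.
#' @param mesh a [surface_mesh()].
#' @return Integer count.
#' @export
mesh_shell_count <- function(mesh) {
  tr <- mesh$triangles
  g <- igraph::graph_from_edgelist(
    rbind(tr[, c(1, 2)], tr[, c(2, 3)]), directed = FALSE)
  comp <- igraph::components(g)
  length(unique(comp$membership[unique(as.vector(tr))]))
}

#' Area-weighted outward vertex normals
#'
#' Each vertex normal is the normalised sum of incident triangle normals
#' weighted by triangle area (the cross-product magnitude carries the
#' weight automatically). Requires consistent outward winding, which all
#' meshes produced by this package have.
#' @param mesh a [surface_mesh()].
#' @return An `n x 3` matrix of unit normals.
#' @export
vertex_normals <- function(mesh) {
  co <- tri_corners(mesh)
  fn <- row_cross(co$b - co$a, co$c - co$a)  # 2*area-weighted face normals
  nv <- nrow(mesh$vertices)
  acc <- matrix(0, nv, 3)
  for (col in 1:3) {
    idx <- mesh$triangles[, col]
    s <- rowsum(fn, idx)
    rows <- as.integer(rownames(s))
    acc[rows, ] <- acc[rows, ] + s
  }
  len <- sqrt(rowSums(acc^2))
  len[len == 0] <- 1
  acc / len
}

#' Flip winding so that outward normals enclose positive volume
#' @param mesh a closed [surface_mesh()].
#' @return The mesh, re-wound if necessary.
#' @export
orient_outward <- function(mesh) {
  if (mesh_volume(mesh, signed = TRUE) < 0)
    mesh$triangles <- mesh$triangles[, c(1, 3, 2), drop = FALSE]
  mesh
}

#' Apply a rigid transform to a mesh
#' @param mesh a [surface_mesh()].
#' @param transform a [rigid_transform()].
#' @return The transformed mesh.
#' @export
transform_mesh <- function(mesh, transform) {
  mesh$vertices <- apply_transform(transform, mesh$vertices)
  mesh
}

#' Weld duplicate vertices
#'
#' Merges vertices whose coordinates agree within `tol` (snap-to-grid
#' welding) and drops degenerate triangles that collapse in the process.
#' @param mesh a [surface_mesh()].
#' @param tol welding tolerance in mm.
#' @return A welded [surface_mesh()].
#' @export
weld_vertices <- function(mesh, tol = 1e-6) {
  v <- mesh$vertices
  key <- paste(round(v[, 1] / tol), round(v[, 2] / tol), round(v[, 3] / tol))
  first <- !duplicated(key)
  map <- match(key, key[first])
  newv <- v[first, , drop = FALSE]
  tr <- matrix(map[mesh$triangles], ncol = 3)
  keep <- tr[, 1] != tr[, 2] & tr[, 2] != tr[, 3] & tr[, 1] != tr[, 3]
  tr <- tr[keep, , drop = FALSE]
  # drop vertices not referenced by any surviving triangle
  used <- sort(unique(as.vector(tr)))
  remap <- integer(nrow(newv))
  remap[used] <- seq_along(used)
  surface_mesh(newv[used, , drop = FALSE], matrix(remap[tr], ncol = 3))
}

#' Laplacian / Taubin mesh smoothing
#'
#' Uniform-weight neighbourhood smoothing. `method = "taubin"` alternates
#' a positive and a negative step (lambda, mu) which smooths with little
#' shrinkage; `"laplacian"` uses the single positive step.
#' @param mesh a [surface_mesh()].
#' @param iterations number of passes.
#' @param lambda positive smoothing factor.
#' @param mu negative (inflation) factor for Taubin smoothing.
#' @param method `"taubin"` or `"laplacian"`.
#' @return The smoothed mesh.
#' @export
smooth_mesh <- function(mesh, iterations = 10, lambda = 0.5, mu = -0.53,
                        method = c("taubin", "laplacian")) {
  method <- match.arg(method)
  factors <- if (method == "taubin") c(lambda, mu) else lambda
  mesh$vertices <- .cpp_laplacian_smooth(mesh$vertices, mesh$triangles,
                                         factors, as.integer(iterations))
  mesh
}

#' Extract an isosurface from a scalar field
#'
#' Marching tetrahedra over the voxel grid: every cube of eight grid
#' nodes is split into six tetrahedra sharing the main diagonal and the
#' level crossing is interpolated linearly on tetrahedron edges. The
#' result is watertight and outward-oriented whenever the region with
#' `field > level` does not touch the grid border.
#' @param field 3-D numeric array; values above `level` are interior.
#' @param level iso level.
#' @param spacing voxel spacing, length-3, mm.
#' @param origin physical coordinate of grid node (1,1,1), mm.
#' @return A welded [surface_mesh()].
#' @export
isosurface <- function(field, level, spacing = c(1, 1, 1),
                       origin = c(0, 0, 0)) {
  d <- dim(field)
  if (length(d) != 3L) stop("field must be a 3-D array")
  res <- .cpp_march_tet(as.numeric(field), as.integer(d), level,
                        as.numeric(spacing), as.numeric(origin))
  orient_outward(surface_mesh(res$vertices, res$triangles))
}
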