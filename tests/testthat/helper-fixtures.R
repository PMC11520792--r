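# Shared fixtures and independent oracles. Everything is generated in
# code; heavyweight objects are memoised for the duration of the run.

.fixture_cache <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (!exists(key, envir = .fixture_cache))
    assign(key, expr, envir = .fixture_cache)
  get(key, envir = .fixture_cache)
}

# sphere mesh from its exact signed distance field
sphere_fixture <- function(r, sp = 0.3, center = c(0, 0, 0)) {
  memo(sprintf("sphere_%g_%g_%g%g%g", r, sp, center[1], center[2], center[3]), {
    ax <- seq(-r - 1.2, r + 1.2, by = sp)
    n <- length(ax)
    g <- as.matrix(expand.grid(ax, ax, ax))
    f <- r - sqrt(rowSums(g^2))
    m <- isosurface(array(f, c(n, n, n)), 0, rep(sp, 3), rep(-r - 1.2, 3))
    m$vertices <- sweep(m$vertices, 2, center, "+")
    m
  })
}

phantom_fixture <- function(kind) {
  memo(paste0("phantom_", kind), make_phantom(kind, seed = 1L))
}

# noise-free CBCT reconstruction of a phantom
segmented_fixture <- function(kind) {
  memo(paste0("segmented_", kind), {
    ph <- phantom_fixture(kind)
    vol <- voxelize(ph$mesh, spacing = 0.2, canals = canal_paths(ph$spec))
    segment_volume(vol)
  })
}

# an axis-aligned unit-cube mesh with outward winding: exact area 6, volume 1
cube_fixture <- function() {
  v <- as.matrix(expand.grid(0:1, 0:1, 0:1))  # binary order: x fastest
  tri <- rbind(
    c(1, 3, 2), c(2, 3, 4),   # z = 0 face (normal -z)
    c(5, 6, 7), c(6, 8, 7),   # z = 1 face (+z)
    c(1, 2, 5), c(2, 6, 5),   # y = 0 (-y)
    c(3, 7, 4), c(4, 7, 8),   # y = 1 (+y)
    c(1, 5, 3), c(3, 5, 7),   # x = 0 (-x)
    c(2, 4, 6), c(4, 8, 6))   # x = 1 (+x)
  orient_outward(surface_mesh(v, tri))
}

# extract the sub-mesh carried by a subset of triangles, keeping only
# the vertices those triangles reference
submesh <- function(mesh, tri_rows) {
  tr <- mesh$triangles[tri_rows, , drop = FALSE]
  used <- sort(unique(as.vector(tr)))
  remap <- integer(nrow(mesh$vertices))
  remap[used] <- seq_along(used)
  surface_mesh(mesh$vertices[used, , drop = FALSE],
               matrix(remap[tr], ncol = 3))
}

grid_axes_of <- function(vol) {
  d <- dim(vol$values)
  lapply(1:3, function(a) vol$origin[a] + (seq_len(d[a]) - 1) * vol$spacing[a])
}

# --- independent geometric oracles (plain R, no package internals) -------

# distance from points P (n x 3) to one triangle, by plane projection with
# barycentric inside test and edge clamping
oracle_tri_dist <- function(P, A, B, C) {
  seg_d <- function(P, a, b) {
    ab <- b - a
    tt <- ((P[, 1] - a[1]) * ab[1] + (P[, 2] - a[2]) * ab[2] +
             (P[, 3] - a[3]) * ab[3]) / sum(ab^2)
    tt <- pmin(pmax(tt, 0), 1)
    sqrt((P[, 1] - a[1] - tt * ab[1])^2 + (P[, 2] - a[2] - tt * ab[2])^2 +
           (P[, 3] - a[3] - tt * ab[3])^2)
  }
  n <- c((B - A)[2] * (C - A)[3] - (B - A)[3] * (C - A)[2],
         (B - A)[3] * (C - A)[1] - (B - A)[1] * (C - A)[3],
         (B - A)[1] * (C - A)[2] - (B - A)[2] * (C - A)[1])
  nn <- sum(n^2)
  w <- sweep(P, 2, A)
  dist_plane <- abs(w %*% n) / sqrt(nn)
  # barycentric coordinates of the in-plane projection
  v0 <- B - A; v1 <- C - A
  d00 <- sum(v0 * v0); d01 <- sum(v0 * v1); d11 <- sum(v1 * v1)
  d20 <- w %*% v0; d21 <- w %*% v1
  den <- d00 * d11 - d01 * d01
  bv <- (d11 * d20 - d01 * d21) / den
  bw <- (d00 * d21 - d01 * d20) / den
  inside <- bv >= 0 & bw >= 0 & (bv + bw) <= 1
  d <- pmin(seg_d(P, A, B), seg_d(P, B, C), seg_d(P, C, A))
  d[inside] <- dist_plane[inside]
  d
}

# brute-force closest distance from points to every triangle of a mesh
oracle_closest <- function(mesh, P) {
  d <- rep(Inf, nrow(P))
  for (t in seq_len(nrow(mesh$triangles))) {
    tr <- mesh$triangles[t, ]
    d <- pmin(d, oracle_tri_dist(P, mesh$vertices[tr[1], ],
                                 mesh$vertices[tr[2], ],
                                 mesh$vertices[tr[3], ]))
  }
  d
}

# parity point-in-mesh oracle: count triangle crossings of a +x ray
oracle_in_mesh <- function(mesh, P) {
  dir <- c(1, 2.13e-5, 5.71e-5)
  dir <- dir / sqrt(sum(dir^2))
  apply(P, 1, function(p) {
    hits <- 0
    for (t in seq_len(nrow(mesh$triangles))) {
      tr <- mesh$triangles[t, ]
      A <- mesh$vertices[tr[1], ]; B <- mesh$vertices[tr[2], ]
      C <- mesh$vertices[tr[3], ]
      e1 <- B - A; e2 <- C - A
      pv <- c(dir[2] * e2[3] - dir[3] * e2[2],
              dir[3] * e2[1] - dir[1] * e2[3],
              dir[1] * e2[2] - dir[2] * e2[1])
      det <- sum(e1 * pv)
      if (abs(det) < 1e-14) next
      tv <- p - A
      u <- sum(tv * pv) / det
      if (u < 0 || u > 1) next
      qv <- c(tv[2] * e1[3] - tv[3] * e1[2],
              tv[3] * e1[1] - tv[1] * e1[3],
              tv[1] * e1[2] - tv[2] * e1[1])
      v <- sum(dir * qv) / det
      if (v < 0 || u + v > 1) next
      tt <- sum(e2 * qv) / det
      if (tt > 0) hits <- hits + 1
    }
    hits %% 2 == 1
  })
}

# count closed loops of the cross-section of a mesh with plane z = z0:
# collect triangle/plane intersection segments, weld their endpoints and
# count connected components of the resulting polyline graph
oracle_slice_loops <- function(mesh, z0, tol = 1e-7) {
  v <- mesh$vertices
  tr <- mesh$triangles
  segs <- list()
  for (t in seq_len(nrow(tr))) {
    zz <- v[tr[t, ], 3] - z0
    if (all(zz > 0) || all(zz < 0)) next
    pts <- list()
    corners <- rbind(v[tr[t, 1], ], v[tr[t, 2], ], v[tr[t, 3], ])
    for (e in list(c(1, 2), c(2, 3), c(3, 1))) {
      za <- zz[e[1]]; zb <- zz[e[2]]
      if ((za > 0 && zb <= 0) || (za <= 0 && zb > 0)) {
        a <- corners[e[1], ]; b <- corners[e[2], ]
        s <- za / (za - zb)
        pts[[length(pts) + 1]] <- a + s * (b - a)
      }
    }
    if (length(pts) == 2) segs[[length(segs) + 1]] <- do.call(rbind, pts)
  }
  if (length(segs) == 0) return(0L)
  ends <- do.call(rbind, segs)
  key <- paste(round(ends[, 1] / tol), round(ends[, 2] / tol))
  id <- match(key, unique(key))
  m <- matrix(id, ncol = 2, byrow = TRUE)
  g <- igraph::graph_from_edgelist(m, directed = FALSE)
  as.integer(igraph::components(g)$no)
}

# naive independent recomputation of summary statistics
oracle_summary <- function(values) {
  sv <- sort(values)
  n <- length(sv)
  med <- if (n %% 2 == 1) sv[(n + 1) / 2] else (sv[n / 2] + sv[n / 2 + 1]) / 2
  list(min = sv[1], max = sv[n], mean = sum(sv) / n, median = med)
}

# random closed blob mesh (union of a few spheres) with <= ~500 faces
blob_fixture <- function(seed) {
  set.seed(seed)
  k <- sample(2:3, 1)
  cs <- matrix(runif(3 * k, -1.0, 1.0), ncol = 3)
  rs <- runif(k, 0.9, 1.4)
  sp <- 1.0
  ax <- seq(-3.6, 3.6, by = sp)
  n <- length(ax)
  g <- as.matrix(expand.grid(ax, ax, ax))
  f <- rep(-Inf, nrow(g))
  for (i in seq_len(k)) {
    f <- pmax(f, rs[i] - sqrt(rowSums(sweep(g, 2, cs[i, ])^2)))
  }
  isosurface(array(f, c(n, n, n)), 0, rep(sp, 3), rep(-4.5, 3))
}
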