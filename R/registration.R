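#' ICP configuration
#'
#' Parameters of the iterative-closest-point registration. Convergence
#' uses the absolute change of the correspondence RMS between
#' iterations, which stays well defined as the residual approaches
#' zero.
#'
#' @param max_iterations iteration cap (>= 1).
#' @param rms_change_tolerance stop when the RMS changes less than this
#'   (mm).
#' @param correspondence_cutoff drop correspondences farther than this
#'   (mm; `Inf` keeps all).
#' @param trim_fraction fraction of the worst correspondences discarded
#'   each iteration (0 keeps all; robustifies against partial overlap).
#' @param subsample_count number of source vertices used for
#'   correspondence search (`Inf` = all; subsampling is uniform-random
#'   and seeded).
#' @param final_full_pass run one full-vertex refinement after
#'   convergence when subsampling was used.
#' @param plane_polish once the point-to-point phase stalls, switch to
#'   linearized point-to-plane steps, which converge much faster in the
#'   tangential modes of smooth surfaces. Polish steps are only accepted
#'   when they do not increase the point-to-surface RMS, so the RMS
#'   history stays non-increasing either way.
#' @param seed integer seed for the subsample draw.
#' @return A list of class `icp_config`.
#' @export
icp_config <- function(max_iterations = 100L, rms_change_tolerance = 1e-6,
                       correspondence_cutoff = Inf, trim_fraction = 0,
                       subsample_count = Inf, final_full_pass = TRUE,
                       plane_polish = TRUE, seed = 1L) {
  stopifnot(max_iterations >= 1, rms_change_tolerance > 0,
            trim_fraction >= 0, trim_fraction < 1)
  structure(list(max_iterations = as.integer(max_iterations),
                 rms_change_tolerance = rms_change_tolerance,
                 correspondence_cutoff = correspondence_cutoff,
                 trim_fraction = trim_fraction,
                 subsample_count = subsample_count,
                 final_full_pass = isTRUE(final_full_pass),
                 plane_polish = isTRUE(plane_polish),
                 seed = as.integer(seed)),
            class = "icp_config")
}

#' Least-squares rigid transform between paired point sets
#'
#' Closed-form solution of `argmin sum w_i ||R s_i + t - t_i||^2` over
#' proper rotations (Kabsch/Umeyama: SVD of the weighted covariance with
#' a determinant sign correction, no scaling).
#'
#' @param source_points,target_points `n x 3` matrices of paired points
#'   (`n >= 3`, not all collinear).
#' @param weights optional non-negative weights, length `n`.
#' @return A [rigid_transform()].
#' @export
best_rigid <- function(source_points, target_points, weights = NULL) {
  s <- as.matrix(source_points)
  t_ <- as.matrix(target_points)
  if (nrow(s) != nrow(t_)) stop("point sets must be paired (equal length)")
  if (nrow(s) < 3) stop("at least 3 point pairs are required")
  if (is.null(weights)) weights <- rep(1, nrow(s))
  w <- weights / sum(weights)
  cs <- colSums(s * w)
  ct <- colSums(t_ * w)
  sc <- sweep(s, 2, cs)
  tc <- sweep(t_, 2, ct)
  H <- t(sc * w) %*% tc
  sv <- svd(H)
  # rank check: collinear/degenerate configurations have rank < 2
  if (sv$d[2] < 1e-12 * max(sv$d[1], 1e-300))
    stop("degenerate (collinear) point configuration")
  d <- sign(det(sv$v %*% t(sv$u)))
  D <- diag(c(1, 1, d))
  R <- sv$v %*% D %*% t(sv$u)
  rigid_transform(R, ct - as.vector(R %*% cs))
}

# deterministic uniform subsample of vertex indices
subsample_idx <- function(n, count, seed) {
  if (!is.finite(count) || count >= n) return(seq_len(n))
  with_local_seed(seed, sample.int(n, count))
}

# RMS of distances from points to a gridded target surface
closest_rms <- function(grid, pts) {
  sqrt(mean(.cpp_grid_closest(grid, pts)$distance^2))
}

#' Coarse alignment by centroids and principal axes
#'
#' Aligns the source centroid and covariance eigenvectors onto the
#' target's. Vertices are weighted by their incident triangle area, so
#' the axes reflect the surface geometry rather than the tessellation
#' density. The four proper sign combinations of the principal axes are
#' all tried and the one with the lowest sampled closest-point RMS
#' wins. Near-isotropic shapes (no reliable axes) fall back to
#' centroid-only alignment.
#'
#' @param source,target [surface_mesh()] objects.
#' @param sample_count vertices sampled for scoring candidates.
#' @param seed seed for the scoring subsample.
#' @return A [rigid_transform()] mapping source onto target.
#' @export
initial_align <- function(source, target, sample_count = 1000L, seed = 1L) {
  vs <- source$vertices
  vt <- target$vertices
  weighted_moments <- function(mesh) {
    co <- tri_corners(mesh)
    area3 <- 0.5 * sqrt(rowSums(row_cross(co$b - co$a, co$c - co$a)^2)) / 3
    w <- numeric(nrow(mesh$vertices))
    for (col in 1:3) {
      s <- rowsum(area3, mesh$triangles[, col])
      rows <- as.integer(rownames(s))
      w[rows] <- w[rows] + s
    }
    w <- w / sum(w)
    ctr <- colSums(mesh$vertices * w)
    dc <- sweep(mesh$vertices, 2, ctr)
    list(center = ctr, cov = crossprod(dc * sqrt(w)))
  }
  ms <- weighted_moments(source)
  mt <- weighted_moments(target)
  cs <- ms$center
  ct <- mt$center
  es <- eigen(ms$cov, symmetric = TRUE)
  et <- eigen(mt$cov, symmetric = TRUE)
  grid <- .cpp_grid_build(vt, target$triangles)
  idx <- subsample_idx(nrow(vs), sample_count, seed)
  pts <- vs[idx, , drop = FALSE]
  # isotropy guard: eigenvalue spread too small to orient reliably
  if (es$values[1] < 1.2 * es$values[3] || et$values[1] < 1.2 * et$values[3]) {
    message("initial_align: near-isotropic shape, centroid-only alignment")
    return(rigid_transform(diag(3), ct - cs))
  }
  Us <- es$vectors
  if (det(Us) < 0) Us[, 3] <- -Us[, 3]
  Ut <- et$vectors
  if (det(Ut) < 0) Ut[, 3] <- -Ut[, 3]
  best <- NULL
  best_rms <- Inf
  for (sx in c(1, -1)) for (sy in c(1, -1)) {
    S <- diag(c(sx, sy, sx * sy))  # proper sign combinations only
    R <- Ut %*% S %*% t(Us)
    tf <- rigid_transform(R, ct - as.vector(R %*% cs))
    rms <- closest_rms(grid, apply_transform(tf, pts))
    if (rms < best_rms) { best_rms <- rms; best <- tf }
  }
  best
}

#' Iterative closest point rigid registration
#'
#' Registers `source` onto `target`: each iteration finds, for a
#' (possibly subsampled) set of source vertices, the exact closest point
#' on the target surface (point-to-triangle, not nearest vertex),
#' optionally trims the worst correspondences, solves the closed-form
#' rigid fit ([best_rigid()]) and composes. With exact closest-point
#' correspondences and no trimming the RMS history is non-increasing
#' (the classic ICP monotonicity guarantee).
#'
#' @param source,target [surface_mesh()] objects with substantial
#'   overlap.
#' @param cfg an [icp_config()].
#' @param init optional initial [rigid_transform()] (e.g. from
#'   [initial_align()]); identity by default.
#' @return A list with `transform` (source -> target
#'   [rigid_transform()]) and `rms_history` (mm, one value per
#'   iteration).
#' @export
icp_register <- function(source, target, cfg = icp_config(), init = NULL) {
  grid <- .cpp_grid_build(target$vertices, target$triangles)
  tf <- if (is.null(init)) rigid_transform() else init
  vs_all <- source$vertices
  idx <- subsample_idx(nrow(vs_all), cfg$subsample_count, cfg$seed)
  co <- tri_corners(target)
  tn <- row_cross(co$b - co$a, co$c - co$a)
  tn <- tn / pmax(sqrt(rowSums(tn^2)), 1e-300)   # target face unit normals
  # switch to plane polish once point steps change the RMS less than this
  switch_tol <- max(cfg$rms_change_tolerance, 1e-4)
  run <- function(tf, pts0, max_iter) {
    rms_hist <- numeric(0)
    prev_rms <- Inf
    prev_tf <- tf
    mode <- "point"
    for (it in seq_len(max_iter)) {
      pts <- apply_transform(tf, pts0)
      cl <- .cpp_grid_closest(grid, pts)
      keep <- cl$distance <= cfg$correspondence_cutoff
      if (cfg$trim_fraction > 0) {
        cutoff <- stats::quantile(cl$distance, 1 - cfg$trim_fraction,
                                  names = FALSE)
        keep <- keep & (cl$distance <= cutoff)
      }
      if (sum(keep) < 3)
        stop("no correspondences survive trimming/cutoff")
      rms <- sqrt(mean(cl$distance[keep]^2))
      if (rms > prev_rms + 1e-12) {
        # only a plane-polish step can get here; reject it and stop
        tf <- prev_tf
        break
      }
      rms_hist <- c(rms_hist, rms)
      converged <- is.finite(prev_rms) &&
        abs(prev_rms - rms) < cfg$rms_change_tolerance
      if (converged && (!cfg$plane_polish || mode == "plane")) break
      if (cfg$plane_polish && mode == "point" &&
          is.finite(prev_rms) && abs(prev_rms - rms) < switch_tol)
        mode <- "plane"
      prev_tf <- tf
      prev_rms <- rms
      p <- pts[keep, , drop = FALSE]
      q <- cl$point[keep, , drop = FALSE]
      if (mode == "point") {
        step <- best_rigid(p, q)
      } else {
        step <- plane_step(p, q, tn[cl$triangle[keep], , drop = FALSE])
      }
      tf <- compose_transforms(step, tf)
    }
    list(tf = tf, rms = rms_hist)
  }
  res <- run(tf, vs_all[idx, , drop = FALSE], cfg$max_iterations)
  if (cfg$final_full_pass && length(idx) < nrow(vs_all)) {
    res2 <- run(res$tf, vs_all, 20L)
    res <- list(tf = res2$tf, rms = c(res$rms, res2$rms))
  }
  list(transform = res$tf, rms_history = res$rms)
}

# linearized point-to-plane rigid step: minimize
# sum_i (n_i . (p_i + w x p_i + t - q_i))^2 over (w, t), then map the
# small rotation w back to SO(3) by the exponential (Rodrigues) map
plane_step <- function(p, q, n) {
  cx <- cbind(p[, 2] * n[, 3] - p[, 3] * n[, 2],
              p[, 3] * n[, 1] - p[, 1] * n[, 3],
              p[, 1] * n[, 2] - p[, 2] * n[, 1])
  A <- cbind(cx, n)
  r <- rowSums(n * (q - p))
  x <- tryCatch(solve(crossprod(A), crossprod(A, r)),
                error = function(e) rep(0, 6))
  w <- x[1:3]
  th <- sqrt(sum(w^2))
  R <- if (th < 1e-300) diag(3) else rotation_about(w, th * 180 / pi)
  rigid_transform(R, x[4:6])
}

#' Merge two partial scans into one mesh
#'
#' Registers `half_b` onto `half_a` with overlap-tolerant trimming, then
#' unions the triangle sets and welds duplicate vertices. This mirrors
#' the optical-scanning workflow where crown and root halves are scanned
#' separately and combined into a whole-tooth model.
#'
#' @param half_a,half_b [surface_mesh()] partial scans overlapping over
#'   a band of the surface.
#' @param cfg an [icp_config()]; a substantial `trim_fraction` (default
#'   0.6 here) makes the registration ignore the non-overlapping parts.
#' @param min_overlap_fraction fraction of `half_b` vertices that must
#'   end up within `overlap_tol` of `half_a` for the merge to be
#'   accepted.
#' @param overlap_tol distance (mm) below which a vertex counts as
#'   lying on the other scan.
#' @return The merged [surface_mesh()].
#' @export
merge_half_scans <- function(half_a, half_b,
                             cfg = icp_config(trim_fraction = 0.6),
                             min_overlap_fraction = 0.1,
                             overlap_tol = 0.05) {
  reg <- icp_register(half_b, half_a, cfg)
  moved <- transform_mesh(half_b, reg$transform)
  grid <- .cpp_grid_build(half_a$vertices, half_a$triangles)
  d <- .cpp_grid_closest(grid, moved$vertices)$distance
  if (mean(d < overlap_tol) < min_overlap_fraction)
    stop("half scans do not overlap; merge refused")
  nv_a <- nrow(half_a$vertices)
  merged <- surface_mesh(rbind(half_a$vertices, moved$vertices),
                         rbind(half_a$triangles, moved$triangles + nv_a))
  weld_vertices(merged, tol = 1e-6)
}
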