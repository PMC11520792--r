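#' Per-vertex deviation field
#'
#' Deviation values (mm) carried on the vertices of a basis mesh.
#' Euclidean fields are unsigned (distance to the closest point on the
#' other surface); normal fields are signed directed distances along the
#' vertex normal, with `NA`-flagged vertices where no intersection lies
#' within range.
#'
#' @param values numeric per-vertex deviations, mm.
#' @param metric `"euclidean"` or `"normal"`.
#' @param missing logical per-vertex flag (no intersection found).
#' @param basis_mesh_id identifier of the mesh carrying the values.
#' @return An object of class `distance_field`.
#' @export
distance_field <- function(values, metric = c("euclidean", "normal"),
                           missing = NULL, basis_mesh_id = "basis") {
  metric <- match.arg(metric)
  values <- as.numeric(values)
  if (is.null(missing)) missing <- is.na(values)
  if (length(missing) != length(values))
    stop("missing flag length must match values")
  if (metric == "euclidean" && any(values[!missing] < 0))
    stop("euclidean deviations must be non-negative")
  structure(list(values = values, metric = metric, missing = missing,
                 basis_mesh_id = basis_mesh_id),
            class = "distance_field")
}

#' @export
print.distance_field <- function(x, ...) {
  cat(sprintf("distance_field (%s) on %s: %d vertices, %d missing\n",
              x$metric, x$basis_mesh_id, length(x$values), sum(x$missing)))
  invisible(x)
}

#' Unsigned closest-point (Euclidean) deviation field
#'
#' For every vertex of `basis`, the exact unsigned distance to the
#' nearest point anywhere on the surface of `other` (point-to-triangle,
#' accelerated by a uniform spatial grid; exact, the grid only prunes).
#' Both meshes must already be registered into a common frame.
#'
#' @param basis mesh whose vertices carry the values.
#' @param other mesh measured against.
#' @param basis_mesh_id label stored in the field.
#' @return A [distance_field()] with no missing values.
#' @export
euclidean_field <- function(basis, other, basis_mesh_id = "basis") {
  if (nrow(basis$vertices) == 0 || nrow(other$triangles) == 0)
    stop("meshes must be non-empty")
  grid <- .cpp_grid_build(other$vertices, other$triangles)
  d <- .cpp_grid_closest(grid, basis$vertices)$distance
  distance_field(d, "euclidean", basis_mesh_id = basis_mesh_id)
}

#' Signed normal-distance deviation field
#'
#' For every vertex of `basis`, a ray is cast along its outward normal
#' in both directions; the nearest intersection with `other` within
#' `max_range` gives the value's magnitude. The sign is positive when
#' the hit lies along the outward normal, i.e. when `other` is locally
#' outside (larger than) `basis`. Vertices without a hit are flagged
#' missing and excluded from summaries.
#'
#' When the basis is the reconstruction/replica model and `other` the
#' natural-tooth scan, positive values therefore mean "natural tooth
#' larger", the convention used in reporting; [compare_models()] flips
#' the sign when the basis is the natural scan so the reported sign
#' always encodes which model the natural tooth exceeds.
#'
#' @param basis closed, outward-oriented mesh carrying the values.
#' @param other mesh measured against.
#' @param max_range maximum search distance along the normal, mm.
#' @param basis_mesh_id label stored in the field.
#' @return A signed [distance_field()].
#' @export
normal_field <- function(basis, other, max_range = 5,
                         basis_mesh_id = "basis") {
  if (nrow(basis$vertices) == 0 || nrow(other$triangles) == 0)
    stop("meshes must be non-empty")
  if (!mesh_is_closed(basis))
    stop("basis mesh is not closed/consistently wound; ",
         "re-orient it (see orient_outward) before computing normals")
  n <- vertex_normals(basis)
  grid <- .cpp_grid_build(other$vertices, other$triangles)
  t_signed <- .cpp_grid_normal_shoot(grid, basis$vertices, n, max_range)
  distance_field(t_signed, "normal", missing = is.na(t_signed),
                 basis_mesh_id = basis_mesh_id)
}

#' Summary statistics of a deviation field
#'
#' Order statistics and moments over the valid (non-missing) values;
#' the median of an even count is the mean of the central pair. For
#' signed fields the absolute-value mean and median are reported too.
#'
#' @param field a [distance_field()].
#' @return A list of class `summary_stats` with `min`, `max`, `mean`,
#'   `median`, `abs_mean`, `abs_median` (signed metrics only, else
#'   `NA`), `n_valid` and `n_missing`.
#' @export
summarize_field <- function(field) {
  v <- field$values[!field$missing]
  if (length(v) == 0) stop("all values are missing; nothing to summarize")
  signed <- field$metric == "normal"
  structure(list(
    min = min(v), max = max(v), mean = mean(v), median = stats::median(v),
    abs_mean = if (signed) mean(abs(v)) else NA_real_,
    abs_median = if (signed) stats::median(abs(v)) else NA_real_,
    n_valid = length(v), n_missing = sum(field$missing)),
    class = "summary_stats")
}

#' @export
print.summary_stats <- function(x, ...) {
  cat(sprintf("min %.4g  mean %.4g  median %.4g  max %.4g (mm), n=%d (%d missing)\n",
              x$min, x$mean, x$median, x$max, x$n_valid, x$n_missing))
  if (!is.na(x$abs_mean))
    cat(sprintf("abs_mean %.4g  abs_median %.4g\n", x$abs_mean, x$abs_median))
  invisible(x)
}

#' Register and compare two surface models
#'
#' The full accuracy-assessment step for one pair: rigidly registers
#' `model` onto `natural_scan` (coarse principal-axes alignment followed
#' by ICP), then computes the Euclidean and signed normal deviation
#' fields on the chosen basis mesh and their summaries.
#'
#' The basis defaults differ by comparison in the study design:
#' deviations of the CBCT reconstruction are expressed on the model
#' mesh, deviations of the replica on the natural-tooth scan. The
#' reported normal sign always encodes "positive = natural tooth
#' locally larger", regardless of basis.
#'
#' @param natural_scan reference mesh (optical scan stand-in); fixed.
#' @param model mesh under assessment (CBCT reconstruction or replica);
#'   moving.
#' @param basis_choice `"model"` or `"natural"`: which mesh carries the
#'   per-vertex fields.
#' @param icp_cfg an [icp_config()].
#' @param max_range normal-ray search range, mm.
#' @return A list with `transform`, `rms_history`, `euclidean`
#'   ([distance_field()]), `normal` ([distance_field()]),
#'   `euclidean_stats`, `normal_stats`, and `basis` (the registered
#'   basis mesh, for rendering).
#' @export
compare_models <- function(natural_scan, model,
                           basis_choice = c("model", "natural"),
                           icp_cfg = icp_config(), max_range = 5) {
  basis_choice <- match.arg(basis_choice)
  init <- initial_align(model, natural_scan, seed = icp_cfg$seed)
  reg <- icp_register(model, natural_scan, icp_cfg, init = init)
  model_reg <- transform_mesh(model, reg$transform)
  if (basis_choice == "model") {
    basis <- model_reg
    other <- natural_scan
    flip <- 1
  } else {
    basis <- natural_scan
    other <- model_reg
    flip <- -1   # hit outward of natural = model larger = natural smaller
  }
  eu <- euclidean_field(basis, other, basis_mesh_id = basis_choice)
  no <- normal_field(basis, other, max_range, basis_mesh_id = basis_choice)
  no$values <- flip * no$values
  list(transform = reg$transform, rms_history = reg$rms_history,
       euclidean = eu, normal = no,
       euclidean_stats = summarize_field(eu),
       normal_stats = summarize_field(no),
       basis = basis)
}
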