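#' Map a deviation field onto blue-to-yellow vertex colours
#'
#' Linear colour ramp from dark blue (`#00008B`) to bright yellow
#' (`#FFFF00`). In `magnitude` mode the ramp spans `[min, max]` of the
#' valid values; in `signed` mode it spans `[most negative, most
#' positive]`, so dark blue marks where the compared model exceeds the
#' natural tooth and bright yellow where the natural tooth is larger.
#' Missing vertices are rendered neutral grey. A constant field maps to
#' the mid-ramp colour.
#'
#' @param mesh the basis [surface_mesh()] of the field.
#' @param field a [distance_field()] on that mesh.
#' @param mode `"magnitude"` or `"signed"`.
#' @return A list of class `colored_mesh` with `mesh`, `colors`
#'   (`n x 3` integer RGB) and `range` (the value span mapped).
#' @export
colormap_mesh <- function(mesh, field, mode = c("magnitude", "signed")) {
  mode <- match.arg(mode)
  if (length(field$values) != nrow(mesh$vertices))
    stop("field basis does not match mesh vertex count")
  v <- field$values
  ok <- !field$missing
  lo <- min(v[ok]); hi <- max(v[ok])
  u <- if (hi > lo) (v - lo) / (hi - lo) else rep(0.5, length(v))
  ramp_lo <- c(0, 0, 139)     # dark blue
  ramp_hi <- c(255, 255, 0)   # bright yellow
  cols <- outer(u, ramp_hi) + outer(1 - u, ramp_lo)
  cols <- matrix(as.integer(round(cols)), ncol = 3)
  cols[!ok, ] <- 128L          # neutral grey for missing vertices
  structure(list(mesh = mesh, colors = cols, range = c(lo, hi), mode = mode),
            class = "colored_mesh")
}

#' Per-comparison report record
#'
#' Bundles the summary statistics of one (tooth, comparison) pair for
#' table building.
#' @param tooth_label tooth name, e.g. `"premolar"`.
#' @param comparison `"cbct_vs_natural"` or `"replica_vs_natural"`.
#' @param euclidean_stats,normal_stats [summarize_field()] results.
#' @param field_file_paths optional character vector of written field
#'   files.
#' @return A list of class `comparison_report`.
#' @export
comparison_report <- function(tooth_label,
                              comparison = c("cbct_vs_natural",
                                             "replica_vs_natural"),
                              euclidean_stats, normal_stats,
                              field_file_paths = character()) {
  comparison <- match.arg(comparison)
  stopifnot(euclidean_stats$min <= euclidean_stats$median,
            euclidean_stats$median <= euclidean_stats$max)
  structure(list(tooth_label = tooth_label, comparison = comparison,
                 euclidean_stats = euclidean_stats,
                 normal_stats = normal_stats,
                 field_file_paths = field_file_paths),
            class = "comparison_report")
}

#' Build the summary deviation table
#'
#' One row per (tooth, comparison, metric) with min / mean / median /
#' max in mm, plus absolute mean and median for the signed normal
#' metric. Values are rounded to 3 significant figures, the precision
#' used for reporting. The table is a pure function of its inputs: no
#' timestamps or run metadata appear in data rows.
#'
#' @param reports list of [comparison_report()] objects.
#' @param path optional CSV output path.
#' @return A `data.frame`; written to `path` as CSV when given.
#' @export
build_report <- function(reports, path = NULL) {
  if (length(reports) < 1) stop("at least one report is required")
  row_of <- function(r, metric) {
    s <- if (metric == "euclidean") r$euclidean_stats else r$normal_stats
    data.frame(tooth = r$tooth_label, comparison = r$comparison,
               metric = metric,
               min_mm = signif(s$min, 3), mean_mm = signif(s$mean, 3),
               median_mm = signif(s$median, 3), max_mm = signif(s$max, 3),
               abs_mean_mm = signif(s$abs_mean, 3),
               abs_median_mm = signif(s$abs_median, 3),
               n_valid = s$n_valid, n_missing = s$n_missing,
               stringsAsFactors = FALSE)
  }
  tab <- do.call(rbind, unlist(lapply(reports, function(r)
    list(row_of(r, "euclidean"), row_of(r, "normal"))), recursive = FALSE))
  rownames(tab) <- NULL
  if (!is.null(path)) write.csv(tab, path, row.names = FALSE)
  tab
}

#' Render a coloured mesh to PNG
#'
#' Simple orthographic flat-shaded render with painter's-algorithm depth
#' sorting; adequate for the semiquantitative deviation maps. The view
#' direction is given as (azimuth, elevation) in degrees.
#'
#' @param cmesh a `colored_mesh` from [colormap_mesh()].
#' @param path PNG output path.
#' @param azimuth,elevation view angles, degrees.
#' @param width,height image size in pixels.
#' @return The path, invisibly.
#' @export
render_mesh_png <- function(cmesh, path, azimuth = 30, elevation = 15,
                            width = 800, height = 1000) {
  mesh <- cmesh$mesh
  az <- azimuth * pi / 180
  el <- elevation * pi / 180
  # camera basis: right, up, forward
  fwd <- c(cos(el) * cos(az), cos(el) * sin(az), sin(el))
  right <- c(-sin(az), cos(az), 0)
  up <- c(-sin(el) * cos(az), -sin(el) * sin(az), cos(el))
  P <- mesh$vertices %*% cbind(right, up, fwd)
  tr <- mesh$triangles
  depth <- (P[tr[, 1], 3] + P[tr[, 2], 3] + P[tr[, 3], 3]) / 3
  ord <- order(depth)
  tricol <- grDevices::rgb((cmesh$colors[tr[, 1], 1] +
                              cmesh$colors[tr[, 2], 1] +
                              cmesh$colors[tr[, 3], 1]) / 3,
                           (cmesh$colors[tr[, 1], 2] +
                              cmesh$colors[tr[, 2], 2] +
                              cmesh$colors[tr[, 3], 2]) / 3,
                           (cmesh$colors[tr[, 1], 3] +
                              cmesh$colors[tr[, 2], 3] +
                              cmesh$colors[tr[, 3], 3]) / 3,
                           maxColorValue = 255)
  grDevices::png(path, width = width, height = height)
  on.exit(grDevices::dev.off())
  graphics::par(mar = c(0, 0, 0, 0))
  graphics::plot(NA, xlim = range(P[, 1]), ylim = range(P[, 2]),
                 asp = 1, axes = FALSE, xlab = "", ylab = "")
  xs <- rbind(matrix(P[t(tr[ord, ]), 1], nrow = 3), NA)
  ys <- rbind(matrix(P[t(tr[ord, ]), 2], nrow = 3), NA)
  graphics::polygon(as.vector(xs), as.vector(ys), col = tricol[ord],
                    border = NA)
  invisible(path)
}

#' Write a per-vertex deviation field as CSV
#'
#' Columns: vertex index, coordinates (mm), value (mm) and missing flag.
#' @param field a [distance_field()].
#' @param mesh the basis [surface_mesh()].
#' @param path CSV output path.
#' @return The path, invisibly.
#' @export
write_field_csv <- function(field, mesh, path) {
  df <- data.frame(vertex_index = seq_along(field$values),
                   x_mm = mesh$vertices[, 1], y_mm = mesh$vertices[, 2],
                   z_mm = mesh$vertices[, 3],
                   value_mm = field$values,
                   missing = field$missing)
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}
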