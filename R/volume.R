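#' CBCT-like scalar volume
#'
#' A 3-D grid of Hounsfield-unit values with physical voxel spacing and
#' origin. The origin is the physical coordinate (mm) of the centre of
#' voxel `[1, 1, 1]`; the coordinate convention is right-handed with all
#' axes in mm.
#'
#' @param values 3-D numeric array of HU values.
#' @param spacing length-3 voxel spacing in mm (default isotropic 0.2 mm,
#'   the 200 micrometre voxel size typical of high-resolution dental CBCT).
#' @param origin length-3 physical coordinate of the first voxel centre, mm.
#' @return An object of class `voxel_volume`.
#' @export
voxel_volume <- function(values, spacing = c(0.2, 0.2, 0.2),
                         origin = c(0, 0, 0)) {
  values <- as.array(values)
  storage.mode(values) <- "double"
  spacing <- as.numeric(spacing)
  origin <- as.numeric(origin)
  if (length(dim(values)) != 3L) stop("values must be a 3-D array")
  if (any(dim(values) < 2L)) stop("grid must have at least 2 voxels per axis")
  if (length(spacing) != 3 || any(!is.finite(spacing)) || any(spacing <= 0))
    stop("spacing must be 3 positive finite values")
  if (length(origin) != 3 || any(!is.finite(origin)))
    stop("origin must be 3 finite values")
  if (!all(is.finite(values))) stop("all voxel values must be finite")
  structure(list(values = values, spacing = spacing, origin = origin),
            class = "voxel_volume")
}

#' @export
print.voxel_volume <- function(x, ...) {
  d <- dim(x$values)
  cat(sprintf("voxel_volume: %d x %d x %d voxels, spacing (%g, %g, %g) mm\n",
              d[1], d[2], d[3], x$spacing[1], x$spacing[2], x$spacing[3]))
  cat(sprintf("  HU range [%.1f, %.1f]\n", min(x$values), max(x$values)))
  invisible(x)
}

#' Binary voxel mask
#'
#' Same grid geometry as the [voxel_volume()] it derives from.
#' @param values 3-D logical array.
#' @param spacing,origin grid geometry, as in [voxel_volume()].
#' @return An object of class `binary_mask`.
#' @export
binary_mask <- function(values, spacing, origin) {
  values <- as.array(values)
  if (length(dim(values)) != 3L) stop("values must be a 3-D array")
  storage.mode(values) <- "logical"
  structure(list(values = values, spacing = as.numeric(spacing),
                 origin = as.numeric(origin)), class = "binary_mask")
}

#' @export
print.binary_mask <- function(x, ...) {
  d <- dim(x$values)
  cat(sprintf("binary_mask: %d x %d x %d voxels, %d foreground\n",
              d[1], d[2], d[3], sum(x$values)))
  invisible(x)
}

#' Write / read a volume as raw int16 plus a JSON header
#'
#' Single-file volume format: `<path>` holds the JSON header (dimensions,
#' spacing, origin, rescale slope/intercept, byte order) and
#' `<path>.raw` the voxel data as little-endian int16. Stored values
#' relate to HU exactly as in CT rescale semantics:
#' `HU = slope * stored + intercept`. The writer picks slope/intercept to
#' cover the value range; lossless whenever the dynamic range allows
#' (slope 1 for typical HU content).
#'
#' @param vol a [voxel_volume()].
#' @param path header file path (data written alongside as `<path>.raw`).
#' @return `write_volume` the path invisibly; `read_volume` the restored
#'   [voxel_volume()].
#' @export
write_volume <- function(vol, path) {
  rng <- range(vol$values)
  # integer-valued volumes within int16 range store losslessly with slope 1
  if (rng[1] >= -32000 && rng[2] <= 32000 &&
      max(abs(vol$values - round(vol$values))) < 1e-6) {
    slope <- 1; intercept <- 0
  } else {
    intercept <- rng[1]
    slope <- max((rng[2] - rng[1]) / 65000, 1e-12)
  }
  stored <- as.integer(round((vol$values - intercept) / slope))
  hdr <- list(format = "toothrep-volume-v1",
              dims = dim(vol$values),
              spacing_mm = vol$spacing,
              origin_mm = vol$origin,
              rescale_slope = slope,
              rescale_intercept = intercept,
              dtype = "int16", byte_order = "little")
  jsonlite::write_json(hdr, path, digits = NA, auto_unbox = FALSE)
  con <- file(paste0(path, ".raw"), "wb")
  on.exit(close(con))
  writeBin(stored, con, size = 2L, endian = "little")
  invisible(path)
}

#' @rdname write_volume
#' @export
read_volume <- function(path) {
  hdr <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (is.null(hdr$format) || hdr$format != "toothrep-volume-v1")
    stop("not a toothrep volume header: ", path)
  dims <- as.integer(hdr$dims)
  if (length(dims) != 3) stop("header dims must have length 3")
  if (any(!is.finite(hdr$spacing_mm)) || any(hdr$spacing_mm <= 0))
    stop("header has invalid spacing")
  raw_path <- paste0(path, ".raw")
  if (!file.exists(raw_path)) stop("missing voxel data file: ", raw_path)
  n <- prod(dims)
  con <- file(raw_path, "rb")
  on.exit(close(con))
  stored <- readBin(con, "integer", n = n, size = 2L, signed = TRUE,
                    endian = "little")
  if (length(stored) != n) stop("truncated voxel data in ", raw_path)
  vals <- as.double(hdr$rescale_slope) * as.double(stored) +
    as.double(hdr$rescale_intercept)
  voxel_volume(array(vals, dims), hdr$spacing_mm, hdr$origin_mm)
}

# physical coordinates of voxel centres along each axis
grid_axes <- function(obj) {
  d <- dim(obj$values)
  lapply(1:3, function(a) obj$origin[a] + (seq_len(d[a]) - 1) * obj$spacing[a])
}
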