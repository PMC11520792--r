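#' Read and write STL surface files
#'
#' `write_stl` emits binary little-endian STL with coordinates in mm.
#' `read_stl` accepts binary or ASCII STL; because STL stores an
#' unindexed triangle soup, reading welds duplicate vertices within
#' `tol` to recover shared topology. STL stores 32-bit floats, so a
#' write/read round trip preserves coordinates only to single precision.
#'
#' @param mesh a [surface_mesh()].
#' @param path file path.
#' @param tol weld tolerance on read, mm.
#' @return `write_stl` the path invisibly; `read_stl` a [surface_mesh()].
#' @export
write_stl <- function(mesh, path) {
  con <- file(path, "wb")
  on.exit(close(con))
  header <- charToRaw(sprintf("%-80s", "toothrep binary STL (mm)"))
  writeBin(header[1:80], con)
  nt <- nrow(mesh$triangles)
  writeBin(as.integer(nt), con, size = 4L, endian = "little")
  co <- tri_corners(mesh)
  n <- row_cross(co$b - co$a, co$c - co$a)
  len <- sqrt(rowSums(n^2))
  len[len == 0] <- 1
  n <- n / len
  # 12 floats + uint16 attribute per facet, assembled as one raw block
  block <- rbind(t(n), t(co$a), t(co$b), t(co$c))  # 12 x nt
  fraw <- writeBin(as.numeric(block), raw(), size = 4L, endian = "little")
  recs <- rbind(matrix(fraw, nrow = 48), matrix(as.raw(0), 2, nt))
  writeBin(as.vector(recs), con)
  invisible(path)
}

#' @rdname write_stl
#' @export
read_stl <- function(path, tol = 1e-6) {
  size <- file.info(path)$size
  if (is.na(size) || size < 15) stop("not a valid STL file: ", path)
  con <- file(path, "rb")
  on.exit(close(con))
  head5 <- readBin(con, "raw", n = 5)
  is_ascii <- identical(rawToChar(head5), "solid")
  if (is_ascii) {
    # could still be binary with a header starting "solid"; check size
    close(con)
    on.exit(NULL)
    txt <- readLines(path, warn = FALSE)
    if (!any(grepl("facet", txt))) is_ascii <- FALSE
    if (is_ascii) {
      vlines <- grep("^\\s*vertex\\s", txt, value = TRUE)
      if (length(vlines) == 0 || length(vlines) %% 3 != 0)
        stop("malformed ASCII STL: ", path)
      coords <- t(vapply(strsplit(trimws(vlines), "\\s+"),
                         function(x) as.numeric(x[2:4]), numeric(3)))
      if (!all(is.finite(coords))) stop("non-finite coordinates in ", path)
      nt <- nrow(coords) / 3
      soup <- surface_mesh(coords,
                           matrix(seq_len(3 * nt), ncol = 3, byrow = TRUE))
      return(weld_vertices(soup, tol))
    }
    con <- file(path, "rb")
    on.exit(close(con))
    readBin(con, "raw", n = 5)
  }
  readBin(con, "raw", n = 75)  # rest of 80-byte header
  nt <- readBin(con, "integer", n = 1, size = 4L, endian = "little")
  expected <- 84 + nt * 50
  if (nt < 1) stop("empty STL (0 triangles): ", path)
  if (size < expected) stop("truncated STL file: ", path)
  rec <- readBin(con, "raw", n = nt * 50)
  m <- matrix(rec, nrow = 50)
  floats <- readBin(as.vector(m[1:48, ]), "numeric", n = 12 * nt, size = 4L,
                    endian = "little")
  fm <- matrix(floats, nrow = 12)
  coords <- matrix(as.vector(fm[4:12, ]), ncol = 3, byrow = TRUE)
  if (!all(is.finite(coords))) stop("non-finite coordinates in ", path)
  soup <- surface_mesh(coords, matrix(seq_len(3 * nt), ncol = 3, byrow = TRUE))
  weld_vertices(soup, tol)
}

#' Write a mesh with per-vertex colours as ASCII PLY
#'
#' @param mesh a [surface_mesh()].
#' @param colors `n x 3` integer matrix of RGB values in 0..255, or NULL.
#' @param path file path.
#' @return The path, invisibly.
#' @export
write_ply <- function(mesh, path, colors = NULL) {
  nv <- nrow(mesh$vertices)
  nt <- nrow(mesh$triangles)
  con <- file(path, "w")
  on.exit(close(con))
  hdr <- c("ply", "format ascii 1.0",
           sprintf("element vertex %d", nv),
           "property float x", "property float y", "property float z")
  if (!is.null(colors)) {
    stopifnot(nrow(colors) == nv, ncol(colors) == 3)
    hdr <- c(hdr, "property uchar red", "property uchar green",
             "property uchar blue")
  }
  hdr <- c(hdr, sprintf("element face %d", nt),
           "property list uchar int vertex_indices", "end_header")
  writeLines(hdr, con)
  if (is.null(colors)) {
    writeLines(sprintf("%.6f %.6f %.6f", mesh$vertices[, 1],
                       mesh$vertices[, 2], mesh$vertices[, 3]), con)
  } else {
    writeLines(sprintf("%.6f %.6f %.6f %d %d %d", mesh$vertices[, 1],
                       mesh$vertices[, 2], mesh$vertices[, 3],
                       colors[, 1], colors[, 2], colors[, 3]), con)
  }
  writeLines(sprintf("3 %d %d %d", mesh$triangles[, 1] - 1L,
                     mesh$triangles[, 2] - 1L, mesh$triangles[, 3] - 1L), con)
  invisible(path)
}
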