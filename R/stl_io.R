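#' Read an STL file (binary or ASCII)
#'
#' The dialect is auto-detected: a file whose length equals
#' 84 + 50 x (facet count in the header) is parsed as binary, anything else
#' as an ASCII `solid`. STL stores each facet's corners independently, so
#' vertices within 1e-6 mm of each other are welded into shared vertices to
#' recover connectivity; the facet count is preserved (minus degenerate
#' facets dropped during validation).
#'
#' @param path path to an STL file.
#' @param merge_tol vertex welding tolerance in mm (default 1e-6).
#' @return a [triangle_mesh()].
#' @export
read_stl <- function(path, merge_tol = 1e-6) {
  sz <- file.size(path)
  if (is.na(sz)) stop(sprintf("cannot read '%s'", path))
  if (sz >= 84) {
    con <- file(path, "rb")
    hdr <- readBin(con, "raw", 80)
    n <- readBin(con, "integer", 1, size = 4, endian = "little")
    close(con)
    if (n >= 0 && sz == 84 + 50 * n) return(read_stl_binary(path, n, merge_tol))
    # a file that *looks* binary (non-text bytes) but has the wrong length
    txt_probe <- rawToChar(hdr[hdr != as.raw(0)])
    if (!grepl("^\\s*solid", txt_probe))
      stop(sprintf("truncated binary STL '%s': header declares %d facets (%d bytes), file has %d bytes",
                   path, n, 84 + 50 * n, sz))
  }
  read_stl_ascii(path, merge_tol)
}

read_stl_binary <- function(path, n, merge_tol) {
  r <- readBin(path, "raw", 84 + 50 * n)
  if (n == 0) stop(sprintf("binary STL '%s' declares zero facets", path))
  base <- 84 + (seq_len(n) - 1) * 50
  idx <- as.vector(outer(1:48, base, `+`))
  fl <- readBin(r[idx], "numeric", n = 12 * n, size = 4, endian = "little")
  m <- matrix(fl, ncol = 12, byrow = TRUE)
  tris <- m[, 4:12, drop = FALSE]  # v1 v2 v3; stored normals are recomputed
  weld_facets(tris, merge_tol)
}

read_stl_ascii <- function(path, merge_tol) {
  lines <- readLines(path, warn = FALSE)
  if (length(lines) == 0 || !grepl("^\\s*solid", lines[1]))
    stop(sprintf("malformed ASCII STL '%s': line 1 does not start with 'solid'", path))
  vidx <- grep("^\\s*vertex\\s", lines)
  if (length(vidx) == 0) stop(sprintf("malformed ASCII STL '%s': no vertex lines", path))
  if (length(vidx) %% 3 != 0)
    stop(sprintf("malformed ASCII STL '%s': %d vertex lines (not a multiple of 3); last at line %d",
                 path, length(vidx), vidx[length(vidx)]))
  toks <- strsplit(trimws(lines[vidx]), "\\s+")
  bad <- which(vapply(toks, length, 1L) != 4L)
  if (length(bad) > 0)
    stop(sprintf("malformed ASCII STL '%s': bad vertex at line %d", path, vidx[bad[1]]))
  coords <- suppressWarnings(
    t(vapply(toks, function(x) as.numeric(x[2:4]), numeric(3))))
  if (anyNA(coords)) {
    bad <- which(apply(is.na(coords), 1, any))[1]
    stop(sprintf("malformed ASCII STL '%s': non-numeric vertex at line %d", path, vidx[bad]))
  }
  nf <- length(vidx) / 3
  tris <- cbind(coords[seq(1, by = 3, length.out = nf), , drop = FALSE],
                coords[seq(2, by = 3, length.out = nf), , drop = FALSE],
                coords[seq(3, by = 3, length.out = nf), , drop = FALSE])
  weld_facets(tris, merge_tol)
}

# tris: nf x 9 matrix (v1 xyz, v2 xyz, v3 xyz); weld duplicates on a grid of
# pitch merge_tol (points within tolerance straddling a grid line may stay
# distinct; at 1e-6 mm this is far below sensor precision).
weld_facets <- function(tris, merge_tol) {
  nf <- nrow(tris)
  all_v <- rbind(tris[, 1:3, drop = FALSE], tris[, 4:6, drop = FALSE],
                 tris[, 7:9, drop = FALSE])
  g <- round(all_v / merge_tol)
  key <- paste(g[, 1], g[, 2], g[, 3])
  uid <- match(key, key[!duplicated(key)])
  verts <- all_v[!duplicated(key), , drop = FALSE]
  faces <- matrix(uid, ncol = 3)  # rows of all_v were stacked v1|v2|v3
  triangle_mesh(verts, faces)
}

#' Write a mesh as STL
#'
#' Output is bit-stable for a fixed input: the binary header is a fixed
#' string, facet normals are recomputed from the vertex winding, and the
#' two attribute bytes are written as zero (STL has no portable color; use
#' [write_ply()] for heatmaps).
#'
#' @param mesh a `triangle_mesh` with at least one face.
#' @param path output path.
#' @param dialect `"binary"` (default) or `"ascii"`.
#' @export
write_stl <- function(mesh, path, dialect = c("binary", "ascii")) {
  dialect <- match.arg(dialect)
  f <- mesh$faces
  if (nrow(f) == 0) stop("refusing to write an empty mesh (zero facets)")
  v <- mesh$vertices
  a <- v[f[, 1], , drop = FALSE]
  b <- v[f[, 2], , drop = FALSE]
  cc <- v[f[, 3], , drop = FALSE]
  nrm <- row_cross(b - a, cc - a)
  len <- row_norms(nrm)
  nrm <- nrm / ifelse(len > 1e-12, len, 1)
  if (dialect == "binary") {
    con <- file(path, "wb")
    on.exit(close(con))
    hdr <- charToRaw(sprintf("%-80s", "facedev binary STL"))[1:80]
    writeBin(hdr, con)
    writeBin(as.integer(nrow(f)), con, size = 4, endian = "little")
    block <- cbind(nrm, a, b, cc)       # nf x 12
    fr <- writeBin(as.numeric(t(block)), raw(), size = 4, endian = "little")
    body <- matrix(as.raw(0), 50, nrow(f))
    body[1:48, ] <- matrix(fr, 48, nrow(f))
    writeBin(as.vector(body), con)
  } else {
    fmt <- function(m) sprintf("%.9g %.9g %.9g", m[, 1], m[, 2], m[, 3])
    lines <- c("solid facedev",
               as.vector(rbind(paste("  facet normal", fmt(nrm)),
                               "    outer loop",
                               paste("      vertex", fmt(a)),
                               paste("      vertex", fmt(b)),
                               paste("      vertex", fmt(cc)),
                               "    endloop",
                               "  endfacet")),
               "endsolid facedev")
    writeLines(lines, path)
  }
  invisible(path)
}

#' Write a mesh as ASCII PLY with optional per-vertex quality and color
#'
#' Used for deviation heatmaps: `quality` carries the (capped) deviation in
#' mm, and `color` the white-to-red ramp, both readable by standard mesh
#' viewers.
#'
#' @param mesh a `triangle_mesh`.
#' @param path output path.
#' @param quality optional numeric per-vertex scalar.
#' @param color optional n x 3 integer matrix of RGB values in 0..255.
#' @export
write_ply <- function(mesh, path, quality = NULL, color = NULL) {
  v <- mesh$vertices
  f <- mesh$faces
  hdr <- c("ply", "format ascii 1.0", "comment facedev heatmap",
           sprintf("element vertex %d", nrow(v)),
           "property float x", "property float y", "property float z")
  cols <- sprintf("%.6f %.6f %.6f", v[, 1], v[, 2], v[, 3])
  if (!is.null(quality)) {
    hdr <- c(hdr, "property float quality")
    cols <- paste(cols, sprintf("%.6f", quality))
  }
  if (!is.null(color)) {
    hdr <- c(hdr, "property uchar red", "property uchar green", "property uchar blue")
    cols <- paste(cols, color[, 1], color[, 2], color[, 3])
  }
  hdr <- c(hdr, sprintf("element face %d", nrow(f)),
           "property list uchar int vertex_indices", "end_header")
  flines <- sprintf("3 %d %d %d", f[, 1] - 1L, f[, 2] - 1L, f[, 3] - 1L)
  writeLines(c(hdr, cols, flines), path)
  invisible(path)
}
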