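#' Construct a triangle mesh
#'
#' The basic surface container used throughout the package: a matrix of 3D
#' vertex coordinates in millimetres (right-handed frame) plus integer face
#' triplets. Facial shells are open surfaces, so boundary edges are allowed
#' and watertightness is never assumed. Degenerate (zero-area) faces are
#' dropped during validation with a message, since segmentation-derived
#' shells commonly contain slivers.
#'
#' @param vertices numeric matrix, n x 3, coordinates in mm.
#' @param faces integer matrix, m x 3, 1-based vertex indices.
#' @param scalar optional per-vertex numeric channel (e.g. a deviation), mm.
#' @param validate validate indices and drop degenerate faces (default TRUE).
#' @return an object of class `triangle_mesh` with elements `vertices`,
#'   `faces` and optionally `scalar`.
#' @export
triangle_mesh <- function(vertices, faces, scalar = NULL, validate = TRUE) {
  vertices <- as.matrix(vertices)
  faces <- matrix(as.integer(as.matrix(faces)), ncol = 3)
  storage.mode(vertices) <- "double"
  if (ncol(vertices) != 3L) stop("'vertices' must have 3 columns")
  if (!is.null(scalar) && length(scalar) != nrow(vertices))
    stop("'scalar' must have one value per vertex")
  m <- structure(list(vertices = vertices, faces = faces, scalar = scalar),
                 class = "triangle_mesh")
  if (validate) m <- validate_mesh(m)
  m
}

validate_mesh <- function(mesh) {
  v <- mesh$vertices
  f <- mesh$faces
  if (anyNA(v) || any(!is.finite(v))) stop("mesh has non-finite vertex coordinates")
  if (nrow(f) > 0) {
    if (min(f) < 1L || max(f) > nrow(v))
      stop("face indices out of range [1, n_vertices]")
    # degenerate: repeated indices or (numerically) zero area
    rep_idx <- f[, 1] == f[, 2] | f[, 2] == f[, 3] | f[, 1] == f[, 3]
    a <- v[f[, 1], , drop = FALSE]
    ar <- 0.5 * row_norms(row_cross(v[f[, 2], , drop = FALSE] - a,
                                    v[f[, 3], , drop = FALSE] - a))
    degen <- rep_idx | ar <= 1e-12
    if (any(degen)) {
      message(sprintf("dropping %d degenerate face(s)", sum(degen)))
      mesh$faces <- f[!degen, , drop = FALSE]
    }
  }
  mesh
}

#' @export
print.triangle_mesh <- function(x, ...) {
  cat(sprintf("triangle_mesh: %d vertices, %d faces%s\n",
              nrow(x$vertices), nrow(x$faces),
              if (!is.null(x$scalar)) ", with scalar channel" else ""))
  bb <- apply(x$vertices, 2, range)
  cat(sprintf("  bbox [%.1f, %.1f] x [%.1f, %.1f] x [%.1f, %.1f] mm\n",
              bb[1, 1], bb[2, 1], bb[1, 2], bb[2, 2], bb[1, 3], bb[2, 3]))
  invisible(x)
}

#' Boundary edges of an open mesh
#'
#' An edge is a boundary edge when exactly one face uses it. Facial shells
#' are open surfaces, so a nonempty result is the norm, not an error.
#'
#' @param mesh a `triangle_mesh`.
#' @return integer matrix, k x 2, vertex index pairs (sorted within row).
#' @export
boundary_edges <- function(mesh) {
  f <- mesh$faces
  if (nrow(f) == 0) return(matrix(integer(0), 0, 2))
  e <- rbind(f[, c(1, 2)], f[, c(2, 3)], f[, c(3, 1)])
  e <- cbind(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]))
  key <- paste(e[, 1], e[, 2])
  tab <- table(key)
  bkey <- names(tab)[tab == 1L]
  e[match(bkey, key), , drop = FALSE]
}

#' Area-weighted per-vertex normals
#'
#' Each vertex normal is the normalized sum of incident face cross products
#' (cross-product magnitude is twice the face area, so this is the usual
#' area weighting). Boundary vertices are handled like any other; isolated
#' vertices receive a zero vector, which callers must treat as "no normal".
#'
#' @param mesh a `triangle_mesh`.
#' @return numeric matrix, n x 3, unit normals (rows of zeros for isolated
#'   vertices).
#' @export
vertex_normals <- function(mesh) {
  v <- mesh$vertices
  f <- mesh$faces
  n <- matrix(0, nrow(v), 3)
  if (nrow(f) == 0) return(n)
  a <- v[f[, 1], , drop = FALSE]
  fn <- row_cross(v[f[, 2], , drop = FALSE] - a, v[f[, 3], , drop = FALSE] - a)
  idx <- c(f[, 1], f[, 2], f[, 3])
  agg <- rowsum(rbind(fn, fn, fn), idx)
  n[as.integer(rownames(agg)), ] <- agg
  len <- row_norms(n)
  ok <- len > 1e-12
  n[ok, ] <- n[ok, , drop = FALSE] / len[ok]
  n[!ok, ] <- 0
  n
}

# Build (and cache on the mesh environment) the C++ BVH index for a mesh.
tri_index <- function(mesh) {
  tri_index_build(mesh$vertices, mesh$faces)
}

#' Closest point on a mesh surface
#'
#' Globally minimal point-to-triangle distance from each query point to the
#' target surface, computed through a bounding-volume hierarchy. The
#' `on_boundary` flag marks results whose closest point lies on a boundary
#' edge (or boundary vertex) of the open target surface; downstream stages
#' use it to reject non-overlap correspondences.
#'
#' @param query numeric vector of length 3 or an n x 3 matrix of query points.
#' @param target a `triangle_mesh` with at least one face, or a prebuilt
#'   index from the internal builder.
#' @param index optional prebuilt spatial index (external pointer) for
#'   repeated queries against the same target.
#' @param boundary optional precomputed [boundary_edges()] matrix.
#' @param method `"bvh"` (default) or `"brute"` (exhaustive per-triangle
#'   minimization in R; the independent reference path used by tests).
#' @return data.frame with columns `distance` (mm), `px`,`py`,`pz` (closest
#'   surface point), `face` (1-based face index) and `on_boundary`.
#' @export
closest_point <- function(query, target, index = NULL, boundary = NULL,
                          method = c("bvh", "brute")) {
  method <- match.arg(method)
  if (is.null(dim(query))) query <- matrix(query, ncol = 3)
  query <- as.matrix(query)
  storage.mode(query) <- "double"
  if (nrow(target$faces) < 1) stop("target mesh has no faces")
  if (method == "bvh") {
    if (is.null(index)) index <- tri_index(target)
    res <- tri_index_query(index, query)
  } else {
    res <- closest_point_brute_impl(query, target)
  }
  if (is.null(boundary)) boundary <- boundary_edges(target)
  onb <- on_boundary_flags(target, res$face, res$bary, boundary)
  data.frame(distance = res$distance,
             px = res$point[, 1], py = res$point[, 2], pz = res$point[, 3],
             face = res$face, on_boundary = onb)
}

# Did the closest point land on a boundary edge/vertex of its face?
# bary[i, j] ~ 0 means the point lies on the edge opposite face vertex j.
on_boundary_flags <- function(mesh, face, bary, bedges, tol = 1e-9) {
  if (nrow(bedges) == 0) return(rep(FALSE, length(face)))
  bkey <- paste(bedges[, 1], bedges[, 2])
  f <- mesh$faces[face, , drop = FALSE]
  onb <- rep(FALSE, length(face))
  # edge opposite corner j is (j+1, j+2)
  opp <- list(c(2L, 3L), c(3L, 1L), c(1L, 2L))
  for (j in 1:3) {
    onedge <- abs(bary[, j]) <= tol
    if (!any(onedge)) next
    e1 <- f[, opp[[j]][1]]
    e2 <- f[, opp[[j]][2]]
    key <- paste(pmin(e1, e2), pmax(e1, e2))
    onb <- onb | (onedge & key %in% bkey)
  }
  # corner case: point exactly at a vertex shared only with boundary edges is
  # already covered (two barycentric coords are ~0, both incident edges test).
  onb
}

# Exhaustive reference implementation: vectorized Ericson closest point over
# all triangles for each query. Used as the oracle path in tests.
closest_point_brute_impl <- function(query, mesh) {
  v <- mesh$vertices
  f <- mesh$faces
  A <- v[f[, 1], , drop = FALSE]
  B <- v[f[, 2], , drop = FALSE]
  C <- v[f[, 3], , drop = FALSE]
  nq <- nrow(query)
  dist <- numeric(nq)
  pts <- matrix(0, nq, 3)
  fid <- integer(nq)
  bar <- matrix(0, nq, 3)
  for (i in seq_len(nq)) {
    r <- point_triangle_all(query[i, ], A, B, C)
    j <- which.min(r$d2)
    dist[i] <- sqrt(r$d2[j])
    pts[i, ] <- r$pt[j, ]
    fid[i] <- j
    bar[i, ] <- r$bary[j, ]
  }
  list(distance = dist, point = pts, face = fid, bary = bar)
}

# Closest point on every triangle (A,B,C rows) to a single point p.
# Ericson's region tests, applied as vectorized masks in reverse chain order
# so that the first-true condition wins, exactly as in the scalar algorithm.
point_triangle_all <- function(p, A, B, C) {
  n <- nrow(A)
  P <- matrix(p, n, 3, byrow = TRUE)
  ab <- B - A; ac <- C - A
  ap <- P - A; bp <- P - B; cp <- P - C
  d1 <- rowSums(ab * ap); d2 <- rowSums(ac * ap)
  d3 <- rowSums(ab * bp); d4 <- rowSums(ac * bp)
  d5 <- rowSums(ab * cp); d6 <- rowSums(ac * cp)
  vc <- d1 * d4 - d3 * d2
  vb <- d5 * d2 - d1 * d6
  va <- d3 * d6 - d5 * d4

  # interior (fallback)
  denom <- va + vb + vc
  v <- vb / denom; w <- vc / denom
  pt <- A + ab * v + ac * w
  bary <- cbind(1 - v - w, v, w)

  set <- function(mask, ptm, barym) {
    if (any(mask)) {
      pt[mask, ] <<- ptm[mask, , drop = FALSE]
      bary[mask, ] <<- barym[mask, , drop = FALSE]
    }
  }
  # reverse chain order: later set() calls override, so the scalar chain's
  # earliest satisfied condition ends up winning.
  mBC <- va <= 0 & (d4 - d3) >= 0 & (d5 - d6) >= 0
  wBC <- (d4 - d3) / ((d4 - d3) + (d5 - d6))
  set(mBC, B + (C - B) * wBC, cbind(0, 1 - wBC, wBC))
  mAC <- vb <= 0 & d2 >= 0 & d6 <= 0
  wAC <- d2 / (d2 - d6)
  set(mAC, A + ac * wAC, cbind(1 - wAC, 0, wAC))
  mC <- d6 >= 0 & d5 <= d6
  set(mC, C, matrix(c(0, 0, 1), n, 3, byrow = TRUE))
  mAB <- vc <= 0 & d1 >= 0 & d3 <= 0
  vAB <- d1 / (d1 - d3)
  set(mAB, A + ab * vAB, cbind(1 - vAB, vAB, 0))
  mB <- d3 >= 0 & d4 <= d3
  set(mB, B, matrix(c(0, 1, 0), n, 3, byrow = TRUE))
  mA <- d1 <= 0 & d2 <= 0
  set(mA, A, matrix(c(1, 0, 0), n, 3, byrow = TRUE))

  dd <- P - pt
  list(d2 = rowSums(dd * dd), pt = pt, bary = bary)
}
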