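# Absolute surface-deviation mapping. Sign (inside/outside) is deliberately
# discarded: the analysis works with the absolute distance between the two
# aligned surfaces, displayed with a 3 mm cap. The raw (uncapped) distance
# is retained for classification — a capped value could never distinguish
# 3.1 mm from 30 mm, and the clinical interval scale is open-ended above
# 3 mm. Measurement direction is scan vertices -> shell surface: the scan
# is the lower-resolution mesh, so sampling it guarantees coverage.

#' Per-vertex absolute deviation of a scan from a reference shell
#'
#' For each scan vertex, the distance to the closest point on the shell
#' surface. Vertices whose closest point lies on the shell's boundary, or
#' whose distance exceeds `max_valid`, are marked invalid: they indicate
#' non-overlap (e.g. crop artifacts at the shell border), not a true
#' soft-tissue deviation.
#'
#' @param scan_aligned the scan mesh, already registered onto the shell.
#' @param shell the reference shell mesh (>= 1 face).
#' @param cap display cap in mm (default 3, the clinical-relevance
#'   threshold); affects `display` only, never `raw`.
#' @param max_valid distances above this (mm) are marked invalid
#'   (default 10 — far above any plausible soft-tissue difference).
#' @return object of class `deviation_field`: `raw`, `display`
#'   (= `min(raw, cap)`, NA when invalid), `valid`, `cap`, `max_valid`.
#' @export
absolute_deviation <- function(scan_aligned, shell, cap = 3, max_valid = 10) {
  if (nrow(shell$faces) < 1) stop("shell mesh is empty")
  if (cap <= 0) stop("cap must be positive")
  cp <- closest_point(scan_aligned$vertices, shell)
  valid <- !cp$on_boundary & cp$distance <= max_valid
  structure(list(raw = cp$distance,
                 display = ifelse(valid, pmin(cp$distance, cap), NA_real_),
                 valid = valid, cap = cap, max_valid = max_valid),
            class = "deviation_field")
}

#' @export
print.deviation_field <- function(x, ...) {
  cat(sprintf("deviation_field: %d vertices (%d valid), cap %.1f mm\n",
              length(x$raw), sum(x$valid), x$cap))
  if (any(x$valid))
    cat(sprintf("  raw deviation: median %.3f, p95 %.3f, max %.3f mm\n",
                median(x$raw[x$valid]),
                quantile(x$raw[x$valid], 0.95, names = FALSE),
                max(x$raw[x$valid])))
  invisible(x)
}

#' Export a deviation heatmap as PLY and CSV
#'
#' Writes `<path>.ply` — the scan mesh with per-vertex `quality` equal to
#' the capped display value and RGB colors on a linear white-to-red ramp
#' over `[0, cap]` (invalid vertices gray, quality -1) — and `<path>.csv`
#' with one row per scan vertex: `vertex_id`, `raw`, `display`, `valid`.
#'
#' @param field a [absolute_deviation()] result computed on `scan_aligned`.
#' @param scan_aligned the mesh the field refers to.
#' @param path output path prefix (without extension).
#' @return invisibly, the two file paths.
#' @export
export_heatmap <- function(field, scan_aligned, path) {
  if (length(field$raw) != nrow(scan_aligned$vertices))
    stop("field and mesh vertex counts differ")
  t01 <- pmin(field$display / field$cap, 1)
  gb <- as.integer(round(255 * (1 - t01)))
  col <- cbind(255L, gb, gb)
  col[!field$valid, ] <- 128L
  q <- ifelse(field$valid, field$display, -1)
  ply <- paste0(path, ".ply")
  csv <- paste0(path, ".csv")
  write_ply(scan_aligned, ply, quality = q, color = col)
  write.csv(data.frame(vertex_id = seq_along(field$raw), raw = field$raw,
                       display = field$display, valid = field$valid),
            csv, row.names = FALSE)
  invisible(c(ply = ply, csv = csv))
}

#' Planar cross-section of a mesh as ordered polylines
#'
#' Intersects the mesh with a plane (default: the median/sagittal plane
#' x = 0) and chains the resulting segments into polylines ordered by arc
#' length. Used to cross-check heatmaps against profile sections.
#'
#' @param mesh a `triangle_mesh`.
#' @param plane_point,plane_normal point on the plane and its normal.
#' @return list of polylines (k x 3 matrices, ordered along the curve);
#'   empty list with a warning when the plane misses the mesh.
#' @export
profile_section <- function(mesh, plane_point = c(0, 0, 0),
                            plane_normal = c(1, 0, 0)) {
  v <- mesh$vertices
  nrm <- plane_normal / sqrt(sum(plane_normal^2))
  s <- as.numeric((v - matrix(plane_point, nrow(v), 3, byrow = TRUE)) %*% nrm)
  s[s == 0] <- 1e-12  # nudge exact hits off the plane
  f <- mesh$faces
  sa <- s[f[, 1]]; sb <- s[f[, 2]]; sc <- s[f[, 3]]
  crosses <- function(u, w) u * w < 0
  segs <- list()
  edge_pt <- function(i1, i2, rows) {
    t <- s[i1[rows]] / (s[i1[rows]] - s[i2[rows]])
    v[i1[rows], , drop = FALSE] +
      (v[i2[rows], , drop = FALSE] - v[i1[rows], , drop = FALSE]) * t
  }
  cab <- crosses(sa, sb); cbc <- crosses(sb, sc); cca <- crosses(sc, sa)
  hit <- cab | cbc | cca
  if (!any(hit)) {
    warning("plane does not intersect the mesh")
    return(list())
  }
  p1 <- matrix(NA_real_, sum(hit), 3)
  p2 <- matrix(NA_real_, sum(hit), 3)
  hrows <- which(hit)
  fill <- function(mask12) which(mask12[hrows])
  # each intersected triangle has exactly two crossing edges
  got <- integer(sum(hit))
  put <- function(pts, rows_local) {
    first <- got[rows_local] == 0L
    p1[rows_local[first], ] <<- pts[first, , drop = FALSE]
    p2[rows_local[!first], ] <<- pts[!first, , drop = FALSE]
    got[rows_local] <<- got[rows_local] + 1L
  }
  rl <- fill(cab); if (length(rl)) put(edge_pt(f[, 1], f[, 2], hrows[rl]), rl)
  rl <- fill(cbc); if (length(rl)) put(edge_pt(f[, 2], f[, 3], hrows[rl]), rl)
  rl <- fill(cca); if (length(rl)) put(edge_pt(f[, 3], f[, 1], hrows[rl]), rl)

  # chain segments into polylines via endpoint keys
  key <- function(p) paste(round(p[, 1], 6), round(p[, 2], 6), round(p[, 3], 6))
  k1 <- key(p1); k2 <- key(p2)
  allk <- unique(c(k1, k2))
  allp <- rbind(p1, p2)[match(allk, c(k1, k2)), , drop = FALSE]
  a <- match(k1, allk); bnd <- match(k2, allk)
  adj <- vector("list", length(allk))
  for (i in seq_along(a)) {
    adj[[a[i]]] <- c(adj[[a[i]]], bnd[i])
    adj[[bnd[i]]] <- c(adj[[bnd[i]]], a[i])
  }
  visited <- rep(FALSE, length(allk))
  polylines <- list()
  walk <- function(start) {
    path <- start
    visited[start] <<- TRUE
    cur <- start
    repeat {
      nxt <- adj[[cur]][!visited[adj[[cur]]]]
      if (length(nxt) == 0) break
      cur <- nxt[1]
      visited[cur] <<- TRUE
      path <- c(path, cur)
    }
    path
  }
  deg <- lengths(adj)
  for (start in order(deg)) {  # open chains (degree 1) first, then cycles
    if (visited[start]) next
    path <- walk(start)
    if (length(path) >= 2)
      polylines[[length(polylines) + 1]] <- allp[path, , drop = FALSE]
  }
  polylines
}
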