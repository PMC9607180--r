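# Geometric fixtures built in code.

# Unit tetrahedron: 4 vertices, 4 faces.
unit_tetrahedron <- function() {
  v <- rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0), c(0, 0, 1))
  f <- rbind(c(1, 3, 2), c(1, 2, 4), c(1, 4, 3), c(2, 3, 4))
  triangle_mesh(v, f)
}

# Square planar patch in z = 0, n x n grid over [0, size]^2.
planar_patch <- function(n = 5, size = 10) {
  g <- expand.grid(x = seq(0, size, length.out = n),
                   y = seq(0, size, length.out = n))
  idx <- matrix(seq_len(n * n), n, n)
  i <- rep(seq_len(n - 1), n - 1)
  j <- rep(seq_len(n - 1), each = n - 1)
  f <- rbind(cbind(idx[cbind(i, j)], idx[cbind(i + 1, j)], idx[cbind(i + 1, j + 1)]),
             cbind(idx[cbind(i, j)], idx[cbind(i + 1, j + 1)], idx[cbind(i, j + 1)]))
  triangle_mesh(cbind(g$x, g$y, 0), f)
}

# Icosphere: subdivided icosahedron projected onto a sphere of given radius.
# level 2 gives 1280 faces.
icosphere <- function(level = 2, radius = 1) {
  phi <- (1 + sqrt(5)) / 2
  v <- rbind(
    c(-1, phi, 0), c(1, phi, 0), c(-1, -phi, 0), c(1, -phi, 0),
    c(0, -1, phi), c(0, 1, phi), c(0, -1, -phi), c(0, 1, -phi),
    c(phi, 0, -1), c(phi, 0, 1), c(-phi, 0, -1), c(-phi, 0, 1))
  v <- v / sqrt(rowSums(v^2))
  f <- rbind(
    c(1, 12, 6), c(1, 6, 2), c(1, 2, 8), c(1, 8, 11), c(1, 11, 12),
    c(2, 6, 10), c(6, 12, 5), c(12, 11, 3), c(11, 8, 7), c(8, 2, 9),
    c(4, 10, 5), c(4, 5, 3), c(4, 3, 7), c(4, 7, 9), c(4, 9, 10),
    c(5, 10, 6), c(3, 5, 12), c(7, 3, 11), c(9, 7, 8), c(10, 9, 2))
  for (lev in seq_len(level)) {
    mid <- new.env()
    key <- function(a, b) paste(min(a, b), max(a, b))
    get_mid <- function(a, b) {
      k <- key(a, b)
      if (!is.null(mid[[k]])) return(mid[[k]])
      p <- (v[a, ] + v[b, ]) / 2
      p <- p / sqrt(sum(p^2))
      v <<- rbind(v, p)
      mid[[k]] <- nrow(v)
      nrow(v)
    }
    nf <- matrix(0L, 0, 3)
    for (i in seq_len(nrow(f))) {
      a <- f[i, 1]; b <- f[i, 2]; cc <- f[i, 3]
      ab <- get_mid(a, b); bc <- get_mid(b, cc); ca <- get_mid(cc, a)
      nf <- rbind(nf, c(a, ab, ca), c(b, bc, ab), c(cc, ca, bc), c(ab, bc, ca))
    }
    f <- nf
  }
  triangle_mesh(v * radius, f)
}

# Random triangle soup with nf faces inside a cube of the given size.
random_soup <- function(nf, size = 10) {
  repeat {
    v <- matrix(runif(9 * nf, 0, size), ncol = 3)
    f <- matrix(seq_len(3 * nf), ncol = 3)
    m <- suppressMessages(triangle_mesh(v, f))
    if (nrow(m$faces) == nf) return(m)
  }
}

# A small random rigid transform.
random_transform <- function(max_deg = 180, max_mm = 20) {
  rt_from_angles(runif(3, -max_deg, max_deg), runif(3, -max_mm, max_mm))
}

row_norms_test <- function(m) sqrt(rowSums(m * m))

expect_rt_equal <- function(a, b, tol = 1e-9) {
  expect_lt(max(abs(a$rotation - b$rotation)), tol)
  expect_lt(max(abs(a$translation - b$translation)), tol)
}
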