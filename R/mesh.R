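#' Graded triangular mesh around 2-D points
#'
#' Builds the finite-element triangulation on which the Matern field is
#' solved. The domain has two zones, because boundary conditions distort the
#' field near the triangulation edge and the distortion must be pushed away
#' from the data: an *inner* rectangle — the data bounding box dilated by
#' `inner_offset_frac` of the data range — is meshed finely, and an annulus
#' out to the *outer* rectangle (dilated by `outer_offset_frac`) is meshed
#' with geometrically coarsening rings. The mesh is a conforming
#' tensor-product triangulation: grid lines are placed along each axis
#' (uniform inside the inner rectangle, growing by a factor 1.5 per ring
#' outside, capped at `max_edge_outer`), every grid cell is split into two
#' counter-clockwise triangles, and vertices are ordered lexicographically,
#' so construction is fully deterministic.
#'
#' By default `max_edge_inner` is chosen so the number of inner vertices is
#' at least the number of data points — the density rule that keeps the
#' piecewise-linear field approximation comparable to the information in
#' the data. Every data point lies strictly inside the inner boundary by
#' construction; a warning is issued for points within one edge length of
#' it, since points hugged too tightly by the boundary are exactly the ones
#' the boundary distortion can affect (isolated extreme outliers deserve
#' investigation before estimation).
#'
#' @param points `n x 2` matrix of (projected, standardized) coordinates.
#' @param inner_offset_frac dilation of the data bounding box forming the
#'   inner boundary, as a fraction of the data range (> 0).
#' @param outer_offset_frac dilation forming the outer boundary
#'   (> `inner_offset_frac`).
#' @param max_edge_inner grid spacing inside the inner rectangle; default
#'   chosen so inner vertices >= `n`.
#' @param max_edge_outer cap on the annulus grid spacing; default
#'   `3 * max_edge_inner`.
#' @return An object of class `evppi_mesh`: `vertices` (V x 2), `triangles`
#'   (M x 3, counter-clockwise), `inner_boundary` / `outer_boundary` vertex
#'   index rings, and the generating grid lines.
#' @export
build_mesh <- function(points, inner_offset_frac = 0.10,
                       outer_offset_frac = 0.35,
                       max_edge_inner = NULL, max_edge_outer = NULL) {
  pts <- as.matrix(points)
  stopifnot(ncol(pts) == 2, all(is.finite(pts)))
  n <- nrow(pts)
  if (n < 3) stop("need at least 3 points to build a mesh")
  if (inner_offset_frac <= 0 || outer_offset_frac <= inner_offset_frac) {
    stop("need 0 < inner_offset_frac < outer_offset_frac")
  }
  rx <- range(pts[, 1]); ry <- range(pts[, 2])
  span <- c(diff(rx), diff(ry))
  span[span == 0] <- max(span, 1)          # degenerate (collinear) direction
  inner <- list(x = rx + c(-1, 1) * inner_offset_frac * span[1],
                y = ry + c(-1, 1) * inner_offset_frac * span[2])
  outer <- list(x = rx + c(-1, 1) * outer_offset_frac * span[1],
                y = ry + c(-1, 1) * outer_offset_frac * span[2])
  if (is.null(max_edge_inner)) {
    area_in <- diff(inner$x) * diff(inner$y)
    max_edge_inner <- min(sqrt(area_in / max(n, 16)),
                          min(diff(inner$x), diff(inner$y)) / 8)
  }
  if (is.null(max_edge_outer)) max_edge_outer <- 3 * max_edge_inner

  grid_lines <- function(lo_in, hi_in, lo_out, hi_out) {
    k <- max(2L, ceiling((hi_in - lo_in) / max_edge_inner) + 1L)
    core <- seq(lo_in, hi_in, length.out = k)
    step <- core[2] - core[1]
    grow <- function(from, bound, dir) {
      out <- numeric(0); x <- from; s <- step
      while (dir * (bound - x) > 1e-12 * max(1, abs(bound))) {
        s <- min(s * 1.5, max_edge_outer)
        x <- if (dir * (bound - x) <= s) bound else x + dir * s
        out <- c(out, x)
      }
      out
    }
    c(rev(grow(lo_in, lo_out, -1)), core, grow(hi_in, hi_out, 1))
  }
  xl <- grid_lines(inner$x[1], inner$x[2], outer$x[1], outer$x[2])
  yl <- grid_lines(inner$y[1], inner$y[2], outer$y[1], outer$y[2])
  nx <- length(xl); ny <- length(yl)
  verts <- cbind(x = rep(xl, times = ny), y = rep(yl, each = nx))
  idx <- function(i, j) (j - 1L) * nx + i
  i <- rep(seq_len(nx - 1), times = ny - 1)
  j <- rep(seq_len(ny - 1), each = nx - 1)
  v00 <- idx(i, j); v10 <- idx(i + 1L, j)
  v01 <- idx(i, j + 1L); v11 <- idx(i + 1L, j + 1L)
  tris <- rbind(cbind(v00, v10, v11), cbind(v00, v11, v01))
  colnames(tris) <- c("v1", "v2", "v3")

  on_ring <- function(lines_x, lines_y) {
    ix <- which(abs(xl - lines_x[1]) < 1e-12 | abs(xl - lines_x[2]) < 1e-12)
    iy <- which(abs(yl - lines_y[1]) < 1e-12 | abs(yl - lines_y[2]) < 1e-12)
    xr <- which(xl >= lines_x[1] - 1e-12 & xl <= lines_x[2] + 1e-12)
    yr <- which(yl >= lines_y[1] - 1e-12 & yl <= lines_y[2] + 1e-12)
    ring <- union(idx(rep(ix, each = length(yr)), rep(yr, times = length(ix))),
                  idx(rep(xr, times = length(iy)), rep(iy, each = length(xr))))
    sort(ring)
  }
  inner_ring <- on_ring(inner$x, inner$y)
  outer_ring <- on_ring(outer$x, outer$y)

  mesh <- structure(
    list(vertices = verts, triangles = tris,
         inner_boundary = inner_ring, outer_boundary = outer_ring,
         xlines = xl, ylines = yl, inner_rect = inner, outer_rect = outer,
         max_edge_inner = max_edge_inner, max_edge_outer = max_edge_outer,
         n_data = n),
    class = "evppi_mesh"
  )
  near <- pts[, 1] < inner$x[1] + max_edge_inner | pts[, 1] > inner$x[2] - max_edge_inner |
    pts[, 2] < inner$y[1] + max_edge_inner | pts[, 2] > inner$y[2] - max_edge_inner
  if (any(near)) {
    warning(sum(near), " point(s) within one edge length of the inner boundary; ",
            "check for outliers")
  }
  mesh
}

#' @export
print.evppi_mesh <- function(x, ...) {
  cat(sprintf("<evppi_mesh> %d vertices, %d triangles (inner spacing %.3g, outer cap %.3g)\n",
              nrow(x$vertices), nrow(x$triangles), x$max_edge_inner, x$max_edge_outer))
  invisible(x)
}

#' Barycentric projector matrix
#'
#' The sparse `n x V` matrix mapping vertex weights to field values at the
#' data points: row `i` holds the barycentric coordinates of point `i`
#' inside its containing triangle (at most three non-zeros, summing to 1).
#' Point location is exact on the tensor-product mesh (grid-cell lookup plus
#' a diagonal test).
#'
#' @param mesh an [build_mesh()] mesh.
#' @param points `n x 2` coordinates; every point must lie inside the mesh.
#' @return A sparse `dgCMatrix`.
#' @export
projector <- function(mesh, points) {
  pts <- as.matrix(points)
  xl <- mesh$xlines; yl <- mesh$ylines
  nx <- length(xl)
  outside <- pts[, 1] < xl[1] - 1e-9 | pts[, 1] > xl[nx] + 1e-9 |
    pts[, 2] < yl[1] - 1e-9 | pts[, 2] > yl[length(yl)] + 1e-9
  if (any(outside)) {
    stop("point(s) outside the mesh: rows ",
         paste(utils::head(which(outside), 5), collapse = ", "))
  }
  i <- pmin(pmax(findInterval(pts[, 1], xl, rightmost.closed = TRUE), 1L), nx - 1L)
  j <- pmin(pmax(findInterval(pts[, 2], yl, rightmost.closed = TRUE), 1L), length(yl) - 1L)
  u <- (pts[, 1] - xl[i]) / (xl[i + 1L] - xl[i])
  v <- (pts[, 2] - yl[j]) / (yl[j + 1L] - yl[j])
  idx <- function(i, j) (j - 1L) * nx + i
  lower <- u >= v   # cell diagonal from (i,j) to (i+1,j+1)
  n <- nrow(pts)
  rows <- rep(seq_len(n), 3)
  cols <- integer(3 * n); w <- numeric(3 * n)
  # lower triangle (v00, v10, v11): weights (1-u, u-v, v)
  lo <- which(lower)
  cols[lo] <- idx(i, j)[lower]; w[lo] <- (1 - u)[lower]
  cols[n + lo] <- idx(i + 1L, j)[lower]; w[n + lo] <- (u - v)[lower]
  cols[2 * n + lo] <- idx(i + 1L, j + 1L)[lower]; w[2 * n + lo] <- v[lower]
  # upper triangle (v00, v11, v01): weights (1-v, u, v-u)
  up <- which(!lower)
  cols[up] <- idx(i, j)[!lower]; w[up] <- (1 - v)[!lower]
  cols[n + up] <- idx(i + 1L, j + 1L)[!lower]; w[n + up] <- u[!lower]
  cols[2 * n + up] <- idx(i, j + 1L)[!lower]; w[2 * n + up] <- (v - u)[!lower]
  Matrix::sparseMatrix(i = rows, j = cols, x = w,
                       dims = c(n, nrow(mesh$vertices)))
}
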