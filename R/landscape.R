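## Interpolated connectivity landscape over the 2-D embedding: exact
## barycentric interpolation on triangles of nearby cells inside the convex
## hull (least-squares plane fallback, also exact for linear fields),
## nearest-neighbour fill outside.

.point_in_hull <- function(px, py, hx, hy, tol = 1e-9) {
  n <- length(hx)
  sgn <- 0
  for (i in seq_len(n)) {
    j <- if (i == n) 1L else i + 1L
    cr <- (hx[j] - hx[i]) * (py - hy[i]) - (hy[j] - hy[i]) * (px - hx[i])
    if (abs(cr) <= tol) next
    s <- sign(cr)
    if (sgn == 0) sgn <- s else if (s != sgn) return(FALSE)
  }
  TRUE
}

#' Interpolate cell-connectivity scores onto a regular grid
#'
#' Builds a `grid_resolution x grid_resolution` grid over the embedding's
#' bounding box (5% margin). Grid points inside the convex hull are
#' interpolated linearly: exact barycentric interpolation on a containing
#' triangle formed from the point's `k_neighbors` nearest cells, with a
#' least-squares plane over those neighbours as fallback (both reproduce a
#' linear field exactly). Points outside the hull take the nearest cell's
#' score. A grid point coinciding with a cell returns that cell's score.
#' If all cells are collinear the whole grid falls back to
#' nearest-neighbour with a warning.
#'
#' @param embedding Cells x 2 coordinate matrix.
#' @param cell_conn Per-cell connectivity scores.
#' @param grid_resolution Grid points per axis (default 100).
#' @param margin Bounding-box margin fraction (default 0.05).
#' @param k_neighbors Neighbourhood size for triangulation (default 15).
#' @return List with `x`, `y` (axis vectors) and `z`
#'   (resolution x resolution matrix, rows indexed by x); suitable for
#'   `contour()` / `persp()`. `as.data.frame` of the `grid` element gives a
#'   long x/y/z table.
#' @export
connectivity_landscape <- function(embedding, cell_conn,
                                   grid_resolution = 100, margin = 0.05,
                                   k_neighbors = 15) {
  pts <- as.matrix(embedding)
  n <- nrow(pts)
  if (n < 3) stop("need at least 3 cells")
  if (length(cell_conn) != n) stop("cell_conn length must match embedding")
  rx <- range(pts[, 1]); ry <- range(pts[, 2])
  mx <- margin * max(diff(rx), .Machine$double.eps)
  my <- margin * max(diff(ry), .Machine$double.eps)
  gx <- seq(rx[1] - mx, rx[2] + mx, length.out = grid_resolution)
  gy <- seq(ry[1] - my, ry[2] + my, length.out = grid_resolution)

  ctr <- sweep(pts, 2, colMeans(pts))
  collinear <- (svd(ctr, nu = 0, nv = 0)$d[2] < 1e-9 * max(svd(ctr, nu = 0,
                                                               nv = 0)$d[1],
                                                           1))
  hull <- grDevices::chull(pts)
  hx <- pts[hull, 1]; hy <- pts[hull, 2]
  if (collinear)
    warning("all cells are collinear; using nearest-neighbour fill everywhere")

  kn <- min(k_neighbors, n)
  tri_idx <- if (kn >= 3) combn(kn, 3) else NULL
  z <- matrix(NA_real_, grid_resolution, grid_resolution)
  for (ix in seq_len(grid_resolution)) {
    px <- gx[ix]
    dx2 <- (pts[, 1] - px)^2
    for (iy in seq_len(grid_resolution)) {
      py <- gy[iy]
      d2 <- dx2 + (pts[, 2] - py)^2
      nn <- which.min(d2)
      if (d2[nn] < 1e-18) { z[ix, iy] <- cell_conn[nn]; next }
      if (collinear || !.point_in_hull(px, py, hx, hy)) {
        z[ix, iy] <- cell_conn[nn]
        next
      }
      nb <- order(d2)[seq_len(kn)]
      val <- NA_real_
      if (!is.null(tri_idx)) {
        ax <- pts[nb, 1]; ay <- pts[nb, 2]
        x1 <- ax[tri_idx[1, ]]; y1 <- ay[tri_idx[1, ]]
        x2 <- ax[tri_idx[2, ]]; y2 <- ay[tri_idx[2, ]]
        x3 <- ax[tri_idx[3, ]]; y3 <- ay[tri_idx[3, ]]
        det <- (y2 - y3) * (x1 - x3) + (x3 - x2) * (y1 - y3)
        l1 <- ((y2 - y3) * (px - x3) + (x3 - x2) * (py - y3)) / det
        l2 <- ((y3 - y1) * (px - x3) + (x1 - x3) * (py - y3)) / det
        l3 <- 1 - l1 - l2
        ok <- which(abs(det) > 1e-12 & l1 >= -1e-9 & l2 >= -1e-9 &
                      l3 >= -1e-9)
        if (length(ok)) {
          tr <- ok[1]
          v <- cell_conn[nb[tri_idx[, tr]]]
          val <- l1[tr] * v[1] + l2[tr] * v[2] + l3[tr] * v[3]
        }
      }
      if (is.na(val)) {
        ## least-squares plane through the neighbourhood
        A <- cbind(1, pts[nb, , drop = FALSE])
        fit <- tryCatch(qr.solve(A, cell_conn[nb]), error = function(e) NULL)
        val <- if (is.null(fit)) cell_conn[nn] else
          drop(c(1, px, py) %*% fit)
      }
      z[ix, iy] <- val
    }
  }
  grid <- data.frame(x = rep(gx, times = grid_resolution),
                     y = rep(gy, each = grid_resolution),
                     z = as.vector(z))
  list(x = gx, y = gy, z = z, grid = grid)
}
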