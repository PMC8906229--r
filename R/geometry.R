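# Planar polygon primitives for contour analysis.
# Vertices are n x 2 matrices in mm, implicitly closed, any orientation.

#' Signed polygon area (shoelace)
#'
#' @param xy n x 2 vertex matrix, implicitly closed.
#' @return Signed area in mm^2 (positive for counter-clockwise).
#' @keywords internal
poly_signed_area <- function(xy) {
  n <- nrow(xy)
  if (n < 3L) return(0)
  x <- xy[, 1L]; y <- xy[, 2L]
  xn <- c(x[-1L], x[1L]); yn <- c(y[-1L], y[1L])
  sum(x * yn - xn * y) / 2
}

#' Even-odd point-in-polygon test (ray casting)
#' @keywords internal
point_in_polygon <- function(px, py, xy) {
  n <- nrow(xy)
  x <- xy[, 1L]; y <- xy[, 2L]
  xn <- c(x[-1L], x[1L]); yn <- c(y[-1L], y[1L])
  crosses <- ((y > py) != (yn > py))
  if (!any(crosses)) return(FALSE)
  xi <- x[crosses] + (py - y[crosses]) / (yn[crosses] - y[crosses]) * (xn[crosses] - x[crosses])
  sum(xi > px) %% 2L == 1L
}

#' Check a polygon for self-intersection
#'
#' Vectorized O(n^2) proper-crossing test over all non-adjacent edge pairs
#' (shared endpoints of adjacent edges do not count as crossings).
#' @keywords internal
poly_self_intersects <- function(xy) {
  n <- nrow(xy)
  if (n < 4L) return(FALSE)
  ax <- xy[, 1L]; ay <- xy[, 2L]
  bx <- c(ax[-1L], ax[1L]); by <- c(ay[-1L], ay[1L])
  ex <- bx - ax; ey <- by - ay
  # M1[i, j] = orientation of edge i's line vs start point of edge j;
  # M2[i, j] = same vs end point of edge j
  M1 <- outer(ex, ay) - outer(ey, ax) - (ex * ay - ey * ax)
  M2 <- outer(ex, by) - outer(ey, bx) - (ex * ay - ey * ax)
  cross <- (M1 * M2 < 0) & (t(M1) * t(M2) < 0)
  idx <- seq_len(n)
  adj <- abs(outer(idx, idx, "-"))
  cross[adj <= 1L | adj == n - 1L] <- FALSE
  any(cross)
}

#' Net area of one slice's polygons with hole subtraction
#'
#' Polygons fully contained inside an odd number of other polygons on the
#' same slice are treated as holes (standard structure-set semantics:
#' even-odd nesting).
#'
#' @param polys List of n x 2 vertex matrices sharing one z.
#' @return Net area in mm^2 (never negative).
#' @keywords internal
slice_net_area <- function(polys) {
  k <- length(polys)
  if (k == 0L) return(0)
  areas <- vapply(polys, function(p) abs(poly_signed_area(p)), numeric(1))
  if (k == 1L) return(areas)
  depth <- vapply(seq_len(k), function(i) {
    p <- polys[[i]][1L, ]
    sum(vapply(seq_len(k)[-i], function(j) {
      point_in_polygon(p[1L], p[2L], polys[[j]])
    }, logical(1)))
  }, numeric(1))
  max(0, sum(areas * ifelse(depth %% 2 == 0, 1, -1)))
}

#' Regular polygon vertices
#' @keywords internal
regular_polygon <- function(cx, cy, r, n = 72L) {
  th <- 2 * pi * (seq_len(n) - 1L) / n
  cbind(cx + r * cos(th), cy + r * sin(th))
}
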