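# Low-level planar polygon utilities. Polygons are n x 2 matrices of vertices
# in mm; the closing edge (last -> first vertex) is implicit. A structure on a
# slice may consist of several rings interpreted with the even-odd rule, so a
# ring contained in another ring is a hole.

#' Signed area of a polygon ring (shoelace formula)
#'
#' Positive for counter-clockwise vertex order.
#'
#' @param poly numeric matrix with columns x, y (mm); closing edge implicit.
#' @return signed area in mm^2.
#' @export
polygon_area <- function(poly) {
  x <- poly[, 1]; y <- poly[, 2]
  xs <- c(x[-1], x[1]); ys <- c(y[-1], y[1])
  sum(x * ys - xs * y) / 2
}

#' Area of a set of even-odd rings
#'
#' Rings contained in an odd number of other rings count as holes.
#'
#' @param rings list of polygon matrices on one slice.
#' @return enclosed area in mm^2.
#' @export
rings_area <- function(rings) {
  if (length(rings) == 0) return(0)
  depth <- ring_depths(rings)
  sum(vapply(seq_along(rings), function(i) {
    abs(polygon_area(rings[[i]])) * if (depth[i] %% 2 == 0) 1 else -1
  }, numeric(1)))
}

# containment depth of each ring: number of other rings containing its first
# vertex (rings are assumed disjoint or nested, never crossing)
ring_depths <- function(rings) {
  vapply(seq_along(rings), function(i) {
    p <- rings[[i]][1, , drop = FALSE]
    sum(vapply(seq_along(rings), function(j) {
      j != i && point_in_ring(rings[[j]], p)
    }, logical(1)))
  }, integer(1))
}

point_in_ring <- function(poly, p) {
  as.logical(mgcv::in.out(rbind(poly, poly[1, ]), matrix(p, ncol = 2)))
}

#' Even-odd point membership for a multi-ring region
#'
#' @param rings list of polygon matrices (even-odd rule).
#' @param pts m x 2 matrix of query points.
#' @return logical vector of length m.
#' @export
points_in_rings <- function(rings, pts) {
  if (length(rings) == 0 || nrow(pts) == 0) return(rep(FALSE, nrow(pts)))
  bnd <- do.call(rbind, lapply(rings, function(r) rbind(r, r[1, ], c(NA, NA))))
  bnd <- bnd[-nrow(bnd), , drop = FALSE]
  as.logical(mgcv::in.out(bnd, pts))
}

#' Regular polygon approximation of a circle
#'
#' @param cx,cy centre (mm).
#' @param r radius (mm).
#' @param n number of vertices.
#' @return n x 2 vertex matrix (counter-clockwise).
#' @export
circle_poly <- function(cx, cy, r, n = 90) {
  th <- seq(0, 2 * pi, length.out = n + 1)[-(n + 1)]
  cbind(cx + r * cos(th), cy + r * sin(th))
}

#' Ellipse polygon
#' @param cx,cy centre (mm).
#' @param a,b half-axes along x and y (mm).
#' @param n number of vertices.
#' @export
ellipse_poly <- function(cx, cy, a, b, n = 120) {
  th <- seq(0, 2 * pi, length.out = n + 1)[-(n + 1)]
  cbind(cx + a * cos(th), cy + b * sin(th))
}

#' Horseshoe (annular sector) polygon
#'
#' An annulus with inner radius `r_in` and outer radius `r_out` from which a
#' wedge of `opening_deg` degrees centred on `opening_dir_deg` is removed,
#' leaving a simply connected ring that nearly encloses the centre.
#'
#' @param cx,cy centre (mm).
#' @param r_in,r_out inner and outer radii (mm).
#' @param opening_deg angular width of the removed wedge (degrees).
#' @param opening_dir_deg direction of the wedge centre (degrees; 270 = -y).
#' @param n vertices per arc.
#' @export
horseshoe_poly <- function(cx, cy, r_in, r_out, opening_deg = 60,
                           opening_dir_deg = 270, n = 120) {
  stopifnot(r_in > 0, r_out > r_in, opening_deg >= 0, opening_deg < 360)
  a0 <- (opening_dir_deg + opening_deg / 2) * pi / 180
  a1 <- (opening_dir_deg + 360 - opening_deg / 2) * pi / 180
  th <- seq(a0, a1, length.out = n)
  outer <- cbind(cx + r_out * cos(th), cy + r_out * sin(th))
  inner <- cbind(cx + r_in * cos(rev(th)), cy + r_in * sin(rev(th)))
  rbind(outer, inner)
}

# densify a ring boundary so consecutive points are <= step apart
densify_ring <- function(poly, step = 0.5) {
  closed <- rbind(poly, poly[1, ])
  out <- vector("list", nrow(poly))
  for (i in seq_len(nrow(poly))) {
    a <- closed[i, ]; b <- closed[i + 1, ]
    len <- sqrt(sum((b - a)^2))
    k <- max(1L, ceiling(len / step))
    t <- seq(0, 1, length.out = k + 1)[-(k + 1)]
    out[[i]] <- cbind(a[1] + t * (b[1] - a[1]), a[2] + t * (b[2] - a[2]))
  }
  do.call(rbind, out)
}

#' Signed boundary gap between two ring sets
#'
#' Minimum edge-to-edge distance between the boundaries of two even-odd
#' regions on a slice. When boundary points of `rings_a` lie inside `rings_b`
#' (or vice versa) the regions interpenetrate and the gap is reported as the
#' negative of the deepest penetration, so the caller can decide how to treat
#' an organ bulging into the target.
#'
#' @param rings_a,rings_b lists of polygon matrices.
#' @param step boundary densification step (mm).
#' @return signed gap in mm.
#' @export
boundary_gap <- function(rings_a, rings_b, step = 0.5) {
  pa <- do.call(rbind, lapply(rings_a, densify_ring, step = step))
  pb <- do.call(rbind, lapply(rings_b, densify_ring, step = step))
  d2 <- outer(pa[, 1], pb[, 1], "-")^2 + outer(pa[, 2], pb[, 2], "-")^2
  gap <- sqrt(min(d2))
  a_in_b <- points_in_rings(rings_b, pa)
  b_in_a <- points_in_rings(rings_a, pb)
  if (any(a_in_b) || any(b_in_a)) {
    depth <- 0
    if (any(a_in_b)) depth <- max(depth, sqrt(min_dist2_to_set(pa[a_in_b, , drop = FALSE], pb)))
    if (any(b_in_a)) depth <- max(depth, sqrt(min_dist2_to_set(pb[b_in_a, , drop = FALSE], pa)))
    return(-depth)
  }
  gap
}

# for each point in pts, squared distance to nearest point of set; returns max
min_dist2_to_set <- function(pts, set) {
  d2 <- outer(pts[, 1], set[, 1], "-")^2 + outer(pts[, 2], set[, 2], "-")^2
  max(apply(d2, 1, min))
}

# TRUE if the ring has any pair of properly crossing edges
ring_self_intersects <- function(poly) {
  n <- nrow(poly)
  if (n < 4) return(FALSE)
  cl <- rbind(poly, poly[1, ])
  for (i in seq_len(n - 2)) {
    jmax <- if (i == 1) n - 1 else n
    js <- seq(i + 2, jmax)
    if (length(js) == 0) next
    if (any(vapply(js, function(j) {
      segments_cross(cl[i, ], cl[i + 1, ], cl[j, ], cl[j + 1, ])
    }, logical(1)))) return(TRUE)
  }
  FALSE
}

segments_cross <- function(p1, p2, p3, p4) {
  d <- function(a, b, c) (b[1] - a[1]) * (c[2] - a[2]) - (b[2] - a[2]) * (c[1] - a[1])
  d1 <- d(p3, p4, p1); d2 <- d(p3, p4, p2); d3 <- d(p1, p2, p3); d4 <- d(p1, p2, p4)
  (d1 * d2 < 0) && (d3 * d4 < 0)
}
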