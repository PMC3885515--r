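#' @title Planar geometry primitives
#' @description
#' Lightweight planar geometry types used throughout fencescape. All
#' coordinates are planar meters in a single projected CRS. A `gs_line` is a
#' list of parts, each an n x 2 coordinate matrix; a `gs_poly` is a list of
#' parts, each a list of closed rings (first exterior, rest holes). These mirror
#' GeoJSON `MultiLineString` / `MultiPolygon` nesting so conversion is direct.
#' @name geom
#' @keywords internal
NULL

as_coord_matrix <- function(x) {
  if (is.matrix(x)) {
    storage.mode(x) <- "double"
    return(x[, 1:2, drop = FALSE])
  }
  m <- do.call(rbind, lapply(x, function(p) as.numeric(p[1:2])))
  m
}

#' Construct a polyline geometry
#'
#' @param ... one or more n x 2 coordinate matrices (or a single list of them),
#'   one per part.
#' @return object of class `gs_line`.
#' @export
gs_line <- function(...) {
  parts <- list(...)
  if (length(parts) == 1 && is.list(parts[[1]]) && !is.matrix(parts[[1]])) {
    parts <- parts[[1]]
  }
  parts <- lapply(parts, as_coord_matrix)
  structure(list(parts = parts), class = "gs_line")
}

#' Construct a polygon geometry
#'
#' @param ... rings (n x 2 closed matrices) forming one part: first exterior,
#'   rest holes. For multipolygons pass a list of parts, each a list of rings.
#' @param parts optional pre-built list of parts.
#' @return object of class `gs_poly`.
#' @export
gs_poly <- function(..., parts = NULL) {
  if (is.null(parts)) {
    rings <- list(...)
    if (length(rings) == 1 && is.list(rings[[1]]) && !is.matrix(rings[[1]]) &&
        is.list(rings[[1]][[1]]) && !is.matrix(rings[[1]][[1]])) {
      parts <- rings[[1]]
    } else if (length(rings) == 1 && is.list(rings[[1]]) && !is.matrix(rings[[1]])) {
      parts <- list(rings[[1]])
    } else {
      parts <- list(rings)
    }
  }
  parts <- lapply(parts, function(p) lapply(p, close_ring))
  structure(list(parts = parts), class = "gs_poly")
}

close_ring <- function(r) {
  r <- as_coord_matrix(r)
  n <- nrow(r)
  if (n < 3) stop("ring needs at least 3 vertices")
  if (!isTRUE(all.equal(r[1, ], r[n, ], tolerance = 1e-12))) r <- rbind(r, r[1, ])
  r
}

#' Axis-aligned rectangle polygon
#' @param xmin,ymin,xmax,ymax corners in meters.
#' @export
gs_rect <- function(xmin, ymin, xmax, ymax) {
  gs_poly(rbind(
    c(xmin, ymin), c(xmax, ymin), c(xmax, ymax), c(xmin, ymax), c(xmin, ymin)
  ))
}

is_gs_line <- function(x) inherits(x, "gs_line")
is_gs_poly <- function(x) inherits(x, "gs_poly")

#' Total length of a polyline geometry in meters
#' @param g a `gs_line`.
#' @export
gs_length <- function(g) {
  stopifnot(is_gs_line(g))
  sum(vapply(g$parts, part_length, numeric(1)))
}

part_length <- function(m) {
  if (nrow(m) < 2) return(0)
  d <- diff(m)
  sum(sqrt(d[, 1]^2 + d[, 2]^2))
}

ring_area_signed <- function(r) {
  n <- nrow(r)
  x <- r[, 1]; y <- r[, 2]
  sum(x[-n] * y[-1] - x[-1] * y[-n]) / 2
}

#' Planar area of a polygon geometry in square meters
#'
#' Shoelace sum over parts; holes subtract regardless of ring orientation.
#' @param g a `gs_poly`.
#' @export
gs_area <- function(g) {
  stopifnot(is_gs_poly(g))
  tot <- 0
  for (p in g$parts) {
    tot <- tot + abs(ring_area_signed(p[[1]]))
    if (length(p) > 1) {
      for (h in p[-1]) tot <- tot - abs(ring_area_signed(h))
    }
  }
  tot
}

#' Perimeter (boundary length) of a polygon geometry in meters
#' @param g a `gs_poly`.
#' @export
gs_perimeter <- function(g) {
  stopifnot(is_gs_poly(g))
  sum(unlist(lapply(g$parts, function(p) vapply(p, part_length, numeric(1)))))
}

#' Bounding box of a geometry
#' @param g geometry.
#' @return numeric `c(xmin, ymin, xmax, ymax)`.
#' @export
gs_bbox <- function(g) {
  m <- gs_coords(g)
  c(min(m[, 1]), min(m[, 2]), max(m[, 1]), max(m[, 2]))
}

gs_coords <- function(g) {
  if (is_gs_line(g)) return(do.call(rbind, g$parts))
  if (is_gs_poly(g)) return(do.call(rbind, unlist(g$parts, recursive = FALSE)))
  if (is.numeric(g)) return(matrix(g[1:2], 1))
  stop("unknown geometry")
}

#' Extract all line segments of a geometry
#' @param g a `gs_line` or `gs_poly` (rings are treated as closed lines).
#' @return matrix with columns x1, y1, x2, y2 (0-row matrix when degenerate).
#' @export
gs_segments <- function(g) {
  mats <- if (is_gs_line(g)) g$parts else unlist(g$parts, recursive = FALSE)
  segs <- lapply(mats, function(m) {
    if (nrow(m) < 2) return(NULL)
    cbind(m[-nrow(m), 1], m[-nrow(m), 2], m[-1, 1], m[-1, 2])
  })
  out <- do.call(rbind, segs)
  if (is.null(out)) out <- matrix(numeric(0), 0, 4)
  colnames(out) <- c("x1", "y1", "x2", "y2")
  out
}

#' Even-odd point-in-polygon test
#'
#' @param x,y point coordinates (vectors allowed).
#' @param g a `gs_poly`. Points on the boundary count as inside.
#' @return logical vector.
#' @export
gs_point_in_poly <- function(x, y, g) {
  stopifnot(is_gs_poly(g))
  inside <- rep(FALSE, length(x))
  for (p in g$parts) {
    in_part <- point_in_ring(x, y, p[[1]])
    if (length(p) > 1) {
      for (h in p[-1]) {
        # boundary of a hole still counts as inside the polygon
        on_h <- point_on_ring(x, y, h)
        in_part <- in_part & (!point_in_ring(x, y, h, strict = TRUE) | on_h)
      }
    }
    inside <- inside | in_part
  }
  inside
}

point_in_ring <- function(px, py, r, strict = FALSE) {
  n <- nrow(r) - 1
  xs <- r[, 1]; ys <- r[, 2]
  res <- logical(length(px))
  for (k in seq_along(px)) {
    x <- px[k]; y <- py[k]
    cross <- FALSE
    on_edge <- FALSE
    j <- n
    for (i in seq_len(n)) {
      xi <- xs[i]; yi <- ys[i]; xj <- xs[j]; yj <- ys[j]
      # edge containment check
      if (point_on_seg(x, y, xi, yi, xj, yj)) { on_edge <- TRUE; break }
      if ((yi > y) != (yj > y)) {
        xint <- (xj - xi) * (y - yi) / (yj - yi) + xi
        if (x < xint) cross <- !cross
      }
      j <- i
    }
    res[k] <- if (on_edge) !strict else cross
  }
  res
}

point_on_ring <- function(px, py, r) {
  n <- nrow(r) - 1
  res <- logical(length(px))
  for (k in seq_along(px)) {
    for (i in seq_len(n)) {
      if (point_on_seg(px[k], py[k], r[i, 1], r[i, 2], r[i + 1, 1], r[i + 1, 2])) {
        res[k] <- TRUE; break
      }
    }
  }
  res
}

point_on_seg <- function(x, y, x1, y1, x2, y2, tol = 1e-9) {
  cross <- (x2 - x1) * (y - y1) - (y2 - y1) * (x - x1)
  if (abs(cross) > tol * (abs(x2 - x1) + abs(y2 - y1) + 1)) return(FALSE)
  dot <- (x - x1) * (x2 - x1) + (y - y1) * (y2 - y1)
  len2 <- (x2 - x1)^2 + (y2 - y1)^2
  dot >= -tol && dot <= len2 + tol
}

#' Distance from points to a set of segments
#'
#' @param px,py point coordinate vectors.
#' @param segs segment matrix as returned by [gs_segments()].
#' @return numeric vector of minimum distances (Inf when `segs` empty).
#' @export
gs_dist_points_segments <- function(px, py, segs) {
  np <- length(px)
  if (nrow(segs) == 0) return(rep(Inf, np))
  dx <- segs[, 3] - segs[, 1]
  dy <- segs[, 4] - segs[, 2]
  len2 <- dx^2 + dy^2
  len2[len2 == 0] <- 1e-300
  out <- numeric(np)
  for (k in seq_len(np)) {
    t <- ((px[k] - segs[, 1]) * dx + (py[k] - segs[, 2]) * dy) / len2
    t <- pmin(1, pmax(0, t))
    qx <- segs[, 1] + t * dx
    qy <- segs[, 2] + t * dy
    out[k] <- sqrt(min((px[k] - qx)^2 + (py[k] - qy)^2))
  }
  out
}

#' Segment-segment intersection points
#'
#' Returns proper crossing and endpoint-touch intersection points between two
#' segment sets. Collinear overlaps contribute their overlap endpoints.
#'
#' @param a,b segment matrices (columns x1,y1,x2,y2).
#' @param tol snap tolerance in meters.
#' @return two-column matrix of intersection points (possibly 0 rows).
#' @export
gs_segment_intersections <- function(a, b, tol = 1e-9) {
  pts <- list()
  if (nrow(a) == 0 || nrow(b) == 0) return(matrix(numeric(0), 0, 2))
  for (i in seq_len(nrow(a))) {
    p <- a[i, 1:2]; r <- a[i, 3:4] - p
    # bbox prefilter
    axmin <- min(a[i, 1], a[i, 3]) - tol; axmax <- max(a[i, 1], a[i, 3]) + tol
    aymin <- min(a[i, 2], a[i, 4]) - tol; aymax <- max(a[i, 2], a[i, 4]) + tol
    cand <- which(pmin(b[, 1], b[, 3]) <= axmax & pmax(b[, 1], b[, 3]) >= axmin &
                  pmin(b[, 2], b[, 4]) <= aymax & pmax(b[, 2], b[, 4]) >= aymin)
    for (j in cand) {
      q <- b[j, 1:2]; s <- b[j, 3:4] - q
      rxs <- r[1] * s[2] - r[2] * s[1]
      qp <- q - p
      qpxr <- qp[1] * r[2] - qp[2] * r[1]
      if (abs(rxs) < tol) {
        if (abs(qpxr) < tol * (sqrt(sum(r^2)) + 1)) {
          # collinear: overlap endpoints
          rr <- sum(r^2)
          if (rr > 0) {
            t0 <- sum(qp * r) / rr
            t1 <- t0 + sum(s * r) / rr
            lo <- max(0, min(t0, t1)); hi <- min(1, max(t0, t1))
            if (hi >= lo - tol) {
              pts[[length(pts) + 1]] <- rbind(p + lo * r, p + hi * r)
            }
          }
        }
      } else {
        t <- (qp[1] * s[2] - qp[2] * s[1]) / rxs
        u <- qpxr / rxs
        if (t >= -tol && t <= 1 + tol && u >= -tol && u <= 1 + tol) {
          pts[[length(pts) + 1]] <- matrix(p + t * r, 1)
        }
      }
    }
  }
  if (!length(pts)) return(matrix(numeric(0), 0, 2))
  m <- do.call(rbind, pts)
  m[!duplicated(round(m / 1e-6) * 1e-6), , drop = FALSE]
}

#' Touching feature pairs in a list of polylines
#'
#' Vectorized all-pairs segment intersection test (crossings, endpoint
#' touches and collinear overlaps all count as touching).
#'
#' @param geoms list of `gs_line`.
#' @param tol snap tolerance in meters.
#' @return two-column matrix of touching feature index pairs (i < j).
#' @export
feature_touch_pairs <- function(geoms, tol = 1e-6) {
  segs <- lapply(geoms, gs_segments)
  ns <- vapply(segs, nrow, integer(1))
  S <- do.call(rbind, segs)
  fid <- rep(seq_along(geoms), ns)
  m <- nrow(S)
  if (m < 2) return(matrix(integer(0), 0, 2))
  idx <- which(upper.tri(matrix(TRUE, m, m)), arr.ind = TRUE)
  a <- idx[, 1]; b <- idx[, 2]
  keep <- fid[a] != fid[b]
  a <- a[keep]; b <- b[keep]
  # bbox prefilter
  ok <- pmin(S[a, 1], S[a, 3]) <= pmax(S[b, 1], S[b, 3]) + tol &
        pmin(S[b, 1], S[b, 3]) <= pmax(S[a, 1], S[a, 3]) + tol &
        pmin(S[a, 2], S[a, 4]) <= pmax(S[b, 2], S[b, 4]) + tol &
        pmin(S[b, 2], S[b, 4]) <= pmax(S[a, 2], S[a, 4]) + tol
  a <- a[ok]; b <- b[ok]
  if (!length(a)) return(matrix(integer(0), 0, 2))
  rx <- S[a, 3] - S[a, 1]; ry <- S[a, 4] - S[a, 2]
  sx <- S[b, 3] - S[b, 1]; sy <- S[b, 4] - S[b, 2]
  qpx <- S[b, 1] - S[a, 1]; qpy <- S[b, 2] - S[a, 2]
  rxs <- rx * sy - ry * sx
  qpxr <- qpx * ry - qpy * rx
  qpxs <- qpx * sy - qpy * sx
  hit <- logical(length(a))
  gen <- abs(rxs) > tol
  t <- qpxs[gen] / rxs[gen]
  u <- qpxr[gen] / rxs[gen]
  hit[gen] <- t >= -tol & t <= 1 + tol & u >= -tol & u <= 1 + tol
  col <- !gen & abs(qpxr) <= tol * (sqrt(rx^2 + ry^2) + 1)
  if (any(col)) {
    rr <- rx[col]^2 + ry[col]^2
    rr[rr == 0] <- 1e-300
    t0 <- (qpx[col] * rx[col] + qpy[col] * ry[col]) / rr
    t1 <- t0 + (sx[col] * rx[col] + sy[col] * ry[col]) / rr
    hit[col] <- pmax(pmin(t0, t1), 0) <= pmin(pmax(t0, t1), 1) + tol
  }
  pairs <- unique(cbind(pmin(fid[a[hit]], fid[b[hit]]),
                        pmax(fid[a[hit]], fid[b[hit]])))
  pairs
}

#' Do two polyline geometries touch or cross?
#' @param ga,gb `gs_line` geometries.
#' @param tol snap tolerance in meters.
#' @export
gs_lines_touch <- function(ga, gb, tol = 1e-6) {
  ba <- gs_bbox(ga); bb <- gs_bbox(gb)
  if (ba[1] > bb[3] + tol || bb[1] > ba[3] + tol ||
      ba[2] > bb[4] + tol || bb[2] > ba[4] + tol) return(FALSE)
  nrow(gs_segment_intersections(gs_segments(ga), gs_segments(gb), tol)) > 0
}

# --- linear referencing on single-part polylines -----------------------------

line_cumlen <- function(m) {
  d <- diff(m)
  c(0, cumsum(sqrt(d[, 1]^2 + d[, 2]^2)))
}

#' Point at distance along a polyline
#' @param g single-part `gs_line`.
#' @param d distance in meters (clamped to `[0, length]`).
#' @return numeric `c(x, y)`.
#' @export
gs_line_interpolate <- function(g, d) {
  m <- g$parts[[1]]
  cl <- line_cumlen(m)
  d <- min(max(d, 0), cl[length(cl)])
  i <- findInterval(d, cl, rightmost.closed = TRUE)
  i <- min(i, nrow(m) - 1)
  seg <- cl[i + 1] - cl[i]
  t <- if (seg > 0) (d - cl[i]) / seg else 0
  m[i, ] + t * (m[i + 1, ] - m[i, ])
}

#' Sub-line between two distances along a polyline
#' @param g single-part `gs_line`.
#' @param d0,d1 distances in meters, `d0 < d1` (clamped).
#' @export
gs_line_substring <- function(g, d0, d1) {
  m <- g$parts[[1]]
  cl <- line_cumlen(m)
  L <- cl[length(cl)]
  d0 <- min(max(d0, 0), L); d1 <- min(max(d1, 0), L)
  if (d1 <= d0) stop("empty substring")
  p0 <- gs_line_interpolate(g, d0)
  p1 <- gs_line_interpolate(g, d1)
  mid <- m[cl > d0 & cl < d1, , drop = FALSE]
  gs_line(rbind(p0, mid, p1))
}

#' Evenly spaced points along a polyline
#'
#' Points at `step` spacing from the start, always including both endpoints'
#' stations (0 and the total length).
#' @param g single-part `gs_line`.
#' @param step spacing in meters.
#' @return matrix of x, y, station (distance along line).
#' @export
gs_line_densify <- function(g, step) {
  L <- gs_length(g)
  st <- unique(c(seq(0, L, by = step), L))
  xy <- t(vapply(st, function(d) gs_line_interpolate(g, d), numeric(2)))
  cbind(xy, station = st)
}

#' Project points onto a polyline
#' @param g single-part `gs_line`.
#' @param px,py point coordinates.
#' @return matrix with columns `station` (distance along) and `dist`
#'   (perpendicular offset distance).
#' @export
gs_line_project <- function(g, px, py) {
  m <- g$parts[[1]]
  cl <- line_cumlen(m)
  segs <- cbind(m[-nrow(m), , drop = FALSE], m[-1, , drop = FALSE])
  dx <- segs[, 3] - segs[, 1]; dy <- segs[, 4] - segs[, 2]
  len2 <- pmax(dx^2 + dy^2, 1e-300)
  out <- matrix(0, length(px), 2, dimnames = list(NULL, c("station", "dist")))
  for (k in seq_along(px)) {
    t <- ((px[k] - segs[, 1]) * dx + (py[k] - segs[, 2]) * dy) / len2
    t <- pmin(1, pmax(0, t))
    qx <- segs[, 1] + t * dx; qy <- segs[, 2] + t * dy
    d2 <- (px[k] - qx)^2 + (py[k] - qy)^2
    i <- which.min(d2)
    out[k, ] <- c(cl[i] + t[i] * sqrt(len2[i]), sqrt(d2[i]))
  }
  out
}

#' Length of segments clipped to a disk
#'
#' Closed-form circle clipping, the kernel of the line-density estimator.
#' @param segs segment matrix (x1,y1,x2,y2).
#' @param cx,cy disk center.
#' @param r disk radius in meters.
#' @return total clipped length in meters.
#' @export
gs_seg_length_in_circle <- function(segs, cx, cy, r) {
  if (nrow(segs) == 0) return(0)
  x1 <- segs[, 1] - cx; y1 <- segs[, 2] - cy
  dx <- segs[, 3] - segs[, 1]; dy <- segs[, 4] - segs[, 2]
  a <- dx^2 + dy^2
  b <- 2 * (x1 * dx + y1 * dy)
  cc <- x1^2 + y1^2 - r^2
  disc <- b^2 - 4 * a * cc
  keep <- disc > 0 & a > 0
  if (!any(keep)) return(0)
  sq <- sqrt(disc[keep])
  t0 <- pmax(0, (-b[keep] - sq) / (2 * a[keep]))
  t1 <- pmin(1, (-b[keep] + sq) / (2 * a[keep]))
  dt <- pmax(0, t1 - t0)
  sum(dt * sqrt(a[keep]))
}

#' @export
print.gs_line <- function(x, ...) {
  cat(sprintf("<gs_line: %d part(s), length %.1f m>\n", length(x$parts), gs_length(x)))
  invisible(x)
}

#' @export
print.gs_poly <- function(x, ...) {
  cat(sprintf("<gs_poly: %d part(s), area %.1f m^2>\n", length(x$parts), gs_area(x)))
  invisible(x)
}
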