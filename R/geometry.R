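# Planar geometry primitives for cell-map analysis: polygon area, even-odd
# point-in-polygon with on-boundary points counted inside, polyline
# projections, ray casting, and convex clipping. All coordinates in um.

#' Signed polygon area (shoelace formula)
#'
#' @param poly n x 2 matrix of vertices (closed implicitly).
#' @return Signed area in the coordinate units squared; positive for
#'   counter-clockwise orientation.
#' @export
polygon_area <- function(poly) {
  poly <- as.matrix(poly)
  x <- poly[, 1]; y <- poly[, 2]
  xn <- c(x[-1], x[1]); yn <- c(y[-1], y[1])
  sum(x * yn - xn * y) / 2
}

polygon_centroid <- function(poly) {
  poly <- as.matrix(poly)
  x <- poly[, 1]; y <- poly[, 2]
  xn <- c(x[-1], x[1]); yn <- c(y[-1], y[1])
  cr <- x * yn - xn * y
  a <- sum(cr) / 2
  if (abs(a) < .Machine$double.eps)
    abort2("degenerate polygon (area ~ 0)", "audiogain_bad_geometry")
  c(sum((x + xn) * cr), sum((y + yn) * cr)) / (6 * a)
}

#' Even-odd point-in-polygon test
#'
#' Vectorized ray-casting with the even-odd rule; points lying on the
#' boundary (within `eps` of an edge) are counted as inside, which makes the
#' counting rule deterministic for cells straddling the region outline.
#'
#' @param px,py point coordinates.
#' @param poly n x 2 polygon vertex matrix.
#' @param eps boundary tolerance in coordinate units.
#' @return Logical vector.
#' @export
point_in_polygon <- function(px, py, poly, eps = 1e-9) {
  poly <- as.matrix(poly)
  n <- nrow(poly)
  if (n < 3 || abs(polygon_area(poly)) <= 0)
    abort2("invalid polygon", "audiogain_bad_geometry")
  inside <- logical(length(px))
  onb <- logical(length(px))
  j <- n
  for (i in seq_len(n)) {
    xi <- poly[i, 1]; yi <- poly[i, 2]
    xj <- poly[j, 1]; yj <- poly[j, 2]
    # boundary: point within eps of segment i-j
    dx <- xj - xi; dy <- yj - yi
    len2 <- dx * dx + dy * dy
    if (len2 > 0) {
      t <- pmin(1, pmax(0, ((px - xi) * dx + (py - yi) * dy) / len2))
      d2 <- (px - (xi + t * dx))^2 + (py - (yi + t * dy))^2
      onb <- onb | d2 <= eps^2
    } else {
      onb <- onb | ((px - xi)^2 + (py - yi)^2 <= eps^2)
    }
    crosses <- ((yi > py) != (yj > py)) &
      (px < (xj - xi) * (py - yi) / (yj - yi) + xi)
    inside <- xor(inside, crosses)
    j <- i
  }
  inside | onb
}

# Distance/projection of points onto a polyline. Returns, per point, the
# nearest polyline point, its segment index, and the distance.
nearest_on_polyline <- function(px, py, line) {
  line <- as.matrix(line)
  ns <- nrow(line) - 1L
  if (ns < 1) abort2("polyline needs >= 2 vertices", "audiogain_bad_geometry")
  best_d2 <- rep(Inf, length(px))
  bx <- by <- tt <- numeric(length(px))
  seg <- integer(length(px))
  for (s in seq_len(ns)) {
    x1 <- line[s, 1]; y1 <- line[s, 2]
    dx <- line[s + 1, 1] - x1; dy <- line[s + 1, 2] - y1
    len2 <- dx * dx + dy * dy
    t <- if (len2 > 0) pmin(1, pmax(0, ((px - x1) * dx + (py - y1) * dy) / len2)) else 0
    qx <- x1 + t * dx; qy <- y1 + t * dy
    d2 <- (px - qx)^2 + (py - qy)^2
    upd <- d2 < best_d2
    best_d2[upd] <- d2[upd]; bx[upd] <- qx[upd]; by[upd] <- qy[upd]
    seg[upd] <- s; tt[upd] <- t[upd]
  }
  list(x = bx, y = by, segment = seg, t = tt, dist = sqrt(best_d2))
}

# Unit normal of polyline at the projection returned by nearest_on_polyline;
# normals of adjacent segments are averaged when the projection falls on a
# vertex. Orientation is arbitrary here; callers orient it.
polyline_normal_at <- function(line, segment, t, vertex_tol = 1e-9) {
  line <- as.matrix(line)
  seg_normal <- function(s) {
    d <- line[s + 1, ] - line[s, ]
    n <- c(-d[2], d[1])
    n / sqrt(sum(n^2))
  }
  n <- seg_normal(segment)
  ns <- nrow(line) - 1L
  if (t <= vertex_tol && segment > 1) n <- n + seg_normal(segment - 1L)
  if (t >= 1 - vertex_tol && segment < ns) n <- n + seg_normal(segment + 1L)
  n / sqrt(sum(n^2))
}

# First intersection of the ray origin + t*dir (t > tol) with a polyline.
# Returns the intersection point and ray parameter, or NULL.
ray_polyline_intersection <- function(origin, dir, line, tol = 1e-9) {
  line <- as.matrix(line)
  best <- Inf; pt <- NULL
  for (s in seq_len(nrow(line) - 1L)) {
    p <- line[s, ]; r <- line[s + 1, ] - p
    den <- dir[1] * r[2] - dir[2] * r[1]
    if (abs(den) < 1e-15) next
    dx <- p[1] - origin[1]; dy <- p[2] - origin[2]
    t_ray <- (dx * r[2] - dy * r[1]) / den
    u <- (dx * dir[2] - dy * dir[1]) / den
    if (t_ray > tol && u >= -tol && u <= 1 + tol && t_ray < best) {
      best <- t_ray
      pt <- origin + t_ray * dir
    }
  }
  if (is.null(pt)) NULL else list(point = pt, t = best)
}

# TRUE if any segment of polyline a properly intersects any segment of b.
polylines_cross <- function(a, b) {
  a <- as.matrix(a); b <- as.matrix(b)
  orient <- function(p, q, r) {
    (q[1] - p[1]) * (r[2] - p[2]) - (q[2] - p[2]) * (r[1] - p[1])
  }
  for (i in seq_len(nrow(a) - 1L)) {
    for (j in seq_len(nrow(b) - 1L)) {
      p1 <- a[i, ]; p2 <- a[i + 1, ]; q1 <- b[j, ]; q2 <- b[j + 1, ]
      d1 <- orient(q1, q2, p1); d2 <- orient(q1, q2, p2)
      d3 <- orient(p1, p2, q1); d4 <- orient(p1, p2, q2)
      if (((d1 > 0 && d2 < 0) || (d1 < 0 && d2 > 0)) &&
          ((d3 > 0 && d4 < 0) || (d3 < 0 && d4 > 0))) return(TRUE)
    }
  }
  FALSE
}

# Sutherland-Hodgman clip of a (possibly concave) subject polygon against a
# convex clip polygon. Returns the clipped vertex matrix (possibly 0 rows).
clip_polygon_convex <- function(subject, clip) {
  subject <- as.matrix(subject); clip <- as.matrix(clip)
  if (polygon_area(clip) < 0) clip <- clip[nrow(clip):1, ]
  out <- subject
  nc <- nrow(clip)
  for (i in seq_len(nc)) {
    if (nrow(out) == 0) break
    a <- clip[i, ]; b <- clip[if (i == nc) 1 else i + 1, ]
    ex <- b[1] - a[1]; ey <- b[2] - a[2]
    inside <- function(p) ex * (p[2] - a[2]) - ey * (p[1] - a[1]) >= -1e-12
    res <- list(); k <- 0
    np <- nrow(out)
    for (j in seq_len(np)) {
      cur <- out[j, ]; prv <- out[if (j == 1) np else j - 1, ]
      ci <- inside(cur); pi <- inside(prv)
      if (ci != pi) {
        # edge crossing: intersect segment prv-cur with clip line a-b
        d <- cur - prv
        den <- ex * d[2] - ey * d[1]
        t <- (ex * (a[2] - prv[2]) - ey * (a[1] - prv[1])) / den
        k <- k + 1; res[[k]] <- prv + t * d
      }
      if (ci) { k <- k + 1; res[[k]] <- cur }
    }
    out <- if (k) do.call(rbind, res) else matrix(numeric(0), 0, 2)
  }
  out
}
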