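# Planar/spherical geometry primitives behind the geospatial module.
#
# Conventions:
#  * a "ring" is an n x 2 numeric matrix of vertices, NOT closed (the first
#    vertex is not repeated at the end);
#  * a "geometry" is a list of parts, each part a list of rings (first ring
#    outer boundary, subsequent rings holes) -- the GeoJSON model;
#  * geographic coordinates are WGS84 lon/lat degrees; projected coordinates
#    are kilometres in a Lambert azimuthal equal-area (LAEA) frame on the
#    authalic sphere, so planar shoelace areas are areas in km2.

#' Lambert azimuthal equal-area projection
#'
#' Builds a projection centered at (`lon0`, `lat0`) on the authalic sphere
#' (radius 6371.0088 km). LAEA preserves areas exactly on the sphere, which
#' is what the km2 range metrics require; the regional extents involved
#' (hundreds of km) keep shape distortion negligible.
#'
#' @param lon0,lat0 Projection center, decimal degrees.
#' @return An object of class `cpi_projection`.
#' @export
laea_projection <- function(lon0, lat0) {
  stopifnot(is.finite(lon0), is.finite(lat0), abs(lat0) <= 90)
  structure(list(lon0 = lon0, lat0 = lat0, radius_km = EARTH_RADIUS_KM),
            class = "cpi_projection")
}

#' @export
print.cpi_projection <- function(x, ...) {
  cat(sprintf("<LAEA projection centered at %.4f, %.4f (authalic sphere, km)>\n",
              x$lon0, x$lat0))
  invisible(x)
}

# Projection centered on the mean of a lon/lat matrix or layer extent.
projection_for <- function(lon, lat) {
  laea_projection(mean(range(lon)), mean(range(lat)))
}

#' Project lon/lat to equal-area plane coordinates
#'
#' @param proj A [laea_projection()].
#' @param lon,lat Numeric vectors of WGS84 coordinates (degrees).
#' @return A two-column matrix of x/y coordinates in km.
#' @export
project_lonlat <- function(proj, lon, lat) {
  stopifnot(inherits(proj, "cpi_projection"))
  rad <- pi / 180
  l0 <- proj$lon0 * rad; f0 <- proj$lat0 * rad
  l <- lon * rad; f <- lat * rad
  dl <- l - l0
  denom <- 1 + sin(f0) * sin(f) + cos(f0) * cos(f) * cos(dl)
  # antipodal point of the center is a singularity of LAEA
  if (any(denom < 1e-12)) {
    stop_validation("point antipodal to the projection center cannot be projected")
  }
  k <- sqrt(2 / denom)
  cbind(x = proj$radius_km * k * cos(f) * sin(dl),
        y = proj$radius_km * k * (cos(f0) * sin(f) - sin(f0) * cos(f) * cos(dl)))
}

project_ring <- function(proj, ring) {
  project_lonlat(proj, ring[, 1], ring[, 2])
}

project_geometry <- function(proj, geom) {
  lapply(geom, function(part) lapply(part, function(r) project_ring(proj, r)))
}

# Signed shoelace area of one ring (units^2 of the coordinates).
ring_area_signed <- function(ring) {
  x <- ring[, 1]; y <- ring[, 2]
  n <- nrow(ring)
  if (n < 3) return(0)
  j <- c(n, seq_len(n - 1))
  sum(x[j] * y - x * y[j]) / 2
}

# Unsigned area of a geometry: outer rings minus holes, summed over parts.
geometry_area <- function(geom) {
  sum(vapply(geom, function(part) {
    a <- abs(ring_area_signed(part[[1]]))
    if (length(part) > 1) {
      a <- a - sum(vapply(part[-1], function(h) abs(ring_area_signed(h)), 0))
    }
    a
  }, 0))
}

# Drop consecutive duplicate vertices and a closing vertex if present.
normalize_ring <- function(ring) {
  ring <- as.matrix(ring)
  if (nrow(ring) >= 2 &&
      isTRUE(all(abs(ring[1, ] - ring[nrow(ring), ]) < 1e-12))) {
    ring <- ring[-nrow(ring), , drop = FALSE]
  }
  if (nrow(ring) >= 2) {
    d <- rowSums(abs(ring - ring[c(nrow(ring), seq_len(nrow(ring) - 1)), , drop = FALSE]))
    keep <- d > 1e-12
    if (!all(keep)) ring <- ring[keep, , drop = FALSE]
  }
  ring
}

# Orient a ring counter-clockwise (positive signed area).
orient_ccw <- function(ring) {
  if (ring_area_signed(ring) < 0) ring[rev(seq_len(nrow(ring))), , drop = FALSE] else ring
}

is_convex_ring <- function(ring, tol = 1e-9) {
  ring <- orient_ccw(normalize_ring(ring))
  n <- nrow(ring)
  if (n < 3) return(FALSE)
  nxt <- c(seq(2, n), 1)
  nxt2 <- nxt[nxt]
  e1 <- ring[nxt, , drop = FALSE] - ring
  e2 <- ring[nxt2, , drop = FALSE] - ring[nxt, , drop = FALSE]
  cross <- e1[, 1] * e2[, 2] - e1[, 2] * e2[, 1]
  scale <- max(abs(ring)) + 1
  all(cross > -tol * scale^2)
}

# Sutherland-Hodgman clip of an arbitrary subject ring against a CONVEX
# clip ring. Returns a ring (possibly with 0 rows when disjoint).
clip_ring_convex <- function(subject, clip, check_convex = TRUE) {
  subject <- normalize_ring(subject)
  clip <- orient_ccw(normalize_ring(clip))
  if (check_convex && !is_convex_ring(clip)) {
    stop_validation("clip polygon must be convex for overlay operations")
  }
  out <- subject
  nc <- nrow(clip)
  for (i in seq_len(nc)) {
    if (nrow(out) == 0) break
    a <- clip[i, ]; b <- clip[if (i == nc) 1 else i + 1, ]
    # signed distance to edge a->b (positive = inside for CCW clip)
    side <- (b[1] - a[1]) * (out[, 2] - a[2]) - (b[2] - a[2]) * (out[, 1] - a[1])
    n <- nrow(out)
    prev <- c(n, seq_len(n - 1))
    res <- matrix(numeric(0), ncol = 2)
    for (j in seq_len(n)) {
      p <- out[j, ]; sp <- side[j]
      q <- out[prev[j], ]; sq <- side[prev[j]]
      if (sp >= 0) {
        if (sq < 0) {
          t <- sq / (sq - sp)
          res <- rbind(res, q + t * (p - q))
        }
        res <- rbind(res, p)
      } else if (sq >= 0) {
        t <- sq / (sq - sp)
        res <- rbind(res, q + t * (p - q))
      }
    }
    out <- normalize_ring(res)
  }
  if (nrow(out) < 3) out <- out[0, , drop = FALSE]
  out
}

# Area of the intersection of a geometry (holes unsupported here) with a
# convex ring.
geometry_clip_area <- function(geom, clip_ring) {
  sum(vapply(geom, function(part) {
    if (length(part) > 1) {
      stop_validation("polygon holes are not supported in overlay operations")
    }
    abs(ring_area_signed(clip_ring_convex(part[[1]], clip_ring)))
  }, 0))
}

# Even-odd (ray casting) point-in-ring test, vectorized over points.
points_in_ring <- function(px, py, ring) {
  ring <- normalize_ring(ring)
  n <- nrow(ring)
  inside <- rep(FALSE, length(px))
  if (n < 3) return(inside)
  xr <- ring[, 1]; yr <- ring[, 2]
  j <- n
  for (i in seq_len(n)) {
    xi <- xr[i]; yi <- yr[i]; xj <- xr[j]; yj <- yr[j]
    crosses <- ((yi > py) != (yj > py)) &
      (px < (xj - xi) * (py - yi) / (yj - yi) + xi)
    inside <- xor(inside, crosses)
    j <- i
  }
  inside
}

# Even-odd containment in a full geometry (outer rings minus holes).
points_in_geometry <- function(px, py, geom) {
  inside <- rep(FALSE, length(px))
  for (part in geom) {
    in_part <- points_in_ring(px, py, part[[1]])
    if (length(part) > 1) {
      for (h in part[-1]) in_part <- in_part & !points_in_ring(px, py, h)
    }
    inside <- inside | in_part
  }
  inside
}

# Convex hull ring (CCW) of a two-column coordinate matrix.
convex_hull_ring <- function(xy) {
  idx <- grDevices::chull(xy[, 1], xy[, 2])
  orient_ccw(xy[rev(idx), , drop = FALSE])
}

# Union area of a list of convex rings via inclusion-exclusion. Used for
# protected-area unions; the number of overlapping layers is small.
convex_union_area <- function(rings) {
  k <- length(rings)
  if (k == 0) return(0)
  if (k > 12) stop_validation("too many overlapping polygons for union (max 12)")
  total <- 0
  # iterate non-empty subsets; intersections of convex rings stay convex
  for (mask in seq_len(2^k - 1)) {
    members <- which(bitwAnd(mask, 2^(seq_len(k) - 1)) > 0)
    inter <- rings[[members[1]]]
    for (m in members[-1]) {
      if (nrow(inter) < 3) break
      inter <- clip_ring_convex(inter, rings[[m]], check_convex = FALSE)
    }
    a <- if (nrow(inter) >= 3) abs(ring_area_signed(inter)) else 0
    total <- total + (-1)^(length(members) + 1) * a
  }
  total
}

# Area of geometry intersected with a union of convex rings.
geometry_union_clip_area <- function(geom, rings) {
  k <- length(rings)
  if (k == 0) return(0)
  if (k > 12) stop_validation("too many overlapping polygons for union (max 12)")
  total <- 0
  for (mask in seq_len(2^k - 1)) {
    members <- which(bitwAnd(mask, 2^(seq_len(k) - 1)) > 0)
    a <- sum(vapply(geom, function(part) {
      ring <- part[[1]]
      for (m in members) {
        if (nrow(ring) < 3) break
        ring <- clip_ring_convex(ring, rings[[m]], check_convex = FALSE)
      }
      if (nrow(ring) >= 3) abs(ring_area_signed(ring)) else 0
    }, 0))
    total <- total + (-1)^(length(members) + 1) * a
  }
  total
}

# Area-weighted centroid of a geometry (outer rings only).
geometry_centroid <- function(geom) {
  cx <- 0; cy <- 0; atot <- 0
  for (part in geom) {
    ring <- normalize_ring(part[[1]])
    n <- nrow(ring)
    j <- c(n, seq_len(n - 1))
    x <- ring[, 1]; y <- ring[, 2]
    cr <- x[j] * y - x * y[j]
    a <- sum(cr) / 2
    if (abs(a) < 1e-15) next
    cx <- cx + sum((x[j] + x) * cr) / 6
    cy <- cy + sum((y[j] + y) * cr) / 6
    atot <- atot + a
  }
  if (abs(atot) < 1e-15) stop_validation("degenerate polygon: zero area centroid")
  c(x = cx / atot, y = cy / atot)
}
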