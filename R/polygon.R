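#' Closed 2D lesion contour in millimetres
#'
#' Constructs a `polygon2d` object from an ordered set of vertices describing
#' a closed freehand ROI drawn on a single axial CT slice. The polygon is
#' implicitly closed (the last vertex connects back to the first). Consecutive
#' duplicate vertices, including a repeated closing vertex, are collapsed.
#'
#' Degenerate contours (fewer than 3 distinct consecutive vertices, or all
#' vertices collinear) are accepted and simply yield zero shape features
#' downstream; they are not errors, because hand-drawn annotations do
#' occasionally collapse to a segment.
#'
#' @param vertices A two-column numeric matrix (or data.frame / list of
#'   length-2 points) of `(x, y)` coordinates in mm.
#' @return An object of class `polygon2d`.
#' @examples
#' sq <- polygon2d(cbind(c(0, 10, 10, 0), c(0, 0, 10, 10)))
#' polygon_area(sq)
#' @export
polygon2d <- function(vertices) {
  v <- as_vertex_matrix(vertices)
  if (nrow(v) < 3L) {
    stop("a polygon needs at least 3 vertices, got ", nrow(v))
  }
  v <- collapse_duplicate_vertices(v)
  structure(list(vertices = v), class = "polygon2d")
}

as_vertex_matrix <- function(vertices) {
  if (is.data.frame(vertices)) vertices <- as.matrix(vertices)
  if (is.list(vertices)) vertices <- do.call(rbind, lapply(vertices, as.numeric))
  v <- matrix(as.numeric(vertices), ncol = 2L,
              dimnames = list(NULL, c("x", "y")))
  if (any(!is.finite(v))) stop("polygon vertices must be finite numbers")
  v
}

collapse_duplicate_vertices <- function(v) {
  n <- nrow(v)
  nxt <- c(seq_len(n)[-1L], 1L)
  dup <- v[, 1L] == v[nxt, 1L] & v[, 2L] == v[nxt, 2L]
  # keep the first vertex of every duplicate run (incl. a repeated closure)
  v[!dup, , drop = FALSE]
}

#' @export
print.polygon2d <- function(x, ...) {
  cat("polygon2d with", nrow(x$vertices), "vertices,",
      format(polygon_area(x), digits = 5), "mm^2\n")
  invisible(x)
}

# Signed shoelace sum and first moments over all edges. Shared kernel for
# area, centroid and the interior second moments; works on a raw matrix so
# the synthetic generator can bypass object construction in hot loops.
.polygon_cross <- function(v) {
  n <- nrow(v)
  nxt <- c(seq_len(n)[-1L], 1L)
  v[, 1L] * v[nxt, 2L] - v[nxt, 1L] * v[, 2L]
}

.polygon_area_signed <- function(v) sum(.polygon_cross(v)) / 2

#' Enclosed area of a lesion contour
#'
#' Computes the area enclosed by the contour as the absolute value of the
#' signed sum of triangle areas fanned from an interior origin. Because the
#' per-triangle contributions are signed before summation, the result equals
#' the true enclosed area for any simple polygon (convex or not) and is
#' independent of the fan origin; it reduces to the shoelace formula.
#'
#' @param polygon A [polygon2d] object.
#' @return Area in mm\eqn{^2} (>= 0). Degenerate contours give 0.
#' @examples
#' polygon_area(polygon2d(cbind(c(0, 40, 0), c(0, 0, 30)))) # 600
#' @export
polygon_area <- function(polygon) {
  stopifnot(inherits(polygon, "polygon2d"))
  v <- polygon$vertices
  if (nrow(v) < 3L) return(0)
  abs(.polygon_area_signed(v))
}

#' Area centroid of a lesion contour
#'
#' @param polygon A [polygon2d] object.
#' @return Numeric `(x, y)` in mm; the vertex mean for degenerate contours.
#' @export
polygon_centroid <- function(polygon) {
  stopifnot(inherits(polygon, "polygon2d"))
  .polygon_centroid(polygon$vertices)
}

.polygon_centroid <- function(v) {
  a <- .polygon_area_signed(v)
  if (a == 0) return(colMeans(v))
  n <- nrow(v)
  nxt <- c(seq_len(n)[-1L], 1L)
  cr <- .polygon_cross(v)
  c(sum((v[, 1L] + v[nxt, 1L]) * cr), sum((v[, 2L] + v[nxt, 2L]) * cr)) / (6 * a)
}

# Covariance matrix of the uniform distribution over the polygon interior,
# from the exact Green's-theorem moment integrals (resolution independent).
.polygon_covariance <- function(v) {
  a <- .polygon_area_signed(v)
  if (a == 0) return(matrix(0, 2L, 2L))
  n <- nrow(v)
  nxt <- c(seq_len(n)[-1L], 1L)
  x0 <- v[, 1L]; y0 <- v[, 2L]; x1 <- v[nxt, 1L]; y1 <- v[nxt, 2L]
  cr <- x0 * y1 - x1 * y0
  ixx <- sum((x0 * x0 + x0 * x1 + x1 * x1) * cr) / 12
  iyy <- sum((y0 * y0 + y0 * y1 + y1 * y1) * cr) / 12
  ixy <- sum((x0 * y1 + 2 * x0 * y0 + 2 * x1 * y1 + x1 * y0) * cr) / 24
  cx <- sum((x0 + x1) * cr) / (6 * a)
  cy <- sum((y0 + y1) * cr) / (6 * a)
  m <- matrix(c(ixx / a - cx * cx, ixy / a - cx * cy,
                ixy / a - cx * cy, iyy / a - cy * cy), 2L, 2L)
  m
}

#' Principal axis lengths of a lesion contour
#'
#' The lesion's major and minor axis lengths are derived from the eigenvalues
#' \eqn{\lambda} of the covariance matrix of the uniform distribution over the
#' polygon interior, computed from exact polygon second moments: each axis is
#' \eqn{4\sqrt{\lambda}}. For an ellipse with semi-axes \eqn{a \ge b} this
#' returns exactly \eqn{(2a, 2b)} — the full axis diameters — which is the
#' convention used for RECIST-style diameter measurements.
#'
#' @param polygon A [polygon2d] object.
#' @return Named numeric vector `c(major, minor)` in mm, with
#'   `major >= minor`. Degenerate contours give `c(0, 0)`.
#' @examples
#' sq <- polygon2d(cbind(c(0, 10, 10, 0), c(0, 0, 10, 10)))
#' principal_axis_lengths(sq) # 4 * 10 / sqrt(12) in both directions
#' @export
principal_axis_lengths <- function(polygon) {
  stopifnot(inherits(polygon, "polygon2d"))
  v <- polygon$vertices
  if (nrow(v) < 3L || .polygon_area_signed(v) == 0) {
    return(c(major = 0, minor = 0))
  }
  m <- .polygon_covariance(v)
  tr2 <- (m[1L, 1L] + m[2L, 2L]) / 2
  det <- m[1L, 1L] * m[2L, 2L] - m[1L, 2L]^2
  disc <- sqrt(max(tr2 * tr2 - det, 0))
  lam <- pmax(c(tr2 + disc, tr2 - disc), 0)
  c(major = 4 * sqrt(lam[1L]), minor = 4 * sqrt(lam[2L]))
}

#' Approximate 3D lesion volume from single-slice features
#'
#' Approximates the lesion's 3D volume from its single largest axial slice as
#' \deqn{V = \frac{2}{3} \, A \, d_{minor}}
#' where \eqn{A} is the in-plane enclosed area and \eqn{d_{minor}} the minor
#' axis length. For a sphere annotated at its equator (\eqn{A = \pi r^2},
#' \eqn{d_{minor} = 2r}) this recovers \eqn{\frac{4}{3}\pi r^3} exactly, and
#' for an ellipsoid of revolution about the major axis it recovers
#' \eqn{\frac{4}{3}\pi a b^2}.
#'
#' @param surface In-plane area in mm^2 (>= 0).
#' @param minor_axis Minor axis length in mm (>= 0).
#' @return Volume in mm^3.
#' @examples
#' lesion_volume(pi * 10^2, 20) # sphere of radius 10 mm
#' @export
lesion_volume <- function(surface, minor_axis) {
  if (any(surface < 0)) stop("surface must be >= 0")
  if (any(minor_axis < 0)) stop("minor_axis must be >= 0")
  (2 / 3) * surface * minor_axis
}

#' Diameter of the sphere with a given volume
#'
#' Converts a volume to the diameter of the equivalent sphere,
#' \eqn{d = 2 (3V / 4\pi)^{1/3}}, in the same length unit as the cube root of
#' the volume unit (cm\eqn{^3} in, cm out). Useful for translating a total
#' tumor volume cutoff into an intuitive size: 90 cm\eqn{^3} corresponds to a
#' single sphere about 5.6 cm across.
#'
#' @param volume Volume (>= 0); vectorised.
#' @return Equivalent-sphere diameter.
#' @examples
#' equivalent_sphere_diameter(90) # ~5.6
#' @export
equivalent_sphere_diameter <- function(volume) {
  if (any(volume < 0)) stop("volume must be >= 0")
  2 * (3 * volume / (4 * pi))^(1 / 3)
}

#' All shape features of one lesion contour
#'
#' Convenience wrapper computing area, principal axis lengths and the
#' approximate 3D volume in one call.
#'
#' @param polygon A [polygon2d] object.
#' @return Named list with `surface` (mm^2), `major_axis` (mm), `minor_axis`
#'   (mm) and `volume` (mm^3), satisfying `volume == 2/3 * surface *
#'   minor_axis` exactly.
#' @export
shape_features <- function(polygon) {
  a <- polygon_area(polygon)
  ax <- principal_axis_lengths(polygon)
  list(surface = a, major_axis = unname(ax["major"]),
       minor_axis = unname(ax["minor"]),
       volume = (2 / 3) * a * unname(ax["minor"]))
}

# Fast path used by lesion_features()/the generator: raw matrix in, the four
# features out, skipping S3 construction.
.shape_features_mat <- function(v) {
  a_signed <- .polygon_area_signed(v)
  a <- abs(a_signed)
  if (nrow(v) < 3L || a == 0) {
    return(c(surface = 0, major_axis = 0, minor_axis = 0, volume = 0))
  }
  m <- .polygon_covariance(v)
  tr2 <- (m[1L, 1L] + m[2L, 2L]) / 2
  det <- m[1L, 1L] * m[2L, 2L] - m[1L, 2L]^2
  disc <- sqrt(max(tr2 * tr2 - det, 0))
  major <- 4 * sqrt(max(tr2 + disc, 0))
  minor <- 4 * sqrt(max(tr2 - disc, 0))
  c(surface = a, major_axis = major, minor_axis = minor,
    volume = (2 / 3) * a * minor)
}
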