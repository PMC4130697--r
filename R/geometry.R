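# Exact planar geometry underlying the graphical rotation measurement.
# All constructions are expressed in the base-edge frame of the vertebral
# body quadrilateral, never in the image axes, which is what makes the
# measurement invariant to scale and to rigid motions of the film.

.cross2 <- function(a, b) a[1] * b[2] - a[2] * b[1]

.norm2 <- function(a) sqrt(sum(a * a))

# Intersection of lines p + t*r and q + u*s; NULL when (numerically) parallel.
.line_intersect <- function(p, r, q, s) {
  den <- .cross2(r, s)
  if (abs(den) < 1e-12 * (.norm2(r) * .norm2(s) + 1e-300)) return(NULL)
  w <- q - p
  list(t = .cross2(w, s) / den, u = .cross2(w, r) / den)
}

.quad_diag <- function(quad) {
  max(.norm2(quad[3, ] - quad[1, ]), .norm2(quad[4, ] - quad[2, ]))
}

# Orthonormal frame attached to the base (bottom) edge of the body quad:
# origin at the bottom-left corner, u along the base edge, v perpendicular
# to it, oriented toward the top edge.
.base_frame <- function(quad) {
  u <- quad[2, ] - quad[1, ]
  len <- .norm2(u)
  if (len < 1e-12) .stop_degenerate("degenerate base edge (zero length)")
  u <- u / len
  v <- c(-u[2], u[1])
  top_mid <- (quad[3, ] + quad[4, ]) / 2
  if (sum((top_mid - quad[1, ]) * v) < 0) v <- -v
  list(origin = quad[1, ], u = u, v = v)
}

.to_frame <- function(p, fr) {
  w <- p - fr$origin
  c(sum(w * fr$u), sum(w * fr$v))
}

.from_frame <- function(p, fr) fr$origin + p[1] * fr$u + p[2] * fr$v

#' Intersection of the diagonals of a quadrilateral
#'
#' The centre-finding primitive of the graphical method: the centre of a
#' vertebral body projection (and of the pedicle quadrangle) is taken as the
#' crossing point of the two diagonals.
#'
#' @param quad 4 x 2 numeric matrix of corners in order bottom-left,
#'   bottom-right, top-right, top-left (any consistent cyclic order works).
#' @return Numeric length-2 point.
#' @examples
#' intersect_diagonals(rbind(c(0, 0), c(4, 0), c(4, 2), c(0, 2)))
#' @export
intersect_diagonals <- function(quad) {
  quad <- .as_quad(quad)
  if (abs(.quad_area(quad)) < 1e-9)
    .stop_degenerate("quadrilateral area below 1e-9 mm^2")
  hit <- .line_intersect(quad[1, ], quad[3, ] - quad[1, ],
                         quad[2, ], quad[4, ] - quad[2, ])
  if (is.null(hit))
    .stop_degenerate("diagonals are parallel")
  if (hit$t < -10 || hit$t > 10 || hit$u < -10 || hit$u > 10)
    .stop_degenerate("diagonal intersection parameter outside [-10, 10]")
  unname(quad[1, ] + hit$t * (quad[3, ] - quad[1, ]))
}

#' Centre of the vertebral body projection (point A)
#'
#' The crossing of the body quadrilateral's diagonals: the graphical centre
#' of the vertebral body width.
#'
#' @param x A [landmark_set()] or a 4 x 2 corner matrix.
#' @return Numeric length-2 point.
#' @export
body_center <- function(x) {
  quad <- if (inherits(x, "landmark_set")) x$body_quad else x
  intersect_diagonals(quad)
}

# Intersection of the base-perpendicular through point p with the edge line
# a -> b; degenerate when parallel or when the hit lies further than
# `extension` times the quad diagonal from the quad centroid.
.perp_edge_hit <- function(p, fr, a, b, quad, what, extension = 2) {
  hit <- .line_intersect(p, fr$v, a, b - a)
  if (is.null(hit))
    .stop_degenerate(sprintf("base-perpendicular is parallel to the %s edge", what))
  pt <- p + hit$t * fr$v
  centroid <- colMeans(quad)
  if (.norm2(pt - centroid) > extension * .quad_diag(quad))
    .stop_degenerate(sprintf(
      "base-perpendicular meets the %s edge beyond %gx the quad diagonal",
      what, extension))
  pt
}

#' Centre of the inter-pedicle distance (point B)
#'
#' Perpendiculars to the base edge are erected through each pedicle
#' inner-contour point; their intersections with the bottom and top edges of
#' the body quadrilateral form a quadrangle whose diagonal crossing is the
#' centre of the distance between the pedicles.
#'
#' @param x A [landmark_set()] with both pedicle points available (after
#'   [concave_fallback()] if one shadow is hidden).
#' @return Numeric length-2 point. The constructed quadrangle is attached as
#'   attribute `"quadrangle"`.
#' @export
pedicle_midpoint <- function(x) {
  stopifnot(inherits(x, "landmark_set"))
  if (anyNA(x$pedicle_left_inner) || anyNA(x$pedicle_right_inner))
    .stop_missing("both pedicle points are required; apply concave_fallback() first")
  quad <- x$body_quad
  fr <- .base_frame(quad)
  mk <- function(p) {
    rbind(.perp_edge_hit(p, fr, quad[1, ], quad[2, ], quad, "bottom"),
          .perp_edge_hit(p, fr, quad[4, ], quad[3, ], quad, "top"))
  }
  lh <- mk(x$pedicle_left_inner)
  rh <- mk(x$pedicle_right_inner)
  quadrangle <- rbind(lh[1, ], rh[1, ], rh[2, ], lh[2, ])
  rownames(quadrangle) <- c("bottom-left", "bottom-right", "top-right", "top-left")
  B <- intersect_diagonals(quadrangle)
  attr(B, "quadrangle") <- quadrangle
  B
}

#' Foot of the perpendicular from the body centre on the base edge (point C)
#'
#' @param A Numeric length-2 point (usually [body_center()]).
#' @param x A [landmark_set()] or corner matrix supplying the base edge; the
#'   edge is extended infinitely.
#' @return Numeric length-2 point.
#' @export
base_foot <- function(A, x) {
  quad <- if (inherits(x, "landmark_set")) x$body_quad else .as_quad(x)
  fr <- .base_frame(quad)
  .from_frame(c(.to_frame(A, fr)[1], 0), fr)
}

#' Three-quarter-height point for the thoracic rule (point D)
#'
#' On the base-perpendicular through the inter-pedicle centre B, halfway
#' between B and that perpendicular's intersection with the top edge of the
#' body. Because B lies at half the body height, D corresponds to three
#' quarters of the vertebral body height.
#'
#' @param B Numeric length-2 point (usually [pedicle_midpoint()]).
#' @param x A [landmark_set()] or corner matrix.
#' @return Numeric length-2 point.
#' @export
three_quarter_point <- function(B, x) {
  quad <- if (inherits(x, "landmark_set")) x$body_quad else .as_quad(x)
  fr <- .base_frame(quad)
  top <- .perp_edge_hit(B, fr, quad[4, ], quad[3, ], quad, "top")
  unname((B + top) / 2)
}

#' Discrepancy of the small-angle linearisation tan(alpha) ~ alpha
#'
#' The method rests on d = x * tan(alpha); reading the construction with a
#' protractor measures the exact angle, but the linearised reading
#' d / x (in radians) overstates it. This returns the discrepancy
#' deg(tan(rad(alpha))) - alpha, which grows from 0.10 degrees at 10 degrees
#' to 3.08 degrees at 30 degrees -- the basis of the method's stated 30
#' degree validity limit.
#'
#' @param alpha_deg Numeric vector of angles in degrees, each in \[0, 90).
#' @return Numeric vector of discrepancies in degrees.
#' @examples
#' small_angle_error(c(10, 15, 20, 25, 30))
#' @export
small_angle_error <- function(alpha_deg) {
  alpha_deg <- as.numeric(alpha_deg)
  if (any(!is.finite(alpha_deg)) || any(alpha_deg < 0) || any(alpha_deg >= 90))
    .stop_domain("alpha_deg must lie in [0, 90) degrees")
  180 / pi * tan(alpha_deg * pi / 180) - alpha_deg
}
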