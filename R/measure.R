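#' Substitute the body contour for a hidden concave-side pedicle
#'
#' Above roughly 30 degrees of rotation the concave-side pedicle shadow
#' merges with the vertebral body contour. The measurement then assumes the
#' pedicle coincides with the contour: the hidden pedicle's inner point is
#' replaced by the point of the corresponding lateral body edge at the same
#' height fraction as the visible pedicle point.
#'
#' @param x A [landmark_set()].
#' @return A `landmark_set` with the hidden pedicle point filled in (the
#'   `concave_pedicle_missing` flag is retained as provenance). When no
#'   pedicle is flagged the input is returned unchanged.
#' @export
concave_fallback <- function(x) {
  stopifnot(inherits(x, "landmark_set"))
  side <- x$concave_pedicle_missing
  if (side == "none") return(x)
  visible <- if (side == "left") x$pedicle_right_inner else x$pedicle_left_inner
  if (anyNA(visible))
    .stop_missing(sprintf(
      "vertebra %s: both pedicle shadows unavailable, rotation is unmeasurable",
      x$level))

  quad <- x$body_quad
  fr <- .base_frame(quad)
  qf <- t(apply(quad, 1, .to_frame, fr = fr))
  z_quad <- mean(qf[3:4, 2])              # mean perpendicular height of top corners
  f <- .to_frame(visible, fr)[2] / z_quad
  f <- min(max(f, 0), 1)
  edge <- if (side == "left") quad[c(1, 4), ] else quad[c(2, 3), ]
  repl <- edge[1, ] + f * (edge[2, ] - edge[1, ])

  x[[paste0("pedicle_", side, "_inner")]] <- unname(repl)
  x
}

#' Compromise rectangle/rhomboid over a wedged vertebral body
#'
#' Wedged (structurally deformed) vertebral bodies pull the graphical body
#' centre toward the wedge apex (drift d'), which biases the rotation
#' reading. The remedy is to overlay a compromise rectangle or rhomboid:
#' its base is parallel to the pedicle suture, its height equals the height
#' of the convex (undeformed) side, and the habitual height/width ratio is
#' preserved.
#'
#' @param contour n x 2 matrix (n >= 4) of body contour points. For n = 4
#'   the rows are interpreted as bottom-left, bottom-right, top-right,
#'   top-left.
#' @param suture_direction Length-2 vector giving the direction of the
#'   pedicle suture (the base of the substitute is drawn parallel to it).
#'   Defaults to the direction of the contour's bottom edge.
#' @param height_tol Relative tolerance below which the two lateral heights
#'   are considered equal; the result is then the minimal-area bounding
#'   parallelogram and carries attribute `ambiguous = TRUE`.
#' @return 4 x 2 corner matrix of the substitute parallelogram, with
#'   attributes `convex_side` (`"left"`, `"right"` or `"ambiguous"`) and
#'   `ambiguous`.
#' @export
wedge_substitute <- function(contour, suture_direction = NULL,
                             height_tol = 1e-6) {
  contour <- as.matrix(contour)
  storage.mode(contour) <- "double"
  if (nrow(contour) < 4L || ncol(contour) != 2L || !all(is.finite(contour)))
    .stop_validation("contour must be an n x 2 matrix of finite points, n >= 4")
  if (is.null(suture_direction)) suture_direction <- contour[2, ] - contour[1, ]
  len <- .norm2(suture_direction)
  if (len < 1e-12) .stop_degenerate("suture direction has zero length")
  u <- suture_direction / len
  v <- c(-u[2], u[1])
  eta <- as.numeric(contour %*% v)
  # for a quad in bottom-left/bottom-right/top-right/top-left order, orient
  # v from the bottom row toward the top row
  if (nrow(contour) == 4L && mean(eta[3:4]) < mean(eta[1:2])) {
    v <- -v; eta <- -eta
  }
  xi <- as.numeric(contour %*% u)

  if (nrow(contour) == 4L) {
    base <- contour[1:2, ]
    h_left <- eta[4] - eta[1]
    h_right <- eta[3] - eta[2]
  } else {
    origin <- contour[which.min(eta), ]
    base <- rbind(origin + (min(xi) - sum(origin * u)) * u,
                  origin + (max(xi) - sum(origin * u)) * u)
    mid <- (min(xi) + max(xi)) / 2
    h_left <- max(eta[xi <= mid]) - min(eta)
    h_right <- max(eta[xi >= mid]) - min(eta)
  }
  if (h_left <= 0 && h_right <= 0)
    .stop_degenerate("contour has no height above its base")

  h <- max(h_left, h_right)
  ambiguous <- abs(h_left - h_right) <= height_tol * h
  out <- rbind(base[1, ], base[2, ], base[2, ] + h * v, base[1, ] + h * v)
  rownames(out) <- c("bottom-left", "bottom-right", "top-right", "top-left")
  attr(out, "convex_side") <- if (ambiguous) "ambiguous"
    else if (h_left > h_right) "left" else "right"
  attr(out, "ambiguous") <- ambiguous
  out
}

#' Apply the wedge substitution to a landmark set
#'
#' Replaces `body_quad` by the compromise parallelogram of
#' [wedge_substitute()] (base parallel to the existing base edge, which the
#' method presumes parallel to the pedicle suture) and marks the set as
#' `substituted`.
#'
#' @param x A [landmark_set()].
#' @return A `landmark_set` with the substituted body quadrilateral.
#' @export
substitute_body <- function(x) {
  stopifnot(inherits(x, "landmark_set"))
  quad <- wedge_substitute(x$body_quad,
                           suture_direction = x$body_quad[2, ] - x$body_quad[1, ])
  landmark_set(x$level, quad,
               pedicle_left_inner = if (anyNA(x$pedicle_left_inner)) NULL else x$pedicle_left_inner,
               pedicle_right_inner = if (anyNA(x$pedicle_right_inner)) NULL else x$pedicle_right_inner,
               concave_pedicle_missing = x$concave_pedicle_missing,
               substituted = TRUE,
               check_extent = FALSE)
}

# Full construction shared by measure_rotation(), plotting and SVG overlay.
.construction <- function(lm) {
  quad <- lm$body_quad
  fr <- .base_frame(quad)
  A <- body_center(quad)
  C <- base_foot(A, quad)
  B <- pedicle_midpoint(lm)
  quadrangle <- attr(B, "quadrangle")
  attr(B, "quadrangle") <- NULL
  rule <- .rule_for_level(lm$level)
  D <- if (rule == "thoracic") three_quarter_point(B, quad) else NULL
  list(frame = fr, A = A, B = B, C = C, D = D,
       pedicle_quadrangle = quadrangle, rule = rule, k = .k_for_rule(rule))
}

#' Measure axial vertebral rotation from AP landmarks
#'
#' Implements the graphical construction: the body centre A (diagonal
#' crossing of the body quadrilateral), its perpendicular foot C on the base
#' edge, and the inter-pedicle centre B (diagonal crossing of the quadrangle
#' cut by the base-perpendiculars through the pedicle inner points). For
#' L1--L4 the rotation is the angle at C between the base-perpendicular
#' through A and the line C-B (B sits at half the body height, criterion
#' x = 0.5 z). For thoracic levels and L5 the line C-D is used instead,
#' where D lies halfway between B and the top edge, i.e. at three quarters
#' of the body height (criterion x = 0.75 z).
#'
#' The angle is the exact arctangent of the constructed triangle; the
#' discrepancy a linearised d/(k z) reading would add is available
#' separately via [small_angle_error()]. The sign is positive when the
#' pedicle centre displaces toward +x of A's perpendicular in the base-edge
#' frame; the magnitude is what a protractor reading reports.
#'
#' @param x A [landmark_set()]. A pedicle flagged `concave_pedicle_missing`
#'   whose coordinate is absent is filled in by [concave_fallback()].
#' @param warn Emit a warning (class `avrot_over_limit`) when |alpha|
#'   exceeds `limit_deg`, the method's stated validity limit.
#' @param limit_deg Validity limit in degrees (default 30).
#' @return An object of class `rotation_measurement`: a list with
#'   `alpha_deg` (signed degrees), `d_mm` (offset of B from A's
#'   perpendicular, along the base edge), `z_mm` (body height used by the
#'   construction), `rule` (`"lumbar"` or `"thoracic"`), `k` (0.5 or 0.75),
#'   the construction points `A`, `B`, `C`, `D` (D `NULL` for the lumbar
#'   rule), and flags `over_limit`, `fallback_used`, `substituted`.
#' @examples
#' lm <- landmark_set("Th6",
#'   body_quad = rbind(c(-15, 0), c(15, 0), c(15, 20), c(-15, 20)),
#'   pedicle_left_inner = c(-8 + 15 * tan(pi / 180 * 21), 10),
#'   pedicle_right_inner = c(8 + 15 * tan(pi / 180 * 21), 10))
#' measure_rotation(lm)  # 21 degrees
#' @export
measure_rotation <- function(x, warn = TRUE, limit_deg = 30) {
  stopifnot(inherits(x, "landmark_set"))
  fallback_used <- FALSE
  if (x$concave_pedicle_missing != "none") {
    side_pt <- x[[paste0("pedicle_", x$concave_pedicle_missing, "_inner")]]
    if (anyNA(side_pt)) {
      x <- concave_fallback(x)
      fallback_used <- TRUE
    }
  } else if (anyNA(x$pedicle_left_inner) || anyNA(x$pedicle_right_inner)) {
    .stop_missing(sprintf(
      "vertebra %s: pedicle point absent and no concave_pedicle_missing flag set",
      x$level))
  }

  con <- .construction(x)
  fr <- con$frame
  target <- if (con$rule == "thoracic") con$D else con$B
  tf <- .to_frame(target, fr) - c(.to_frame(con$C, fr)[1], 0)
  if (tf[2] <= 0)
    .stop_degenerate("construction point does not lie above the base edge")
  alpha <- atan2(tf[1], tf[2]) * 180 / pi
  d <- .to_frame(con$B, fr)[1] - .to_frame(con$C, fr)[1]
  z <- tf[2] / con$k

  over <- abs(alpha) > limit_deg
  if (over && warn) .warn_over_limit(alpha, limit_deg)

  structure(
    list(level = x$level, rule = con$rule, k = con$k,
         alpha_deg = alpha, d_mm = d, z_mm = z,
         A = con$A, B = con$B, C = con$C, D = con$D,
         pedicle_quadrangle = con$pedicle_quadrangle,
         frame = fr, landmarks = x,
         over_limit = over, fallback_used = fallback_used,
         substituted = x$substituted),
    class = "rotation_measurement")
}

#' @export
print.rotation_measurement <- function(x, ...) {
  cat(sprintf("Axial vertebral rotation, vertebra %s (%s rule, k = %.2f)\n",
              x$level, x$rule, x$k))
  cat(sprintf("  alpha = %.2f deg   (d = %.2f mm, z = %.2f mm)\n",
              x$alpha_deg, x$d_mm, x$z_mm))
  flags <- c(if (x$over_limit) "above 30 deg validity limit",
             if (x$fallback_used) "concave pedicle taken from body contour",
             if (x$substituted) "wedge-substituted body quad")
  if (length(flags)) cat("  flags:", paste(flags, collapse = "; "), "\n")
  invisible(x)
}

#' @export
as.data.frame.rotation_measurement <- function(x, ...) {
  data.frame(vertebra = x$level, rule = x$rule,
             alpha_deg = x$alpha_deg, d_mm = x$d_mm, z_mm = x$z_mm,
             over_limit = x$over_limit, fallback_used = x$fallback_used,
             substituted = x$substituted,
             stringsAsFactors = FALSE)
}

#' Plot the measurement construction
#'
#' Draws the body outline, its diagonals, the pedicle perpendiculars and
#' quadrangle, the base-perpendicular through the body centre, and the
#' rotation line, with the construction points labelled.
#'
#' @param x A `rotation_measurement`.
#' @param ... Passed to [graphics::plot()].
#' @return `x`, invisibly.
#' @export
plot.rotation_measurement <- function(x, ...) {
  lmk <- x$landmarks
  quad <- lmk$body_quad
  pts <- rbind(quad, x$A, x$B, x$C, if (!is.null(x$D)) x$D)
  rng_x <- range(pts[, 1]); rng_y <- range(pts[, 2])
  graphics::plot(NA, xlim = rng_x + c(-5, 5), ylim = rng_y + c(-5, 5),
                 asp = 1, xlab = "x [mm]", ylab = "y [mm]",
                 main = sprintf("%s: alpha = %.2f deg", x$level, x$alpha_deg), ...)
  graphics::polygon(quad[, 1], quad[, 2], border = "black")
  graphics::segments(quad[1, 1], quad[1, 2], quad[3, 1], quad[3, 2], col = "grey50")
  graphics::segments(quad[2, 1], quad[2, 2], quad[4, 1], quad[4, 2], col = "grey50")
  qd <- x$pedicle_quadrangle
  graphics::polygon(qd[, 1], qd[, 2], border = "steelblue", lty = 2)
  graphics::segments(qd[1, 1], qd[1, 2], qd[3, 1], qd[3, 2], col = "steelblue")
  graphics::segments(qd[2, 1], qd[2, 2], qd[4, 1], qd[4, 2], col = "steelblue")
  top_A <- x$C + (x$A - x$C) * 10
  graphics::segments(x$C[1], x$C[2], top_A[1], top_A[2], col = "darkgreen")
  target <- if (is.null(x$D)) x$B else x$D
  graphics::segments(x$C[1], x$C[2], target[1], target[2], col = "firebrick", lwd = 2)
  nm <- c("A", "B", "C", if (!is.null(x$D)) "D")
  pm <- rbind(x$A, x$B, x$C, x$D)
  graphics::points(pm[, 1], pm[, 2], pch = 19)
  graphics::text(pm[, 1], pm[, 2], nm, pos = 4)
  invisible(x)
}
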