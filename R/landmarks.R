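#' Vertebral levels understood by the package
#'
#' Thoracic levels `Th1`--`Th12` and lumbar levels `L1`--`L5`.
#'
#' @return Character vector of valid level tags.
#' @export
vertebral_levels <- function() c(paste0("Th", 1:12), paste0("L", 1:5))

.check_level <- function(level) {
  if (!is.character(level) || length(level) != 1L ||
      !(level %in% vertebral_levels()))
    .stop_validation(sprintf(
      "invalid vertebral level '%s' (expected Th1-Th12 or L1-L5)",
      as.character(level)[1]))
  level
}

# Measurement rule: L1-L4 use the half-height (k = 0.5) construction, all
# thoracic levels and L5 the three-quarter-height (k = 0.75) construction.
.rule_for_level <- function(level) {
  if (level %in% paste0("L", 1:4)) "lumbar" else "thoracic"
}

.k_for_rule <- function(rule) if (rule == "lumbar") 0.5 else 0.75

.group_for_level <- function(level) {
  ifelse(grepl("^Th", level), "Thoracic",
         ifelse(level == "L5", "L5", "L1-L4"))
}

.as_point <- function(p, what = "point") {
  if (is.null(p) || (length(p) == 1L && is.na(p))) return(c(NA_real_, NA_real_))
  p <- as.numeric(unlist(p))
  if (length(p) != 2L)
    .stop_validation(sprintf("%s must have exactly 2 coordinates", what))
  p
}

.as_quad <- function(q) {
  if (is.list(q)) q <- do.call(rbind, lapply(q, .as_point, what = "body corner"))
  q <- as.matrix(q)
  storage.mode(q) <- "double"
  if (!all(dim(q) == c(4L, 2L)))
    .stop_validation("body_quad must consist of four 2-D points")
  if (!all(is.finite(q)))
    .stop_validation("body_quad coordinates must be finite")
  rownames(q) <- c("bottom-left", "bottom-right", "top-right", "top-left")
  q
}

.quad_area <- function(q) {
  i <- 1:4; j <- c(2:4, 1)
  sum(q[i, 1] * q[j, 2] - q[j, 1] * q[i, 2]) / 2
}

.segments_cross <- function(p1, p2, q1, q2) {
  hit <- .line_intersect(p1, p2 - p1, q1, q2 - q1)
  if (is.null(hit)) return(FALSE)
  eps <- 1e-12
  hit$t > eps && hit$t < 1 - eps && hit$u > eps && hit$u < 1 - eps
}

.quad_is_simple <- function(q) {
  # opposite edges must not cross: (1-2, 3-4) and (2-3, 4-1)
  !(.segments_cross(q[1, ], q[2, ], q[3, ], q[4, ]) ||
      .segments_cross(q[2, ], q[3, ], q[4, ], q[1, ]))
}

#' Landmark set for one vertebra on an AP radiograph
#'
#' Bundles the annotated landmarks the rotation measurement needs: the four
#' corners of the vertebral body projection (a simple quadrilateral given as
#' bottom-left, bottom-right, top-right, top-left), the inner-contour
#' reference point of each pedicle shadow, and bookkeeping flags.
#' Coordinates are continuous millimetres in a y-up image frame; files
#' annotated in y-down pixel frames are converted by [read_landmarks()].
#'
#' A pedicle point may be `NULL`/`NA` only when the corresponding side is
#' named in `concave_pedicle_missing`; the measurement then substitutes the
#' vertebral body contour for the hidden pedicle (see [concave_fallback()]).
#'
#' @param level Vertebral level tag, one of [vertebral_levels()].
#' @param body_quad 4 x 2 numeric matrix (or list of four points) with rows
#'   bottom-left, bottom-right, top-right, top-left.
#' @param pedicle_left_inner,pedicle_right_inner Numeric length-2 points, or
#'   `NULL`/`NA` for a hidden pedicle.
#' @param concave_pedicle_missing `"none"`, `"left"` or `"right"`: which
#'   pedicle shadow has merged with the body contour (rotation above roughly
#'   30 degrees hides the concave-side pedicle).
#' @param substituted Logical; `TRUE` when `body_quad` is a compromise
#'   rectangle/rhomboid drawn over a wedged vertebra (see
#'   [substitute_body()]).
#' @param check_extent Logical; verify that visible pedicle points lie within
#'   the body quadrilateral's extent in the base-edge frame. Annotation
#'   files are checked strictly; the simulator disables the check because a
#'   strongly rotated pedicle's true geometric position can fall outside the
#'   silhouette.
#'
#' @return An object of class `landmark_set`.
#' @examples
#' lm <- landmark_set("L2",
#'   body_quad = rbind(c(-21, 0), c(21, 0), c(21, 28), c(-21, 28)),
#'   pedicle_left_inner = c(-12, 14), pedicle_right_inner = c(12, 14))
#' measure_rotation(lm)
#' @export
landmark_set <- function(level, body_quad,
                         pedicle_left_inner = NULL,
                         pedicle_right_inner = NULL,
                         concave_pedicle_missing = c("none", "left", "right"),
                         substituted = FALSE,
                         check_extent = TRUE) {
  level <- .check_level(level)
  quad <- .as_quad(body_quad)
  concave_pedicle_missing <- match.arg(concave_pedicle_missing)
  pl <- .as_point(pedicle_left_inner, "pedicle_left_inner")
  pr <- .as_point(pedicle_right_inner, "pedicle_right_inner")

  area <- .quad_area(quad)
  if (abs(area) < 1e-9)
    .stop_validation("body_quad is degenerate (area below 1e-9 mm^2)")
  if (!.quad_is_simple(quad))
    .stop_validation("body_quad is self-intersecting")

  for (side in c("left", "right")) {
    p <- if (side == "left") pl else pr
    if (anyNA(p) && concave_pedicle_missing != side)
      .stop_validation(sprintf(
        "pedicle_%s_inner is absent but concave_pedicle_missing is '%s'",
        side, concave_pedicle_missing))
    if (!anyNA(p) && !all(is.finite(p)))
      .stop_validation(sprintf("pedicle_%s_inner must be finite", side))
  }

  obj <- structure(
    list(level = level, body_quad = quad,
         pedicle_left_inner = pl, pedicle_right_inner = pr,
         concave_pedicle_missing = concave_pedicle_missing,
         substituted = isTRUE(substituted)),
    class = "landmark_set")

  if (check_extent) .check_pedicle_extent(obj)
  obj
}

# Pedicle points must sit inside the quad's bounding box in the base-edge
# frame; a pedicle flagged as merged with the contour is exempt.
.check_pedicle_extent <- function(lm) {
  fr <- .base_frame(lm$body_quad)
  qf <- t(apply(lm$body_quad, 1, .to_frame, fr = fr))
  tol <- 1e-6 * .quad_diag(lm$body_quad) + 1e-9
  for (side in c("left", "right")) {
    p <- lm[[paste0("pedicle_", side, "_inner")]]
    if (anyNA(p) || lm$concave_pedicle_missing == side) next
    pf <- .to_frame(p, fr)
    if (pf[1] < min(qf[, 1]) - tol || pf[1] > max(qf[, 1]) + tol ||
        pf[2] < min(qf[, 2]) - tol || pf[2] > max(qf[, 2]) + tol)
      .stop_validation(sprintf(
        "pedicle_%s_inner lies outside the vertebral body extent (level %s)",
        side, lm$level))
  }
  invisible(lm)
}

#' @export
print.landmark_set <- function(x, ...) {
  cat(sprintf("AP landmark set: vertebra %s (%s rule)\n",
              x$level, .rule_for_level(x$level)))
  q <- x$body_quad
  cat(sprintf("  body quad  : (%.2f,%.2f) (%.2f,%.2f) (%.2f,%.2f) (%.2f,%.2f)\n",
              q[1, 1], q[1, 2], q[2, 1], q[2, 2], q[3, 1], q[3, 2], q[4, 1], q[4, 2]))
  fmt_p <- function(p) if (anyNA(p)) "hidden" else sprintf("(%.2f, %.2f)", p[1], p[2])
  cat(sprintf("  pedicles   : left %s, right %s\n",
              fmt_p(x$pedicle_left_inner), fmt_p(x$pedicle_right_inner)))
  if (x$concave_pedicle_missing != "none")
    cat(sprintf("  concave pedicle merged with body contour: %s\n",
                x$concave_pedicle_missing))
  if (x$substituted)
    cat("  body quad is a compromise rectangle/rhomboid (wedge substitution)\n")
  invisible(x)
}
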