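# Validation harness: recovery statistics across simulated raters, the
# analytic small-angle error table, and Nash-Moe grading as a comparator.

#' Per-group recovery statistics of a measurement series
#'
#' Bias and spread of the measurement residuals (measured - defined),
#' grouped the way spinal levels share a measurement rule: `Thoracic`,
#' `L1-L4`, `L5`, plus a pooled `All` row. The SD reported is that of the
#' residuals, not of the raw readings.
#'
#' @param x A data frame with columns `defined_alpha_deg`,
#'   `measured_alpha_deg` and `level` (as produced by [measure_series()];
#'   the shorter names `defined`/`measured` are also accepted).
#' @return A data frame of class `recovery_table` with columns `group`,
#'   `bias_deg`, `sd_deg`, `n`. Groups with no observations are omitted
#'   with a message.
#' @export
recovery_stats <- function(x) {
  x <- as.data.frame(x)
  defined <- x$defined_alpha_deg %||% x$defined
  measured <- x$measured_alpha_deg %||% x$measured
  if (is.null(defined) || is.null(measured) || is.null(x$level))
    .stop_validation("recovery_stats() needs columns defined/measured alpha and level")
  if (!nrow(x)) .stop_validation("no observations")
  resid <- measured - defined
  group <- .group_for_level(x$level)

  one <- function(g, r) data.frame(group = g, bias_deg = mean(r),
                                   sd_deg = stats::sd(r), n = length(r),
                                   stringsAsFactors = FALSE)
  rows <- list()
  for (g in c("Thoracic", "L1-L4", "L5")) {
    r <- resid[group == g]
    if (!length(r)) {
      message("recovery_stats: no observations in group '", g, "', omitted")
      next
    }
    rows[[g]] <- one(g, r)
  }
  rows[["All"]] <- one("All", resid)
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("recovery_table", "data.frame")
  out
}

#' @export
print.recovery_table <- function(x, digits = 2, ...) {
  cat("Recovery of defined rotation (residual = measured - defined)\n")
  y <- as.data.frame(x)
  y$bias_deg <- round(y$bias_deg, digits)
  y$sd_deg <- round(y$sd_deg, digits)
  print.data.frame(y, row.names = FALSE, ...)
  invisible(x)
}

#' Analytic table of the small-angle linearisation error
#'
#' Tabulates [small_angle_error()] at the requested angles, rounded to two
#' decimals for display (matching the precision the error list is usually
#' quoted at).
#'
#' @param alphas Angles in degrees, each in \[0, 90); defaults to the five
#'   canonical values 10--30.
#' @return Data frame with columns `alpha_deg` and `error_deg`.
#' @examples
#' error_table()  # 0.10, 0.35, 0.85, 1.72, 3.08
#' @export
error_table <- function(alphas = c(10, 15, 20, 25, 30)) {
  data.frame(alpha_deg = alphas,
             error_deg = round(small_angle_error(alphas), 2))
}

#' Nash-Moe rotation grade
#'
#' The classical five-level (0--4) ordinal grading of axial rotation from
#' the position of the convex-side pedicle across the vertebral width,
#' provided as a coarse comparator for the continuous measurement. The
#' convex side is identified from the direction of pedicle displacement.
#' Segment convention (the standard one): the convex hemivertebra, from its
#' lateral edge to the midline, is divided into thirds; grade 0 = pedicles
#' symmetric, grades 1--3 = convex pedicle within successive thirds toward
#' the midline, grade 4 = at or past the midline.
#'
#' @param x A [landmark_set()].
#' @param sym_tol_frac Displacement below this fraction of the body width
#'   counts as symmetric (grade 0). Default 0.02.
#' @return Integer grade 0--4.
#' @export
nash_moe_grade <- function(x, sym_tol_frac = 0.02) {
  stopifnot(inherits(x, "landmark_set"))
  if (x$concave_pedicle_missing != "none" &&
      anyNA(x[[paste0("pedicle_", x$concave_pedicle_missing, "_inner")]]))
    x <- concave_fallback(x)
  if (anyNA(x$pedicle_left_inner) || anyNA(x$pedicle_right_inner))
    .stop_missing(sprintf(
      "vertebra %s: pedicle point absent and no concave_pedicle_missing flag set",
      x$level))

  quad <- x$body_quad
  fr <- .base_frame(quad)
  xiA <- .to_frame(body_center(quad), fr)[1]
  xiL <- .to_frame(x$pedicle_left_inner, fr)[1]
  xiR <- .to_frame(x$pedicle_right_inner, fr)[1]
  width <- abs(.to_frame(quad[2, ], fr)[1] - .to_frame(quad[1, ], fr)[1])
  disp <- (xiL + xiR) / 2 - xiA
  if (abs(disp) <= sym_tol_frac * width) return(0L)

  # pedicles displace toward the concave side; the convex pedicle is the
  # one migrating toward the midline
  if (disp > 0) {   # displacement toward +x: convex side is the left
    edge <- .to_frame(quad[1, ], fr)[1]
    p <- (xiL - edge) / (xiA - edge)
  } else {
    edge <- .to_frame(quad[2, ], fr)[1]
    p <- (edge - xiR) / (edge - xiA)
  }
  if (p >= 1) return(4L)
  as.integer(1L + min(2L, max(0L, floor(3 * p))))
}
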