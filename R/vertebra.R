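# Digital analogue of the vertebral rotation device: a parametric vertebra
# whose AP projection at a known rotation yields the landmark set the
# graphical method consumes.

.model_defaults <- function(level) {
  switch(.group_for_level(level),
    "Thoracic" = list(z_mm = 20, width_mm = 30, pedicle_gap_mm = 16, ratio = 1.21),
    "L1-L4"    = list(z_mm = 28, width_mm = 42, pedicle_gap_mm = 24, ratio = 0.86),
    "L5"       = list(z_mm = 28, width_mm = 46, pedicle_gap_mm = 26, ratio = 0.86))
}

#' Parametric 3-D vertebra model
#'
#' Dimensions of the solid whose AP projection the simulator produces. The
#' pedicle rotation radius `x_mm` is the transverse-plane lever arm of the
#' inter-pedicle midpoint, x = LED/2 + SCD/2 (half lower end-plate depth
#' plus half spinal canal depth); anatomically x/z = 1.21 for thoracic
#' levels and 0.86 for L1--L4 (L5, anatomically lumbar, defaults to 0.86
#' although it is measured with the thoracic rule).
#'
#' @param level Vertebral level tag, one of [vertebral_levels()].
#' @param z_mm Posterior vertebral body height (VBHp), mm.
#' @param width_mm Vertebral body width, mm.
#' @param x_mm Pedicle rotation radius, mm; defaults to the anatomical
#'   ratio times `z_mm`.
#' @param pedicle_gap_mm Inner inter-pedicle distance, mm.
#' @param wedge_deg Wedging angle of the upper endplate, degrees
#'   (0 = no deformity); see [apply_wedge()].
#' @return An object of class `vertebra_model`.
#' @examples
#' vertebra_model("Th6", z_mm = 20)  # x = 24.2 (ratio 1.21)
#' vertebra_model("L2", z_mm = 30)   # x = 25.8 (ratio 0.86)
#' @export
vertebra_model <- function(level, z_mm = NULL, width_mm = NULL, x_mm = NULL,
                           pedicle_gap_mm = NULL, wedge_deg = 0) {
  level <- .check_level(level)
  d <- .model_defaults(level)
  z_mm <- z_mm %||% d$z_mm
  width_mm <- width_mm %||% d$width_mm
  pedicle_gap_mm <- pedicle_gap_mm %||% d$pedicle_gap_mm
  x_mm <- x_mm %||% (d$ratio * z_mm)
  vals <- c(z_mm = z_mm, width_mm = width_mm, x_mm = x_mm,
            pedicle_gap_mm = pedicle_gap_mm)
  if (any(!is.finite(vals)) || any(vals <= 0))
    .stop_validation("all vertebra dimensions must be positive and finite")
  m <- structure(
    list(level = level, z_mm = z_mm, width_mm = width_mm, x_mm = x_mm,
         pedicle_gap_mm = pedicle_gap_mm, wedge_deg = 0),
    class = "vertebra_model")
  if (wedge_deg != 0) m <- apply_wedge(m, wedge_deg) else m
}

#' Criterion-exact phantom
#'
#' A [vertebra_model()] whose rotation radius is set exactly to the
#' method's criterion, x = k z (k = 0.5 for L1--L4, 0.75 for thoracic
#' levels and L5). On this phantom the tan-model projection followed by
#' [measure_rotation()] recovers the defined rotation exactly, which makes
#' it the reference object for inversion tests.
#'
#' @inheritParams vertebra_model
#' @param ... Passed to [vertebra_model()].
#' @return A `vertebra_model` with `x_mm = k * z_mm`.
#' @export
criterion_phantom <- function(level, ...) {
  m <- vertebra_model(level, ...)
  m$x_mm <- .k_for_rule(.rule_for_level(level)) * m$z_mm
  m
}

#' @export
print.vertebra_model <- function(x, ...) {
  cat(sprintf("Vertebra model %s: z = %g mm, width = %g mm, x = %g mm (x/z = %.3f),\n",
              x$level, x$z_mm, x$width_mm, x$x_mm, x$x_mm / x$z_mm))
  cat(sprintf("  inter-pedicle gap = %g mm, wedge = %g deg\n",
              x$pedicle_gap_mm, x$wedge_deg))
  invisible(x)
}

#' Wedge the upper endplate of a vertebra model
#'
#' Tilts the upper endplate so that one lateral height is reduced while the
#' convex-side height is preserved, emulating the wedged vertebral bodies of
#' severe structural scoliotic curves. The short side is the left one in
#' the projected quadrilateral.
#'
#' @param x A [vertebra_model()].
#' @param wedge_deg Wedging angle in degrees, 0 <= wedge_deg < 30.
#' @return The modified `vertebra_model`.
#' @export
apply_wedge <- function(x, wedge_deg) {
  stopifnot(inherits(x, "vertebra_model"))
  if (!is.finite(wedge_deg) || wedge_deg < 0 || wedge_deg >= 30)
    .stop_domain("wedge_deg must lie in [0, 30) degrees")
  if (x$width_mm * tan(wedge_deg * pi / 180) >= x$z_mm)
    .stop_domain("wedge would reduce the short-side height below zero")
  x$wedge_deg <- wedge_deg
  x
}

#' Project a vertebra model to AP landmarks at a known rotation
#'
#' The body silhouette is a quadrilateral of the model's width and
#' height(s); the silhouette width is held constant under rotation (the
#' real decrease is slight and has no observable influence on the
#' width/height ratio). The pedicle inner points start symmetric about the
#' body midline at half height and are displaced horizontally by
#' d = x tan(alpha) (`"tan"`, the method's stated relation) or
#' d = x sin(alpha) (`"sin"`, the orthographic projection of a point at
#' radius x); both forward models are provided because the two disagree
#' above small angles and the measurement is agnostic to the choice.
#'
#' The concave-side pedicle is flagged `concave_pedicle_missing` when the
#' rotation exceeds `visibility_limit_deg` or when its projected inner
#' point leaves the silhouette extent (the geometric merge with the body
#' contour). The true coordinates are always recorded -- the digital device
#' knows its ground truth; set `drop_hidden = TRUE` to blank the hidden
#' pedicle's coordinates as a human annotator would, forcing
#' [concave_fallback()] at measurement time.
#'
#' @param x A [vertebra_model()].
#' @param alpha_deg Defined rotation in degrees (|alpha| < 90 for the tan
#'   model).
#' @param forward_model `"tan"` or `"sin"`.
#' @param visibility_limit_deg Rotation beyond which the concave pedicle is
#'   flagged hidden (default 30).
#' @param pedicle_height_frac Height of the pedicle inner point as a
#'   fraction of the body height (default 0.5).
#' @param drop_hidden Blank the flagged pedicle's coordinates.
#' @return A [landmark_set()] with attribute `defined_alpha_deg`.
#' @examples
#' ph <- criterion_phantom("Th6")
#' measure_rotation(project_ap(ph, 21))  # recovers 21 degrees exactly
#' @export
project_ap <- function(x, alpha_deg, forward_model = c("tan", "sin"),
                       visibility_limit_deg = 30,
                       pedicle_height_frac = 0.5,
                       drop_hidden = FALSE) {
  stopifnot(inherits(x, "vertebra_model"))
  forward_model <- match.arg(forward_model)
  if (!is.finite(alpha_deg))
    .stop_domain("alpha_deg must be finite")
  if (forward_model == "tan" && abs(alpha_deg) >= 90)
    .stop_domain("the tan forward model requires |alpha| < 90 degrees")
  a <- alpha_deg * pi / 180
  d <- if (forward_model == "tan") x$x_mm * tan(a) else x$x_mm * sin(a)

  w2 <- x$width_mm / 2
  z_right <- x$z_mm
  z_left <- x$z_mm - x$width_mm * tan(x$wedge_deg * pi / 180)
  quad <- rbind(c(-w2, 0), c(w2, 0), c(w2, z_right), c(-w2, z_left))

  eta_p <- pedicle_height_frac * x$z_mm
  pl <- c(-x$pedicle_gap_mm / 2 + d, eta_p)
  pr <- c(x$pedicle_gap_mm / 2 + d, eta_p)

  missing_side <- "none"
  concave <- if (alpha_deg > 0) "right" else if (alpha_deg < 0) "left" else "none"
  if (concave != "none") {
    ped <- if (concave == "right") pr else pl
    outside <- ped[1] < -w2 || ped[1] > w2
    if (abs(alpha_deg) > visibility_limit_deg || outside)
      missing_side <- concave
  }

  if (drop_hidden && missing_side != "none") {
    if (missing_side == "left") pl <- NULL else pr <- NULL
  }

  lm <- landmark_set(x$level, quad,
                     pedicle_left_inner = pl, pedicle_right_inner = pr,
                     concave_pedicle_missing = missing_side,
                     check_extent = FALSE)
  attr(lm, "defined_alpha_deg") <- alpha_deg
  lm
}

# Per-record seed: an explicit, documented function of (seed, rater, angle
# index) so every observation of a series is reproducible in isolation.
.record_seed <- function(seed, rater_id, angle_idx) {
  as.integer((as.numeric(seed) + 100003 * rater_id + 1009 * (angle_idx - 1)) %%
               2147483647)
}

#' Simulate a rotation-device measurement series
#'
#' The digital analogue of mounting a vertebra on the rotation device and
#' reading the full angle series: one observation per (angle, rater).
#' Rater noise is independent Gaussian jitter (SD `noise_sd_mm`, mm) added
#' to every landmark coordinate; each record's noise is seeded
#' deterministically from `(seed, rater_id, angle index)` so a series is
#' reproducible record by record, and the same standard draws are scaled by
#' `noise_sd_mm` so measurement spread is exactly monotone in the noise
#' level at a fixed seed.
#'
#' @param x A [vertebra_model()].
#' @param alphas Defined rotations in degrees; default the device's 0--45
#'   degree range in 3 degree steps.
#' @param n_raters Number of simulated raters (>= 1).
#' @param noise_sd_mm Landmark jitter SD in millimetres (>= 0).
#' @param seed Base integer seed.
#' @param ... Passed to [project_ap()] (`forward_model`,
#'   `visibility_limit_deg`, `drop_hidden`, ...).
#' @return An object of class `rotation_series`: a list of observations,
#'   each with `defined_alpha_deg`, `rater_id`, `seed` (the record seed)
#'   and `landmarks`.
#' @export
generate_series <- function(x, alphas = seq(0, 45, by = 3), n_raters = 1,
                            noise_sd_mm = 0, seed = 1L, ...) {
  stopifnot(inherits(x, "vertebra_model"))
  if (n_raters < 1) .stop_domain("n_raters must be >= 1")
  if (noise_sd_mm < 0) .stop_domain("noise_sd_mm must be >= 0")
  obs <- vector("list", length(alphas) * n_raters)
  idx <- 0L
  for (r in seq_len(n_raters)) {
    for (i in seq_along(alphas)) {
      lm <- project_ap(x, alphas[i], ...)
      rs <- .record_seed(seed, r, i)
      lm <- .perturb_landmarks(lm, noise_sd_mm, rs)
      idx <- idx + 1L
      obs[[idx]] <- list(defined_alpha_deg = alphas[i], rater_id = r,
                         seed = rs, landmarks = lm)
    }
  }
  structure(list(observations = obs, model = x,
                 params = list(alphas = alphas, n_raters = n_raters,
                               noise_sd_mm = noise_sd_mm, seed = seed)),
            class = "rotation_series")
}

.perturb_landmarks <- function(lm, noise_sd_mm, record_seed) {
  set.seed(record_seed)
  eps <- matrix(stats::rnorm(12), ncol = 2, byrow = TRUE) * noise_sd_mm
  quad <- lm$body_quad + eps[1:4, ]
  pl <- if (anyNA(lm$pedicle_left_inner)) NULL else lm$pedicle_left_inner + eps[5, ]
  pr <- if (anyNA(lm$pedicle_right_inner)) NULL else lm$pedicle_right_inner + eps[6, ]
  out <- landmark_set(lm$level, quad,
                      pedicle_left_inner = pl, pedicle_right_inner = pr,
                      concave_pedicle_missing = lm$concave_pedicle_missing,
                      substituted = lm$substituted,
                      check_extent = FALSE)
  attr(out, "defined_alpha_deg") <- attr(lm, "defined_alpha_deg")
  out
}

#' @export
print.rotation_series <- function(x, ...) {
  p <- x$params
  cat(sprintf("Rotation-device series: %s, %d angles x %d rater(s), noise SD %g mm, seed %s\n",
              x$model$level, length(p$alphas), p$n_raters, p$noise_sd_mm, p$seed))
  invisible(x)
}

#' @rdname generate_series
#' @param object A `vertebra_model`.
#' @param nsim Number of simulated raters (passed as `n_raters`).
#' @export
simulate.vertebra_model <- function(object, nsim = 1, seed = 1L, ...) {
  generate_series(object, n_raters = nsim, seed = seed %||% 1L, ...)
}

#' Measure every observation of a simulated series
#'
#' @param series A [generate_series()] result.
#' @param warn Passed to [measure_rotation()] (default `FALSE`: above-limit
#'   observations are recorded in the `over_limit` column instead of
#'   warning once per record).
#' @return A data frame with one row per observation: `defined_alpha_deg`,
#'   `measured_alpha_deg`, `level`, `group`, `rater_id`, `seed`,
#'   `over_limit`, `fallback_used`.
#' @export
measure_series <- function(series, warn = FALSE) {
  stopifnot(inherits(series, "rotation_series"))
  rows <- lapply(series$observations, function(ob) {
    m <- measure_rotation(ob$landmarks, warn = warn)
    data.frame(defined_alpha_deg = ob$defined_alpha_deg,
               measured_alpha_deg = m$alpha_deg,
               level = ob$landmarks$level,
               group = .group_for_level(ob$landmarks$level),
               rater_id = ob$rater_id, seed = ob$seed,
               over_limit = m$over_limit, fallback_used = m$fallback_used,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
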