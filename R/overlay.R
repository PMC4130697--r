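# SVG overlay of the graphical construction: the numbered steps of the
# procedure (1 body outline, 2 body diagonals, 3 pedicle perpendiculars,
# 4 pedicle quadrangle and its diagonals, 5 base-perpendicular through the
# body centre, 6 rotation line C-B for the lumbar rule / 7 rotation line
# C-D for the thoracic rule) plus labelled points A, B, C (and D).

.svg_num <- function(x) formatC(x, format = "fg", digits = 6)

#' Render the measurement construction as an SVG overlay
#'
#' @param result A `rotation_measurement` (from [measure_rotation()]).
#' @param path Output path for the SVG file.
#' @return `path`, invisibly.
#' @export
render_overlay <- function(result, path) {
  stopifnot(inherits(result, "rotation_measurement"))
  lm <- result$landmarks
  quad <- lm$body_quad
  qd <- result$pedicle_quadrangle
  pts <- rbind(quad, qd, result$A, result$B, result$C,
               if (!is.null(result$D)) result$D)
  pad <- 8
  x0 <- min(pts[, 1]) - pad; x1 <- max(pts[, 1]) + pad
  y0 <- min(pts[, 2]) - pad; y1 <- max(pts[, 2]) + pad
  # image frame is y-up; SVG is y-down
  Y <- function(y) y1 + y0 - y
  P <- function(p) sprintf("%s,%s", .svg_num(p[1]), .svg_num(Y(p[2])))
  seg <- function(a, b, cls, style) sprintf(
    '<line class="%s" x1="%s" y1="%s" x2="%s" y2="%s" style="%s"/>',
    cls, .svg_num(a[1]), .svg_num(Y(a[2])), .svg_num(b[1]), .svg_num(Y(b[2])), style)
  poly <- function(m, cls, style) sprintf(
    '<polygon class="%s" points="%s" style="%s"/>',
    cls, paste(apply(m, 1, P), collapse = " "), style)
  marker <- function(p, label) c(
    sprintf('<circle class="construction-point" cx="%s" cy="%s" r="0.8" style="fill:black"/>',
            .svg_num(p[1]), .svg_num(Y(p[2]))),
    sprintf('<text class="construction-label" x="%s" y="%s" font-size="4">%s</text>',
            .svg_num(p[1] + 1.2), .svg_num(Y(p[2]) - 1.2), label))

  fr <- result$frame
  perp_through <- function(p) {
    h <- max(y1 - y0, x1 - x0)
    list(a = p - fr$v * h, b = p + fr$v * h)
  }
  pA <- perp_through(result$C)
  thin <- "stroke:grey;stroke-width:0.3;fill:none"
  body <- "stroke:black;stroke-width:0.6;fill:none"
  accent <- "stroke:firebrick;stroke-width:0.6;fill:none"

  steps <- list()
  steps[["step-1"]] <- poly(quad, "body-outline", body)
  steps[["step-2"]] <- c(seg(quad[1, ], quad[3, ], "body-diagonal", thin),
                         seg(quad[2, ], quad[4, ], "body-diagonal", thin))
  steps[["step-3"]] <- c(seg(qd[1, ], qd[4, ], "pedicle-perpendicular", thin),
                         seg(qd[2, ], qd[3, ], "pedicle-perpendicular", thin))
  steps[["step-4"]] <- c(poly(qd, "pedicle-quadrangle", thin),
                         seg(qd[1, ], qd[3, ], "pedicle-diagonal", thin),
                         seg(qd[2, ], qd[4, ], "pedicle-diagonal", thin))
  steps[["step-5"]] <- seg(pA$a, pA$b, "center-perpendicular",
                           "stroke:darkgreen;stroke-width:0.5;fill:none")
  if (result$rule == "lumbar") {
    steps[["step-6"]] <- seg(result$C, result$B, "rotation-line", accent)
  } else {
    steps[["step-7"]] <- seg(result$C, result$D, "rotation-line", accent)
  }

  labels <- c(marker(result$A, "A"), marker(result$B, "B"), marker(result$C, "C"),
              if (!is.null(result$D)) marker(result$D, "D"))

  groups <- vapply(names(steps), function(nm) paste0(
    sprintf('<g class="%s">', nm), paste(steps[[nm]], collapse = ""), "</g>"),
    character(1))

  svg <- c(
    '<?xml version="1.0" encoding="UTF-8"?>',
    sprintf('<svg xmlns="http://www.w3.org/2000/svg" viewBox="%s %s %s %s" width="%smm" height="%smm">',
            .svg_num(x0), .svg_num(y0), .svg_num(x1 - x0), .svg_num(y1 - y0),
            .svg_num(x1 - x0), .svg_num(y1 - y0)),
    sprintf('<title>%s: alpha = %.2f deg (%s rule)</title>',
            result$level, result$alpha_deg, result$rule),
    groups,
    sprintf('<g class="points">%s</g>', paste(labels, collapse = "")),
    "</svg>")
  ok <- tryCatch({ writeLines(svg, path); TRUE },
                 error = function(e) FALSE)
  if (!ok) .stop_io(sprintf("cannot write overlay to %s", path))
  invisible(path)
}
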