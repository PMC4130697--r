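# Independent oracles and generators used to freeze expected values.

# intersection of the infinite lines p1-p2 and q1-q2 via a 2x2 linear solve
oracle_line_point <- function(p1, p2, q1, q2) {
  A <- cbind(p2 - p1, -(q2 - q1))
  t <- solve(A, q1 - p1)
  unname(p1 + t[1] * (p2 - p1))
}

oracle_diag_intersection <- function(quad) {
  oracle_line_point(quad[1, ], quad[3, ], quad[2, ], quad[4, ])
}

rot2 <- function(theta) {
  matrix(c(cos(theta), sin(theta), -sin(theta), cos(theta)), 2, 2)
}

# rigid motion + uniform scaling of a whole landmark set
transform_landmarks <- function(lm, scale = 1, theta = 0, shift = c(0, 0)) {
  R <- rot2(theta)
  tp <- function(p) {
    if (anyNA(p)) return(NULL)
    as.numeric(R %*% (scale * p) + shift)
  }
  quad <- t(apply(lm$body_quad, 1, function(p) as.numeric(R %*% (scale * p) + shift)))
  landmark_set(lm$level, quad,
               pedicle_left_inner = tp(lm$pedicle_left_inner),
               pedicle_right_inner = tp(lm$pedicle_right_inner),
               concave_pedicle_missing = lm$concave_pedicle_missing,
               substituted = lm$substituted)
}

# reflection about the base-perpendicular through the body centre A
mirror_landmarks <- function(lm) {
  quad <- lm$body_quad
  u <- quad[2, ] - quad[1, ]
  u <- u / sqrt(sum(u * u))
  A <- body_center(quad)
  refl <- function(p) p - 2 * sum((p - A) * u) * u
  q2 <- rbind(refl(quad[2, ]), refl(quad[1, ]), refl(quad[4, ]), refl(quad[3, ]))
  flip <- c(none = "none", left = "right", right = "left")
  landmark_set(lm$level, q2,
               pedicle_left_inner = refl(lm$pedicle_right_inner),
               pedicle_right_inner = refl(lm$pedicle_left_inner),
               concave_pedicle_missing = unname(flip[lm$concave_pedicle_missing]),
               substituted = lm$substituted)
}

# valid random landmark set (simple quad, pedicles inside the extent),
# placed at a random pose in the image frame
random_landmark_set <- function() {
  level <- sample(vertebral_levels(), 1)
  w <- runif(1, 24, 44)
  hl <- runif(1, 16, 30)
  hr <- hl * runif(1, 0.92, 1.08)
  s_top <- runif(1, -2, 2)
  quad <- rbind(c(-w / 2, 0), c(w / 2, 0),
                c(w / 2 + s_top, hr), c(-w / 2 + s_top, hl))
  h <- min(hl, hr)
  d <- runif(1, -0.15, 0.15) * w
  pl <- c(runif(1, -0.32, -0.08) * w + d, runif(1, 0.3, 0.7) * h)
  pr <- c(runif(1, 0.08, 0.32) * w + d, runif(1, 0.3, 0.7) * h)
  lm <- landmark_set(level, quad, pl, pr)
  transform_landmarks(lm, scale = 1, theta = runif(1, -pi, pi),
                      shift = runif(2, -50, 50))
}

# rectangle-body landmark set with a prescribed pedicle-centre offset d
rect_landmarks <- function(level, w, z, d, gap = 0.5 * w, ped_h = 0.5 * z) {
  landmark_set(level,
               rbind(c(-w / 2, 0), c(w / 2, 0), c(w / 2, z), c(-w / 2, z)),
               pedicle_left_inner = c(-gap / 2 + d, ped_h),
               pedicle_right_inner = c(gap / 2 + d, ped_h),
               check_extent = FALSE)
}
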