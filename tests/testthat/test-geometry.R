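test_that("diagonal intersection matches symmetry and the linear-solve oracle", {
  expect_equal(intersect_diagonals(rbind(c(0, 0), c(1, 0), c(1, 1), c(0, 1))),
               c(0.5, 0.5))
  expect_equal(intersect_diagonals(rbind(c(0, 0), c(4, 0), c(4, 2), c(0, 2))),
               c(2, 1))
  q <- rbind(c(0, 0), c(4, 0), c(3, 2), c(1, 2))
  expect_equal(intersect_diagonals(q), oracle_diag_intersection(q))
  expect_equal(intersect_diagonals(q), c(2, 4 / 3))
})

test_that("degenerate quadrilaterals are rejected with a geometry error", {
  flat <- rbind(c(0, 0), c(1, 0), c(2, 0), c(3, 0))
  expect_error(intersect_diagonals(flat), class = "avrot_degenerate_geometry")
})

test_that("body centre is the diagonal crossing and drifts toward a wedge apex", {
  rect <- rbind(c(-10, 0), c(10, 0), c(10, 24), c(-10, 24))
  expect_equal(body_center(rect)[1], 0)
  rhomboid <- rbind(c(0, 0), c(30, 0), c(34, 24), c(4, 24))
  expect_equal(body_center(rhomboid), c(17, 12))
  expect_equal(body_center(rhomboid), oracle_diag_intersection(rhomboid))
  # wedged body, short (apex) side on the left: centre pulled left of the
  # base midpoint
  wedged <- rbind(c(-15, 0), c(15, 0), c(15, 20), c(-15, 14))
  expect_lt(body_center(wedged)[1], 0)
})

test_that("pedicle midpoint: closed form on rectangles, oracle on slanted quads", {
  lm <- landmark_set("L2", rbind(c(-20, 0), c(20, 0), c(20, 30), c(-20, 30)),
                     c(-8, 14), c(12, 16))
  expect_equal(pedicle_midpoint(lm), c(2, 15), ignore_attr = TRUE)

  sym <- landmark_set("L2", rbind(c(-20, 0), c(20, 0), c(20, 30), c(-20, 30)),
                      c(-9, 15), c(9, 15))
  expect_equal(pedicle_midpoint(sym), c(0, 15), ignore_attr = TRUE)

  # slanted top edge: brute-force the constructed quadrangle with the oracle
  quad <- rbind(c(-20, 0), c(20, 0), c(22, 31), c(-18, 27))
  lm2 <- landmark_set("Th8", quad, c(-7, 13), c(9, 15))
  corners <- function(p) {
    bot <- oracle_line_point(p, p + c(0, 1), quad[1, ], quad[2, ])
    top <- oracle_line_point(p, p + c(0, 1), quad[4, ], quad[3, ])
    rbind(bot, top)
  }
  lh <- corners(c(-7, 13)); rh <- corners(c(9, 15))
  expected <- oracle_diag_intersection(rbind(lh[1, ], rh[1, ], rh[2, ], lh[2, ]))
  expect_equal(pedicle_midpoint(lm2), expected, ignore_attr = TRUE,
               tolerance = 1e-12)
})

test_that("base foot is the perpendicular projection on the (extended) base", {
  rect <- rbind(c(0, 0), c(4, 0), c(4, 2), c(0, 2))
  expect_equal(base_foot(c(2, 1), rect), c(2, 0))
  expect_equal(base_foot(c(3, 0), rect), c(3, 0))  # point already on the base

  theta <- 10 * pi / 180
  quad <- t(apply(rect, 1, function(p) as.numeric(rot2(theta) %*% p)))
  A <- as.numeric(rot2(theta) %*% c(2, 1.3))
  C <- base_foot(A, quad)
  # |AC| equals the point-line distance to the base line
  b1 <- quad[1, ]; b2 <- quad[2, ]
  dist <- abs((b2[1] - b1[1]) * (b1[2] - A[2]) - (b1[1] - A[1]) * (b2[2] - b1[2])) /
    sqrt(sum((b2 - b1)^2))
  expect_equal(sqrt(sum((A - C)^2)), dist, tolerance = 1e-12)
  expect_equal(sum((C - b1) * c(-(b2 - b1)[2], (b2 - b1)[1])), 0, tolerance = 1e-9)
})

test_that("three-quarter point halves the distance from B to the top edge", {
  rect <- rbind(c(-20, 0), c(20, 0), c(20, 40), c(-20, 40))
  expect_equal(three_quarter_point(c(5, 20), rect), c(5, 30))
  expect_equal(three_quarter_point(c(5, 40), rect), c(5, 40))  # B on the top edge

  quad <- rbind(c(-20, 0), c(20, 0), c(24, 42), c(-16, 36))
  B <- c(3, 19)
  top <- oracle_line_point(B, B + c(0, 1), quad[4, ], quad[3, ])
  expect_equal(three_quarter_point(B, quad), (B + top) / 2, tolerance = 1e-12)
})

test_that("measured angle follows the closed form atan(d / (k z))", {
  # perfectly symmetric landmarks
  expect_equal(measure_rotation(rect_landmarks("L3", 40, 30, 0))$alpha_deg, 0)

  d_lum <- 15 * tan(20 * pi / 180)
  m <- measure_rotation(rect_landmarks("L3", 40, 30, d_lum))
  expect_equal(m$alpha_deg, 20, tolerance = 1e-9)
  expect_equal(m$rule, "lumbar")
  expect_equal(m$k, 0.5)
  expect_equal(m$d_mm, d_lum, tolerance = 1e-12)
  expect_equal(m$z_mm, 30, tolerance = 1e-12)
  expect_null(m$D)

  d_th <- 30 * tan(21 * pi / 180)
  mt <- measure_rotation(rect_landmarks("Th6", 44, 40, d_th))
  expect_equal(mt$alpha_deg, 21, tolerance = 1e-9)
  expect_equal(mt$rule, "thoracic")
  expect_equal(mt$k, 0.75)
  expect_false(is.null(mt$D))

  # L5 is measured with the thoracic rule
  m5 <- measure_rotation(rect_landmarks("L5", 44, 40, d_th))
  expect_equal(m5$rule, "thoracic")
  expect_equal(m5$alpha_deg, 21, tolerance = 1e-9)

  # sign convention: pedicle centre toward -x gives a negative angle
  mn <- measure_rotation(rect_landmarks("L3", 40, 30, -d_lum))
  expect_equal(mn$alpha_deg, -20, tolerance = 1e-9)
})

test_that("rotations above the validity limit are flagged, not fatal", {
  d <- 15 * tan(36 * pi / 180)
  expect_warning(m <- measure_rotation(rect_landmarks("L3", 44, 30, d)),
                 class = "avrot_over_limit")
  expect_true(m$over_limit)
  expect_equal(m$alpha_deg, 36, tolerance = 1e-9)
  expect_silent(m2 <- measure_rotation(rect_landmarks("L3", 44, 30, d), warn = FALSE))
  expect_true(m2$over_limit)
})

test_that("a pedicle absent without the concave flag is a missing-landmark error", {
  quad <- rbind(c(-15, 0), c(15, 0), c(15, 20), c(-15, 20))
  expect_error(landmark_set("Th6", quad, pedicle_left_inner = NULL,
                            pedicle_right_inner = c(8, 10)),
               class = "avrot_validation_error")
  lm <- landmark_set("Th6", quad, c(-8, 10), c(8, 10))
  lm$pedicle_right_inner <- c(NA_real_, NA_real_)
  expect_error(measure_rotation(lm), class = "avrot_missing_landmark")
})

test_that("small-angle linearisation error matches the canonical values and is increasing", {
  expect_equal(small_angle_error(0), 0)
  expect_equal(round(small_angle_error(c(10, 15, 20, 25, 30)), 2),
               c(0.10, 0.35, 0.85, 1.72, 3.08))
  grid <- seq(0.5, 89.5, by = 0.5)
  expect_true(all(diff(small_angle_error(grid)) > 0))
  expect_error(small_angle_error(90), class = "avrot_domain_error")
  expect_error(small_angle_error(-1), class = "avrot_domain_error")
})
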