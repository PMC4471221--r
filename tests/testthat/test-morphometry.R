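test_that("polyline_length sums Euclidean segments and rejects short input", {
  expect_equal(polyline_length(rbind(c(0, 0, 0), c(3, 4, 0))), 5)
  expect_equal(polyline_length(rbind(c(0, 0, 0), c(1, 0, 0), c(1, 1, 0))), 2)
  expect_error(polyline_length(rbind(c(0, 0, 0))), class = "invalid_input")
})

test_that("polyline_length matches quadrature arc length on a dense spiral", {
  g <- generate_spiral_landmarks(2.5, 2.0, 0.8, points_per_turn = 240)
  expect_equal(polyline_length(g$path), g$truth$params$ecl,
               tolerance = 0.002)
})

test_that("polyline_length is rigid-motion invariant", {
  g <- generate_spiral_landmarks(2.2, 1.8, 0.9, points_per_turn = 100,
                                 axial_rise = 0.2)
  len0 <- polyline_length(g$path)
  set.seed(11)
  for (i in 1:5) {
    R <- rot_xyz(runif(1, 0, pi), runif(1, 0, pi), runif(1, 0, pi))
    moved <- unclass(g$path) %*% t(R) +
      matrix(runif(3, -9, 9), nrow(g$path), 3, byrow = TRUE)
    expect_equal(polyline_length(moved), len0, tolerance = 1e-9)
  }
})

test_that("spiral_center recovers circle centers and rejects degeneracy", {
  p <- landmark_path(circle_path(1, 1, 100), role = "spiral")
  ctr <- spiral_center(p)
  expect_lt(sqrt(sum(ctr$center_A^2)), 1e-9)

  set.seed(42)
  noisy <- circle_path(1, 1, 100) + matrix(rnorm(300, 0, 0.01), 100, 3)
  ctr_n <- spiral_center(landmark_path(noisy, role = "spiral"))
  expect_lt(sqrt(sum(ctr_n$center_A^2)), 0.02)
  # agrees with the algebraic least-squares circle fit oracle
  oracle <- kasa_circle_center(noisy[, 1:2])
  expect_lt(sqrt(sum((ctr_n$center_A[1:2] - oracle)^2)), 0.02)

  line <- cbind(seq(0, 1, length.out = 10), 0, 0)
  expect_error(spiral_center(landmark_path(line, role = "spiral")),
               class = "singular_geometry")
})

test_that("fit_turn_circles: fixed-center least-squares radii", {
  p <- landmark_path(circle_path(2, 1.2, 150), role = "spiral")
  g <- fit_turn_circles(p, spiral_center(p))
  expect_equal(g$R1, 2, tolerance = 1e-9)
  expect_equal(g$R2, 2, tolerance = 1e-9)

  # two concentric half circles (radius 2 then 1) forming one path
  th1 <- seq(0, pi, length.out = 101)[-101]
  th2 <- seq(pi, 2 * pi, length.out = 101)
  pts <- rbind(cbind(2 * cos(th1), 2 * sin(th1), 0),
               cbind(cos(th2), sin(th2), 0))
  g2 <- fit_turn_circles(landmark_path(pts, role = "spiral"), c(0, 0, 0))
  expect_equal(g2$R1, 1, tolerance = 1e-9)
  expect_equal(g2$R2, 2, tolerance = 1e-9)

  half <- landmark_path(circle_path(1, 0.5, 60), role = "spiral")
  expect_error(fit_turn_circles(half, c(0, 0, 0)),
               class = "insufficient_turns")
})

test_that("fit_turn_circles ratio matches generator truth at the true center", {
  g <- generate_spiral_landmarks(2.5, 2.0, 0.8, points_per_turn = 240)
  geo <- fit_turn_circles(g$path, g$truth$params$center)
  expect_equal(geo$R2 / geo$R1, g$truth$params$cur_expected_measured,
               tolerance = 0.02)
})

test_that("count_turns counts signed sweep in either winding direction", {
  semi <- landmark_path(circle_path(1, 0.5, 50), role = "spiral")
  expect_equal(count_turns(semi, c(0, 0, 0)), 0.5, tolerance = 1e-9)
  one_half <- landmark_path(circle_path(1, 1.5, 200), role = "spiral")
  expect_equal(count_turns(one_half, c(0, 0, 0)), 1.5, tolerance = 1e-9)
  # reversed winding
  rev_path <- landmark_path(circle_path(1, 1.5, 200)[200:1, ],
                            role = "spiral", start = "apex")
  expect_equal(count_turns(rev_path, c(0, 0, 0)), 1.5, tolerance = 1e-9)

  g <- generate_spiral_landmarks(2.7, 2.0, 0.8, points_per_turn = 185,
                                 seed = 9)
  expect_equal(count_turns(g$path, spiral_center(g$path)), 2.7,
               tolerance = 0.01 / 2.7)

  at_center <- landmark_path(rbind(c(0, 0, 0), c(1, 0, 0), c(1, 1, 0),
                                   c(0, 1, 0)), role = "spiral")
  expect_error(count_turns(at_center, c(0, 0, 0)),
               class = "undefined_angle")
})

test_that("curvature_gradient is the radius ratio with validation", {
  expect_equal(curvature_gradient(1, 1), 1)
  expect_equal(curvature_gradient(1, 2), 2)
  expect_error(curvature_gradient(0, 1), class = "invalid_input")
  expect_error(curvature_gradient(1, -1), class = "invalid_input")
})

test_that("oval_window_area: planar polygon area on the best-fit plane", {
  sq <- landmark_path(rbind(c(0, 0, 0), c(1, 0, 0), c(1, 0.5, 0),
                            c(1, 1, 0), c(0, 1, 0)), role = "window")
  expect_equal(oval_window_area(sq), 1, tolerance = 1e-12)

  circ <- generate_window_outline(1, 1, 360)
  expect_equal(oval_window_area(circ$path), pi, tolerance = 0.001)

  flat <- generate_window_outline(2, 1, 200, plane_tilt = 0)
  tilted <- generate_window_outline(2, 1, 200, plane_tilt = 40)
  expect_equal(oval_window_area(tilted$path), oval_window_area(flat$path),
               tolerance = 1e-9)

  bowtie <- landmark_path(rbind(c(0, 0, 0), c(1, 1, 0), c(1, 0, 0),
                                c(0, 1, 0), c(-0.5, 0.5, 0)),
                          role = "window")
  expect_error(oval_window_area(bowtie), class = "invalid_outline")
})

test_that("measure_cochlea combines components; missing outline -> OWA NA", {
  p <- landmark_path(circle_path(1, 1.5, 400), role = "spiral")
  m <- measure_cochlea(p)
  expect_equal(m$tur, 1.5, tolerance = 1e-6)
  expect_equal(m$cur, 1, tolerance = 1e-6)
  expect_equal(m$ecl, 1.5 * 2 * pi, tolerance = 1e-4)
  expect_equal(m$recl, m$ecl / m$tur)
  expect_true(is.na(m$owa))

  w <- generate_window_outline(1.5, 0.9, 240)
  m2 <- measure_cochlea(p, w$path)
  expect_equal(m2$owa, pi * 1.5 * 0.9, tolerance = 1e-3)
})

test_that("measurements respect scaling and path-reversal invariances", {
  g <- generate_spiral_landmarks(2.4, 2.0, 0.9, points_per_turn = 150,
                                 axial_rise = 0.25)
  m <- measure_cochlea(g$path)
  s <- 3.7
  scaled <- landmark_path(unclass(g$path) * s, role = "spiral")
  ms <- measure_cochlea(scaled)
  expect_equal(ms$tur, m$tur, tolerance = 1e-9)
  expect_equal(ms$cur, m$cur, tolerance = 1e-9)
  expect_equal(ms$ecl, s * m$ecl, tolerance = 1e-9)

  w <- generate_window_outline(1.5, 0.9, 240)
  ws <- landmark_path(unclass(w$path) * s, role = "window")
  expect_equal(oval_window_area(ws), s^2 * oval_window_area(w$path),
               tolerance = 1e-9)

  revd <- landmark_path(unclass(g$path)[nrow(g$path):1, ],
                        role = "spiral", start = "apex")
  mr <- measure_cochlea(revd)
  expect_equal(mr$ecl, m$ecl, tolerance = 1e-12)
  expect_equal(mr$tur, m$tur, tolerance = 1e-9)
  expect_equal(mr$cur, m$cur, tolerance = 1e-6)
})

test_that("reporting rounds half away from zero, stats stay full precision", {
  df <- report_measurements(data.frame(ECL = 20.25, TUR = -0.25,
                                       CUR = 2.449, RECL = 8.1 / 0.9,
                                       OWA = 3.725))
  expect_equal(df$ECL, 20.3)
  expect_equal(df$TUR, -0.3)
  expect_equal(df$CUR, 2.4)
  expect_equal(df$OWA, 3.73)

  p <- landmark_path(circle_path(1, 1.5, 400), role = "spiral")
  m <- measure_cochlea(p)
  expect_equal(m$recl, m$ecl / m$tur)  # RECL from unrounded parts
})
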