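# path length with via points and wrapping

test_that("straight and collinear-via paths equal the chord length", {
  g <- default_geom()
  b <- list(name = "x", femur = c(0, 0, 0), tibia = c(0, -30, 0),
            via = NULL, wrap = NA)
  expect_equal(path_length(b, g, pose6()), 30)
  b$via <- list(list(point = c(0, -15, 0), body = "femur"))
  expect_equal(path_length(b, g, pose6()), 30)
})

test_that("sphere wrap matches an independent geodesic oracle and is continuous", {
  g <- default_geom()
  # chord passing 1 mm inside a 10 mm sphere
  center <- c(0, -20, 0); radius <- 10
  a <- c(-30, -11, 0); b2 <- c(30, -11, 0)
  g$wrap_objects$test_sphere <- list(name = "test_sphere", shape = "sphere",
                                     center = center, radius = radius,
                                     body = "femur")
  bund <- list(name = "w", femur = a, tibia = b2, via = NULL,
               wrap = "test_sphere")
  got <- path_length(bund, g, pose6())
  chord <- sqrt(sum((b2 - a)^2))
  expect_gt(got, chord)

  # oracle: numeric minimisation of A -> P1 (circle) + arc + P2 -> B in the
  # plane through A, B and the centre (all z = 0 here), with a feasibility
  # penalty keeping the straight legs outside the circle
  seg_clearance <- function(p, q) {
    pq <- q - p
    t <- max(0, min(1, sum((center[1:2] - p) * pq) / sum(pq^2)))
    sqrt(sum((p + t * pq - center[1:2])^2))
  }
  path_len <- function(th) {
    p1 <- center[1:2] + radius * c(cos(th[1]), sin(th[1]))
    p2 <- center[1:2] + radius * c(cos(th[2]), sin(th[2]))
    arc <- radius * abs(th[2] - th[1])
    pen <- 1e4 * (max(0, radius - seg_clearance(a[1:2], p1))^2 +
                    max(0, radius - seg_clearance(p2, b2[1:2]))^2)
    sqrt(sum((p1 - a[1:2])^2)) + arc + sqrt(sum((p2 - b2[1:2])^2)) + pen
  }
  opt <- stats::optim(c(2.2, 0.9), path_len, method = "Nelder-Mead",
                      control = list(reltol = 1e-15, maxit = 20000))
  expect_equal(got, opt$value, tolerance = 1e-6)

  # continuity across wrap engagement: sweep the chord height through the
  # tangency and check for jumps
  heights <- seq(-10.5, -9.5, by = 0.01)
  lens <- vapply(heights, function(h) {
    bb <- bund; bb$femur[2] <- h; bb$tibia[2] <- h
    path_length(bb, g, pose6())
  }, 0)
  expect_lt(max(abs(diff(lens))), 0.05)
  expect_true(all(diff(lens) <= 1e-9))  # shallower chord, shorter wrap
})

test_that("cylinder wrap exceeds the chord and unrolls the axial travel", {
  g <- default_geom()
  g$wrap_objects$test_cyl <- list(name = "test_cyl", shape = "cylinder",
                                  center = c(0, -20, 0), axis = c(0, 0, 1),
                                  radius = 10, body = "femur")
  bund <- list(name = "w", femur = c(-30, -11, -5), tibia = c(30, -11, 5),
               via = NULL, wrap = "test_cyl")
  got <- path_length(bund, g, pose6())
  chord <- sqrt(sum((c(60, 0, 10))^2))
  expect_gt(got, chord)
  # unrolled geodesic: sqrt(planar_wrapped^2 + dz^2), planar length from the
  # same 2-D oracle as the sphere case
  center <- c(0, -20); radius <- 10; a <- c(-30, -11); b2 <- c(30, -11)
  seg_clearance <- function(p, q) {
    pq <- q - p
    t <- max(0, min(1, sum((center - p) * pq) / sum(pq^2)))
    sqrt(sum((p + t * pq - center)^2))
  }
  path_len <- function(th) {
    p1 <- center + radius * c(cos(th[1]), sin(th[1]))
    p2 <- center + radius * c(cos(th[2]), sin(th[2]))
    pen <- 1e4 * (max(0, radius - seg_clearance(a, p1))^2 +
                    max(0, radius - seg_clearance(p2, b2))^2)
    sqrt(sum((p1 - a)^2)) + radius * abs(th[2] - th[1]) +
      sqrt(sum((p2 - b2)^2)) + pen
  }
  opt <- stats::optim(c(2.2, 0.9), path_len, method = "Nelder-Mead",
                      control = list(reltol = 1e-15, maxit = 20000))
  expect_equal(got, sqrt(opt$value^2 + 100), tolerance = 1e-6)
})

test_that("attachment inside a wrap object raises a geometry error", {
  g <- default_geom()
  g$wrap_objects$test_sphere <- list(name = "test_sphere", shape = "sphere",
                                     center = c(0, -20, 0), radius = 10,
                                     body = "femur")
  bund <- list(name = "w", femur = c(0, -18, 0), tibia = c(0, -60, 0),
               via = NULL, wrap = "test_sphere")
  expect_error(path_length(bund, g, pose6()), "inside wrap")
})

test_that("path length is continuous in pose on the placed specimen", {
  g <- default_geom()
  m <- intact_model()
  poses <- seq(0, 100, by = 1)
  for (nm in c("aMCL", "iMCL", "pMCL", "LCL")) {
    lens <- vapply(poses, function(f)
      path_length(m$bundles[[nm]], g, pose6(flex = f)), 0)
    expect_lt(max(abs(diff(lens))), 1.0, label = nm)  # < 1 mm per degree
  }
})
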