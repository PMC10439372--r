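test_that("glenoid frames are orthonormal and inclination rotations invert", {
  fr <- glenoid_frame(c(0.1, 1.4, 0.17), c(0.1, 1.451, 0.17))
  M <- cbind(fr$x_axis, fr$y_axis, fr$z_axis)
  expect_equal(crossprod(M), diag(3), tolerance = 1e-12)

  f0 <- incline_glenoid(fr, 0)
  expect_equal(f0$y_axis, fr$y_axis, tolerance = 1e-12)

  f1 <- incline_glenoid(fr, 0.7)
  expect_equal(f1$centroid, fr$centroid)                    # centroid preserved
  expect_equal(f1$x_axis, fr$x_axis, tolerance = 1e-12)     # x axis preserved
  M1 <- cbind(f1$x_axis, f1$y_axis, f1$z_axis)
  expect_equal(crossprod(M1), diag(3), tolerance = 1e-9)

  back <- incline_glenoid(f1, -0.7)
  expect_equal(back$superior_point, fr$superior_point, tolerance = 1e-9)
})

test_that("a 0.9 cm landmark shift on the calibrated arm inclines 10 degrees", {
  d <- glenoid_superior_distance(0.3)       # 3 sd / tan(10 deg)
  expect_equal(d, 0.05104, tolerance = 1e-4)
  fr <- glenoid_frame(c(0, 0, 0), c(0, d, 0))
  f1 <- incline_glenoid(fr, 0.9)
  ang <- rad2deg(acos(sum(f1$y_axis * fr$y_axis)))
  expect_equal(ang, 10, tolerance = 1e-6)
})

test_that("attachment perturbation is mean + sd * draw with clamping counted", {
  m <- c(-0.1, 0.3, 0.6); s <- c(0.01, 0.035, 0.035)
  expect_equal(perturb_attachment(m, s, c(0, 0, 0)), m)
  expect_equal(perturb_attachment(m, s, c(1, 1, 1)), m + s)
  expect_error(perturb_attachment(m, -s, c(0, 0, 0)), "SD")

  reset_clamp_counter()
  out <- perturb_attachment(c(0.99, 0, 0), c(0.05, 0.01, 0.01), c(3, 0, 0))
  expect_equal(out[1], 1)                  # clamped to the bone bound
  expect_equal(clamp_counter(), 1L)
  reset_clamp_counter()

  ## sample SD of each axis within 2% of specification at n = 1e5
  set.seed(99)
  draws <- matrix(stats::rnorm(3e5), ncol = 3)
  pert <- t(apply(draws, 1, function(d) perturb_attachment(m, s, d)))
  expect_equal(unname(apply(pert, 2, stats::sd)), s, tolerance = 0.02)
})

test_that("element coupling preserves per-axis ratios under parent shifts", {
  expect_equal(couple_elements(c(0.2, 0.3, 0.6), c(0.5, -0.1, 0)),
               c(0.3, 0.27, 0.6))
  expect_equal(couple_elements(c(0.2, 0.3, 0.6), c(0, 0, 0)), c(0.2, 0.3, 0.6))
  parent <- c(0.21, 0.33, 0.58); off <- c(0.1, -0.2, 0.05)
  child <- couple_elements(parent, off)
  shifted <- parent + c(0.01, -0.02, 0.03)
  child2 <- couple_elements(shifted, off)
  expect_equal(child2 / shifted, child / parent, tolerance = 1e-12)
  expect_error(couple_elements(c(0, 0.3, 0.6), c(0.5, 0, 0)), "percentage base")
})

test_that("coupled muscle elements translate as units under perturbation", {
  draw <- list(infraspinatus_origin = c(0.8, -1.2, 0.5),
               subscapularis_origin = c(-0.4, 0.9, 1.1),
               supraspinatus_origin = c(0, 0, 0),
               deltoid_insertion = c(1.5, -0.5, 0.2))
  f0 <- resolve_attachment_fractions(human_sp)
  f1 <- resolve_attachment_fractions(human_sp, draw)
  ## child/parent per-axis ratio identical before and after perturbation
  pairs <- list(c("infraspinatus_lower", "infraspinatus_upper", "origin"),
                c("subscapularis_middle", "subscapularis_upper", "origin"),
                c("subscapularis_lower", "subscapularis_upper", "origin"),
                c("deltoid_anterior", "deltoid_middle", "insertion"),
                c("deltoid_posterior", "deltoid_middle", "insertion"))
  for (pr in pairs) {
    r0 <- f0[[pr[1]]][[pr[3]]] / f0[[pr[2]]][[pr[3]]]
    r1 <- f1[[pr[1]]][[pr[3]]] / f1[[pr[2]]][[pr[3]]]
    expect_equal(r1, r0, tolerance = 1e-12, label = pr[1])
  }
})

test_that("straight paths, sphere wraps and error cases behave as derived", {
  ## no obstacle: straight line
  p <- solve_path(c(0, 0, 0), c(0.1, 0, 0))
  expect_false(p$wrapped)
  expect_equal(p$path_length, 0.1)
  expect_equal(nrow(p$via_points), 2)
  expect_equal(p$insertion_direction, c(-1, 0, 0))

  ## symmetric through-centre sphere wrap: closed-form tangent + arc length
  sph <- list(type = "sphere", centre = c(0, 0, 0), radius = 1, bone = "humerus")
  d <- 2
  p <- solve_path(c(-d, 0, 0), c(d, 0, 0), list(sph), hint = c(0, 1, 0))
  expect_true(p$wrapped)
  expected <- 2 * sqrt(d^2 - 1) + 1 * (pi - 2 * acos(1 / d))
  expect_equal(p$path_length, expected, tolerance = 1e-9)
  expect_gt(p$path_length, 2 * d)

  ## wrapped length exceeds straight length; Lipschitz in the origin
  p1 <- solve_path(c(-d + 1e-4, 0, 0), c(d, 0, 0), list(sph), hint = c(0, 1, 0))
  expect_lt(abs(p1$path_length - p$path_length), 1.01e-4)

  expect_error(solve_path(c(0.5, 0, 0), c(3, 0, 0), list(sph)), "inside")
  expect_error(solve_path(c(1, 1, 1), c(1, 1, 1)), "coincide")
})

test_that("wrap path length is minimal-side and never below straight length", {
  sph <- list(type = "sphere", centre = c(0, 0, 0), radius = 0.025, bone = "humerus")
  cyl <- list(type = "cylinder", point = c(0, 0, 0), axis = c(0, 1, 0),
              radius = 0.02, bone = "humerus")
  set.seed(5)
  for (k in 1:60) {
    o <- stats::rnorm(3, 0, 0.08); i <- stats::rnorm(3, 0, 0.08)
    if (vnorm(o) < 0.03 || vnorm(i) < 0.03 || vnorm(i - o) < 1e-3) next
    p <- solve_path(o, i, list(sph))
    expect_gte(p$path_length, p$straight_length - 1e-12)
    if (sqrt(o[1]^2 + o[3]^2) > 0.025 && sqrt(i[1]^2 + i[3]^2) > 0.025) {
      pc <- solve_path(o, i, list(cyl))
      expect_gte(pc$path_length, pc$straight_length - 1e-12)
    }
  }
})

test_that("moment arms follow r cross u and vanish through the joint centre", {
  ## straight line of action through the centre
  p <- solve_path(c(0, 0.3, 0), c(0, -0.2, 0))
  expect_equal(moment_arm(p, c(0, 0, 0)), c(0, 0, 0), tolerance = 1e-12)

  ## planar toy: r = (0.05, 0, 0), u = (0, 1, 0) -> arm (0, 0, 0.05)
  p <- solve_path(c(0.05, 1, 0), c(0.05, 0, 0))
  expect_equal(moment_arm(p, c(0, 0, 0)), c(0, 0, 0.05), tolerance = 1e-12)
})

test_that("moment arms satisfy the tendon-excursion identity on wrapped paths", {
  geom <- build_model_geometry(human_sp, generate_posture("mid_support", human_sp, 1))
  gh <- geom$gh
  rot_about_gh <- function(v, axis, th) gh + rotate_about(v - gh, axis, th)
  h <- 1e-5

  check_excursion <- function(element, wrap_template) {
    e <- human_sp$muscle_elements[[element]]
    f0 <- resolve_attachment_fractions(human_sp)
    frames <- cuffmc:::.bone_frames(human_sp, generate_posture("mid_support", human_sp, 1))
    o <- cuffmc:::.attachment_world(f0[[element]]$origin, e$origin$bone, frames, human_sp)
    i <- cuffmc:::.attachment_world(f0[[element]]$insertion, e$insertion$bone, frames, human_sp)
    for (axis in list(c(1, 0, 0), c(0, 0, 1), unitize(c(1, 0.3, 0.5)))) {
      lens <- vapply(c(-h, h), function(th) {
        wraps <- list(wrap_template)
        if (wraps[[1]]$type == "cylinder") {
          wraps[[1]]$axis <- rotate_about(wraps[[1]]$axis, axis, th)
        }
        solve_path(o, rot_about_gh(i, axis, th), wraps)$path_length
      }, 0)
      dL <- (lens[2] - lens[1]) / (2 * h)
      p0 <- solve_path(o, i, list(wrap_template))
      m <- moment_arm(p0, gh)
      expect_lt(abs(dL + sum(m * axis)), 1e-3,
                label = sprintf("%s about (%.1f,%.1f,%.1f)", element,
                                axis[1], axis[2], axis[3]))
      expect_true(p0$wrapped)
    }
  }

  sph <- list(type = "sphere", centre = gh, radius = human_sp$fixture$humeral_head_radius,
              bone = "humerus")
  check_excursion("supraspinatus", sph)
  check_excursion("infraspinatus_upper", sph)
})
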