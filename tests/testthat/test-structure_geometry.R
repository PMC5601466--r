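test_that("SASA of an isolated sphere matches the analytic area within 1%", {
  m <- toy_model("A", 1, 0)
  r <- c(C = 0.15); probe <- 0.14; R <- 0.29
  got <- sasa(m, probe = probe, n_points = 960, radii = r)
  expect_lt(abs(got / (4 * pi * R^2) - 1), 0.01)

  # two atoms beyond interaction range: exactly additive
  m2 <- toy_model(c("A", "B"), 1, c(0, 1))
  expect_equal(sasa(m2, probe = probe, radii = r),
               2 * sasa(m2, atoms = 1L, probe = probe, radii = r))

  # convergence on a partially buried pair: denser point sets approach
  # the analytic two-sphere union area
  pair <- toy_model(c("A", "B"), 1, c(0, 0.29))
  errs <- vapply(c(32, 960, 7680), function(np)
    abs(sasa(pair, probe = probe, n_points = np, radii = r) -
          two_sphere_union_area(R, 0.29)), numeric(1))
  expect_lt(errs[3], errs[1])
  expect_lt(errs[3] / two_sphere_union_area(R, 0.29), 0.005)
})

test_that("two intersecting spheres reproduce the spherical-cap closed form", {
  r <- c(C = 0.15); probe <- 0.14; R <- 0.29; d <- 0.29
  m <- toy_model(c("A", "B"), 1, c(0, d))
  expect_lt(abs(sasa(m, probe = probe, n_points = 960, radii = r) /
                  two_sphere_union_area(R, d) - 1), 0.01)

  # contact area of the two single-atom regions: 2*pi*R*(R - d/2)
  a <- region_selection("a", data.frame(chain = "A", first = 1, last = 1))
  b <- region_selection("b", data.frame(chain = "B", first = 1, last = 1))
  ca <- contact_area(m, a, b, probe = probe, n_points = 960, radii = r)
  expect_lt(abs(ca / (2 * pi * R * (R - d / 2)) - 1), 0.02)

  # symmetry is exact; beyond range the contact area vanishes
  expect_identical(ca, contact_area(m, b, a, probe = probe, radii = r))
  far <- toy_model(c("A", "B"), 1, c(0, 2))
  expect_lt(abs(contact_area(far, a, b, probe = probe, radii = r)), 1e-6)

  expect_error(contact_area(m, a, a, radii = r), "overlap")
  expect_error(sasa(toy_model("A", 1, 0, element = "Xx"), radii = r),
               "Xx")
})

test_that("contact-area series falls monotonically as a helix pair separates", {
  frames <- gen_toy_structure("helix_pair",
                              list(n_res = 8, gap = 0.45,
                                   offsets = c(0, 0.3, 0.8, 2, 5)))
  a <- region_selection("A", data.frame(chain = "A", first = 1, last = 8))
  b <- region_selection("B", data.frame(chain = "B", first = 1, last = 8))
  cs <- contact_area_series(frames, a, b, elongation = 0:4,
                            n_points = 240)
  expect_s3_class(cs, "contact_area_series")
  expect_true(all(diff(cs$ca) <= 1e-9))
  expect_lt(cs$ca[5], 1e-6)
  expect_gt(cs$ca[1], 0.5)
  expect_error(contact_area_series(list(), a, b, numeric(0)), "empty")
})

test_that("interface trimming drops two terminal residues and changes the area", {
  # terminal residues of the two rods almost touch end-on: with trim 0
  # they contribute contact; with trim 2 the regions move out of range
  at <- rbind(
    toy_model("A", 1:4, x = c(0, 0.15, 0.3, 0.45))$atoms,
    toy_model("A", 5:8, x = c(0.9, 1.05, 1.2, 1.35))$atoms)
  m <- structure_model(at)
  a0 <- region_selection("left",  data.frame(chain = "A", first = 1, last = 4))
  b0 <- region_selection("right", data.frame(chain = "A", first = 5, last = 8))
  a2 <- region_selection("left",  data.frame(chain = "A", first = 1, last = 4),
                         trim = 1)
  b2 <- region_selection("right", data.frame(chain = "A", first = 5, last = 8),
                         trim = 1)
  ca0 <- contact_area(m, a0, b0, n_points = 240)
  ca2 <- contact_area(m, a2, b2, n_points = 240)
  expect_gt(ca0, 0.01)
  expect_lt(ca2, ca0 / 2)
  expect_error(region_selection("x", data.frame(chain = "A", first = 1,
                                                last = 4), trim = 2),
               "empty after trimming")
})

test_that("tilt angles recover constructed geometry and its invariances", {
  rod <- function(ang) gen_toy_structure("tilted_rod",
                                         list(n_res = 6, angle_deg = ang))
  ts <- tilt_angles(list(rod(30)), anchor_mid = c("A", 1),
                    anchor_n = c("A", 3), anchor_c = c("A", 6))
  expect_equal(ts$alpha1, 30, tolerance = 1e-6)
  expect_equal(ts$alpha2, 30, tolerance = 1e-6)

  for (ang in c(0, 90, 180)) {
    t1 <- tilt_angles(list(rod(ang)), c("A", 1), c("A", 2), c("A", 6))
    expect_equal(t1$alpha1, ang, tolerance = 1e-6)
  }

  # rigid translation and anchor-vector scaling leave the angle unchanged
  m <- rod(55)
  shifted <- m
  shifted$atoms$x <- shifted$atoms$x + 7
  shifted$atoms$y <- shifted$atoms$y - 3
  shifted$atoms$z <- shifted$atoms$z + 1
  t_a <- tilt_angles(list(m), c("A", 1), c("A", 2), c("A", 6))
  t_b <- tilt_angles(list(shifted), c("A", 1), c("A", 2), c("A", 6))
  t_c <- tilt_angles(list(m), c("A", 1), c("A", 4), c("A", 6))  # longer vector
  expect_equal(t_a$alpha1, t_b$alpha1, tolerance = 1e-9)
  expect_equal(t_a$alpha1, t_c$alpha1, tolerance = 1e-9)

  expect_error(tilt_angles(list(m), c("A", 1), c("A", 99), c("A", 6)),
               "A:99")
})

test_that("max_tilt takes the larger channel maximised over frames", {
  s <- structure(list(traj_id = "t", alpha1 = c(10, 40, 25),
                      alpha2 = c(20, 15, 87)), class = "tilt_series")
  expect_equal(max_tilt(s), 87)
  s1 <- structure(list(traj_id = "t", alpha1 = 10, alpha2 = 20),
                  class = "tilt_series")
  expect_equal(max_tilt(s1), 20)
  empty <- structure(list(traj_id = "t", alpha1 = numeric(),
                          alpha2 = numeric()), class = "tilt_series")
  expect_error(max_tilt(empty), "empty")
})
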