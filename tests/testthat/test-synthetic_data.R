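test_that("generators are pure functions of spec and seed", {
  t1 <- gen_force_trace(1, 50, noise_sd = 30, duration = 10, seed = 3)
  t2 <- gen_force_trace(1, 50, noise_sd = 30, duration = 10, seed = 3)
  expect_identical(t1, t2)
  t3 <- gen_force_trace(1, 50, noise_sd = 30, duration = 10, seed = 4)
  expect_false(identical(t1$f1, t3$f1))

  r1 <- gen_bell_ruptures(0.3, 1e-5, 830, replicas = 5, seed = 12)
  r2 <- gen_bell_ruptures(0.3, 1e-5, 830, replicas = 5, seed = 12)
  expect_identical(r1, r2)

  c1 <- gen_ca_series(seed = 8)
  expect_identical(c1, gen_ca_series(seed = 8))

  o1 <- gen_order_counts(1.2, 33, seed = 5)
  expect_identical(o1, gen_order_counts(1.2, 33, seed = 5))

  # the global RNG stream is left untouched
  set.seed(1); before <- .Random.seed
  invisible(gen_force_trace(1, 50, noise_sd = 10, duration = 1, seed = 99))
  expect_identical(.Random.seed, before)
})

test_that("noiseless force ramps obey F = k_eff * v * t with planted drops", {
  tr <- gen_force_trace(v_pull = 1, k_eff = 50, duration = 10, noise_sd = 0)
  F <- combine_forces(tr)
  expect_equal(F[length(F)], 500, tolerance = 1e-9)
  expect_equal(F, 50 * tr$time, tolerance = 1e-9)

  tr_drop <- gen_force_trace(1, 50, events = data.frame(elong = 10,
                                                        drop_frac = 1),
                             duration = 20, noise_sd = 0)
  F_drop <- combine_forces(tr_drop)
  expect_equal(max(F_drop), 500, tolerance = 1e-9)
  expect_equal(tr_drop$v_pull * tr_drop$time[which.max(F_drop)], 10,
               tolerance = 0.05 + 1e-9)
})

test_that("first-passage rupture samples follow the Bell statistics", {
  x_b <- 0.3; k_off <- 1e-5; k_spring <- 830; kTv <- kT(300, "pN.nm")
  v <- 1
  r <- k_spring * v
  expect_gt(r * x_b / (k_off * kTv), 1e3)  # high reduced loading rate
  smp <- gen_bell_ruptures(x_b, k_off, k_spring, velocities = v,
                           replicas = 10000, seed = 21)
  modal <- bell_modal_force(x_b, k_off, k_spring, v)
  # the sample density peaks at the Bell prediction within 5%
  d <- density(smp$F_r_pN)
  expect_lt(abs(d$x[which.max(d$y)] / modal - 1), 0.05)

  # doubling the velocity shifts the mean by about (kT/x_b) ln 2
  smp2 <- gen_bell_ruptures(x_b, k_off, k_spring, velocities = 2 * v,
                            replicas = 10000, seed = 22)
  shift <- mean(smp2$F_r_pN) - mean(smp$F_r_pN)
  expect_lt(abs(shift - (kTv / x_b) * log(2)), 0.15 * (kTv / x_b) * log(2))

  # support: all samples within (0, the 1 - 1e-9 survival quantile]
  q_hi <- (kTv / x_b) *
    log1p(-(r * x_b) / (k_off * kTv) * log(1e-9))
  expect_true(all(smp$F_r_pN > 0 & smp$F_r_pN <= q_hi))
})

test_that("synthetic contact-area series support baseline and detection", {
  # stationary AR(1): CA_low matches the analytic Gaussian quartiles
  gen <- gen_ca_series(eq_mean = 3, ar_coef = 0.8, innov_sd = 0.15,
                       events = data.frame(center = numeric(),
                                           width = numeric()),
                       n_eq = 100000, seed = 17)
  b <- baseline(gen$equilibrium)
  sd_stat <- 0.15 / sqrt(1 - 0.8^2)
  q1_true <- qnorm(0.25, 3, sd_stat); q3_true <- qnorm(0.75, 3, sd_stat)
  expect_equal(b$ca_low, q1_true - 1.5 * (q3_true - q1_true),
               tolerance = 0.05)

  # a planted event is recovered within one sample spacing
  gen_ev <- gen_ca_series(eq_mean = 3, events = data.frame(center = 40,
                                                           width = 1),
                          dx = 0.05, seed = 18)
  b2 <- baseline(gen_ev$equilibrium)
  ev <- detect_event(gen_ev$series, b2)
  truth <- logistic_crossing(3, 40, 1, b2$ca_low / 2)
  expect_lt(abs(ev$start - truth), 0.05 + 1e-9)
})

test_that("toy structures carry their constructed geometric truth", {
  rod <- gen_toy_structure("tilted_rod", list(angle_deg = 30, n_res = 5))
  ts <- tilt_angles(list(rod), c("A", 1), c("A", 3), c("A", 5))
  expect_equal(max_tilt(ts), 30, tolerance = 1e-6)

  far <- gen_toy_structure("sphere_pair", list(separation = 3))
  a <- region_selection("a", data.frame(chain = "A", first = 1, last = 1))
  b <- region_selection("b", data.frame(chain = "B", first = 1, last = 1))
  expect_lt(abs(contact_area(far, a, b)), 1e-6)

  frames <- gen_toy_structure("helix_pair",
                              list(n_res = 6, gap = 0.45,
                                   offsets = seq(0, 2, by = 0.5)))
  ha <- region_selection("A", data.frame(chain = "A", first = 1, last = 6))
  hb <- region_selection("B", data.frame(chain = "B", first = 1, last = 6))
  cas <- contact_area_series(frames, ha, hb, elongation = 0:4,
                             n_points = 240)
  expect_true(all(diff(cas$ca) <= 1e-9))
})

test_that("order-count draws follow the logistic-binomial law", {
  big <- gen_order_counts(0, 10000, seed = 6)
  expect_lt(abs(big$k / big$n - 0.5), 0.015)

  skew <- gen_order_counts(1.2, 100000, seed = 7)
  expect_lt(abs(skew$k / skew$n - p_from_ddg(1.2)), 0.005)

  expect_equal(gen_order_counts(Inf, 50, seed = 8)$k, 0L)
  expect_equal(gen_order_counts(-Inf, 50, seed = 8)$k, 50L)
})
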