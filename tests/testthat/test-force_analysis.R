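test_that("the two force channels combine antisymmetrically", {
  tr <- force_trace(c(0, 0.05, 0.1), c(100, 100, 0), c(-100, -90, 0), 1, 830)
  expect_equal(combine_forces(tr), c(100, 95, 0))
})

test_that("Gaussian smoothing preserves constants, is linear, and sets sigma from the pull speed", {
  tr_const <- gen_force_trace(v_pull = 1, k_eff = 0, duration = 10)
  tr_const$f1 <- rep(250, length(tr_const$f1))
  tr_const$f2 <- -tr_const$f1
  for (w in c(0.1, 1)) {
    st <- smooth_trace(tr_const, elong_width = w)
    expect_equal(st$force, rep(250, length(st$force)), tolerance = 1e-9)
  }

  # sigma in time follows the velocity: 0.1 nm at 1/100 nm/ns is 10 ns
  tr_slow <- gen_force_trace(v_pull = 1 / 100, k_eff = 50, duration = 100)
  expect_equal(smooth_trace(tr_slow, 0.1)$sigma_time, 10)
  expect_equal(smooth_trace(gen_force_trace(1, 50, duration = 5), 0.1)$sigma_time,
               0.1)

  # unit impulse maps to a discrete Gaussian of unit sum centred at the pulse
  n <- 401L
  tr_imp <- force_trace(seq(0, 20, by = 0.05), rep(0, n), rep(0, n), 1, 830)
  tr_imp$f1[201] <- 1; tr_imp$f2[201] <- -1
  st <- smooth_trace(tr_imp, elong_width = 0.1)
  dt <- 0.05
  kern <- dnorm(seq(-8, 8) * dt, sd = 0.1)
  kern <- kern / sum(kern)
  expect_equal(st$force[193:209], kern, tolerance = 1e-9)
  expect_equal(sum(st$force), 1, tolerance = 1e-9)
  expect_equal(which.max(st$force), 201L)

  # linearity and shift by a constant
  f <- sin(seq(0, 6, length.out = n)) * 100
  tr_a <- force_trace(tr_imp$time, f, -f, 1, 830)
  tr_b <- force_trace(tr_imp$time, 2 * f + 50, -(2 * f + 50), 1, 830)
  expect_equal(smooth_trace(tr_b, 0.2)$force,
               2 * smooth_trace(tr_a, 0.2)$force + 50, tolerance = 1e-9)

  # smoothing never exceeds the raw maximum
  expect_lte(max(smooth_trace(tr_a, 0.5)$force), max(f))

  tr_bad <- force_trace(c(0, 0.05, 0.2), c(0, 0, 0), c(0, 0, 0), 1, 830)
  expect_error(smooth_trace(tr_bad), "non-uniform")
})

test_that("rupture force is the maximum of the first 20 nm and monotone in the window", {
  # sawtooth: 600 pN peak at 12 nm, larger 800 pN peak at 30 nm
  tr <- gen_force_trace(
    v_pull = 1, k_eff = 50,
    events = data.frame(elong = c(12, 30), drop_frac = c(1, 1)),
    duration = 40, noise_sd = 0)
  st <- smooth_trace(tr, 0.1)
  rec <- rupture_force(st)
  # closed-form oracle: a ramp of slope s with a cliff of height h at x_p,
  # smoothed by a Gaussian of sd sigma, peaks at max_x s*x - h*pnorm((x-x_p)/sigma)
  smoothed_peak <- function(s, h, x_p, sigma) {
    stats::optimize(function(x) s * x - h * pnorm((x - x_p) / sigma),
                    c(x_p - 6 * sigma, x_p + sigma), maximum = TRUE)$objective
  }
  # the sampled drop takes effect half a step past the planted elongation
  expect_equal(rec$F_r_pN, smoothed_peak(50, 600, 12.025, 0.1),
               tolerance = 2e-3)
  expect_equal(rec$peak_x_nm, 12, tolerance = 0.5)
  expect_false(rec$truncated)
  # widening the window picks up the higher later peak (900 pN ramp at 30 nm)
  rec40 <- rupture_force(st, first_peak_window = 40)
  expect_gte(rec40$F_r_pN, rec$F_r_pN)
  # the second ramp restarts from zero at the sample after the drop
  expect_equal(rec40$F_r_pN, smoothed_peak(50, 900, 30.025, 0.1) - 50 * 12.05,
               tolerance = 2e-3)

  # monotone ramp: the window boundary is the argmax
  ramp <- smooth_trace(gen_force_trace(1, 30, duration = 20))
  rec_r <- rupture_force(ramp)
  expect_equal(rec_r$peak_x_nm, 20, tolerance = 1e-6)

  short <- smooth_trace(gen_force_trace(1, 30, duration = 10))
  expect_true(rupture_force(short)$truncated)
})

test_that("smoothing bias at a planted sawtooth peak follows the closed form", {
  # a cliff drop smoothed by a Gaussian peaks where the ramp slope equals
  # the drop's Gaussian derivative; the bias scales with sigma * slope
  tr <- gen_force_trace(1, 50, events = data.frame(elong = 10, drop_frac = 1),
                        duration = 25, noise_sd = 0)
  for (w in c(0.1, 1)) {
    # window short of the recovering ramp so the planted peak is the max
    rec <- rupture_force(smooth_trace(tr, w), first_peak_window = 12)
    oracle <- stats::optimize(
      function(x) 50 * x - 500 * pnorm((x - 10.025) / w),
      c(10 - 6 * w, 10 + w), maximum = TRUE)$objective
    expect_equal(rec$F_r_pN, oracle, tolerance = 2e-3)
    expect_lt(abs(rec$F_r_pN - 500), 3.5 * w * 50)
  }
})

test_that("peak counting honours prominence and separation thresholds", {
  tri <- function(centers, heights, width = 4) {
    x <- seq(0, 60, by = 0.05)
    y <- rep(0, length(x))
    for (i in seq_along(centers))
      y <- pmax(y, heights[i] * pmax(0, 1 - abs(x - centers[i]) / width))
    force_trace(x, y, -y, 1, 830)
  }
  st3 <- smooth_trace(tri(c(10, 25, 40), c(500, 500, 500)), 0.1)
  expect_equal(count_peaks(st3, prominence = 100, min_separation = 5)$n, 3L)

  st2 <- smooth_trace(tri(c(10, 25, 40), c(500, 80, 500)), 0.1)
  expect_equal(count_peaks(st2, prominence = 100, min_separation = 5)$n, 2L)

  flat <- smooth_trace(gen_force_trace(1, 0, duration = 20))
  expect_equal(count_peaks(flat, 100, 5)$n, 0L)

  # the two smoothing widths agree on well-separated peaks (and ordering)
  st_wide <- smooth_trace(tri(c(10, 25, 40), c(500, 300, 400)), 1)
  pk_narrow <- count_peaks(smooth_trace(tri(c(10, 25, 40), c(500, 300, 400)), 0.1), 100, 5)
  pk_wide <- count_peaks(st_wide, 100, 5)
  expect_equal(pk_narrow$n, pk_wide$n)
  expect_equal(order(pk_narrow$peaks$force_pN), order(pk_wide$peaks$force_pN))
})
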