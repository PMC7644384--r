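test_that("trim_borders removes floor(fraction*N) samples from each end", {
  mk <- function(n) pen_samples(seq_len(n) * 0.02, seq_len(n), 0)
  s100 <- trim_borders(mk(100), 0.05)
  expect_equal(nrow(s100), 90)
  expect_equal(s100$x[1], 6)       # indices 6..95 kept
  expect_equal(s100$x[90], 95)
  expect_equal(nrow(trim_borders(mk(20), 0.05)), 18)
  expect_identical(trim_borders(mk(10), 0), mk(10))
  for (n in c(17, 40, 101, 250))
    expect_equal(nrow(trim_borders(mk(n), 0.05)), n - 2 * floor(0.05 * n))
  expect_error(trim_borders(mk(3), 0.4), "too short")
  expect_error(trim_borders(mk(2), 0.05), "too few")
})

test_that("path_length sums pen-down segments and skips lifts", {
  s <- pen_samples(c(0, 0.02, 0.04), c(0, 10, 25), 0)
  expect_equal(path_length(s), 25)
  sq <- pen_samples(seq(0, 0.08, by = 0.02),
                    c(0, 10, 10, 0, 0), c(0, 0, 10, 10, 0))
  expect_equal(path_length(sq), 40)
  lifted <- pen_samples(c(0, 0.02, 0.04), c(0, 10, 25), 0,
                        pen_down = c(TRUE, FALSE, TRUE))
  expect_equal(path_length(lifted), 0)
  expect_error(path_length(s[1, , drop = FALSE]), ">= 2")
})

test_that("a generated circle's traced length matches its perimeter", {
  tr <- generate_copy_trial(quiet_profile(speed_shape = "constant"),
                            "circle", "spontaneous", seed = 5)
  expect_equal(path_length(tr$samples), attr(tr, "truth")$L,
               tolerance = 0.005)
})

test_that("raw_speed is displacement over actual time difference", {
  t <- seq(0, 0.2, by = 0.02)
  s <- pen_samples(t, 500 * t, 0)
  prof <- raw_speed(s)
  expect_equal(prof$v, rep(500, 10))
  expect_equal(prof$t_mid, t[-11] + 0.01)
  still <- pen_samples(t, 5, 3)
  expect_equal(raw_speed(still)$v, rep(0, 10))
  dup <- s; dup$t[4] <- dup$t[3]
  expect_error(raw_speed(dup), "timestamp")
})

test_that("raw_speed excludes pairs spanning a pen lift", {
  t <- seq(0, 0.1, by = 0.02)
  s <- pen_samples(t, 100 * t, 0,
                   pen_down = c(TRUE, TRUE, FALSE, TRUE, TRUE, TRUE))
  prof <- raw_speed(s)
  expect_length(prof$v, 3)          # pairs (1,2), (4,5), (5,6)
  expect_equal(length(unique(prof$run)), 2)
})

test_that("raw_speed matches the minimum-jerk closed form on a generated stroke", {
  tr <- generate_copy_trial(quiet_profile(), "circle", "spontaneous",
                            seed = 8)
  truth <- attr(tr, "truth")
  prof <- raw_speed(tr$samples)
  tau <- prof$t_mid / truth$T_total
  v_true <- truth$L / truth$T_total * 30 * (tau^2 - 2 * tau^3 + tau^4)
  rel_rms <- sqrt(mean((prof$v - v_true)^2)) / mean(v_true)
  expect_lt(rel_rms, 0.02)
})

test_that("the low-pass stage has unit DC gain, kills 20 Hz, keeps 1 Hz", {
  t <- seq(0, 6, by = 0.02)
  mid <- t > 1 & t < 5                  # avoid filter edge transients
  const <- speed_profile(t, rep(300, length(t)))
  expect_equal(lowpass_speed(const)$v, rep(300, length(t)),
               tolerance = 1e-9)
  ripple <- speed_profile(t, 300 + 50 * sin(2 * pi * 20 * t))
  out <- lowpass_speed(ripple)
  expect_lt(max(abs(out$v[mid] - 300)), 0.1 * 50)   # >90% attenuation
  slow <- speed_profile(t, 300 + 50 * sin(2 * pi * 1 * t))
  outs <- lowpass_speed(slow)
  amp <- (max(outs$v[mid]) - min(outs$v[mid])) / 2
  expect_equal(amp, 50, tolerance = 0.05)
})

test_that("lowpass refuses short or irregular runs unless told to fall back", {
  short <- speed_profile(seq(0, 0.1, by = 0.02), rep(10, 6))
  expect_error(lowpass_speed(short), "skip filtering")
  expect_warning(out <- lowpass_speed(short, fallback = TRUE), "raw")
  expect_equal(out$v, short$v)
  set.seed(1)
  tj <- cumsum(runif(40, 0.01, 0.03))
  jitter <- speed_profile(tj, rep(10, 40))
  expect_error(lowpass_speed(jitter), "irregular")
})

test_that("mean_speed recovers a constant programmed speed within 1%", {
  tr <- line_trial(speed = 120, duration = 3)
  expect_equal(mean_speed(tr), 120, tolerance = 0.01)
  gen <- generate_copy_trial(quiet_profile(speed_shape = "constant"),
                             "circle", "spontaneous", seed = 3)
  expect_equal(mean_speed(gen), attr(gen, "truth")$speed,
               tolerance = 0.01)
})

test_that("mean_speed is equivariant to spatial scaling and time compression", {
  tr <- generate_copy_trial(quiet_profile(), "circle", "spontaneous",
                            seed = 9)
  base <- mean_speed(tr)
  for (k in c(0.5, 2, 3.7)) {
    scaled <- tr
    scaled$samples$x <- tr$samples$x * k
    scaled$samples$y <- tr$samples$y * k
    expect_equal(mean_speed(scaled), k * base, tolerance = 1e-9)
  }
  fast <- tr
  fast$samples$t <- tr$samples$t / 2
  expect_equal(mean_speed(fast) / base, 2, tolerance = 0.02)
})
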