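test_that("geometries encode ID = A / W and the stated dimensions", {
  g <- make_geometry("circle", A = 100 * pi, W = 10)
  expect_equal(g$ID, 10 * pi, tolerance = 1e-9)
  ctr <- colMeans(g$center_path)
  radii <- sqrt((g$center_path[, 1] - ctr[1])^2 +
                  (g$center_path[, 2] - ctr[2])^2)
  expect_equal(mean(radii), 50, tolerance = 1e-3)

  sq <- make_geometry("square", A = 160, W = 8)
  expect_equal(sq$ID, 20)
  expect_equal(diff(range(sq$center_path[, 1])), 40, tolerance = 1e-9)

  w <- make_geometry("word_ele", A = 200, W = 20)
  expect_equal(penlaws:::poly_length(w$center_path), 200,
               tolerance = 0.001)
  expect_equal(w$gates, c(20, 180))
  expect_error(make_geometry("triangle", 100, 10), "unsupported")
})

test_that("ID is invariant to scaling A and W together", {
  for (k in c(0.25, 3, 11)) {
    a <- make_geometry("square", A = 160, W = 8)
    b <- make_geometry("square", A = 160 * k, W = 8 * k)
    expect_identical(a$ID, b$ID)
  }
})

test_that("outside_fraction is the outside arc length over total arc", {
  geom <- line_geometry(W = 10)
  on_path <- offset_fixture(0.5, 0)
  expect_equal(outside_fraction(on_path, geom), 0)
  all_out <- offset_fixture(0.999, 10)
  expect_gt(outside_fraction(all_out, geom), 0.99)
  mid <- offset_fixture(0.41, 10)
  expect_equal(outside_fraction(mid, geom), 0.41, tolerance = 0.01)
})

test_that("exclusion is strict at the 40% boundary", {
  geom <- line_geometry(W = 10)
  a41 <- assess_tunnel_trial(offset_fixture(0.41, 10), geom)
  expect_true(a41$excluded)
  expect_true(is.na(a41$MT))
  a39 <- assess_tunnel_trial(offset_fixture(0.39, 10), geom)
  expect_false(a39$excluded)
  a40 <- assess_tunnel_trial(offset_fixture(0.40, 10), geom)
  expect_false(a40$excluded)   # "more than 40%" keeps the boundary case
})

test_that("movement time measures the central section of symbols", {
  # ideal constant-speed circle, two laps in 8 s -> central lap takes 4 s
  g <- make_geometry("circle", A = 200, W = 20)
  th0 <- pi / 2
  t <- seq(0, 8, by = 0.02)
  th <- th0 - 2 * pi * (2 * t / 8)   # clockwise like the template
  r <- 200 / (2 * pi)
  tr <- trial_recording("S1", "primary", "tunnel", "circle",
                        geometry_id = g$geometry_id,
                        samples = pen_samples(t, r * cos(th), r * sin(th)))
  expect_equal(movement_time(tr, g), 4, tolerance = 0.005)
})

test_that("word movement time runs between the two gate crossings", {
  g <- make_geometry("word_ele", A = 200, W = 20)
  # constant-speed traversal of the center path in 5 s; gates at 10%/90%
  seg <- penlaws:::poly_segments(g$center_path)
  t <- seq(0, 5, by = 0.01)
  pos <- penlaws:::interp_along(g$center_path,
                                penlaws:::poly_cum(g$center_path),
                                seg$total * t / 5)
  tr <- trial_recording("S1", "primary", "tunnel", "word_ele",
                        geometry_id = g$geometry_id,
                        samples = pen_samples(t, pos[, 1], pos[, 2]))
  expect_equal(movement_time(tr, g), 4, tolerance = 0.01)
})

test_that("generated steering trials hit their programmed movement time", {
  p <- quiet_profile()
  for (item in c("circle", "square", "word_ele")) {
    g <- make_geometry(item, A = 250, W = 250 / 18)
    tr <- generate_tunnel_trial(p, g, seed = 4)
    expect_equal(movement_time(tr, g), attr(tr, "truth")$MT_target,
                 tolerance = 0.02 / attr(tr, "truth")$MT_target)
  }
  # lateral noise does not break the measurement while gates are crossed
  pn <- quiet_profile(); pn$lateral_noise_sd <- 0.6
  g <- make_geometry("circle", A = 250, W = 250 / 12)
  tr <- generate_tunnel_trial(pn, g, seed = 6)
  expect_equal(movement_time(tr, g), attr(tr, "truth")$MT_target,
               tolerance = 0.03)
})

test_that("a trial that never completes the course is flagged incomplete", {
  g <- make_geometry("circle", A = 200, W = 20)
  t <- seq(0, 2, by = 0.02)
  r <- 200 / (2 * pi)
  th <- pi / 2 - 2 * pi * (0.3 * t / 2)   # only 30% of one lap
  tr <- trial_recording("S1", "primary", "tunnel", "circle",
                        geometry_id = g$geometry_id,
                        samples = pen_samples(t, r * cos(th), r * sin(th)))
  expect_error(movement_time(tr, g), "incomplete")
  expect_equal(assess_tunnel_trial(tr, g)$status, "incomplete")
})

test_that("fit_steering recovers noiseless parameters exactly", {
  ids <- c(8, 12, 18, 27, 40)
  f <- fit_steering(data.frame(ID = ids, MT = 0.5 + 0.1 * ids),
                    subject_id = "S1", item = "circle")
  expect_equal(f$a, 0.5, tolerance = 1e-9)
  expect_equal(f$b, 0.1, tolerance = 1e-9)
  expect_equal(f$R2, 1)
  expect_equal(f$RMSE, 0, tolerance = 1e-9)
  expect_equal(f$IP, 10, tolerance = 1e-9)
  expect_equal(f$global_MT, median(0.5 + 0.1 * ids))
})

test_that("an ID-independent MT yields a non-significant flat fit", {
  f <- fit_steering(data.frame(ID = c(8, 12, 18, 27, 40), MT = rep(2, 5)))
  expect_equal(f$R2, 0)
  expect_equal(f$p, 1)
  expect_true(is.na(f$IP))
})

test_that("degenerate designs and too-few trials are errors", {
  expect_error(fit_steering(data.frame(ID = c(8, 8, 8), MT = 1:3)),
               "degenerate")
  expect_error(fit_steering(data.frame(ID = c(8, 12), MT = 1:2)), ">= 3")
})

test_that("critical_r2 matches the F-quantile identity", {
  expect_equal(critical_r2(12, 0.05), 4.747 / (4.747 + 12),
               tolerance = 1e-4)
  expect_lt(critical_r2(12, 0.9999), 1e-4)     # alpha -> 1 limit
  expect_gt(critical_r2(5, 0.05), critical_r2(30, 0.05))
})
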