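# Shared fixtures, all built in code.

# straight-line trial at constant velocity (mm/s), 50 Hz
line_trial <- function(speed = 100, duration = 2, fs = 50, angle = 0,
                       item = "circle", modality = "spontaneous") {
  t <- seq(0, duration, by = 1 / fs)
  trial_recording("S1", "primary", "copy", item, modality = modality,
                  samples = pen_samples(t, speed * t * cos(angle),
                                        speed * t * sin(angle)))
}

# two-stroke trace with a given arc fraction offset laterally from a
# straight center line (pen lifted at the offset jump, so the jump adds
# no traced length): exact outside fractions for the exclusion rule
offset_fixture <- function(frac_outside, offset, length_mm = 100,
                           step = 0.2) {
  x1 <- seq(0, frac_outside * length_mm, by = step)
  x2 <- seq(frac_outside * length_mm, length_mm, by = step)
  t <- seq_along(c(x1, 0, x2)) * 0.02
  n1 <- length(x1)
  trial_recording(
    "S1", "primary", "tunnel", "word_ele", geometry_id = "line",
    samples = pen_samples(
      t, c(x1, x1[n1], x2), c(rep(offset, n1), offset / 2, rep(0, length(x2))),
      pen_down = c(rep(TRUE, n1), FALSE, rep(TRUE, length(x2)))))
}

# straight "virtual tunnel" the offset fixture is judged against
line_geometry <- function(W = 10, length_mm = 100) {
  list(geometry_id = "line", item = "word_ele",
       center_path = cbind(seq(0, length_mm, length.out = 201), 0),
       closed = FALSE, W = W, A = length_mm, ID = length_mm / W,
       laps_required = 1L, gates = c(0.1, 0.9) * length_mm)
}

# noise-free motor profile
quiet_profile <- function(group = "primary", ...) {
  p <- default_motor_profile(group)
  p$lateral_noise_sd <- 0
  p$fraction_noise_sd <- 0
  p$mt_noise_sd <- 0
  mods <- list(...)
  for (nm in names(mods)) p[[nm]] <- mods[[nm]]
  p
}

# field-by-field session comparison (coordinates to 1e-9 mm)
expect_session_equal <- function(a, b) {
  expect_equal(length(a$trials), length(b$trials))
  expect_equal(a$device$pixels_per_mm, b$device$pixels_per_mm)
  expect_equal(a$device$y_axis, b$device$y_axis)
  for (i in seq_along(a$trials)) {
    ta <- a$trials[[i]]; tb <- b$trials[[i]]
    for (f in c("subject_id", "group", "game", "item", "modality",
                "geometry_id", "trial_index"))
      expect_equal(ta[[f]], tb[[f]], info = paste("trial", i, "field", f))
    expect_equal(ta$samples$t, tb$samples$t, tolerance = 1e-12)
    expect_equal(ta$samples$x, tb$samples$x, tolerance = 1e-9)
    expect_equal(ta$samples$y, tb$samples$y, tolerance = 1e-9)
    expect_equal(ta$samples$pen_down, tb$samples$pen_down)
  }
}

# tiny cohort for plumbing tests
small_cohort <- function(seed = 42, n = 2) {
  generate_cohort(default_cohort_config(n_primary = n, n_kindergarten = n,
                                        tunnel_reps = c(1, 1, 1, 1, 1)),
                  seed = seed)
}
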