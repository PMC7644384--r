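# four-bump word whose valleys are exact y = 0 cusps at known samples
bump_word <- function(n_bumps = 4, fs = 50) {
  t <- seq(0, n_bumps, by = 1 / fs)
  tr <- trial_recording("S1", "primary", "copy", "word_mele",
                        modality = "spontaneous",
                        samples = pen_samples(t, 30 * t,
                                              20 * abs(sin(pi * t))))
  tr
}

test_that("word transitions are found at the construction valleys", {
  tr <- bump_word()
  sb <- segment_word(tr, 4, smooth_cutoff_hz = Inf)
  expect_equal(sb$transitions, c(51L, 101L, 151L))  # t = 1, 2, 3
  expect_length(sb$labels, 4)
  expect_equal(sb$durations, rep(1, 4), tolerance = 1e-9)
})

test_that("n_letters = 1 yields a single interval and no transitions", {
  sb <- segment_word(bump_word(), 1)
  expect_length(sb$transitions, 0)
  expect_length(sb$durations, 1)
})

test_that("manual boundaries override automatic detection", {
  tr <- bump_word()
  tr$manual_boundaries <- c(40L, 90L, 140L)
  sb <- segment_word(tr, 4)
  expect_equal(sb$transitions, c(40L, 90L, 140L))
  tr$manual_boundaries <- c(40L, 90L)
  expect_error(segment_word(tr, 4), "manual_boundaries")
})

test_that("a featureless trace raises a segmentation-failure error", {
  t <- seq(0, 2, by = 0.02)
  flat <- trial_recording("S1", "primary", "copy", "word_mele",
                          modality = "spontaneous",
                          samples = pen_samples(t, 60 * t, 10 * t))
  expect_error(segment_word(flat, 4, smooth_cutoff_hz = Inf),
               "segmentation failure")
})

test_that("sequences segment one interval per stroke, with durations from pen lifts", {
  tr <- generate_copy_trial(quiet_profile(), "sequence", "spontaneous",
                            seed = 21)
  sb <- segment_sequence(tr, expected_symbols = 3)
  expect_length(sb$durations, 3)
  expect_equal(sb$durations, attr(tr, "truth")$durations,
               tolerance = 0.02 / min(attr(tr, "truth")$durations))
  expect_error(segment_sequence(tr, expected_symbols = 4), "mismatch")
})

test_that("fraction times follow their defining arithmetic", {
  tr <- generate_copy_trial(quiet_profile(fraction_template = rep(1, 3) / 3),
                            "sequence", "spontaneous", seed = 2)
  fr <- fraction_times(segment_sequence(tr, 3))
  expect_equal(fr$fractions, rep(1 / 3, 3), tolerance = 1e-12)

  # durations 2, 1, 1 -> (0.5, 0.25, 0.25)
  sb <- structure(list(type = "sequence", labels = paste0("s", 1:3),
                       transitions = integer(0),
                       arc_fractions = numeric(0),
                       t_start = c(0, 2.5, 4), t_end = c(2, 3.5, 5),
                       durations = c(2, 1, 1)),
                  class = "segment_boundaries")
  expect_equal(fraction_times(sb)$fractions, c(0.5, 0.25, 0.25))
  # charging pen-up gaps to the preceding element changes the split
  expect_equal(fraction_times(sb, include_penup = TRUE)$fractions,
               c(2.5, 1.5, 1) / 5)
})

test_that("fractions sum to one and are invariant to rescaling", {
  set.seed(31)
  for (i in 1:5) {
    p <- default_motor_profile("primary")
    tr <- generate_copy_trial(p, "sequence", "spontaneous")
    fr <- fraction_times(segment_sequence(tr, 3))$fractions
    expect_equal(sum(fr), 1, tolerance = 1e-9)
    expect_true(all(fr > 0 & fr < 1))
    # uniform time rescaling: exactly invariant
    tr2 <- tr; tr2$samples$t <- tr$samples$t * 3.5
    expect_equal(fraction_times(segment_sequence(tr2, 3))$fractions, fr)
    # uniform spatial scaling: exactly invariant
    tr3 <- tr; tr3$samples$x <- tr$samples$x * 2
    tr3$samples$y <- tr$samples$y * 2
    expect_equal(fraction_times(segment_sequence(tr3, 3))$fractions, fr)
  }
})

test_that("noiseless words reproduce the programmed fraction times", {
  tr <- generate_copy_trial(quiet_profile(), "word_mele", "spontaneous",
                            seed = 13)
  truth <- attr(tr, "truth")
  fr <- fraction_times(segment_word(tr, 4))
  # each boundary lands within one sample of the programmed transition,
  # so each fraction is off by at most two sample periods
  expect_lt(max(abs(fr$fractions - truth$fractions)),
            2 * 0.02 / truth$T_total)
})

test_that("homothety holds across modalities for compliant generators", {
  set.seed(17)
  p <- default_motor_profile("primary")
  frs <- sapply(c("big", "slow"), function(m) {
    fr <- replicate(8, fraction_times(segment_sequence(
      generate_copy_trial(p, "sequence", m), 3))$fractions)
    apply(fr, 1, median)
  })
  expect_lt(max(abs(frs[, "big"] - frs[, "slow"])), 0.02)
})
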