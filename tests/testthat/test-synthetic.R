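test_that("templates are unit-length with the advertised structure", {
  for (item in c("circle", "square", "triangle", "word_mele", "word_ele",
                 "sequence")) {
    tpl <- make_template(item)
    tot <- sum(vapply(tpl$parts, function(p) penlaws:::poly_length(p$xy),
                      numeric(1)))
    expect_equal(tot, 1, tolerance = 1e-6)
  }
  expect_length(make_template("word_mele")$boundaries, 3)
  expect_length(make_template("word_ele")$boundaries, 2)
  expect_equal(make_template("square")$n_corners, 4L)
  expect_equal(nrow(make_template("sequence")$elements), 3)
  expect_error(make_template("star"), "unsupported")
})

test_that("generation is deterministic given config and seed", {
  a <- generate_cohort(default_cohort_config(2, 2, c(1, 1, 1, 1, 1)), 7)
  b <- generate_cohort(default_cohort_config(2, 2, c(1, 1, 1, 1, 1)), 7)
  p1 <- withr::local_tempfile(fileext = ".csv")
  p2 <- withr::local_tempfile(fileext = ".csv")
  write_session(a, p1); write_session(b, p2)
  expect_identical(readLines(p1), readLines(p2))
  c_ <- generate_cohort(default_cohort_config(2, 2, c(1, 1, 1, 1, 1)), 8)
  expect_false(identical(
    a$trials[[1]]$samples$x, c_$trials[[1]]$samples$x))
})

test_that("beta = 1 scales speed with size at constant duration", {
  p <- quiet_profile()
  sp <- generate_copy_trial(p, "circle", "spontaneous", seed = 1)
  bg <- generate_copy_trial(p, "circle", "big", seed = 1)
  expect_equal(mean_speed(bg) / mean_speed(sp), 2, tolerance = 0.03)
  dur <- function(tr) max(tr$samples$t)
  expect_equal(dur(bg) / dur(sp), 1, tolerance = 0.02)
})

test_that("beta = 0 leaves speed flat so duration scales with size", {
  p <- quiet_profile(isochrony_beta = 0)
  sp <- generate_copy_trial(p, "circle", "spontaneous", seed = 2)
  bg <- generate_copy_trial(p, "circle", "big", seed = 2)
  expect_equal(mean_speed(bg) / mean_speed(sp), 1, tolerance = 0.03)
  dur <- function(tr) max(tr$samples$t)
  expect_equal(dur(bg) / dur(sp), 2, tolerance = 0.02)
})

test_that("noiseless sequences follow the fraction template exactly", {
  p <- quiet_profile(fraction_template = c(0.5, 0.3, 0.2))
  tr <- generate_copy_trial(p, "sequence", "spontaneous", seed = 3)
  fr <- fraction_times(segment_sequence(tr, 3))$fractions
  T_total <- attr(tr, "truth")$T_total
  expect_equal(fr, c(0.5, 0.3, 0.2), tolerance = 0.02 / T_total)
})

test_that("noiseless tunnel trials realise the steering law exactly", {
  p <- quiet_profile()
  g <- make_geometry("square", A = 250, W = 250 / 27)
  tr <- generate_tunnel_trial(p, g, seed = 5)
  expect_equal(attr(tr, "truth")$MT_target,
               p$steering_a + p$steering_b * g$ID)
  expect_equal(movement_time(tr, g), p$steering_a + p$steering_b * g$ID,
               tolerance = 0.02)
})

test_that("programmed excursions push trials over the exclusion rule", {
  p <- quiet_profile()
  g <- make_geometry("word_ele", A = 200, W = 200 / 14)
  tr <- generate_tunnel_trial(p, g, seed = 6,
                              excursion = list(start = 0.2, end = 0.61))
  of <- outside_fraction(tr, g)
  expect_gt(of, 0.4)
  expect_true(assess_tunnel_trial(tr, g)$excluded)
  tr2 <- generate_tunnel_trial(p, g, seed = 6,
                               excursion = list(start = 0.2, end = 0.45))
  expect_lt(abs(outside_fraction(tr2, g) - 0.25), 0.08)
})

test_that("cohorts mirror the study protocol", {
  ses <- generate_cohort(default_cohort_config(3, 4, c(1, 1, 1, 1, 1)),
                         seed = 9)
  meta <- penlaws:::.trial_meta(ses$trials)
  subj <- unique(meta[c("subject_id", "group")])
  expect_equal(sum(subj$group == "primary"), 3)
  expect_equal(sum(subj$group == "kindergarten"), 4)
  # word copying is a primary-school item only
  expect_equal(sum(meta$item == "word_mele" &
                     meta$group == "kindergarten"), 0)
  expect_gt(sum(meta$item == "word_mele" & meta$group == "primary"), 0)
  # no triangle in the tunnel game; the word tunnel is run by both groups
  expect_equal(sum(meta$game == "tunnel" & meta$item == "triangle"), 0)
  expect_gt(sum(meta$game == "tunnel" & meta$item == "word_ele" &
                  meta$group == "kindergarten"), 0)
  # 5 IDs x reps per tunnel item and subject
  tun <- meta[meta$game == "tunnel" & meta$subject_id == "P01" &
                meta$item == "circle", ]
  expect_equal(nrow(tun), 5)
  expect_equal(length(unique(tun$geometry_id)), 5)
  # every trial passes validation
  expect_true(all(vapply(ses$trials,
                         function(tr) length(validate_trial(tr)) == 0,
                         logical(1))))
})
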