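# Seedable synthetic pen-trajectory generator.  Cohorts are generated
# with the statistical structure the analysis assumes -- isochrony
# (speed scaling with size, exponent beta), homothety (a per-element
# fraction-time template held constant across modalities), and
# steering-law compliance (target movement times linear in the index of
# difficulty) -- with configurable violation profiles, so every pipeline
# stage is testable without child recordings.

.default_modality_factors <- list(
  spontaneous = list(size = 1, speed = 1),
  big = list(size = 2, speed = 1),
  small = list(size = 0.5, speed = 1),
  fast = list(size = 1, speed = 1.5),
  slow = list(size = 1, speed = 0.6))

#' Default motor profile of a synthetic subject
#'
#' Bundles the generative parameters of one subject: isochrony exponent
#' (`beta = 1`: speed scales in proportion to size at constant duration;
#' `beta = 0`: no modulation, so bigger shapes take proportionally
#' longer), base speed and sizes, the fraction-time template noise, the
#' steering-law intercept/slope and movement-time noise, lateral tremor,
#' and pen-lift durations.  Kindergarten profiles differ from primary
#' ones in the direction the developmental contrasts expect: 1.8x the
#' steering slope, 2x the movement-time noise, 1.5x the lateral noise.
#'
#' @param group `"primary"` or `"kindergarten"`.
#' @return An object of class `motor_profile` (a named list; every field
#'   can be overridden by assignment).
#' @export
default_motor_profile <- function(group = c("primary", "kindergarten")) {
  group <- match.arg(group)
  p <- list(
    isochrony_beta = 1,          # speed ~ size^beta at fixed duration
    base_speed = 60,             # mm/s, spontaneous modality
    base_size_mm = c(word_mele = 120, circle = 150, square = 150,
                     triangle = 150, sequence = 220),
    fraction_template = NULL,    # NULL: template arc shares
    fraction_noise_sd = 0.02,    # sd on per-element fractions
    lateral_noise_sd = 0.3,      # mm, tremor about the template path
    steering_a = 0.8,            # s, steering-law intercept
    steering_b = 0.08,           # s per ID unit, steering-law slope
    mt_noise_sd = 0.2,           # s, movement-time noise
    lift_s = 0.3,                # s, pen-up duration between symbols
    excursion_prob = 0,          # chance of a programmed border excursion
    speed_shape = "minimum_jerk",  # or "constant"
    modality_factors = .default_modality_factors)
  if (group == "kindergarten") {
    p$steering_b <- p$steering_b * 1.8
    p$mt_noise_sd <- p$mt_noise_sd * 2
    p$lateral_noise_sd <- p$lateral_noise_sd * 1.5
  }
  structure(p, class = "motor_profile")
}

.mjerk <- function(tau) 10 * tau^3 - 15 * tau^4 + 6 * tau^5

.element_fractions <- function(profile, tpl) {
  fr <- profile$fraction_template
  if (is.null(fr)) fr <- tpl$elements$s1 - tpl$elements$s0
  if (profile$fraction_noise_sd > 0) {
    fr <- fr + rnorm(length(fr), 0, profile$fraction_noise_sd)
    fr <- pmax(fr, 0.02)
  }
  fr / sum(fr)
}

# Position(s) on the scaled template at global ink-arc coordinates s
# (unit scale), for elements living on a single part.
.template_xy <- function(tpl, part_idx, s, L) {
  part <- tpl$parts[[part_idx]]
  interp_along(part$xy, part$cum, s - part$offset) * L
}

#' Generate a copy-game trial
#'
#' Samples a 50-Hz trajectory along the scaled item template.  The
#' overall speed is `base_speed * size_factor^beta * speed_factor`, so the
#' trial obeys isochrony exactly when `beta = 1` (duration independent of
#' size) and violates it when `beta = 0`.  Element durations follow the
#' fraction-time template perturbed by `fraction_noise_sd` and
#' renormalised; within each element the speed profile is a minimum-jerk
#' bell (or constant, per `profile$speed_shape`).  Sequences get pen-up
#' hover samples between symbols.  Additive Gaussian lateral noise is
#' applied to all coordinates.
#'
#' The generating ground truth (element durations, boundary arc
#' fractions, total length, programmed mean speed) is attached as
#' `attr(trial, "truth")`; it is in-memory metadata, not part of the
#' serialised session format.
#'
#' @param profile A [default_motor_profile()] (possibly modified).
#' @param item Copy item (`"word_mele"`, `"circle"`, `"square"`,
#'   `"triangle"`, `"sequence"`).
#' @param modality One of the five instruction modalities.
#' @param size_mm Total inked path length of the spontaneous execution;
#'   defaults to `profile$base_size_mm[item]`.
#' @param seed Optional integer seed; `NULL` continues the current RNG
#'   stream (used by [generate_cohort()]).
#' @param subject_id,group,trial_index Trial metadata.
#' @param fs Sampling rate, Hz.
#' @return A [trial_recording()] with a `"truth"` attribute.
#' @export
generate_copy_trial <- function(profile, item, modality, size_mm = NULL,
                                seed = NULL, subject_id = "S1",
                                group = "primary", trial_index = 1L,
                                fs = 50) {
  if (!is.null(seed)) set.seed(seed)
  mf <- profile$modality_factors[[modality]]
  if (is.null(mf)) stop("invalid modality: ", modality)
  tpl <- make_template(item)
  if (is.null(size_mm)) size_mm <- unname(profile$base_size_mm[item])
  dt <- 1 / fs
  L <- size_mm * mf$size
  v <- profile$base_speed * mf$size^profile$isochrony_beta * mf$speed
  T_total <- L / v
  fr <- .element_fractions(profile, tpl)
  durations <- T_total * fr
  el <- tpl$elements
  k <- nrow(el)
  has_lifts <- any(vapply(tpl$parts, `[[`, TRUE, "lift_after"))
  shape_fun <- if (identical(profile$speed_shape, "constant")) identity
    else .mjerk
  if (!has_lifts) {
    # connected trace: one uniform global grid (the end point is appended
    # only when it is at least half a sample away, keeping the grid
    # filterable downstream)
    edges <- cumsum(c(0, durations))
    tt <- seq(0, T_total, by = dt)
    if (T_total - tt[length(tt)] > dt / 2) tt <- c(tt, T_total)
    ki <- pmin(findInterval(tt, edges, rightmost.closed = TRUE), k)
    tau <- pmin(1, (tt - edges[ki]) / durations[ki])
    s <- el$s0[ki] + (el$s1[ki] - el$s0[ki]) * shape_fun(tau)
    xy <- .template_xy(tpl, 1L, s, L)
    t_all <- tt
    down <- rep(TRUE, length(tt))
    el_start_t <- edges[-(k + 1)]
    el_end_t <- edges[-1]
    # boundary positions as arc fractions of the sampled (noise-free)
    # trace -- the measurable ground truth for segmentation checks
    if (k > 1L) {
      cumarc <- poly_cum(xy)
      bs <- approx(tt, cumarc, xout = edges[2:k], rule = 2)$y
      boundary_trace_fracs <- bs / cumarc[length(cumarc)]
      trace_t <- tt
      trace_arc <- cumarc
    } else trace_t <- trace_arc <- boundary_trace_fracs <- numeric(0)
  } else {
    trace_t <- trace_arc <- boundary_trace_fracs <- numeric(0)
    t_all <- numeric(0); xy <- NULL; down <- logical(0)
    el_start_t <- el_end_t <- numeric(0)
    t0 <- 0
    for (j in seq_len(k)) {
      Tk <- durations[j]
      tt <- seq(0, Tk, by = dt)
      if (Tk - tt[length(tt)] > dt / 2) tt <- c(tt, Tk)
      tau <- tt / Tk
      s <- el$s0[j] + (el$s1[j] - el$s0[j]) * shape_fun(tau)
      pxy <- .template_xy(tpl, el$part[j], s, L)
      t_all <- c(t_all, t0 + tt)
      xy <- rbind(xy, pxy)
      down <- c(down, rep(TRUE, length(tt)))
      el_start_t <- c(el_start_t, t0)
      el_end_t <- c(el_end_t, t0 + Tk)
      t0 <- t0 + Tk
      if (tpl$parts[[el$part[j]]]$lift_after && j < k) {
        lift <- profile$lift_s
        th <- seq(dt, lift - dt / 2, by = dt)
        if (length(th)) {
          from <- pxy[nrow(pxy), ]
          to <- .template_xy(tpl, el$part[j + 1L], el$s0[j + 1L], L)
          w <- th / lift
          hov <- cbind(from[1] + (to[1] - from[1]) * w,
                       from[2] + (to[2] - from[2]) * w)
          t_all <- c(t_all, t0 + th)
          xy <- rbind(xy, hov)
          down <- c(down, rep(FALSE, length(th)))
        }
        t0 <- t0 + lift
      }
    }
  }
  if (profile$lateral_noise_sd > 0)
    xy <- xy + matrix(rnorm(length(xy), 0, profile$lateral_noise_sd),
                      ncol = 2)
  trial <- trial_recording(
    subject_id = subject_id, group = group, game = "copy", item = item,
    modality = modality, trial_index = trial_index,
    samples = pen_samples(t_all, xy[, 1], xy[, 2], pen_down = down))
  attr(trial, "truth") <- list(
    durations = durations, fractions = fr,
    boundary_fracs = el$s1[-k],  # ink-arc positions of element boundaries
    boundary_trace_fracs = boundary_trace_fracs,
    trace_t = trace_t, trace_arc = trace_arc,
    element_start_t = el_start_t, element_end_t = el_end_t,
    L = L, speed = v, T_total = T_total)
  trial
}

#' Generate a tunnel-game trial
#'
#' The target movement time of the measured central section is drawn from
#' the steering law, `MT* = a + b * ID + N(0, mt_noise_sd)` (redrawn while
#' nonpositive, bounded retries), and the pen traverses the center path at
#' the constant speed realising it: twice around for symbols, one pass
#' for words, with lead-in/lead-out at the same speed.  Lateral deviation
#' is an Ornstein-Uhlenbeck (AR(1)) process of stationary sd
#' `lateral_noise_sd` applied along the path normal, plus an optional
#' programmed excursion beyond the borders to exercise the exclusion
#' rule.
#'
#' @param profile A [default_motor_profile()].
#' @param geom A [make_geometry()].
#' @param seed Optional integer seed (`NULL`: current RNG stream).
#' @param excursion Optional `list(start, end, offset)`: arc fractions of
#'   the full trace between which the pen is pushed `offset` mm off the
#'   center line (cosine-ramped edges); `offset` defaults to `geom$W`.
#' @param subject_id,group,trial_index Trial metadata.
#' @param fs Sampling rate, Hz.
#' @return A [trial_recording()] with a `"truth"` attribute holding the
#'   programmed `MT_target` and `ID`.
#' @export
generate_tunnel_trial <- function(profile, geom, seed = NULL,
                                  excursion = NULL, subject_id = "S1",
                                  group = "primary", trial_index = 1L,
                                  fs = 50) {
  if (!is.null(seed)) set.seed(seed)
  dt <- 1 / fs
  mt <- -1
  for (i in 1:20) {
    mt <- profile$steering_a + profile$steering_b * geom$ID +
      rnorm(1, 0, profile$mt_noise_sd)
    if (mt > 0.1) break
  }
  if (mt <= 0.1) stop("could not draw a positive movement time")
  path <- geom$center_path
  if (geom$closed && geom$laps_required == 2L)
    path <- rbind(path, path[-1, , drop = FALSE])
  cum <- poly_cum(path)
  total <- cum[length(cum)]
  P <- total / geom$laps_required
  M <- if (geom$item == "word_ele") geom$gates[2] - geom$gates[1] else P
  v <- M / mt
  T_total <- total / v
  tt <- seq(0, T_total, by = dt)
  if (T_total - tt[length(tt)] > dt / 2) tt <- c(tt, T_total)
  s <- v * tt
  base <- interp_along(path, cum, s)
  # unit tangents/normals along the trace
  d <- rbind(base[2, ] - base[1, ], diff(base))
  dn <- sqrt(d[, 1]^2 + d[, 2]^2)
  dn[dn == 0] <- 1
  nx <- -d[, 2] / dn; ny <- d[, 1] / dn
  n <- length(tt)
  off <- numeric(n)
  if (profile$lateral_noise_sd > 0) {
    phi <- exp(-dt / 0.15)
    off[1] <- rnorm(1, 0, profile$lateral_noise_sd)
    innov <- rnorm(n - 1, 0, profile$lateral_noise_sd * sqrt(1 - phi^2))
    for (i in 2:n) off[i] <- phi * off[i - 1] + innov[i - 1]
  }
  if (!is.null(excursion)) {
    amp <- if (is.null(excursion$offset)) geom$W else excursion$offset
    frac <- s / total
    ramp <- 0.01
    w <- rep(0, n)
    inside <- frac >= excursion$start & frac <= excursion$end
    w[inside] <- 1
    lead <- frac >= excursion$start - ramp & frac < excursion$start
    w[lead] <- (1 - cos(pi * (frac[lead] - excursion$start + ramp) / ramp)) / 2
    tail_ <- frac > excursion$end & frac <= excursion$end + ramp
    w[tail_] <- (1 + cos(pi * (frac[tail_] - excursion$end) / ramp)) / 2
    off <- off + amp * w
  }
  xy <- cbind(base[, 1] + off * nx, base[, 2] + off * ny)
  trial <- trial_recording(
    subject_id = subject_id, group = group, game = "tunnel",
    item = geom$item, geometry_id = geom$geometry_id,
    trial_index = trial_index,
    samples = pen_samples(tt, xy[, 1], xy[, 2], pen_down = TRUE))
  attr(trial, "truth") <- list(MT_target = mt, ID = geom$ID, speed = v)
  trial
}

#' Default tunnel geometry catalogue
#'
#' Five indices of difficulty per item family, spanning a comparable
#' range with roughly geometric spacing so the steering regression has
#' even leverage: symbols at `ID = 8, 12, 18, 27, 40` and the word at
#' `ID = 6, 9, 14, 21, 32`.  Amplitudes are fixed per item and widths
#' derived as `W = A / ID`.
#'
#' @param symbol_ids,word_ids Index-of-difficulty values.
#' @param A_symbol,A_word Amplitudes in mm.
#' @return Named list of [make_geometry()] objects keyed by geometry id.
#' @export
default_geometry_catalog <- function(symbol_ids = c(8, 12, 18, 27, 40),
                                     word_ids = c(6, 9, 14, 21, 32),
                                     A_symbol = 250, A_word = 200) {
  geoms <- list()
  for (item in c("circle", "square")) {
    for (id in symbol_ids) {
      g <- make_geometry(item, A = A_symbol, W = A_symbol / id,
                         geometry_id = sprintf("%s_id%g", item, id))
      geoms[[g$geometry_id]] <- g
    }
  }
  for (id in word_ids) {
    g <- make_geometry("word_ele", A = A_word, W = A_word / id,
                       geometry_id = sprintf("word_ele_id%g", id))
    geoms[[g$geometry_id]] <- g
  }
  geoms
}

#' Default cohort configuration
#'
#' Mirrors the study protocol: 15 primary-school and 19 kindergarten
#' subjects; copy game with five modalities, word copying by the primary
#' group only; tunnel game on circle, square and word paths at five
#' indices of difficulty with 14 trials per subject and item (so each
#' steering regression has 12 residual degrees of freedom).
#'
#' @param n_primary,n_kindergarten Group sizes.
#' @param tunnel_reps Repetitions of each of the five IDs, summing to the
#'   per-item trial count.
#' @return Configuration list for [generate_cohort()].
#' @export
default_cohort_config <- function(n_primary = 15, n_kindergarten = 19,
                                  tunnel_reps = c(3, 3, 3, 3, 2)) {
  list(
    groups = list(
      primary = list(
        n = n_primary, profile = default_motor_profile("primary"),
        copy_items = c("word_mele", "circle", "square", "triangle",
                       "sequence")),
      kindergarten = list(
        n = n_kindergarten, profile = default_motor_profile("kindergarten"),
        copy_items = c("circle", "square", "triangle", "sequence"))),
    modalities = names(.default_modality_factors),
    tunnel_items = c("circle", "square", "word_ele"),
    tunnel_reps = tunnel_reps,
    subject_sd = list(base_speed = 0.15, steering_a = 0.15,
                      steering_b = 0.2),
    geometries = default_geometry_catalog())
}

.perturb_profile <- function(profile, sds) {
  profile$base_speed <- profile$base_speed * exp(rnorm(1, 0, sds$base_speed))
  profile$steering_a <- profile$steering_a * exp(rnorm(1, 0, sds$steering_a))
  profile$steering_b <- profile$steering_b * exp(rnorm(1, 0, sds$steering_b))
  profile
}

#' Generate a synthetic cohort session
#'
#' Full two-group session following the study protocol; reproducible
#' given the seed (two runs with the same configuration and seed yield
#' byte-identical session files).
#'
#' @param config A [default_cohort_config()] (possibly modified).
#' @param seed Integer seed.
#' @return A [session_data()] carrying the geometry catalogue; each trial
#'   keeps its `"truth"` attribute.
#' @export
generate_cohort <- function(config = default_cohort_config(), seed = 1) {
  set.seed(seed)
  geoms <- config$geometries
  by_item <- split(geoms, vapply(geoms, `[[`, "", "item"))
  trials <- list()
  for (gname in names(config$groups)) {
    grp <- config$groups[[gname]]
    prefix <- toupper(substr(gname, 1, 1))
    for (si in seq_len(grp$n)) {
      sid <- sprintf("%s%02d", prefix, si)
      prof <- .perturb_profile(grp$profile, config$subject_sd)
      ti <- 1L
      for (item in grp$copy_items) {
        for (mod in config$modalities) {
          trials[[length(trials) + 1L]] <- generate_copy_trial(
            prof, item, mod, subject_id = sid, group = gname,
            trial_index = ti)
          ti <- ti + 1L
        }
      }
      for (item in config$tunnel_items) {
        item_geoms <- by_item[[item]]
        for (gi in seq_along(item_geoms)) {
          for (rep_i in seq_len(config$tunnel_reps[gi])) {
            exc <- NULL
            if (prof$excursion_prob > 0 &&
                runif(1) < prof$excursion_prob) {
              len <- runif(1, 0.2, 0.6)
              start <- runif(1, 0.05, 0.9 - len)
              exc <- list(start = start, end = start + len)
            }
            trials[[length(trials) + 1L]] <- generate_tunnel_trial(
              prof, item_geoms[[gi]], excursion = exc, subject_id = sid,
              group = gname, trial_index = ti)
            ti <- ti + 1L
          }
        }
      }
    }
  }
  session_data(trials, geometries = geoms)
}
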