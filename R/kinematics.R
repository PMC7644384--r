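# Copy-task kinematics: border trimming, path length, discrete speed,
# zero-phase low-pass filtering, and the per-execution mean speed that the
# isochrony analysis consumes.

#' Trim trajectory borders
#'
#' Removes the first and last `floor(fraction * N)` samples of a trial to
#' avoid border effects at pen landing and lift (default 5% each end,
#' counted in samples).
#'
#' @param samples Sample table (see [pen_samples()]) with at least 3 rows.
#' @param fraction Fraction to discard at each end, in `[0, 0.5)`.
#' @return The trimmed sample table.
#' @export
trim_borders <- function(samples, fraction = 0.05) {
  stopifnot(fraction >= 0, fraction < 0.5)
  n <- nrow(samples)
  if (n < 3L) stop("too few samples to trim (need >= 3, got ", n, ")")
  k <- floor(fraction * n)
  out <- samples[(k + 1L):(n - k), , drop = FALSE]
  if (nrow(out) < 2L)
    stop("trial too short: fewer than 2 samples remain after trimming")
  out
}

#' Traced path length
#'
#' Sum of Euclidean distances between adjacent pen-down samples; airborne
#' (pen-up) gaps contribute nothing.
#'
#' @param samples Sample table with at least 2 rows.
#' @return Length in mm.
#' @export
path_length <- function(samples) {
  n <- nrow(samples)
  if (n < 2L) stop("path_length needs >= 2 samples")
  dx <- diff(samples$x)
  dy <- diff(samples$y)
  ok <- samples$pen_down[-n] & samples$pen_down[-1]
  sum(sqrt(dx[ok]^2 + dy[ok]^2))
}

#' Construct a speed profile
#'
#' Low-level constructor, mainly useful for testing the filtering stage in
#' isolation; analysis code obtains profiles from [raw_speed()].
#'
#' @param t_mid Midpoint times of the sample pairs, seconds.
#' @param v Speeds, mm/s.
#' @param run Integer id of the contiguous pen-down run each pair belongs
#'   to (filtering never crosses a pen-up gap).
#' @param filtered Logical flag.
#' @return An object of class `speed_profile`.
#' @export
speed_profile <- function(t_mid, v, run = rep(1L, length(v)),
                          filtered = FALSE) {
  stopifnot(length(t_mid) == length(v), length(run) == length(v))
  structure(list(t_mid = as.numeric(t_mid), v = as.numeric(v),
                 run = as.integer(run), filtered = isTRUE(filtered)),
            class = "speed_profile")
}

#' @export
print.speed_profile <- function(x, ...) {
  cat(sprintf("<speed_profile> %d point(s), %s, mean %.3g mm/s\n",
              length(x$v), if (x$filtered) "filtered" else "raw",
              mean(x$v)))
  invisible(x)
}

#' Discrete speed of a trajectory
#'
#' Speed of each sample pair: Euclidean displacement divided by the actual
#' timestamp difference, at the pair's midpoint time.  Pairs spanning a
#' pen-up gap are excluded, so multi-stroke trials yield one contiguous
#' run per stroke.
#'
#' @param samples Sample table with >= 2 rows and strictly increasing `t`.
#' @return A [speed_profile()] with `filtered = FALSE`.
#' @export
raw_speed <- function(samples) {
  n <- nrow(samples)
  if (n < 2L) stop("raw_speed needs >= 2 samples")
  dt <- diff(samples$t)
  if (any(dt <= 0))
    stop("duplicate or decreasing timestamp at sample index ",
         which(dt <= 0)[1] + 1L)
  ok <- samples$pen_down[-n] & samples$pen_down[-1]
  if (!any(ok)) stop("no adjacent pen-down sample pairs")
  v <- sqrt(diff(samples$x)^2 + diff(samples$y)^2) / dt
  t_mid <- (samples$t[-n] + samples$t[-1]) / 2
  # new run whenever at least one pair was dropped in between
  idx <- which(ok)
  run <- cumsum(c(1L, diff(idx) > 1L))
  speed_profile(t_mid[ok], v[ok], run = run)
}

.uniform_dt <- function(t_mid, tol = 0.2) {
  dt <- diff(t_mid)
  med <- median(dt)
  list(ok = med > 0 && all(abs(dt - med) <= tol * med), fs = 1 / med)
}

# Zero-phase filtering with odd-reflection padding at both ends:
# signal::filtfilt alone assumes zero initial conditions, which drags the
# edges of the output toward zero.
.zerophase <- function(bf, x) {
  n <- length(x)
  np <- min(n - 1L, 60L)
  head_pad <- 2 * x[1] - x[(np + 1L):2]
  tail_pad <- 2 * x[n] - x[(n - 1L):(n - np)]
  signal::filtfilt(bf, c(head_pad, x, tail_pad))[(np + 1L):(np + n)]
}

#' Low-pass filter a speed profile
#'
#' Zero-phase (forward--backward) Butterworth low-pass, applied separately
#' to each contiguous pen-down run; negative outputs are clamped to zero.
#' Filtering assumes near-uniform sampling: a run whose inter-sample
#' intervals deviate from their median by more than 20%, or that is
#' shorter than 15 points, or whose rate does not exceed twice the cutoff,
#' cannot be filtered.
#'
#' @param profile A [speed_profile()].
#' @param cutoff_hz Cutoff frequency, Hz.
#' @param order Butterworth order.
#' @param fallback If `TRUE`, runs that cannot be filtered are passed
#'   through unchanged (with a warning) instead of raising an error.
#' @return The filtered [speed_profile()] (`filtered = TRUE` when every
#'   run was filtered).
#' @export
lowpass_speed <- function(profile, cutoff_hz = 10, order = 4,
                          fallback = FALSE) {
  stopifnot(inherits(profile, "speed_profile"))
  v <- profile$v
  all_filtered <- TRUE
  for (r in unique(profile$run)) {
    sel <- profile$run == r
    nr <- sum(sel)
    reason <- NULL
    if (nr < 15L) {
      reason <- sprintf("run of %d points is too short to filter (need >= 15); skip filtering for this trial", nr)
    } else {
      u <- .uniform_dt(profile$t_mid[sel])
      if (!u$ok)
        reason <- "sampling too irregular to filter (>20% jitter about the median interval)"
      else if (u$fs <= 2 * cutoff_hz)
        reason <- sprintf("sampling rate %.3g Hz does not exceed twice the %g Hz cutoff", u$fs, cutoff_hz)
    }
    if (!is.null(reason)) {
      if (!fallback) stop(reason)
      warning(reason, "; returning raw speeds for this run")
      all_filtered <- FALSE
      next
    }
    bf <- signal::butter(order, cutoff_hz / (u$fs / 2), type = "low")
    v[sel] <- pmax(0, .zerophase(bf, profile$v[sel]))
  }
  speed_profile(profile$t_mid, v, run = profile$run,
                filtered = all_filtered)
}

#' Mean execution speed of a copy trial
#'
#' The single speed scalar used by the isochrony analysis: trim the first
#' and last 5% of the samples, compute discrete speeds, low-pass filter at
#' 10 Hz (zero phase), and average over all pen-down pairs.
#'
#' @param trial A valid copy [trial_recording()].
#' @param trim_fraction Border fraction discarded at each end.
#' @param cutoff_hz Low-pass cutoff, Hz.
#' @param order Butterworth order.
#' @return Mean speed in mm/s.
#' @export
mean_speed <- function(trial, trim_fraction = 0.05, cutoff_hz = 10,
                       order = 4) {
  sam <- trim_borders(trial$samples, trim_fraction)
  prof <- raw_speed(sam)
  prof <- suppressWarnings(
    lowpass_speed(prof, cutoff_hz = cutoff_hz, order = order,
                  fallback = TRUE))
  mean(prof$v)
}
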