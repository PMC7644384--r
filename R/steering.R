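# Tunnel-task steering analysis: tunnel geometry and index of difficulty
# (ID = A / W), movement-time extraction with the central-section discard
# rules, the >40% outside-path exclusion rule, and the per-subject
# steering-law regression MT = a + b * ID with its derived indices
# (R^2, RMSE, IP = 1/b, global MT).

#' Construct a tunnel geometry
#'
#' Builds the center polyline of a tunnel-shaped path and its index of
#' difficulty `ID = A / W`, where `W` is the border-to-border width and
#' `A` the amplitude of the gesture: the perimeter for symbols and the
#' path length for words, both measured along the center of the path.
#'
#' @param item `"circle"`, `"square"`, or `"word_ele"`.
#' @param A Amplitude in mm (> 0).
#' @param W Tunnel width in mm (> 0).
#' @param geometry_id Identifier; autogenerated when `NULL`.
#' @param gates For `word_ele`, the two gate positions (first-letter entry,
#'   last-letter exit) as fractions of the path length; movement time is
#'   measured between the first crossing of the first gate and the last
#'   crossing of the second.
#' @param n_points Vertices of the center polyline.
#' @return An object of class `tunnel_geometry` with fields
#'   `center_path`, `closed`, `W`, `A`, `ID`, `laps_required` (2 for
#'   symbols, 1 for words) and, for words, `gates` in mm of arc length.
#' @export
make_geometry <- function(item, A, W, geometry_id = NULL,
                          gates = c(0.1, 0.9), n_points = 721) {
  stopifnot(A > 0, W > 0)
  if (!item %in% c("circle", "square", "word_ele"))
    stop("unsupported tunnel item: ", item)
  tpl <- make_template(item)
  xy <- tpl$parts[[1]]$xy * A  # templates have unit arc length
  closed <- tpl$parts[[1]]$closed
  if (item == "circle") xy <- resample_polyline(xy, n_points)
  if (is.null(geometry_id))
    geometry_id <- sprintf("%s_id%g", item, A / W)
  structure(list(
    geometry_id = geometry_id, item = item, center_path = xy,
    closed = closed, W = W, A = A, ID = A / W,
    laps_required = if (item == "word_ele") 1L else 2L,
    gates = if (item == "word_ele") gates * A else NULL),
    class = "tunnel_geometry")
}

#' @export
print.tunnel_geometry <- function(x, ...) {
  cat(sprintf("<tunnel_geometry> %s: A=%.4g mm, W=%.4g mm, ID=%.4g\n",
              x$geometry_id, x$A, x$W, x$ID))
  invisible(x)
}

#' Fraction of the trace outside the tunnel borders
#'
#' A traced segment counts as outside when its midpoint lies farther than
#' `W / 2` from the center path; the returned value is the outside arc
#' length over the total traced arc length.  Trials with more than 40% of
#' the trace outside are excluded from the steering analysis (strict
#' inequality: a trace at exactly 40% is retained).
#'
#' @param trial A tunnel [trial_recording()] with >= 2 pen-down samples.
#' @param geom The [make_geometry()] the trial was steered on.
#' @return Fraction in `[0, 1]`.
#' @export
outside_fraction <- function(trial, geom) {
  sam <- trial$samples
  n <- nrow(sam)
  if (sum(sam$pen_down) < 2L)
    stop("tunnel trial needs >= 2 pen-down samples")
  seg <- poly_segments(geom$center_path)
  ok <- sam$pen_down[-n] & sam$pen_down[-1]  # pairs spanning a lift drop out
  dx <- diff(sam$x)[ok]; dy <- diff(sam$y)[ok]
  len <- sqrt(dx^2 + dy^2)
  if (sum(len) <= 0) stop("zero trace length")
  mids <- cbind(sam$x[-n][ok] + dx / 2, sam$y[-n][ok] + dy / 2)
  d <- polyline_distances(mids, seg)
  sum(len[d > geom$W / 2]) / sum(len)
}

.first_crossing <- function(prog, t, L) {
  i <- which(prog >= L)[1]
  if (is.na(i)) return(NA_real_)
  if (i == 1L) return(t[1])
  t[i - 1L] + (L - prog[i - 1L]) / (prog[i] - prog[i - 1L]) *
    (t[i] - t[i - 1L])
}

.last_crossing <- function(prog, t, L) {
  n <- length(prog)
  up <- which(prog[-1L] >= L & prog[-n] < L)
  if (!length(up)) {
    if (prog[1] >= L) return(t[1])
    return(NA_real_)
  }
  i <- up[length(up)] + 1L
  t[i - 1L] + (L - prog[i - 1L]) / (prog[i] - prog[i - 1L]) *
    (t[i] - t[i - 1L])
}

#' Movement time of a tunnel trial
#'
#' Projects each pen-down sample onto the center path, unwraps the
#' arc-length progress (with hysteresis: the projection may not jump more
#' than 25% of the path length between consecutive samples), and measures
#' the central section of the execution.  For symbols, steered twice
#' around (progress 0 to 2P), the first and last half-laps are discarded:
#' MT is the time from progress `0.5 P` to `1.5 P`, i.e. one complete
#' central circle, or the central four of the eight traced square sides.
#' For the word, MT runs from the first crossing of the entry gate to the
#' last crossing of the exit gate.  Crossing times are linearly
#' interpolated between samples.
#'
#' @param trial A non-excluded tunnel [trial_recording()].
#' @param geom The trial's [make_geometry()].
#' @return Movement time in seconds.
#' @export
movement_time <- function(trial, geom) {
  sam <- trial$samples[trial$samples$pen_down, , drop = FALSE]
  if (nrow(sam) < 2L) stop("tunnel trial needs >= 2 pen-down samples")
  seg <- poly_segments(geom$center_path)
  prog <- unwrap_progress(cbind(sam$x, sam$y), seg, closed = geom$closed)
  P <- seg$total
  if (geom$item == "word_ele") {
    g <- geom$gates
    t1 <- .first_crossing(prog, sam$t, g[1])
    t2 <- .last_crossing(prog, sam$t, g[2])
  } else {
    t1 <- .first_crossing(prog, sam$t, 0.5 * P)
    t2 <- .first_crossing(prog, sam$t, 1.5 * P)
  }
  if (is.na(t1) || is.na(t2) || t2 <= t1)
    stop("incomplete trial: progress never reached the measurement ",
         "landmarks (subject ", trial$subject_id, ", geometry ",
         geom$geometry_id, ")")
  t2 - t1
}

#' Assess a tunnel trial against the exclusion rule
#'
#' Convenience wrapper combining [outside_fraction()], the strict >40%
#' exclusion rule, and [movement_time()].
#'
#' @param trial,geom As in [movement_time()].
#' @param max_outside Exclusion threshold on the outside fraction.
#' @return List with `outside_fraction`, `excluded`, `MT` (`NA` when
#'   excluded or unmeasurable) and `status` (`"ok"`, `"excluded"`, or
#'   `"incomplete"`).
#' @export
assess_tunnel_trial <- function(trial, geom, max_outside = 0.4) {
  of <- outside_fraction(trial, geom)
  excluded <- of > max_outside
  mt <- NA_real_
  status <- "ok"
  if (excluded) {
    status <- "excluded"
  } else {
    mt <- tryCatch(movement_time(trial, geom), error = function(e) NA_real_)
    if (is.na(mt)) status <- "incomplete"
  }
  list(outside_fraction = of, excluded = excluded, MT = mt, status = status)
}

#' Per-subject steering-law regression
#'
#' Ordinary least squares of movement time on the index of difficulty,
#' `MT = a + b * ID`.  Reports the coefficients, `R^2`, the regression
#' RMSE (`sqrt(SSres / n)`), the slope's F-test p-value on `(1, n - 2)`
#' degrees of freedom, the index of performance `IP = 1 / b` (defined only
#' for significant fits with positive slope) and the global MT, the median
#' movement time across all IDs.
#'
#' @param trials `data.frame` with numeric columns `ID` and `MT` (already
#'   restricted to non-excluded, measurable trials); an optional logical
#'   `excluded` column is honoured by dropping those rows.
#' @param alpha Significance level for defining IP.
#' @param subject_id,item Carried through into the result for reporting.
#' @return An object of class `steering_fit`.
#' @export
fit_steering <- function(trials, alpha = 0.05, subject_id = NA_character_,
                         item = NA_character_) {
  if (!is.null(trials$excluded))
    trials <- trials[!trials$excluded, , drop = FALSE]
  trials <- trials[is.finite(trials$ID) & is.finite(trials$MT), ,
                   drop = FALSE]
  n <- nrow(trials)
  if (n < 3L) stop("fit_steering needs >= 3 usable trials, got ", n)
  if (length(unique(trials$ID)) < 2L)
    stop("degenerate design: all trials share one index of difficulty")
  fit <- lm(MT ~ ID, data = trials)
  a <- unname(coef(fit)[1]); b <- unname(coef(fit)[2])
  res <- trials$MT - (a + b * trials$ID)
  ssres <- sum(res^2)
  sstot <- sum((trials$MT - mean(trials$MT))^2)
  if (sstot <= .Machine$double.eps * n * max(1, mean(trials$MT)^2)) {
    r2 <- 0; p <- 1
  } else {
    r2 <- 1 - ssres / sstot
    f <- if (ssres <= 0) Inf else (sstot - ssres) / (ssres / (n - 2))
    p <- pf(f, 1, n - 2, lower.tail = FALSE)
  }
  structure(list(
    subject_id = subject_id, item = item, n = n, a = a, b = b,
    R2 = r2, RMSE = sqrt(ssres / n), p = p,
    IP = if (p < alpha && b > 0) 1 / b else NA_real_,
    global_MT = median(trials$MT)),
    class = "steering_fit")
}

#' @export
print.steering_fit <- function(x, ...) {
  cat(sprintf(
    "<steering_fit> %s/%s: MT = %.3g + %.3g ID (n=%d, R2=%.3f, RMSE=%.3g s, p=%.3g)\n  IP=%.4g, global MT=%.3g s\n",
    x$subject_id, x$item, x$a, x$b, x$n, x$R2, x$RMSE, x$p, x$IP,
    x$global_MT))
  invisible(x)
}

#' Minimal significant R-squared of a simple regression
#'
#' The smallest coefficient of determination at which a one-predictor
#' linear regression with `df` residual degrees of freedom is significant
#' at level `alpha`, via the F(1, df) quantile:
#' `R2crit = F / (F + df)`.  With 12 residual degrees of freedom and
#' `alpha = 0.05` this is 0.28 (2 dp), the threshold separating
#' significant from non-significant steering fits at the study's trial
#' count.
#'
#' @param df Residual degrees of freedom (>= 1).
#' @param alpha Significance level in `(0, 1)`.
#' @return The critical R-squared.
#' @export
critical_r2 <- function(df, alpha = 0.05) {
  stopifnot(df >= 1, alpha > 0, alpha < 1)
  f <- qf(1 - alpha, 1, df)
  f / (f + df)
}
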