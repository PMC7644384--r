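# Element segmentation: letters of a cursive word (transition = lowest
# point between two letters) and symbols of a sequence (stroke = symbol),
# plus the fraction-time statistic used by the homothety analysis.

#' Segment a cursive word into letters
#'
#' The transition between two cursive letters is the lowest point of the
#' trace between them.  Candidate transitions are interior local minima of
#' the (smoothed) canonical y coordinate of the concatenated pen-down
#' trace; among candidates at least `min_sep_fraction` of the total arc
#' length apart (and that far from either end), the `n_letters - 1` with
#' the lowest y are selected.  A trial carrying `manual_boundaries`
#' bypasses detection entirely.
#'
#' Unexpected pen lifts inside a word are tolerated: strokes are
#' concatenated in time before the minima search, so a lift point is
#' itself a candidate transition.
#'
#' @param trial A copy [trial_recording()] of a (mostly) connected word.
#' @param n_letters Number of letters expected (>= 1).
#' @param min_sep_fraction Minimum arc-length separation between selected
#'   transitions, as a fraction of total arc length.
#' @param smooth_cutoff_hz Cutoff of the zero-phase low-pass applied to y
#'   before the minima search (cursive letter content lies well below it);
#'   set to `Inf` to search the raw coordinate.
#' @return An object of class `segment_boundaries` with the ordered
#'   element labels, the transition sample indices (into the concatenated
#'   pen-down trace), their arc-length fractions, and the per-element time
#'   intervals.
#' @export
segment_word <- function(trial, n_letters, min_sep_fraction = 0.05,
                         smooth_cutoff_hz = 6) {
  stopifnot(n_letters >= 1)
  strokes <- split_strokes(trial)
  sam <- do.call(rbind, strokes)
  n <- nrow(sam)
  labels <- paste0("element", seq_len(n_letters))
  if (n_letters == 1L)
    return(.word_bounds(sam, integer(0), labels))
  if (!is.null(trial$manual_boundaries)) {
    b <- sort(unique(as.integer(trial$manual_boundaries)))
    if (length(b) != n_letters - 1L || any(b <= 1L) || any(b >= n))
      stop("manual_boundaries must give ", n_letters - 1L,
           " interior sample indices")
    return(.word_bounds(sam, b, labels))
  }
  arc <- poly_cum(cbind(sam$x, sam$y))
  total <- arc[n]
  if (total <= 0) stop("degenerate word trace of zero length")
  # only y is smoothed (for valley detection): cursive traces contain
  # near-cusps whose shape any coordinate smoothing would distort
  ys <- .smooth_series(sam$y, sam$t, smooth_cutoff_hz)
  i <- 2:(n - 1L)
  is_min <- ys[i] <= ys[i - 1L] & ys[i] <= ys[i + 1L] &
    (ys[i] < ys[i - 1L] | ys[i] < ys[i + 1L])
  cand <- i[is_min]
  sep <- min_sep_fraction * total
  cand <- cand[arc[cand] >= sep & arc[cand] <= total - sep]
  cand <- cand[order(ys[cand])]
  chosen <- integer(0)
  for (c0 in cand) {
    if (length(chosen) == n_letters - 1L) break
    if (all(abs(arc[c0] - arc[chosen]) >= sep))
      chosen <- c(chosen, c0)
  }
  if (length(chosen) < n_letters - 1L)
    stop("segmentation failure: found ", length(chosen),
         " qualifying y-minima, need ", n_letters - 1L,
         " (subject ", trial$subject_id,
         "); supply manual_boundaries for this trial")
  # refine each transition on a lightly smoothed y: heavy smoothing
  # locates valleys robustly but drags their position toward the flatter
  # neighbour, so take the argmin in a narrow window around the detection
  yf <- .smooth_series(sam$y, sam$t, 10)
  win <- 0.015 * total
  chosen <- vapply(chosen, function(c0) {
    cand <- which(abs(arc - arc[c0]) <= win)
    cand <- cand[cand > 1L & cand < n]
    cand[which.min(yf[cand])]
  }, integer(1))
  .word_bounds(sam, sort(chosen), labels, arc = arc)
}

.smooth_series <- function(v, t, cutoff_hz) {
  if (!is.finite(cutoff_hz) || length(v) < 15L) return(v)
  dt <- diff(t)
  med <- median(dt)
  if (med <= 0 || any(abs(dt - med) > 0.5 * med)) return(v)
  fs <- 1 / med
  if (fs <= 2 * cutoff_hz) return(v)
  bf <- signal::butter(4, cutoff_hz / (fs / 2), type = "low")
  .zerophase(bf, v)
}

.word_bounds <- function(sam, transitions, labels, arc = NULL) {
  if (is.null(arc)) arc <- poly_cum(cbind(sam$x, sam$y))
  n <- nrow(sam)
  edges <- c(1L, transitions, n)
  structure(list(
    type = "word", labels = labels, transitions = transitions,
    arc_fractions = if (length(transitions)) arc[transitions] / arc[n]
      else numeric(0),
    t_start = sam$t[edges[-length(edges)]],
    t_end = sam$t[edges[-1L]],
    durations = sam$t[edges[-1L]] - sam$t[edges[-length(edges)]]),
    class = "segment_boundaries")
}

#' Segment a symbol sequence by pen lifts
#'
#' Each stroke of a multi-stroke trial is one symbol: the first and last
#' frames with the pen on the surface delimit the symbol.
#'
#' @param trial A copy [trial_recording()] whose strokes correspond 1:1 to
#'   symbols.
#' @param expected_symbols Optional expected symbol count; a stroke-count
#'   mismatch is an error naming both counts.
#' @param labels Optional element labels (defaults to `symbol1`, ...).
#' @return A `segment_boundaries` object with per-symbol time intervals.
#' @export
segment_sequence <- function(trial, expected_symbols = NULL, labels = NULL) {
  strokes <- split_strokes(trial)
  k <- length(strokes)
  if (!is.null(expected_symbols) && k != expected_symbols)
    stop("stroke/symbol count mismatch: trial has ", k,
         " stroke(s) but ", expected_symbols, " symbol(s) expected")
  if (is.null(labels)) labels <- paste0("symbol", seq_len(k))
  t_start <- vapply(strokes, function(s) s$t[1], numeric(1))
  t_end <- vapply(strokes, function(s) s$t[nrow(s)], numeric(1))
  structure(list(type = "sequence", labels = labels,
                 transitions = integer(0), arc_fractions = numeric(0),
                 t_start = t_start, t_end = t_end,
                 durations = t_end - t_start),
            class = "segment_boundaries")
}

#' @export
print.segment_boundaries <- function(x, ...) {
  cat(sprintf("<segment_boundaries> %s, %d element(s): %s\n", x$type,
              length(x$labels),
              paste(sprintf("%s=%.3gs", x$labels, x$durations),
                    collapse = " ")))
  invisible(x)
}

#' Fraction of time per element
#'
#' The homothety statistic: each element's duration divided by the total
#' execution duration.  For symbol sequences the airborne time between
#' symbols is excluded from both numerator and denominator by default
#' ("time dedicated to an element" is ink-on-surface time); set
#' `include_penup = TRUE` to charge each inter-symbol gap to the preceding
#' element instead.
#'
#' @param bounds A `segment_boundaries` from [segment_word()] or
#'   [segment_sequence()].
#' @param trial The trial the boundaries were computed on (unused for
#'   word boundaries; kept for a uniform signature).
#' @param include_penup Include inter-symbol pen-up time (sequences only).
#' @return An object of class `fraction_times`: list with `fractions`
#'   (summing to 1) and `labels`.
#' @export
fraction_times <- function(bounds, trial = NULL, include_penup = FALSE) {
  stopifnot(inherits(bounds, "segment_boundaries"))
  dur <- bounds$durations
  if (include_penup && bounds$type == "sequence" && length(dur) > 1L) {
    k <- length(dur)
    dur <- c(bounds$t_start[-1L] - bounds$t_start[-k],
             dur[k])
  }
  tot <- sum(dur)
  if (tot <= 0) stop("zero total element duration")
  structure(list(fractions = dur / tot, labels = bounds$labels),
            class = "fraction_times")
}

#' @export
print.fraction_times <- function(x, ...) {
  cat("<fraction_times>",
      paste(sprintf("%s=%.3f", x$labels, x$fractions), collapse = " "),
      "\n")
  invisible(x)
}
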