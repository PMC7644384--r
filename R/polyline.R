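# Polyline geometry helpers shared by the templates, the tunnel analysis
# and the generators.  All polylines are 2-column matrices in mm; closed
# paths carry their first vertex repeated at the end so that cumulative
# arc length spans the full perimeter.

poly_seglen <- function(xy) {
  d <- diff(xy)
  sqrt(d[, 1]^2 + d[, 2]^2)
}

poly_cum <- function(xy) c(0, cumsum(poly_seglen(xy)))

poly_length <- function(xy) sum(poly_seglen(xy))

# Drop consecutive duplicated vertices (zero-length segments break approx()).
poly_dedupe <- function(xy, tol = 1e-12) {
  if (nrow(xy) < 2L) return(xy)
  keep <- c(TRUE, poly_seglen(xy) > tol)
  xy[keep, , drop = FALSE]
}

# Resample to n vertices equally spaced in arc length.
resample_polyline <- function(xy, n) {
  xy <- poly_dedupe(xy)
  cum <- poly_cum(xy)
  s <- seq(0, cum[length(cum)], length.out = n)
  interp_along(xy, cum, s)
}

# Positions at arc-length coordinates s (vectorised).
interp_along <- function(xy, cum, s) {
  cbind(
    approx(cum, xy[, 1], xout = s, rule = 2)$y,
    approx(cum, xy[, 2], xout = s, rule = 2)$y
  )
}

# Precompute segment data for repeated point projections.
poly_segments <- function(xy) {
  xy <- poly_dedupe(xy)
  n <- nrow(xy)
  a <- xy[-n, , drop = FALSE]
  d <- diff(xy)
  len <- sqrt(d[, 1]^2 + d[, 2]^2)
  list(a = a, d = d, len = len, len2 = len^2, cum0 = poly_cum(xy)[-n],
       total = sum(len))
}

# Project one point onto the polyline; optionally restrict candidate
# segments to an arc-length window around prev_s (hysteresis for closed or
# self-intersecting paths).  Returns c(s, dist).
project_point <- function(px, py, seg, prev_s = NULL, window = NULL,
                          closed = FALSE) {
  tt <- ((px - seg$a[, 1]) * seg$d[, 1] + (py - seg$a[, 2]) * seg$d[, 2]) /
    pmax(seg$len2, 1e-300)
  tt <- pmin(pmax(tt, 0), 1)
  qx <- seg$a[, 1] + tt * seg$d[, 1]
  qy <- seg$a[, 2] + tt * seg$d[, 2]
  d2 <- (px - qx)^2 + (py - qy)^2
  if (!is.null(prev_s) && !is.null(window)) {
    s_cand <- seg$cum0 + tt * seg$len
    delta <- s_cand - prev_s
    if (closed) {
      P <- seg$total
      delta <- (delta + P / 2) %% P - P / 2
    }
    ok <- abs(delta) <= window
    if (any(ok)) d2[!ok] <- Inf
  }
  j <- which.min(d2)
  c(s = seg$cum0[j] + tt[j] * seg$len[j], dist = sqrt(d2[j]))
}

# Distances of many points to the polyline (no arc tracking).
polyline_distances <- function(pts, seg) {
  vapply(seq_len(nrow(pts)), function(i) {
    project_point(pts[i, 1], pts[i, 2], seg)[["dist"]]
  }, numeric(1))
}

# Monotone unwrapped arc-length progress of a traced point sequence along a
# center path.  For closed paths progress keeps increasing across laps;
# consecutive projections are constrained to move at most max_jump of the
# path length, which prevents aliasing at self-intersections.
unwrap_progress <- function(pts, seg, closed = FALSE, max_jump = 0.25) {
  n <- nrow(pts)
  P <- seg$total
  win <- max_jump * P
  prog <- numeric(n)
  p0 <- project_point(pts[1, 1], pts[1, 2], seg)
  s_prev <- p0[["s"]]
  # A trace is assumed to start near the path origin: map a projection that
  # falls just before the start line to a small negative progress.
  prog[1] <- if (closed && s_prev > 0.75 * P) s_prev - P else s_prev
  if (n > 1) {
    for (i in 2:n) {
      pi <- project_point(pts[i, 1], pts[i, 2], seg,
                          prev_s = s_prev, window = win, closed = closed)
      delta <- pi[["s"]] - s_prev
      if (closed) delta <- (delta + P / 2) %% P - P / 2
      prog[i] <- prog[i - 1] + delta
      s_prev <- pi[["s"]]
    }
  }
  prog
}
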