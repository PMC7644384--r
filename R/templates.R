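# Shape templates for the synthetic generator and the tunnel geometries.
# Every template is normalised so its total inked arc length is 1; words
# and sequences expose element boundaries (arc-length fractions / pen-lift
# markers) that generators treat as ground truth.

# Arch from (0, y0) to (width, y1) peaking at `peak`; used for the cursive
# 'm'.  Endpoint values are exact; the peak is hit at t = 1/2.
.arch <- function(y0, y1, peak, width, n = 40) {
  t <- seq(0, 1, length.out = n)
  y <- y0 * cos(pi * t / 2)^2 + y1 * sin(pi * t / 2)^2 +
    (peak - (y0 + y1) / 2) * sin(pi * t)
  cbind(width * t, y)
}

# Cursive loop (ascender or small 'e' bowl): starts and ends on the
# baseline, single hump in y, loop in x when loop_x exceeds advance/(2*pi).
.loop <- function(height, advance, loop_x, n = 60) {
  t <- seq(0, 1, length.out = n)
  cbind(advance * t - loop_x * sin(2 * pi * t),
        height / 2 * (1 - cos(2 * pi * t)))
}

.letter_m <- function() {
  h <- 0.5; dip <- 0.12; w <- 0.22
  rbind(.arch(0, dip, h, w),
        .arch(dip, dip, h, w)[-1, ],
        .arch(dip, 0, h, w)[-1, ])
}
.letter_e <- function() .loop(0.35, 0.30, 0.10)
.letter_l <- function() .loop(0.95, 0.34, 0.13)

# Concatenate letters so each starts where the previous ended (joins on
# the baseline are the construction valleys).  Returns xy plus join rows.
.assemble_word <- function(letters) {
  xy <- letters[[1]]
  joins <- integer(0)
  for (i in seq_along(letters)[-1]) {
    shift <- xy[nrow(xy), ]
    joins <- c(joins, nrow(xy))
    nxt <- sweep(letters[[i]][-1, , drop = FALSE], 2, -shift)
    xy <- rbind(xy, nxt)
  }
  list(xy = xy, joins = joins)
}

.unit_circle <- function(n = 181) {
  th <- seq(pi / 2, pi / 2 - 2 * pi, length.out = n)  # start top, clockwise
  cbind(cos(th), sin(th))
}
.unit_square <- function() {
  corners <- rbind(c(0, 0), c(1, 0), c(1, 1), c(0, 1), c(0, 0))
  resample_polyline(corners, 201)
}
.unit_triangle <- function() {
  corners <- rbind(c(0, 0), c(1, 0), c(0.5, sqrt(3) / 2), c(0, 0))
  resample_polyline(corners, 202)  # 201 segments, 67 per side
}

.template_cache <- new.env(parent = emptyenv())

#' Shape template of a copy or tunnel item
#'
#' Unit-scale polyline(s) of an item: closed symbol outlines, cursive-like
#' words assembled from loop and arch primitives with letter joins on the
#' baseline, and the three-symbol sequence with pen-lift markers.  The
#' total inked arc length is 1; multiplying coordinates by `L` yields a
#' shape of total path length `L`.
#'
#' @param item One of `"circle"`, `"square"`, `"triangle"`, `"sequence"`,
#'   `"word_mele"`, `"word_ele"`.
#' @return An object of class `shape_template`: `parts` (list of
#'   `label`/`xy`/`closed`/`lift_after`), `elements` (data frame with the
#'   label, part index, and global ink-arc range `s0`, `s1` of each
#'   element), `boundaries` (interior element boundaries as arc
#'   fractions), and `n_corners` for polygonal symbols.
#' @export
make_template <- function(item) {
  if (!is.null(.template_cache[[item]])) return(.template_cache[[item]])
  tpl <- switch(item,
    circle = .symbol_template(item, .unit_circle(), NA_integer_),
    square = .symbol_template(item, .unit_square(), 4L),
    triangle = .symbol_template(item, .unit_triangle(), 3L),
    sequence = .sequence_template(),
    word_mele = .word_template(item,
      list(.letter_m(), .letter_e(), .letter_l(), .letter_e()),
      c("m", "e1", "l", "e2")),
    word_ele = .word_template(item,
      list(.letter_e(), .letter_l(), .letter_e()),
      c("e1", "l", "e2")),
    stop("unsupported item: ", item))
  .template_cache[[item]] <- tpl
  tpl
}

.symbol_template <- function(item, xy, n_corners) {
  xy <- xy / poly_length(xy)
  structure(list(
    item = item,
    parts = list(list(label = item, xy = xy, closed = TRUE,
                      lift_after = FALSE, cum = poly_cum(xy), offset = 0)),
    elements = data.frame(label = item, part = 1L, s0 = 0, s1 = 1),
    boundaries = numeric(0), labels = item, n_corners = n_corners),
    class = "shape_template")
}

.word_template <- function(item, letters, labels) {
  asm <- .assemble_word(letters)
  xy <- asm$xy / poly_length(asm$xy)
  cum <- poly_cum(xy)
  bounds <- cum[asm$joins] / cum[length(cum)]
  s0 <- c(0, bounds); s1 <- c(bounds, 1)
  structure(list(
    item = item,
    parts = list(list(label = item, xy = xy, closed = FALSE,
                      lift_after = FALSE, cum = cum, offset = 0)),
    elements = data.frame(label = labels, part = 1L, s0 = s0, s1 = s1),
    boundaries = bounds, labels = labels, n_corners = NA_integer_),
    class = "shape_template")
}

.sequence_template <- function() {
  shapes <- list(circle = .unit_circle(), square = .unit_square(),
                 triangle = .unit_triangle())
  # equal ink arc per symbol, laid out left to right
  shapes <- lapply(shapes, function(s) s / poly_length(s))
  xoff <- 0
  parts <- list()
  for (i in seq_along(shapes)) {
    s <- shapes[[i]]
    s[, 1] <- s[, 1] - min(s[, 1]) + xoff
    xoff <- max(s[, 1]) + 0.08
    parts[[i]] <- list(label = names(shapes)[i], xy = s, closed = TRUE,
                       lift_after = i < length(shapes), cum = poly_cum(s),
                       offset = (i - 1) / 3)
  }
  # renormalise the ensemble so total ink arc is 1
  tot <- sum(vapply(parts, function(p) p$cum[length(p$cum)], numeric(1)))
  parts <- lapply(parts, function(p) {
    p$xy <- p$xy / tot; p$cum <- p$cum / tot; p
  })
  k <- length(parts)
  structure(list(
    item = "sequence", parts = parts,
    elements = data.frame(label = names(shapes), part = seq_len(k),
                          s0 = (seq_len(k) - 1) / k, s1 = seq_len(k) / k),
    boundaries = seq_len(k - 1) / k, labels = names(shapes),
    n_corners = NA_integer_), class = "shape_template")
}

#' @export
print.shape_template <- function(x, ...) {
  cat(sprintf("<shape_template> %s: %d part(s), %d element(s)\n",
              x$item, length(x$parts), nrow(x$elements)))
  invisible(x)
}
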