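# Canonical data model for pen recordings and the on-disk session format.
#
# Canonical frame: millimetres, y increasing upward, origin at the canvas
# bottom-left.  Device metadata (pixels_per_mm, y_axis, and, for y-down
# devices, canvas_height_px) describes the on-disk convention; readers
# convert to the canonical frame, writers convert back, so a write/read
# round trip is the identity.

.groups <- c("kindergarten", "primary")
.games <- c("copy", "tunnel")
.items <- c("word_mele", "circle", "square", "triangle", "sequence", "word_ele")
.modalities <- c("spontaneous", "big", "small", "fast", "slow")

#' Construct a pen sample table
#'
#' @param t Time in seconds, strictly increasing within a trial.
#' @param x,y Coordinates in mm, canonical y-up frame.
#' @param pen_down Logical; `TRUE` while the stylus touches the surface.
#' @param pressure Optional unitless pressure in `[0, 1]`; `NA` if absent.
#' @return A `data.frame` with columns `t`, `x`, `y`, `pen_down`, `pressure`.
#' @export
pen_samples <- function(t, x, y, pen_down = TRUE, pressure = NA_real_) {
  data.frame(t = as.numeric(t), x = as.numeric(x), y = as.numeric(y),
             pen_down = rep_len(as.logical(pen_down), length(t)),
             pressure = rep_len(as.numeric(pressure), length(t)))
}

#' Construct a trial recording
#'
#' One pen execution: metadata plus an ordered sample table.  Copy trials
#' carry a `modality` and no geometry; tunnel trials carry a `geometry_id`
#' and no modality.
#'
#' @param subject_id Opaque subject identifier.
#' @param group `"kindergarten"` or `"primary"`.
#' @param game `"copy"` or `"tunnel"`.
#' @param item One of `r paste0('\x60"', .items, '"\x60', collapse = ", ")`.
#' @param modality Copy-game instruction condition, or `NA` for tunnel trials.
#' @param geometry_id Tunnel geometry reference, or `NA` for copy trials.
#' @param trial_index Integer distinguishing repeated executions.
#' @param samples Sample table from [pen_samples()].
#' @param manual_boundaries Optional integer sample indices overriding
#'   automatic letter segmentation (see [segment_word()]).
#' @return An object of class `trial_recording`.
#' @export
trial_recording <- function(subject_id, group, game, item,
                            modality = NA_character_,
                            geometry_id = NA_character_,
                            trial_index = 1L, samples,
                            manual_boundaries = NULL) {
  structure(
    list(subject_id = as.character(subject_id), group = as.character(group),
         game = as.character(game), item = as.character(item),
         modality = as.character(modality),
         geometry_id = as.character(geometry_id),
         trial_index = as.integer(trial_index), samples = samples,
         manual_boundaries = manual_boundaries),
    class = "trial_recording")
}

#' Validate a trial recording
#'
#' Checks the structural invariants of a trial: known enum values, at least
#' two pen-down samples, strictly increasing timestamps, finite
#' coordinates, pressure in `[0, 1]` when present, modality/geometry
#' consistency with the game, and the item/game restrictions (`word_mele`
#' is a copy item, `word_ele` a tunnel item, and the triangle never appears
#' in the tunnel game).
#'
#' @param trial A [trial_recording()].
#' @return Character vector of violations; empty when the trial is valid.
#' @export
validate_trial <- function(trial) {
  bad <- character(0)
  sam <- trial$samples
  if (!is.data.frame(sam) || nrow(sam) < 2L) {
    bad <- c(bad, "fewer than 2 samples")
    return(bad)
  }
  if (!trial$group %in% .groups) bad <- c(bad, "unknown group")
  if (!trial$game %in% .games) bad <- c(bad, "unknown game")
  if (!trial$item %in% .items) bad <- c(bad, "unknown item")
  if (sum(sam$pen_down) < 2L) bad <- c(bad, "fewer than 2 pen-down samples")
  if (any(!is.finite(sam$t)) || any(!is.finite(sam$x)) ||
      any(!is.finite(sam$y)))
    bad <- c(bad, "non-finite sample values")
  else if (any(diff(sam$t) <= 0)) bad <- c(bad, "non-monotone timestamps")
  pr <- sam$pressure[!is.na(sam$pressure)]
  if (length(pr) && (any(pr < 0) || any(pr > 1)))
    bad <- c(bad, "pressure outside [0, 1]")
  if (trial$game == "copy") {
    if (is.na(trial$modality) || !trial$modality %in% .modalities)
      bad <- c(bad, "copy trial without valid modality")
    if (!is.na(trial$geometry_id)) bad <- c(bad, "copy trial with geometry")
    if (trial$item == "word_ele") bad <- c(bad, "word_ele is a tunnel item")
  } else if (trial$game == "tunnel") {
    if (is.na(trial$geometry_id)) bad <- c(bad, "tunnel trial without geometry")
    if (!is.na(trial$modality)) bad <- c(bad, "tunnel trial with modality")
    if (trial$item %in% c("word_mele", "triangle", "sequence"))
      bad <- c(bad, sprintf("item '%s' not allowed in tunnel game", trial$item))
  }
  bad
}

#' Construct a session
#'
#' @param trials List of [trial_recording()] objects.
#' @param device Device metadata: `pixels_per_mm` (> 0), `y_axis`
#'   (`"up"` or `"down"`), and `canvas_height_px` (required when
#'   `y_axis == "down"`).
#' @param geometries Optional list of [make_geometry()] objects used by the
#'   session's tunnel trials.
#' @return An object of class `session_data`.
#' @export
session_data <- function(trials = list(),
                         device = list(pixels_per_mm = 1, y_axis = "up",
                                       canvas_height_px = NA_real_),
                         geometries = NULL) {
  if (is.null(device$canvas_height_px)) device$canvas_height_px <- NA_real_
  stopifnot(device$pixels_per_mm > 0, device$y_axis %in% c("up", "down"))
  if (device$y_axis == "down" && !is.finite(device$canvas_height_px))
    stop("y-down device metadata requires canvas_height_px")
  structure(list(device = device, trials = trials, geometries = geometries),
            class = "session_data")
}

#' @export
print.session_data <- function(x, ...) {
  cat(sprintf("<session_data> %d trial(s), device %.3g px/mm, y-%s\n",
              length(x$trials), x$device$pixels_per_mm, x$device$y_axis))
  invisible(x)
}

# device-frame -> canonical mm y-up
.canonicalize <- function(x, y, device) {
  ppm <- device$pixels_per_mm
  if (identical(device$y_axis, "down"))
    list(x = x / ppm, y = (device$canvas_height_px - y) / ppm)
  else
    list(x = x / ppm, y = y / ppm)
}

# canonical -> device frame (inverse of .canonicalize)
.devicize <- function(x, y, device) {
  ppm <- device$pixels_per_mm
  if (identical(device$y_axis, "down"))
    list(x = x * ppm, y = device$canvas_height_px - y * ppm)
  else
    list(x = x * ppm, y = y * ppm)
}

.session_format <- function(path, format) {
  if (!is.null(format)) return(match.arg(format, c("csv", "json")))
  if (grepl("\\.json$", path, ignore.case = TRUE)) "json" else "csv"
}

.csv_cols <- c("subject_id", "group", "game", "item", "modality",
               "geometry_id", "trial_index", "t", "x", "y", "pen_down",
               "pressure")

# Quarantine invalid trials; keep the reasons in a validation report.
.validate_session <- function(trials) {
  reasons <- lapply(trials, validate_trial)
  bad <- lengths(reasons) > 0
  report <- if (any(bad)) {
    data.frame(
      subject_id = vapply(trials[bad], `[[`, "", "subject_id"),
      trial_index = vapply(trials[bad], `[[`, 1L, "trial_index"),
      item = vapply(trials[bad], `[[`, "", "item"),
      reason = vapply(reasons[bad], paste, "", collapse = "; "))
  } else {
    data.frame(subject_id = character(0), trial_index = integer(0),
               item = character(0), reason = character(0))
  }
  list(trials = trials[!bad], report = report)
}

#' Read a session file
#'
#' Reads the long-format CSV dialect (one row per sample, device metadata
#' on a leading `#device` line) or the nested JSON dialect.  Coordinates
#' are converted to the canonical mm, y-up frame using the device
#' metadata.  Trials violating structural invariants are quarantined, not
#' silently dropped: they are removed from `$trials` and listed with
#' reasons in the `"validation"` attribute of the result.
#'
#' @param path Path to a `.csv` or `.json` session file.
#' @param format `"csv"`, `"json"`, or `NULL` to infer from the extension.
#' @return A [session_data()] object; `attr(, "validation")` holds the
#'   quarantine report (zero-row data frame when all trials are valid).
#' @export
read_session <- function(path, format = NULL) {
  if (!file.exists(path)) stop("session file not found: ", path)
  format <- .session_format(path, format)
  if (format == "csv") .read_session_csv(path) else .read_session_json(path)
}

.parse_device_line <- function(line) {
  if (!startsWith(line, "#device")) stop("missing #device header line")
  kv <- strsplit(trimws(sub("^#device", "", line)), "[[:space:]]+")[[1]]
  pairs <- strsplit(kv, "=", fixed = TRUE)
  vals <- setNames(vapply(pairs, `[`, "", 2), vapply(pairs, `[`, "", 1))
  list(pixels_per_mm = as.numeric(vals[["pixels_per_mm"]]),
       y_axis = unname(vals[["y_axis"]]),
       canvas_height_px = if ("canvas_height_px" %in% names(vals))
         suppressWarnings(as.numeric(vals[["canvas_height_px"]]))
       else NA_real_)
}

.read_session_csv <- function(path) {
  first <- readLines(path, n = 1L)
  device <- .parse_device_line(first)
  df <- read.csv(path, skip = 1L, header = TRUE, na.strings = c("NA", ""))
  missing_cols <- setdiff(.csv_cols, names(df))
  if (length(missing_cols))
    stop("session CSV missing required column(s): ",
         paste(missing_cols, collapse = ", "))
  for (col in c("subject_id", "group", "game", "item", "modality",
                "geometry_id"))
    df[[col]] <- as.character(df[[col]])
  trials <- list()
  if (nrow(df)) {
    key <- paste(df$subject_id, df$game, df$item, df$modality,
                 df$geometry_id, df$trial_index, sep = "\r")
    for (k in unique(key)) {
      rows <- df[key == k, , drop = FALSE]
      xy <- .canonicalize(rows$x, rows$y, device)
      trials[[length(trials) + 1L]] <- trial_recording(
        subject_id = rows$subject_id[1], group = rows$group[1],
        game = rows$game[1], item = rows$item[1],
        modality = rows$modality[1], geometry_id = rows$geometry_id[1],
        trial_index = rows$trial_index[1],
        samples = pen_samples(rows$t, xy$x, xy$y,
                              pen_down = rows$pen_down != 0,
                              pressure = rows$pressure))
    }
  }
  vs <- .validate_session(trials)
  out <- session_data(vs$trials, device = device)
  attr(out, "validation") <- vs$report
  out
}

.read_session_json <- function(path) {
  obj <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  if (is.null(obj$device)) stop("session JSON missing required field: device")
  device <- list(
    pixels_per_mm = as.numeric(obj$device$pixels_per_mm),
    y_axis = obj$device$y_axis,
    canvas_height_px = if (is.null(obj$device$canvas_height_px)) NA_real_
      else as.numeric(obj$device$canvas_height_px))
  trials <- lapply(obj$trials, function(tr) {
    for (f in c("subject_id", "group", "game", "item", "samples"))
      if (is.null(tr[[f]]))
        stop("session JSON trial missing required field: ", f)
    m <- do.call(rbind, lapply(tr$samples, function(s)
      vapply(s, function(v) if (is.null(v)) NA_real_ else as.numeric(v),
             numeric(1))))
    xy <- .canonicalize(m[, 2], m[, 3], device)
    trial_recording(
      subject_id = tr$subject_id, group = tr$group, game = tr$game,
      item = tr$item,
      modality = if (is.null(tr$modality)) NA_character_ else tr$modality,
      geometry_id = if (is.null(tr$geometry_id)) NA_character_
        else tr$geometry_id,
      trial_index = if (is.null(tr$trial_index)) 1L
        else as.integer(tr$trial_index),
      samples = pen_samples(m[, 1], xy$x, xy$y, pen_down = m[, 4] != 0,
                            pressure = m[, 5]),
      manual_boundaries = if (is.null(tr$manual_boundaries)) NULL
        else as.integer(unlist(tr$manual_boundaries)))
  })
  geoms <- NULL
  if (!is.null(obj$geometries))
    geoms <- lapply(obj$geometries, function(g)
      make_geometry(g$item, A = as.numeric(g$A), W = as.numeric(g$W),
                    geometry_id = g$geometry_id))
  vs <- .validate_session(trials)
  out <- session_data(vs$trials, device = device, geometries = geoms)
  attr(out, "validation") <- vs$report
  out
}

#' Write a session file
#'
#' Inverse of [read_session()]: canonical coordinates are converted back to
#' the device's on-disk convention so that a write/read round trip is the
#' identity on valid sessions.
#'
#' @param session A [session_data()] object.
#' @param path Output path (`.csv` or `.json`).
#' @param format `"csv"`, `"json"`, or `NULL` to infer from the extension.
#' @return `path`, invisibly.
#' @export
write_session <- function(session, path, format = NULL) {
  stopifnot(inherits(session, "session_data"))
  format <- .session_format(path, format)
  if (format == "csv") .write_session_csv(session, path)
  else .write_session_json(session, path)
  invisible(path)
}

.device_line <- function(device) {
  line <- sprintf("#device pixels_per_mm=%.17g y_axis=%s",
                  device$pixels_per_mm, device$y_axis)
  if (is.finite(device$canvas_height_px))
    line <- paste0(line, sprintf(" canvas_height_px=%.17g",
                                 device$canvas_height_px))
  line
}

.write_session_csv <- function(session, path) {
  rows <- lapply(session$trials, function(tr) {
    xy <- .devicize(tr$samples$x, tr$samples$y, session$device)
    data.frame(subject_id = tr$subject_id, group = tr$group, game = tr$game,
               item = tr$item, modality = tr$modality,
               geometry_id = tr$geometry_id, trial_index = tr$trial_index,
               t = tr$samples$t, x = xy$x, y = xy$y,
               pen_down = as.integer(tr$samples$pen_down),
               pressure = tr$samples$pressure)
  })
  df <- if (length(rows)) do.call(rbind, rows)
  else as.data.frame(setNames(rep(list(character(0)), length(.csv_cols)),
                              .csv_cols))
  con <- file(path, open = "wt", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(.device_line(session$device), con)
  write.csv(df, con, row.names = FALSE, na = "")
}

.write_session_json <- function(session, path) {
  obj <- list(
    device = session$device,
    trials = lapply(session$trials, function(tr) {
      xy <- .devicize(tr$samples$x, tr$samples$y, session$device)
      out <- list(subject_id = tr$subject_id, group = tr$group,
                  game = tr$game, item = tr$item, modality = tr$modality,
                  geometry_id = tr$geometry_id,
                  trial_index = tr$trial_index,
                  samples = unname(cbind(tr$samples$t, xy$x, xy$y,
                                         as.numeric(tr$samples$pen_down),
                                         tr$samples$pressure)))
      if (!is.null(tr$manual_boundaries))
        out$manual_boundaries <- tr$manual_boundaries
      out
    }))
  if (!is.null(session$geometries))
    obj$geometries <- lapply(session$geometries, function(g)
      list(geometry_id = g$geometry_id, item = g$item, A = g$A, W = g$W))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       na = "null", pretty = FALSE)
}

#' Split a trial into strokes
#'
#' A stroke is a maximal contiguous run of pen-down samples; the first and
#' last frames of a stroke are the beginning and end of the drawn element.
#'
#' @param trial A [trial_recording()].
#' @return List of sample `data.frame`s, one per stroke, in temporal order.
#' @export
split_strokes <- function(trial) {
  sam <- trial$samples
  if (!any(sam$pen_down))
    stop("empty trial: no pen-down samples (subject ", trial$subject_id, ")")
  r <- rle(sam$pen_down)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  idx <- which(r$values)
  lapply(idx, function(i) sam[starts[i]:ends[i], , drop = FALSE])
}
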