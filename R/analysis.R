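# End-to-end cohort analysis: instruction compliance, isochrony,
# homothety, developmental contrasts and the steering-law battery, with
# full provenance (every input trial ends up analysed, excluded or
# quarantined, and the counts reconcile).

.subject_table <- function(trials) {
  unique(data.frame(
    subject_id = vapply(trials, `[[`, "", "subject_id"),
    group = vapply(trials, `[[`, "", "group")))
}

.trial_meta <- function(trials) {
  data.frame(
    idx = seq_along(trials),
    subject_id = vapply(trials, `[[`, "", "subject_id"),
    group = vapply(trials, `[[`, "", "group"),
    game = vapply(trials, `[[`, "", "game"),
    item = vapply(trials, `[[`, "", "item"),
    modality = vapply(trials, `[[`, "", "modality"),
    geometry_id = vapply(trials, `[[`, "", "geometry_id"),
    trial_index = vapply(trials, `[[`, 1L, "trial_index"))
}

# subjects x modalities matrix of a per-trial statistic
.modality_matrix <- function(trials, meta, sel, stat_fun, modalities,
                             subjects) {
  m <- matrix(NA_real_, nrow = length(subjects), ncol = length(modalities),
              dimnames = list(subjects, modalities))
  for (i in which(sel)) {
    v <- tryCatch(stat_fun(trials[[i]]), error = function(e) NA_real_)
    r <- meta$subject_id[i]; c0 <- meta$modality[i]
    if (r %in% subjects && c0 %in% modalities) {
      cur <- m[r, c0]
      m[r, c0] <- if (is.na(cur)) v else mean(c(cur, v))  # average repeats
    }
  }
  m
}

.omnibus_with_posthoc <- function(m, alpha) {
  res <- tryCatch(friedman_blocks(m), error = function(e) NULL)
  if (is.null(res)) return(NULL)
  if (!res$degenerate && res$p < alpha)
    res$posthoc <- posthoc_pairs(m[complete.cases(m), , drop = FALSE],
                                 alpha = alpha)
  res
}

#' Run the full cohort analysis
#'
#' Executes the analysis stages in order on a validated session:
#' instruction compliance (Wilcoxon matched pairs on big-vs-small path
#' length), isochrony (per group and item: Friedman of mean speed across
#' modalities, Bonferroni post hoc on significance), the developmental
#' contrast (Mann-Whitney on spontaneous-modality speed between groups),
#' homothety (per element: Friedman of fraction times across modalities),
#' and the steering-law battery (per-subject regressions after the >40%
#' exclusion rule, plus group and item contrasts on global MT, RMSE and
#' IP).  Stage-level failures are collected; independent stages continue.
#'
#' @param session A [session_data()], e.g. from [read_session()] or
#'   [generate_cohort()].
#' @param config Optional list: `alpha` (default 0.05), `geometries`
#'   (defaults to `session$geometries`), `word_letters` (default 4 for
#'   the copy word), `max_outside` (default 0.4).
#' @return An object of class `cohort_result` with elements `compliance`,
#'   `isochrony`, `developmental`, `homothety`, `steering` (per-subject
#'   fits and contrasts), `exclusion_log`, `validation`, and `counts`.
#' @export
run_analysis <- function(session, config = list()) {
  alpha <- config$alpha %||% 0.05
  geoms <- config$geometries %||% session$geometries
  word_letters <- config$word_letters %||% 4L
  max_outside <- config$max_outside %||% 0.4
  trials <- session$trials
  if (!length(trials)) {
    warning("empty session: nothing to analyse")
    return(structure(list(
      compliance = NULL, isochrony = list(), developmental = list(),
      homothety = list(), steering = list(fits = NULL, contrasts = list()),
      exclusion_log = NULL,
      validation = attr(session, "validation"),
      counts = c(input = 0L, analysed = 0L, excluded = 0L, invalid = 0L),
      alpha = alpha), class = "cohort_result"))
  }
  meta <- .trial_meta(trials)
  subj <- .subject_table(trials)
  modalities <- names(.default_modality_factors)
  copy_sel <- meta$game == "copy"

  ## -- compliance: big vs small traced length, paired by subject --------
  len_mat <- .modality_matrix(trials, meta, copy_sel,
                              function(tr) path_length(tr$samples),
                              c("big", "small"), subj$subject_id)
  ok <- complete.cases(len_mat)
  compliance <- tryCatch(
    wilcoxon_matched(len_mat[ok, "big"], len_mat[ok, "small"]),
    error = function(e) NULL)

  ## -- isochrony: Friedman of mean speed across modalities --------------
  isochrony <- list()
  for (g in unique(subj$group)) {
    gsub <- subj$subject_id[subj$group == g]
    for (item in unique(meta$item[copy_sel & meta$group == g])) {
      sel <- copy_sel & meta$group == g & meta$item == item
      m <- .modality_matrix(trials, meta, sel, mean_speed, modalities, gsub)
      res <- .omnibus_with_posthoc(m, alpha)
      if (!is.null(res))
        isochrony[[paste(g, item, sep = ":")]] <- res
    }
  }

  ## -- developmental contrast: spontaneous speed between groups ---------
  developmental <- list()
  if (length(unique(subj$group)) == 2) {
    for (item in c("circle", "square", "triangle", "sequence")) {
      sp <- lapply(c("primary", "kindergarten"), function(g) {
        idx <- which(copy_sel & meta$group == g & meta$item == item &
                       meta$modality == "spontaneous")
        vapply(idx, function(i)
          tryCatch(mean_speed(trials[[i]]), error = function(e) NA_real_),
          numeric(1))
      })
      sp <- lapply(sp, function(v) v[is.finite(v)])
      if (length(sp[[1]]) >= 3 && length(sp[[2]]) >= 3)
        developmental[[item]] <- mann_whitney(sp[[1]], sp[[2]])
    }
  }

  ## -- homothety: per-element Friedman of fraction times ----------------
  homothety <- list()
  .fractions_of <- function(tr) {
    if (tr$item == "sequence")
      fraction_times(segment_sequence(tr, expected_symbols = 3L))$fractions
    else
      fraction_times(segment_word(tr, n_letters = word_letters))$fractions
  }
  for (g in unique(subj$group)) {
    gsub <- subj$subject_id[subj$group == g]
    for (item in intersect(c("word_mele", "sequence"),
                           unique(meta$item[copy_sel & meta$group == g]))) {
      sel <- which(copy_sel & meta$group == g & meta$item == item)
      n_el <- if (item == "sequence") 3L else word_letters
      mats <- lapply(seq_len(n_el), function(e)
        matrix(NA_real_, length(gsub), length(modalities),
               dimnames = list(gsub, modalities)))
      for (i in sel) {
        fr <- tryCatch(.fractions_of(trials[[i]]),
                       error = function(e) NULL)
        if (is.null(fr) || length(fr) != n_el) next
        for (e in seq_len(n_el))
          mats[[e]][meta$subject_id[i], meta$modality[i]] <- fr[e]
      }
      for (e in seq_len(n_el)) {
        res <- .omnibus_with_posthoc(mats[[e]], alpha)
        if (!is.null(res))
          homothety[[sprintf("%s:%s:element%d", g, item, e)]] <- res
      }
    }
  }

  ## -- steering: exclusion, MT, per-subject fits, contrasts -------------
  tun_idx <- which(meta$game == "tunnel")
  excl_rows <- list()
  fits <- list()
  if (length(tun_idx) && length(geoms)) {
    assess <- data.frame(idx = tun_idx, MT = NA_real_, ID = NA_real_,
                         outside = NA_real_, excluded = FALSE,
                         status = "missing-geometry")
    for (r in seq_along(tun_idx)) {
      i <- tun_idx[r]
      geom <- geoms[[meta$geometry_id[i]]]
      if (is.null(geom)) next
      a <- tryCatch(assess_tunnel_trial(trials[[i]], geom,
                                        max_outside = max_outside),
                    error = function(e) NULL)
      if (is.null(a)) { assess$status[r] <- "error"; next }
      assess$MT[r] <- a$MT; assess$ID[r] <- geom$ID
      assess$outside[r] <- a$outside_fraction
      assess$excluded[r] <- a$excluded; assess$status[r] <- a$status
    }
    excl_rows <- cbind(meta[assess$idx,
                            c("subject_id", "group", "item", "trial_index")],
                       assess[c("ID", "MT", "outside", "excluded",
                                "status")])
    for (sid in unique(meta$subject_id[tun_idx])) {
      for (item in unique(meta$item[tun_idx])) {
        rows <- excl_rows[excl_rows$subject_id == sid &
                            excl_rows$item == item &
                            excl_rows$status == "ok", , drop = FALSE]
        fit <- tryCatch(
          fit_steering(data.frame(ID = rows$ID, MT = rows$MT),
                       alpha = alpha, subject_id = sid, item = item),
          error = function(e) NULL)
        if (!is.null(fit)) fits[[paste(sid, item, sep = ":")]] <- fit
      }
    }
  }
  fit_df <- if (length(fits)) do.call(rbind, lapply(fits, function(f)
    data.frame(subject_id = f$subject_id, item = f$item,
               group = subj$group[match(f$subject_id, subj$subject_id)],
               n = f$n, a = f$a, b = f$b, R2 = f$R2, RMSE = f$RMSE,
               p = f$p, significant = f$p < alpha, IP = f$IP,
               global_MT = f$global_MT, row.names = NULL)))
  else NULL

  contrasts <- list()
  if (!is.null(fit_df)) {
    for (metric in c("global_MT", "RMSE", "IP")) {
      for (item in unique(fit_df$item)) {
        d <- fit_df[fit_df$item == item & is.finite(fit_df[[metric]]), ]
        gs <- split(d[[metric]], d$group)
        if (length(gs) == 2 && all(lengths(gs) >= 3))
          contrasts[[paste("group", metric, item, sep = ":")]] <-
            mann_whitney(gs$kindergarten, gs$primary)
      }
      # symbol/word contrast within each group (Friedman across items)
      for (g in unique(fit_df$group)) {
        d <- fit_df[fit_df$group == g & is.finite(fit_df[[metric]]), ]
        if (length(unique(d$item)) >= 3) {
          m <- tapply(d[[metric]], list(d$subject_id, d$item), mean)
          res <- .omnibus_with_posthoc(m, alpha)
          if (!is.null(res))
            contrasts[[paste("item", metric, g, sep = ":")]] <- res
        }
      }
    }
  }

  validation <- attr(session, "validation")
  n_invalid <- if (is.null(validation)) 0L else nrow(validation)
  n_excluded <- if (length(excl_rows))
    sum(excl_rows$status != "ok") else 0L
  counts <- c(input = length(trials) + n_invalid,
              analysed = length(trials) - n_excluded,
              excluded = n_excluded, invalid = n_invalid)
  structure(list(
    compliance = compliance, isochrony = isochrony,
    developmental = developmental, homothety = homothety,
    steering = list(fits = fit_df, contrasts = contrasts),
    exclusion_log = if (length(excl_rows)) excl_rows else NULL,
    validation = validation, counts = counts, alpha = alpha),
    class = "cohort_result")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.cohort_result <- function(x, ...) {
  cat("<cohort_result>\n  trials:",
      paste(names(x$counts), x$counts, sep = "=", collapse = ", "), "\n")
  if (!is.null(x$compliance))
    cat(sprintf("  compliance (big vs small length): p=%.3g\n",
                x$compliance$p))
  for (k in names(x$isochrony))
    cat(sprintf("  isochrony %s: p=%.3g\n", k, x$isochrony[[k]]$p))
  nh <- sum(vapply(x$homothety, function(r) r$p < x$alpha, TRUE))
  cat(sprintf("  homothety: %d/%d elements with a modality effect\n",
              nh, length(x$homothety)))
  if (!is.null(x$steering$fits))
    cat(sprintf("  steering: %d fits, %d significant\n",
                nrow(x$steering$fits), sum(x$steering$fits$significant)))
  invisible(x)
}

.flatten_stat <- function(key, res) {
  data.frame(test = key, name = res$test_name,
             statistic = res$statistic, p = res$p,
             exact = res$exact, row.names = NULL)
}

.fmt_num <- function(df) {
  for (j in seq_along(df))
    if (is.numeric(df[[j]])) df[[j]] <- signif(df[[j]], 6)
  df
}

#' Write the analysis result tables
#'
#' Writes machine-readable result surfaces under `out_dir`:
#' `steering_fits.csv` (per-subject a, b, R2, RMSE, p, IP, global MT),
#' `stat_tests.csv` (every omnibus test), `posthoc.csv` (post-hoc pair
#' outcomes for significant omnibus tests only), `exclusion_log.csv`, and
#' `summary.json` mirroring the whole result.  Numbers are fixed to six
#' significant digits, so re-running on the same inputs reproduces
#' byte-identical files.
#'
#' @param result A `cohort_result` from [run_analysis()].
#' @param out_dir Output directory, created if needed.
#' @return Character vector of files written, invisibly.
#' @export
render_report <- function(result, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  written <- character(0)
  w <- function(df, name) {
    p <- file.path(out_dir, name)
    write.csv(.fmt_num(df), p, row.names = FALSE, na = "")
    written <<- c(written, p)
  }
  omni <- c(
    if (!is.null(result$compliance)) list(compliance = result$compliance),
    result$isochrony,
    setNames(result$developmental,
             paste0("developmental:", names(result$developmental))),
    result$homothety, result$steering$contrasts)
  if (length(omni))
    w(do.call(rbind, Map(.flatten_stat, names(omni), omni)),
      "stat_tests.csv")
  ph <- list()
  for (k in names(omni))
    if (!is.null(omni[[k]]$posthoc))
      ph[[k]] <- cbind(test = k, omni[[k]]$posthoc)
  if (length(ph)) w(do.call(rbind, ph), "posthoc.csv")
  if (!is.null(result$steering$fits)) w(result$steering$fits,
                                        "steering_fits.csv")
  if (!is.null(result$exclusion_log)) w(result$exclusion_log,
                                        "exclusion_log.csv")
  summary_obj <- list(
    alpha = result$alpha, counts = as.list(result$counts),
    compliance_p = if (!is.null(result$compliance)) result$compliance$p,
    isochrony = lapply(result$isochrony, function(r)
      list(p = signif(r$p, 6), significant = r$p < result$alpha)),
    homothety = lapply(result$homothety, function(r)
      list(p = signif(r$p, 6), significant = r$p < result$alpha)),
    developmental = lapply(result$developmental, function(r)
      list(p = signif(r$p, 6))),
    steering_contrasts = lapply(result$steering$contrasts, function(r)
      list(p = signif(r$p, 6))))
  sp <- file.path(out_dir, "summary.json")
  jsonlite::write_json(summary_obj, sp, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  written <- c(written, sp)
  invisible(written)
}
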