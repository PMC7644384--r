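# Nonparametric statistical battery: Wilcoxon matched pairs, Friedman
# with Bonferroni post hoc, Mann-Whitney U.  Ties are handled with
# midranks throughout.  Exact p-values are computed by complete
# enumeration (or a convolution equivalent) below fixed size thresholds
# and by normal/chi-square approximations above them, so that study-sized
# samples (n = 15 or 19) take the approximate path as any standard
# package would.
#
# Two-sided exact p convention: min(1, 2 * min(lower tail, upper tail)),
# the same doubling rule stats::wilcox.test applies.

.stat_result <- function(test_name, statistic, p, n, exact,
                         degenerate = FALSE, posthoc = NULL, note = NULL) {
  structure(list(test_name = test_name, statistic = unname(statistic),
                 p = min(1, max(0, p)), n = n, exact = exact,
                 degenerate = degenerate, posthoc = posthoc, note = note),
            class = "stat_result")
}

#' @export
print.stat_result <- function(x, ...) {
  cat(sprintf("<stat_result> %s: statistic=%.4g, p=%.4g (%s%s)\n",
              x$test_name, x$statistic, x$p,
              if (x$exact) "exact" else "approximate",
              if (x$degenerate) ", degenerate" else ""))
  if (!is.null(x$posthoc)) {
    cat("  post hoc (Bonferroni):\n")
    print(x$posthoc, row.names = FALSE)
  }
  invisible(x)
}

.two_sided_p <- function(dist, obs, weights = NULL, eps = 1e-9) {
  if (is.null(weights)) weights <- rep(1 / length(dist), length(dist))
  lo <- sum(weights[dist <= obs + eps])
  hi <- sum(weights[dist >= obs - eps])
  min(1, 2 * min(lo, hi))
}

#' Wilcoxon matched-pairs signed-rank test
#'
#' Zero differences are removed; ties among absolute differences receive
#' midranks.  The statistic is `V`, the sum of ranks of positive
#' differences.  The p-value is exact (enumeration over all `2^n` sign
#' assignments) for `n <= exact_max` pairs and a normal approximation with
#' tie correction and continuity correction otherwise.
#'
#' @param x,y Paired numeric vectors of equal length; at least 5 nonzero
#'   differences must remain.
#' @param alternative `"two.sided"`, `"greater"` (x tends above y), or
#'   `"less"`.
#' @param exact_max Largest n for which the exact distribution is used.
#' @return A `stat_result`.
#' @export
wilcoxon_matched <- function(x, y, alternative = "two.sided",
                             exact_max = 12L) {
  alternative <- match.arg(alternative, c("two.sided", "greater", "less"))
  stopifnot(length(x) == length(y))
  d <- x - y
  d <- d[d != 0]
  n <- length(d)
  if (n == 0L) stop("degenerate: all paired differences are zero")
  if (n < 5L)
    stop("wilcoxon_matched needs >= 5 nonzero differences, got ", n)
  r <- rank(abs(d))
  V <- sum(r[d > 0])
  if (n <= exact_max) {
    sums <- 0
    for (ri in r) sums <- c(sums, sums + ri)  # 2^n equally likely V values
    p <- switch(alternative,
      two.sided = .two_sided_p(sums, V),
      greater = mean(sums >= V - 1e-9),
      less = mean(sums <= V + 1e-9))
    exact <- TRUE
  } else {
    mu <- n * (n + 1) / 4
    tie <- tapply(r, r, length)
    sig2 <- n * (n + 1) * (2 * n + 1) / 24 - sum(tie^3 - tie) / 48
    z <- (V - mu - sign(V - mu) * 0.5) / sqrt(sig2)
    p <- switch(alternative,
      two.sided = 2 * pnorm(-abs(z)),
      greater = pnorm(z, lower.tail = FALSE),
      less = pnorm(z))
    exact <- FALSE
  }
  .stat_result("wilcoxon_matched", c(V = V), p, n, exact)
}

#' Mann-Whitney U test
#'
#' Midranks for ties; the statistic is `U = R1 - n1 (n1 + 1) / 2` with
#' `R1` the rank sum of the first group.  Exact p by enumeration over all
#' `choose(n1 + n2, n1)` group labelings when `n1 + n2 <= exact_max`,
#' normal approximation with tie and continuity corrections otherwise.
#'
#' @param g1,g2 Numeric vectors, each with >= 3 observations.
#' @param alternative `"two.sided"`, `"greater"` (g1 tends above g2), or
#'   `"less"`.
#' @param exact_max Largest pooled n for which enumeration is used.
#' @return A `stat_result`.
#' @export
mann_whitney <- function(g1, g2, alternative = "two.sided",
                         exact_max = 12L) {
  alternative <- match.arg(alternative, c("two.sided", "greater", "less"))
  n1 <- length(g1); n2 <- length(g2)
  if (n1 < 3L || n2 < 3L)
    stop("mann_whitney needs >= 3 observations per group")
  N <- n1 + n2
  r <- rank(c(g1, g2))
  U <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  if (N <= exact_max) {
    picks <- combn(N, n1)
    Udist <- colSums(matrix(r[picks], nrow = n1)) - n1 * (n1 + 1) / 2
    p <- switch(alternative,
      two.sided = .two_sided_p(Udist, U),
      greater = mean(Udist >= U - 1e-9),
      less = mean(Udist <= U + 1e-9))
    exact <- TRUE
  } else {
    mu <- n1 * n2 / 2
    tie <- tapply(r, r, length)
    sig2 <- n1 * n2 / 12 * (N + 1 - sum(tie^3 - tie) / (N * (N - 1)))
    z <- (U - mu - sign(U - mu) * 0.5) / sqrt(sig2)
    p <- switch(alternative,
      two.sided = 2 * pnorm(-abs(z)),
      greater = pnorm(z, lower.tail = FALSE),
      less = pnorm(z))
    exact <- FALSE
  }
  .stat_result("mann_whitney", c(U = U), p, c(n1 = n1, n2 = n2), exact)
}

# All permutations of 1:k as a (k! x k) matrix.
.perm_matrix <- function(k) {
  if (k == 1L) return(matrix(1L, 1, 1))
  sub <- .perm_matrix(k - 1L)
  do.call(rbind, lapply(seq_len(k), function(i) {
    rest <- seq_len(k)[-i]
    cbind(i, matrix(rest[sub], nrow = nrow(sub)))
  }))
}

.friedman_stat <- function(Rsum, n, k, A) {
  C <- n * k * (k + 1)^2 / 4
  denom <- A - C
  if (denom <= 1e-12) return(0)
  (k - 1) * sum((Rsum - n * (k + 1) / 2)^2) / denom
}

# Exact permutation p for the Friedman statistic: the distribution of the
# vector of column rank sums is built by convolution over subjects (each
# subject's rank row is permuted uniformly and independently).  The
# tie-correction term A = sum r_ij^2 is invariant under within-row
# permutation, so the statistic depends on the column sums alone.
.friedman_exact_p <- function(R, obs) {
  n <- nrow(R); k <- ncol(R)
  A <- sum(R^2)
  perms <- .perm_matrix(k)
  states <- matrix(0, nrow = 1, ncol = k)
  wts <- 1
  for (i in seq_len(n)) {
    rows <- matrix(R[i, ][perms], nrow = nrow(perms))
    m <- nrow(states)
    newS <- states[rep(seq_len(m), each = nrow(rows)), , drop = FALSE] +
      rows[rep(seq_len(nrow(rows)), times = m), , drop = FALSE]
    newW <- rep(wts, each = nrow(rows)) / nrow(rows)
    key <- apply(round(newS * 2), 1, paste, collapse = ",")
    agg <- rowsum(newW, key)
    uk <- rownames(agg)
    states <- do.call(rbind, lapply(strsplit(uk, ","), function(v)
      as.numeric(v) / 2))
    wts <- agg[, 1]
  }
  stats <- apply(states, 1, .friedman_stat, n = n, k = k, A = A)
  sum(wts[stats >= obs - 1e-9])
}

#' Friedman rank test for repeated measures
#'
#' Within-subject midranks; the tie-corrected chi-square statistic is
#' referred to a chi-square distribution with `k - 1` degrees of freedom,
#' except for small designs (`<= exact_max_n` subjects and
#' `<= exact_max_k` conditions) where the exact permutation distribution
#' is used.  Subjects with missing cells are dropped (their count is
#' recorded in `note`).  When every subject's row is constant the
#' statistic is 0 and p = 1, flagged `degenerate`.
#'
#' @param blocks Numeric matrix, subjects in rows, conditions in columns
#'   (>= 3 columns).
#' @param exact_max_n,exact_max_k Exact-mode size thresholds.
#' @return A `stat_result`.
#' @export
friedman_blocks <- function(blocks, exact_max_n = 6L, exact_max_k = 4L) {
  blocks <- as.matrix(blocks)
  k <- ncol(blocks)
  if (k < 3L) stop("friedman_blocks needs >= 3 conditions")
  complete <- complete.cases(blocks)
  dropped <- sum(!complete)
  blocks <- blocks[complete, , drop = FALSE]
  n <- nrow(blocks)
  if (n < 2L) stop("friedman_blocks needs >= 2 complete subjects")
  R <- t(apply(blocks, 1, rank))
  A <- sum(R^2)
  Rsum <- colSums(R)
  stat <- .friedman_stat(Rsum, n, k, A)
  degenerate <- (A - n * k * (k + 1)^2 / 4) <= 1e-12
  if (degenerate) {
    p <- 1; exact <- TRUE
  } else if (n <= exact_max_n && k <= exact_max_k) {
    p <- .friedman_exact_p(R, stat); exact <- TRUE
  } else {
    p <- pchisq(stat, df = k - 1, lower.tail = FALSE); exact <- FALSE
  }
  .stat_result("friedman", c(chisq = stat), p, n, exact,
               degenerate = degenerate,
               note = if (dropped) sprintf(
                 "%d subject(s) dropped for missing cells", dropped))
}

#' Pairwise Wilcoxon post hoc with Bonferroni adjustment
#'
#' All `choose(k, 2)` condition pairs are compared with
#' [wilcoxon_matched()]; raw p-values are Bonferroni-adjusted
#' (`adjusted = min(1, m * raw)`).  Meant to follow a significant
#' [friedman_blocks()] omnibus test.
#'
#' @param blocks Matrix as in [friedman_blocks()] (incomplete subjects
#'   dropped).
#' @param alpha Significance level for the `significant` flag.
#' @param labels Condition labels (defaults to column names).
#' @return `data.frame` with one row per pair: `cond1`, `cond2`,
#'   `median_diff` (median of cond1 - cond2), `raw_p`, `adjusted_p`,
#'   `significant`.
#' @export
posthoc_pairs <- function(blocks, alpha = 0.05, labels = NULL) {
  blocks <- as.matrix(blocks)
  blocks <- blocks[complete.cases(blocks), , drop = FALSE]
  k <- ncol(blocks)
  if (is.null(labels))
    labels <- if (!is.null(colnames(blocks))) colnames(blocks)
      else paste0("cond", seq_len(k))
  pairs <- combn(k, 2)
  raw <- numeric(ncol(pairs))
  mdiff <- numeric(ncol(pairs))
  for (j in seq_len(ncol(pairs))) {
    i1 <- pairs[1, j]; i2 <- pairs[2, j]
    mdiff[j] <- median(blocks[, i1] - blocks[, i2])
    raw[j] <- tryCatch(
      wilcoxon_matched(blocks[, i1], blocks[, i2])$p,
      error = function(e) 1)  # all-zero differences: no evidence
  }
  adj <- p.adjust(raw, method = "bonferroni")
  data.frame(cond1 = labels[pairs[1, ]], cond2 = labels[pairs[2, ]],
             median_diff = mdiff, raw_p = raw, adjusted_p = adj,
             significant = adj < alpha)
}
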