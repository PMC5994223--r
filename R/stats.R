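#' Group summary records (mean, SEM, n)
#'
#' Container for printed per-group summaries, the form in which figure
#' captions usually report results (e.g. "19.65 +/- 3.39 dots/cell, n = 4").
#'
#' @param group character vector of group labels.
#' @param mean,sem,n numeric vectors (SEM = standard error of the mean;
#'   each `n >= 2`, each `sem >= 0`).
#' @return data.frame of class `group_summary`.
#' @export
group_summary <- function(group, mean, sem, n) {
  stopifnot(length(group) == length(mean), length(mean) == length(sem),
            length(sem) == length(n), all(n >= 2), all(sem >= 0))
  structure(data.frame(group = as.character(group), mean = mean, sem = sem,
                       n = as.integer(n), stringsAsFactors = FALSE),
            class = c("group_summary", "data.frame"))
}

#' Summarize raw replicate groups
#'
#' @param groups named list of numeric replicate vectors.
#' @return a [group_summary()] data.frame.
#' @export
summarize_groups <- function(groups) {
  stopifnot(is.list(groups), length(groups) >= 1L)
  if (is.null(names(groups))) names(groups) <- paste0("g", seq_along(groups))
  group_summary(names(groups),
                vapply(groups, mean, 0),
                vapply(groups, function(v) stats::sd(v) / sqrt(length(v)), 0),
                vapply(groups, length, 0L))
}

#' Reconstruct raw replicate values matching a printed summary exactly
#'
#' Produces `n` values whose sample mean equals `mean` and whose sample
#' standard deviation (denominator `n - 1`) equals `sem * sqrt(n)`, using a
#' symmetric two-point construction: for even `n`, half the values at
#' `mean - d` and half at `mean + d` with `d = sd * sqrt((n - 1) / n)`; for
#' odd `n`, one value at `mean` and `(n - 1) / 2` pairs at `mean +/- sd`.
#' Any ANOVA computed from such reconstructions is identical to the
#' summary-statistics ANOVA.
#'
#' @param mean,sem,n scalars as in [group_summary()].
#' @return numeric vector of length `n`.
#' @export
reconstruct_from_summary <- function(mean, sem, n) {
  stopifnot(n >= 2, sem >= 0)
  s <- sem * sqrt(n)
  if (n %% 2 == 0) {
    d <- s * sqrt((n - 1) / n)
    rep(c(mean - d, mean + d), each = n / 2)
  } else {
    c(mean, rep(c(mean - s, mean + s), each = (n - 1) / 2))
  }
}

new_anova_result <- function(F, df1, df2, p, ms_within, note = NULL) {
  structure(list(F = F, df_between = df1, df_within = df2, p = p,
                 ms_within = ms_within, note = note),
            class = "anova_result")
}

#' @export
print.anova_result <- function(x, ...) {
  cat(sprintf("One-way ANOVA: F(%d, %d) = %.4g, p = %.4g (MS within = %.4g)\n",
              x$df_between, x$df_within, x$F, x$p, x$ms_within))
  if (!is.null(x$note)) cat("  note:", x$note, "\n")
  invisible(x)
}

#' One-way fixed-effects ANOVA from raw replicates
#'
#' Classical between/within decomposition; the p-value comes from the F
#' distribution with `k - 1` and `sum(n_i - 1)` degrees of freedom. When all
#' observations are identical the statistic degenerates to `F = 0`, `p = 1`.
#'
#' @param groups list (optionally named) of numeric vectors, one per group;
#'   at least two groups, each with at least two values.
#' @return object of class `anova_result` with fields `F`, `df_between`,
#'   `df_within`, `p`, `ms_within`.
#' @export
#' @examples
#' anova_oneway(list(a = c(1, 2, 3), b = c(4, 5, 6)))
anova_oneway <- function(groups) {
  stopifnot(is.list(groups), length(groups) >= 2L,
            all(vapply(groups, length, 0L) >= 2L))
  n <- vapply(groups, length, 0L)
  m <- vapply(groups, mean, 0)
  gm <- sum(n * m) / sum(n)
  ss_b <- sum(n * (m - gm)^2)
  ss_w <- sum(vapply(groups, function(v) sum((v - mean(v))^2), 0))
  df1 <- length(groups) - 1L
  df2 <- sum(n) - length(groups)
  ms_w <- ss_w / df2
  if (ss_w == 0 && ss_b == 0)
    return(new_anova_result(0, df1, df2, 1, 0,
                            "degenerate: zero variance everywhere"))
  F <- (ss_b / df1) / ms_w
  new_anova_result(F, df1, df2, stats::pf(F, df1, df2, lower.tail = FALSE),
                   ms_w)
}

#' One-way ANOVA from printed mean/SEM/n summaries
#'
#' Computes the identical decomposition as [anova_oneway()] using only group
#' summaries: the between-group sum of squares from the n-weighted means and
#' the within-group mean square as the pooled variance
#' `sum((n_i - 1) * sd_i^2) / sum(n_i - 1)` with `sd_i = sem_i * sqrt(n_i)`.
#' Agrees to machine precision with [anova_oneway()] run on any raw data
#' reproducing the same summaries (see [reconstruct_from_summary()]).
#'
#' @param summaries a [group_summary()] data.frame (>= 2 rows).
#' @return an `anova_result`.
#' @export
#' @examples
#' s <- group_summary(c("GAD2", "MAG", "other"),
#'                    mean = c(19.65, 6.73, 4.72),
#'                    sem = c(3.39, 0.61, 0.23), n = c(4, 4, 4))
#' anova_from_summary(s)
anova_from_summary <- function(summaries) {
  stopifnot(inherits(summaries, "group_summary") || is.data.frame(summaries),
            nrow(summaries) >= 2L)
  n <- summaries$n; m <- summaries$mean
  sd <- summaries$sem * sqrt(n)
  gm <- sum(n * m) / sum(n)
  ss_b <- sum(n * (m - gm)^2)
  df1 <- nrow(summaries) - 1L
  df2 <- sum(n - 1L)
  ms_w <- sum((n - 1L) * sd^2) / df2
  if (ms_w == 0) {
    if (ss_b == 0) {
      warning("degenerate input: all SEMs zero and equal means; F reported as 0")
      return(new_anova_result(0, df1, df2, 1, 0, "degenerate"))
    }
    return(new_anova_result(Inf, df1, df2, 0, 0,
                            "zero within-group variance with unequal means"))
  }
  F <- (ss_b / df1) / ms_w
  new_anova_result(F, df1, df2, stats::pf(F, df1, df2, lower.tail = FALSE),
                   ms_w)
}

#' Tukey's honestly-significant-difference test from group summaries
#'
#' All-pairs comparisons after a one-way ANOVA. For each pair the
#' studentized-range statistic is
#' `q = |mean_a - mean_b| / sqrt(ms_within / 2 * (1/n_a + 1/n_b))`
#' (the Tukey-Kramer form, which reduces to `|diff| / sqrt(ms_within / n)`
#' for balanced groups), and the adjusted p-value is the upper tail of the
#' studentized range distribution with `k` groups and the ANOVA's within
#' degrees of freedom.
#'
#' @param summaries a [group_summary()] data.frame (or a named list of raw
#'   replicate vectors, which is summarized first).
#' @param anova optional `anova_result` for the same groups; computed with
#'   [anova_from_summary()] when missing.
#' @return data.frame of class `tukey_result`: `group_a`, `group_b`,
#'   `mean_diff` (a - b), `q_statistic`, `p_adjusted`.
#' @export
tukey_hsd <- function(summaries, anova = NULL) {
  if (is.list(summaries) && !is.data.frame(summaries))
    summaries <- summarize_groups(summaries)
  k <- nrow(summaries)
  if (k < 2L) stop("Tukey's test needs at least two groups")
  if (is.null(anova)) anova <- anova_from_summary(summaries)
  pairs <- utils::combn(k, 2L)
  out <- data.frame(
    group_a = summaries$group[pairs[1L, ]],
    group_b = summaries$group[pairs[2L, ]],
    mean_diff = summaries$mean[pairs[1L, ]] - summaries$mean[pairs[2L, ]],
    stringsAsFactors = FALSE)
  na <- summaries$n[pairs[1L, ]]; nb <- summaries$n[pairs[2L, ]]
  se <- sqrt(anova$ms_within / 2 * (1 / na + 1 / nb))
  out$q_statistic <- ifelse(se > 0, abs(out$mean_diff) / se,
                            ifelse(out$mean_diff == 0, 0, Inf))
  out$p_adjusted <- stats::ptukey(out$q_statistic, nmeans = k,
                                  df = anova$df_within, lower.tail = FALSE)
  structure(out, class = c("tukey_result", "data.frame"))
}

#' @export
print.tukey_result <- function(x, ...) {
  cat("Tukey multiple comparisons (studentized range):\n")
  print.data.frame(format(as.data.frame(x), digits = 4), right = FALSE)
  invisible(x)
}

#' Two-way fixed-effects ANOVA on a complete crossed design
#'
#' Fits `value ~ A * B` with [stats::aov()] and reports main-effect and
#' interaction F tests, plus Tukey comparisons on factor A (e.g. genotype)
#' when requested. Used in this workflow for genotype-by-count-bin
#' histograms; note that using binned counts as responses violates
#' independence across bins, so treat those p-values as descriptive.
#'
#' @param data data.frame with the response and two factors.
#' @param response,factor_a,factor_b column names.
#' @param tukey_on_a also compute Tukey comparisons for `factor_a`?
#' @return list of class `anova2_result`: `table` (data.frame with `term`,
#'   `df`, `F`, `p`), `ms_within`, `df_within`, and optionally `tukey_a`
#'   (the [stats::TukeyHSD()] matrix for factor A).
#' @export
anova_twoway <- function(data, response, factor_a, factor_b,
                         tukey_on_a = FALSE) {
  stopifnot(all(c(response, factor_a, factor_b) %in% names(data)))
  d <- data.frame(y = data[[response]],
                  A = factor(data[[factor_a]]), B = factor(data[[factor_b]]))
  cells <- table(d$A, d$B)
  if (any(cells == 0L))
    stop("incomplete design: every factor-A x factor-B cell needs data (no imputation)")
  terms_out <- c(factor_a, factor_b, paste(factor_a, factor_b, sep = ":"))
  # constant response: every decomposition term is exactly zero
  if (stats::var(d$y) <= 1e-20 * max(mean(d$y^2), 1)) {
    ka <- nlevels(d$A); kb <- nlevels(d$B)
    tab <- data.frame(term = terms_out,
                      df = c(ka - 1L, kb - 1L, (ka - 1L) * (kb - 1L)),
                      F = 0, p = 1)
    out <- list(table = tab, ms_within = 0,
                df_within = nrow(d) - ka * kb)
    if (tukey_on_a) out$tukey_a <- NULL
    return(structure(out, class = "anova2_result"))
  }
  fit <- stats::aov(y ~ A * B, data = d)
  sm <- summary(fit)[[1L]]
  terms <- trimws(rownames(sm))
  resid_i <- which(terms == "Residuals")
  tab <- data.frame(term = terms_out,
                    df = sm$Df[-resid_i],
                    F = sm$`F value`[-resid_i],
                    p = sm$`Pr(>F)`[-resid_i])
  out <- list(table = tab, ms_within = sm$`Mean Sq`[resid_i],
              df_within = sm$Df[resid_i])
  if (tukey_on_a) out$tukey_a <- stats::TukeyHSD(fit, "A")$A
  structure(out, class = "anova2_result")
}

#' @export
print.anova2_result <- function(x, ...) {
  cat("Two-way ANOVA:\n")
  print.data.frame(format(x$table, digits = 4), right = FALSE)
  cat(sprintf("  residual MS = %.4g on %d df\n", x$ms_within, x$df_within))
  invisible(x)
}

#' Relative abundance of two isoforms from paired measurements
#'
#' For each replicate (animal) with paired measurements `a` and `b` (e.g.
#' dots/area obtained with the two isoform-specific probes on matched
#' sections), computes `pct_a = 100 * a / (a + b)` and `pct_b = 100 - pct_a`,
#' then the group mean and SEM over replicates. Replicates with `a + b = 0`
#' carry no isoform information and are excluded with a warning.
#'
#' @param counts_a,counts_b numeric vectors of paired per-replicate
#'   measurements (same length).
#' @param pair_label label for the pair, e.g. `"JMa/JMb"`.
#' @return object of class `isoform_abundance`: list with `pair_label`,
#'   `per_replicate` (data.frame `a`, `b`, `pct_a`, `pct_b`), `mean_pct_a`,
#'   `sem_pct_a`, `mean_pct_b`, `sem_pct_b`, `n`.
#' @export
#' @examples
#' relative_abundance(c(30, 28, 35, 31), c(10, 9, 12, 11), "JMa/JMb")
relative_abundance <- function(counts_a, counts_b, pair_label = "a/b") {
  stopifnot(length(counts_a) == length(counts_b),
            all(counts_a >= 0), all(counts_b >= 0))
  tot <- counts_a + counts_b
  drop <- tot == 0
  if (any(drop))
    warning(sum(drop), " replicate(s) with a + b = 0 excluded")
  a <- counts_a[!drop]; b <- counts_b[!drop]
  if (length(a) == 0L) stop("no informative replicates")
  pct_a <- 100 * a / (a + b)
  per <- data.frame(a = a, b = b, pct_a = pct_a, pct_b = 100 - pct_a)
  sem <- function(v) if (length(v) > 1L) stats::sd(v) / sqrt(length(v)) else NA_real_
  structure(list(pair_label = pair_label, per_replicate = per,
                 mean_pct_a = mean(pct_a), sem_pct_a = sem(pct_a),
                 mean_pct_b = mean(100 - pct_a), sem_pct_b = sem(pct_a),
                 n = length(a)),
            class = "isoform_abundance")
}

#' @export
print.isoform_abundance <- function(x, ...) {
  lab <- strsplit(x$pair_label, "/", fixed = TRUE)[[1L]]
  if (length(lab) != 2L) lab <- c("a", "b")
  cat(sprintf("Relative isoform abundance (%s; n = %d):\n", x$pair_label, x$n))
  cat(sprintf("  %s: %.2f%% +/- %.2f (SEM)\n", lab[1L], x$mean_pct_a,
              x$sem_pct_a))
  cat(sprintf("  %s: %.2f%% +/- %.2f (SEM)\n", lab[2L], x$mean_pct_b,
              x$sem_pct_b))
  invisible(x)
}
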