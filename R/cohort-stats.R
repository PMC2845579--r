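# Paired longitudinal statistics: two-sided paired Student t tests per
# metric (baseline vs follow-up) plus within-timepoint targeted vs
# non-targeted contrasts, reported as mean +/- SD with p values at
# alpha = 0.05. A Holm-adjusted column is emitted alongside for
# transparency; the primary significance flag uses the unadjusted p.

#' Two-sided paired Student t test
#'
#' Pairs with a missing value on either side are dropped (count reported).
#' Zero-variance differences are handled as limits: all-zero differences
#' give `t = 0, p = 1`; constant non-zero differences give `p = 0` with a
#' `degenerate` flag (the test statistic is unbounded).
#'
#' @param baseline,followup Paired numeric vectors (same length).
#' @param metric Optional metric name carried into the result.
#' @param alpha Significance level (default 0.05).
#' @return List of class `"paired_comparison"`: `metric`, `n`,
#'   `mean_baseline`, `sd_baseline`, `mean_followup`, `sd_followup`,
#'   `mean_diff`, `t`, `df`, `p`, `significant`, `degenerate`,
#'   `n_dropped`.
#' @examples
#' paired_t(c(1, 2, 3), c(2, 3, 5))  # t = 4, p ~ 0.057
#' @export
paired_t <- function(baseline, followup, metric = NA_character_,
                     alpha = 0.05) {
  if (length(baseline) != length(followup))
    cmr_invalid("baseline and followup must have equal length")
  ok <- is.finite(baseline) & is.finite(followup)
  n_dropped <- sum(!ok)
  b <- baseline[ok]; f <- followup[ok]
  n <- length(b)
  if (n < 2L)
    cmr_compute_error("fewer than 2 complete pairs (", n, ") for ", metric)
  d <- f - b
  degenerate <- sd(d) == 0
  if (degenerate) {
    tt <- if (mean(d) == 0) 0 else sign(mean(d)) * Inf
    p <- if (mean(d) == 0) 1 else 0
  } else {
    ht <- t.test(f, b, paired = TRUE)
    tt <- unname(ht$statistic)
    p <- ht$p.value
  }
  structure(list(metric = metric, n = n,
                 mean_baseline = mean(b), sd_baseline = sd(b),
                 mean_followup = mean(f), sd_followup = sd(f),
                 mean_diff = mean(d), t = tt, df = n - 1L, p = p,
                 significant = p < alpha, degenerate = degenerate,
                 n_dropped = n_dropped),
            class = "paired_comparison")
}

#' @export
print.paired_comparison <- function(x, ...) {
  cat(sprintf(
    "%s: %.2f +/- %.2f vs %.2f +/- %.2f (n = %d), t = %.3f, P = %.4g%s\n",
    x$metric %||% "metric", x$mean_baseline, x$sd_baseline,
    x$mean_followup, x$sd_followup, x$n, x$t, x$p,
    if (isTRUE(x$significant)) " *" else ""))
  invisible(x)
}

comparison_row <- function(cmp, comparison) {
  data.frame(comparison = comparison, metric = cmp$metric, n = cmp$n,
             mean_baseline = cmp$mean_baseline, sd_baseline = cmp$sd_baseline,
             mean_followup = cmp$mean_followup, sd_followup = cmp$sd_followup,
             mean_diff = cmp$mean_diff, t = cmp$t, p = cmp$p,
             significant = cmp$significant)
}

#' Summarise a paired cohort table
#'
#' Runs a paired baseline-vs-follow-up t test for every metric column and,
#' for regional metric pairs (`*_targeted` / `*_nontargeted`), a paired
#' targeted-vs-non-targeted contrast within each timepoint (each subject
#' contributes both regions). Metrics absent from the table are listed as
#' skipped, not fatal. In targeted-vs-non-targeted rows the "baseline"
#' columns hold the targeted region and the "followup" columns the
#' non-targeted region.
#'
#' @param table A long-format cohort table (see [generate_cohort()]):
#'   columns `subject_id`, `timepoint` (`"baseline"` / `"followup"`) and
#'   one column per metric.
#' @param metrics Metric columns to analyse; defaults to every numeric
#'   column.
#' @param alpha Significance level (default 0.05).
#' @return List of class `"cohort_summary"`: `comparisons` (data frame,
#'   one row per test, with unadjusted `p`, Holm-adjusted `p_holm` — the
#'   adjusted column is supplementary, the primary analysis is
#'   unadjusted — and `significant` at `alpha`) and `skipped`.
#' @export
summarize_cohort <- function(table, metrics = NULL, alpha = 0.05) {
  if (!all(c("subject_id", "timepoint") %in% names(table)))
    cmr_invalid("cohort table needs subject_id and timepoint columns")
  if (anyDuplicated(table[, c("subject_id", "timepoint")]))
    cmr_invalid("duplicated (subject_id, timepoint) keys")
  metrics <- metrics %||%
    names(table)[vapply(table, is.numeric, logical(1L))]
  skipped <- setdiff(metrics, names(table))
  metrics <- intersect(metrics, names(table))
  b <- table[table$timepoint == "baseline", , drop = FALSE]
  f <- table[table$timepoint == "followup", , drop = FALSE]
  b <- b[order(b$subject_id), , drop = FALSE]
  f <- f[order(f$subject_id), , drop = FALSE]
  if (!identical(b$subject_id, f$subject_id))
    cmr_invalid("each subject needs exactly one baseline and one followup row")

  rows <- list()
  for (m in metrics) {
    rows[[length(rows) + 1L]] <- comparison_row(
      paired_t(b[[m]], f[[m]], metric = m, alpha = alpha),
      "baseline_vs_followup")
  }
  # Regional contrasts: targeted vs non-targeted within each timepoint
  targ <- grep("_targeted$", metrics, value = TRUE)
  for (m in targ) {
    m_non <- sub("_targeted$", "_nontargeted", m)
    if (!m_non %in% metrics) next
    for (tp in c("baseline", "followup")) {
      side <- if (tp == "baseline") b else f
      rows[[length(rows) + 1L]] <- comparison_row(
        paired_t(side[[m]], side[[m_non]],
                 metric = sub("_targeted$", "", m), alpha = alpha),
        paste0("targeted_vs_nontargeted_", tp))
    }
  }
  cmp <- do.call(rbind, rows)
  cmp$p_holm <- p.adjust(cmp$p, method = "holm")
  rownames(cmp) <- NULL
  structure(list(comparisons = cmp, skipped = skipped, alpha = alpha),
            class = "cohort_summary")
}

#' @export
print.cohort_summary <- function(x, ...) {
  cat(format_cohort_report(x), sep = "\n")
  invisible(x)
}

# Human-readable report mirroring the mean +/- SD (P = ...) layout of a
# clinical results section.
format_cohort_report <- function(summary) {
  cmp <- summary$comparisons
  lines <- c("Paired cohort comparisons",
             sprintf("alpha = %.3g (two-sided paired t tests)", summary$alpha),
             "")
  for (grp in unique(cmp$comparison)) {
    lines <- c(lines, grp, strrep("-", nchar(grp)))
    g <- cmp[cmp$comparison == grp, , drop = FALSE]
    for (i in seq_len(nrow(g))) {
      lines <- c(lines, sprintf(
        "  %-28s %6.2f +/- %-6.2f vs %6.2f +/- %-6.2f (n=%d, P = %.3g)%s",
        g$metric[i], g$mean_baseline[i], g$sd_baseline[i],
        g$mean_followup[i], g$sd_followup[i], g$n[i], g$p[i],
        if (g$significant[i]) " *" else ""))
    }
    lines <- c(lines, "")
  }
  if (length(summary$skipped))
    lines <- c(lines, paste("skipped metrics:",
                            paste(summary$skipped, collapse = ", ")))
  lines
}
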