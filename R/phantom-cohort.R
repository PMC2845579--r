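# Paired virtual cohort: per-subject baseline / follow-up metric draws with
# configured marginal means and SDs and a Gaussian-copula within-subject
# correlation. This is the ground-truth table the imaging pipeline tries to
# recover and the input of the cohort-statistics stage.

#' Generate a paired virtual cohort
#'
#' For every metric in `config$effect_sizes`, draws per-subject baseline
#' and follow-up values from a bivariate normal with the configured
#' marginal `(mean, sd)` pairs and within-subject correlation `config$rho`
#' (Gaussian copula; the two margins are normal, so this is a plain
#' bivariate normal). Physiologically positive metrics are floored at a
#' small positive value and percentage metrics clipped to `[0, 100]`.
#' Deterministic under the config seed: identical configs give
#' byte-identical tables.
#'
#' @param config A [phantom_config()] (needs `n_subjects >= 2`).
#' @return A long-format data frame of class `"cohort_table"` keyed by
#'   `(subject_id, timepoint)` with one column per metric; `timepoint` is
#'   `"baseline"` or `"followup"`.
#' @examples
#' tab <- generate_cohort(phantom_config(seed = 7, n_subjects = 12))
#' head(tab)
#' @export
generate_cohort <- function(config) {
  validate_phantom_config(config)
  if (config$n_subjects < 2L)
    cmr_invalid("n_subjects must be >= 2 for paired analysis")
  n <- config$n_subjects
  rho <- config$rho
  if (abs(rho) > 1) cmr_invalid("rho must be in [-1, 1]")
  set.seed(config$seed)
  base <- data.frame(subject_id = sprintf("S%02d", seq_len(n)))
  out <- rbind(cbind(base, timepoint = "baseline"),
               cbind(base, timepoint = "followup"))
  for (metric in names(config$effect_sizes)) {
    es <- config$effect_sizes[[metric]]
    z1 <- rnorm(n)
    z2 <- rho * z1 + sqrt(1 - rho^2) * rnorm(n)
    b <- es$baseline[1L] + es$baseline[2L] * z1
    f <- es$followup[1L] + es$followup[2L] * z2
    b <- clamp_metric(metric, b)
    f <- clamp_metric(metric, f)
    out[[metric]] <- c(b, f)
  }
  out <- out[order(out$subject_id, out$timepoint), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("cohort_table", "data.frame")
  out
}

# Flows and volumes must stay positive; percentages stay in [0, 100].
clamp_metric <- function(metric, x) {
  if (grepl("^(mbf|mpr)", metric)) return(pmax(x, 0.05))
  if (grepl("^pct|^ef", metric)) return(pmin(pmax(x, 0), 100))
  if (grepl("^(edv|mass|thickening)", metric)) return(pmax(x, 1))
  x
}
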