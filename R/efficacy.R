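#' Significance stars at the conventional thresholds
#'
#' Pure function of the p-value: `"***"` for p < 0.001, `"**"` for
#' p < 0.01, `"*"` for p < 0.05, `""` otherwise.
#' @param p numeric vector of p-values.
#' @return character vector of star annotations.
#' @export
significance_stars <- function(p) {
  ifelse(p < 0.001, "***", ifelse(p < 0.01, "**", ifelse(p < 0.05, "*", "")))
}

#' Normality-gated paired pre/post comparison of one endpoint
#'
#' Tests a paired baseline/follow-up change: a Shapiro-Wilk test on the
#' paired differences decides between the paired t-test (differences
#' compatible with normality, `shapiro_p >= alpha_normality`) and the
#' Wilcoxon signed-rank test (otherwise); the chosen test is two-tailed.
#' Direction is the sign of the mean difference (follow-up minus baseline).
#' Zero differences are dropped by the signed-rank convention; if every
#' difference is zero the result is flagged degenerate with `p = 1` and
#' direction `"none"`. Constant nonzero differences defeat the normality
#' test and fall through to the signed-rank branch, flagged.
#'
#' @param baseline,followup equal-length paired numeric vectors.
#' @param alpha two-tailed significance level for the change test.
#' @param alpha_normality level of the Shapiro-Wilk gate.
#' @param endpoint optional endpoint name carried into the result.
#' @return object of class `efficacy_result`: one-row data frame with
#'   `endpoint`, `n_pairs`, `baseline_mean`, `followup_mean`, `diff_mean`,
#'   `shapiro_p`, `test_used` (`"paired_t"`/`"wilcoxon"`/`"degenerate"`),
#'   `p_value`, `direction` (`"decrease"`/`"increase"`/`"none"`),
#'   `significant`, `stars`, `degenerate`.
#' @export
paired_change_test <- function(baseline, followup, alpha = 0.05,
                               alpha_normality = 0.05, endpoint = "endpoint") {
  if (length(baseline) != length(followup)) {
    stop("baseline and followup must be paired (equal length)")
  }
  keep <- !(is.na(baseline) | is.na(followup))
  baseline <- baseline[keep]
  followup <- followup[keep]
  n <- length(baseline)
  if (n < 3L) stop("need at least 3 complete pairs")
  d <- followup - baseline
  dm <- mean(d)

  if (all(d == 0)) {
    res <- data.frame(endpoint = endpoint, n_pairs = n,
                      baseline_mean = mean(baseline),
                      followup_mean = mean(followup), diff_mean = 0,
                      shapiro_p = NA_real_, test_used = "degenerate",
                      p_value = 1, direction = "none", significant = FALSE,
                      stars = "", degenerate = TRUE, stringsAsFactors = FALSE)
    class(res) <- c("efficacy_result", "data.frame")
    return(res)
  }

  constant <- stats::sd(d) == 0
  shapiro_p <- if (constant) NA_real_ else stats::shapiro.test(d)$p.value
  use_t <- !constant && shapiro_p >= alpha_normality
  p <- if (use_t) {
    stats::t.test(followup, baseline, paired = TRUE,
                  alternative = "two.sided")$p.value
  } else {
    suppressWarnings(
      stats::wilcox.test(followup, baseline, paired = TRUE,
                         alternative = "two.sided")$p.value)
  }
  res <- data.frame(
    endpoint = endpoint, n_pairs = n, baseline_mean = mean(baseline),
    followup_mean = mean(followup), diff_mean = dm, shapiro_p = shapiro_p,
    test_used = if (use_t) "paired_t" else "wilcoxon", p_value = p,
    direction = if (dm < 0) "decrease" else if (dm > 0) "increase" else "none",
    significant = p < alpha, stars = significance_stars(p),
    degenerate = constant, stringsAsFactors = FALSE)
  class(res) <- c("efficacy_result", "data.frame")
  res
}

#' Default efficacy endpoints and their improvement directions
#'
#' The FSLI plus its eight component parameters. Improvement direction:
#' wrinkle volumes (UEW_V, ML_V, NF_V), the Cutometer F4 readout and the
#' FSLI itself improve downward; epidermal thickness ET, elasticity R2 and
#' Q1, and collagen CC2 improve upward.
#' @return named character vector mapping endpoint to `"decrease"` or
#'   `"increase"`.
#' @export
efficacy_endpoints <- function() {
  c(FSLI = "decrease", ET = "increase", R2 = "increase", Q1 = "increase",
    CC2 = "increase", UEW_V = "decrease", ML_V = "decrease",
    NF_V = "decrease", F4 = "decrease")
}

#' Paired pre/post efficacy panel over laxity-related endpoints
#'
#' Runs [paired_change_test()] per endpoint on two tables sharing ids,
#' attaches star annotations, and flags `improved` when a significant
#' change moves in the endpoint's improvement direction.
#'
#' @param baseline_table,followup_table data frames with an `id` column and
#'   the endpoint columns; ids must match one-to-one.
#' @param endpoints named character vector of improvement directions
#'   (default [efficacy_endpoints()]); endpoints absent from either table
#'   are skipped silently.
#' @param alpha,alpha_normality passed to [paired_change_test()].
#' @return data frame of class `efficacy_panel`, one row per endpoint, with
#'   the [paired_change_test()] fields plus `improves_by` and `improved`.
#' @export
efficacy_panel <- function(baseline_table, followup_table,
                           endpoints = efficacy_endpoints(), alpha = 0.05,
                           alpha_normality = 0.05) {
  unmatched <- c(setdiff(baseline_table$id, followup_table$id),
                 setdiff(followup_table$id, baseline_table$id))
  if (length(unmatched)) {
    stop("unmatched participant id(s) between visits: ",
         paste(unique(unmatched), collapse = ", "))
  }
  fu <- followup_table[match(baseline_table$id, followup_table$id), ,
                       drop = FALSE]
  use <- names(endpoints)[names(endpoints) %in% names(baseline_table) &
                            names(endpoints) %in% names(fu)]
  rows <- lapply(use, function(ep) {
    res <- paired_change_test(baseline_table[[ep]], fu[[ep]], alpha = alpha,
                              alpha_normality = alpha_normality,
                              endpoint = ep)
    res$improves_by <- unname(endpoints[[ep]])
    res$improved <- res$significant && res$direction == endpoints[[ep]]
    res
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("efficacy_panel", "data.frame")
  out
}
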