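#' Wilcoxon rank-sum test (normal approximation)
#'
#' Two-sample rank-sum test with midranks for ties; the two-sided p-value
#' uses the normal approximation with tie-corrected variance and continuity
#' correction (the standard large-sample treatment, here via
#' `stats::wilcox.test(exact = FALSE, correct = TRUE)`). When every value in
#' both samples is identical the p-value is 1 by convention.
#'
#' @param a,b numeric samples (both nonempty).
#' @return list with `statistic` (rank sum of the first sample, midranks) and
#'   `p_value` (two-sided).
#' @export
wilcoxon_rank_sum <- function(a, b) {
  if (length(a) == 0 || length(b) == 0)
    cm_stop("both samples must be nonempty", "invalid_argument")
  r <- rank(c(a, b))
  w <- sum(r[seq_along(a)])
  if (length(unique(c(a, b))) == 1L)
    return(list(statistic = w, p_value = 1))
  p <- stats::wilcox.test(a, b, exact = FALSE, correct = TRUE)$p.value
  list(statistic = w, p_value = p)
}

#' Shapiro-Wilk normality p-value
#'
#' Contract-level wrapper around `stats::shapiro.test` for checking the
#' approximate normality of a bootstrap draw vector.
#'
#' @param draws numeric vector, 3 to 5000 values, not all identical.
#' @return the Shapiro-Wilk p-value.
#' @export
shapiro_normality <- function(draws) {
  draws <- draws[!is.na(draws)]
  if (length(draws) < 3 || length(draws) > 5000)
    cm_stop("Shapiro-Wilk requires between 3 and 5000 values",
            "invalid_argument")
  if (length(unique(draws)) == 1L)
    cm_stop("constant draws: normality test undefined", "invalid_argument")
  stats::shapiro.test(draws)$p.value
}

#' Run the outcome-neutral validity gates
#'
#' The four pre-registered validity checks that do not depend on the
#' hypotheses' direction:
#' \itemize{
#'   \item reliability: Cronbach's alpha of both outcome scales at least 0.6;
#'   \item manipulation strength: the cooling-off period lowers the mean
#'     negative-emotion score by at least 20 percentage points
#'     (Vid-Short vs Vid-Long);
#'   \item attrition: no arm's share of the total sample shifts by more than
#'     10 percentage points between the start and the end of the survey;
#'   \item filler effect: a Wilcoxon rank-sum test of the donation score
#'     between Novid-Short and Novid-Long; if it rejects at 5\% AND the
#'     absolute mean difference exceeds 2 percentage points, the main
#'     estimator is invalid and the alternative estimator (cool-off direct
#'     effect correction) is required.
#' }
#'
#' @param scored scored participant table with the raw item columns.
#' @param start_counts,end_counts named per-arm participant counts at the
#'   start and the end of the survey (names: the four arm labels).
#' @return a `validity_report`: the measured quantities, per-gate pass flags
#'   and the `use_alternative_estimator` switch.
#' @export
run_validity_gates <- function(scored, start_counts, end_counts) {
  summ <- summarize_arms(scored)
  for (cnt in list(start_counts, end_counts))
    if (!all(ARM_LEVELS %in% names(cnt)))
      cm_stop("start/end counts must cover all four arms",
              "incomplete_design")
  rel <- outcome_reliability(scored)
  drop <- arm_value(summ, "Vid-Short", "mean_neg_emotion_score") -
    arm_value(summ, "Vid-Long", "mean_neg_emotion_score")
  start_share <- start_counts[ARM_LEVELS] / sum(start_counts[ARM_LEVELS])
  end_share <- end_counts[ARM_LEVELS] / sum(end_counts[ARM_LEVELS])
  shift_pp <- 100 * abs(end_share - start_share)
  arms <- arm_label(scored$D, scored$C)
  w <- wilcoxon_rank_sum(
    scored$donation_score[arms == "Novid-Short"],
    scored$donation_score[arms == "Novid-Long"])
  diff_ns_nl <- abs(
    arm_value(summ, "Novid-Short", "mean_donation_score") -
      arm_value(summ, "Novid-Long", "mean_donation_score"))
  gates <- list(
    reliability_donations = rel$alpha_donations >= 0.6,
    reliability_emotions = rel$alpha_emotions >= 0.6,
    emotion_drop = drop >= 0.20,
    attrition = all(shift_pp <= 10))
  structure(list(
    alpha_donations = rel$alpha_donations,
    alpha_emotions = rel$alpha_emotions,
    cooloff_emotion_drop = drop,
    attrition_shift_per_arm = shift_pp,
    wilcoxon_p = w$p_value,
    novid_cooloff_diff = diff_ns_nl,
    gates = gates,
    use_alternative_estimator = w$p_value < 0.05 && diff_ns_nl > 0.02),
    class = "validity_report")
}

#' @export
print.validity_report <- function(x, ...) {
  ok <- function(g) if (g) "pass" else "FAIL"
  cat("Outcome-neutral validity gates:\n")
  cat(sprintf("  alpha donations %.3f (%s) | alpha emotions %.3f (%s)\n",
              x$alpha_donations, ok(x$gates$reliability_donations),
              x$alpha_emotions, ok(x$gates$reliability_emotions)))
  cat(sprintf("  cool-off emotion drop %.3f (>= 0.20: %s)\n",
              x$cooloff_emotion_drop, ok(x$gates$emotion_drop)))
  cat(sprintf("  max attrition shift %.2fpp (<= 10pp: %s)\n",
              max(x$attrition_shift_per_arm), ok(x$gates$attrition)))
  cat(sprintf("  Novid cool-off check: p = %.3f, |diff| = %.4f -> %s\n",
              x$wilcoxon_p, x$novid_cooloff_diff,
              if (x$use_alternative_estimator)
                "alternative estimator required" else "main estimator valid"))
  invisible(x)
}
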