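#' Share of the total effect explained by mediation
#'
#' From paired bootstrap draws of the total and mediated effects, computes
#' the per-draw ratio mediated / total with two registered conventions: a
#' non-positive mediated draw explains 0\% of the total effect (floored at
#' 0), and ratios above 1 are winsorized to 1. Draws with a non-positive
#' total effect are excluded from the ratio and reported as a count.
#'
#' @param tt_draws,m_draws equal-length paired bootstrap draws of the total
#'   and mediated effects (e.g. from [bootstrap_effects()]).
#' @return a `mediated_share_result`: the share draws (all in \[0, 1\]),
#'   `share_at_zero` (fraction of included draws with a non-positive mediated
#'   effect), `winsorized_fraction` (fraction capped at 1), `median`,
#'   `pct_95`, the central 95\% interval `ci_95`, and `n_excluded`.
#' @export
mediated_share <- function(tt_draws, m_draws) {
  if (length(tt_draws) != length(m_draws))
    cm_stop("draw vectors must be paired and of equal length",
            "invalid_argument")
  keep <- !is.na(tt_draws) & !is.na(m_draws) & tt_draws > 0
  n_excluded <- sum(!keep)
  if (!any(keep))
    cm_stop("no draws with a positive total effect: share undefined",
            "undefined_share")
  tt <- tt_draws[keep]; m <- m_draws[keep]
  raw <- m / tt
  share <- pmin(pmax(ifelse(m <= 0, 0, raw), 0), 1)
  structure(list(
    draws = share,
    share_at_zero = mean(m <= 0),
    winsorized_fraction = mean(m > 0 & raw > 1),
    median = median(share),
    pct_95 = boot_percentile(share, 0.95),
    ci_95 = c(boot_percentile(share, 0.025), boot_percentile(share, 0.975)),
    n_excluded = n_excluded),
    class = "mediated_share_result")
}

#' @export
print.mediated_share_result <- function(x, ...) {
  cat("Share of the total effect explained by the mediated effect:\n")
  cat(sprintf("  median %.3f | 95th pct %.3f | 95%% CI [%.2f, %.2f]\n",
              x$median, x$pct_95, x$ci_95[1], x$ci_95[2]))
  cat(sprintf("  mass at 0: %.3f | winsorized at 1: %.3f | excluded draws: %d\n",
              x$share_at_zero, x$winsorized_fraction, x$n_excluded))
  invisible(x)
}

two_arm_contrast <- function(values, arms, arm_hi, arm_lo) {
  a <- values[arms == arm_hi]; b <- values[arms == arm_lo]
  w <- wilcoxon_rank_sum(a, b)
  c(diff = mean(a) - mean(b), p = w$p_value)
}

#' Per-emotion treatment contrasts
#'
#' Mean differences of each raw emotion item (1-7 Likert) with two-sided
#' Wilcoxon rank-sum p-values, for the video contrast (Vid-Short minus
#' Novid-Short) and the cooling-off contrast (Vid-Long minus Vid-Short).
#'
#' @param table participant table with the six raw `emo_*` columns.
#' @return data.frame: `emotion`, `diff_video`, `p_video`, `diff_cooloff`,
#'   `p_cooloff`.
#' @export
per_emotion_effects <- function(table) {
  miss <- setdiff(c("D", "C", EMOTION_COLS), names(table))
  if (length(miss))
    cm_stop(paste("missing columns:", paste(miss, collapse = ", ")),
            "schema_error")
  arms <- arm_label(table$D, table$C)
  rows <- lapply(EMOTION_COLS, function(col) {
    v <- two_arm_contrast(table[[col]], arms, "Vid-Short", "Novid-Short")
    w <- two_arm_contrast(table[[col]], arms, "Vid-Long", "Vid-Short")
    data.frame(emotion = sub("emo_", "", col),
               diff_video = v[["diff"]], p_video = v[["p"]],
               diff_cooloff = w[["diff"]], p_cooloff = w[["p"]])
  })
  do.call(rbind, rows)
}

#' Per-option donation contrasts and extensive margin
#'
#' For each of the seven donation options: the mean difference in cents
#' between Vid-Short and Novid-Short, a two-sided Wilcoxon rank-sum p-value,
#' and the extensive-margin difference in the share of participants donating
#' a strictly positive amount.
#'
#' @param table participant table with the seven raw `don_*` columns.
#' @return data.frame: `option`, `mean_diff_cents`, `p_value`,
#'   `donor_share_diff`.
#' @export
per_option_effects <- function(table) {
  miss <- setdiff(c("D", "C", DONATION_COLS), names(table))
  if (length(miss))
    cm_stop(paste("missing columns:", paste(miss, collapse = ", ")),
            "schema_error")
  arms <- arm_label(table$D, table$C)
  vs <- arms == "Vid-Short"; ns <- arms == "Novid-Short"
  rows <- lapply(seq_along(DONATION_COLS), function(i) {
    v <- table[[DONATION_COLS[i]]]
    w <- wilcoxon_rank_sum(v[vs], v[ns])
    data.frame(option = i,
               mean_diff_cents = mean(v[vs]) - mean(v[ns]),
               p_value = w$p_value,
               donor_share_diff = mean(v[vs] > 0) - mean(v[ns] > 0))
  })
  do.call(rbind, rows)
}

#' Aggregate expert forecasts and compare with realizations
#'
#' Summarizes a table of per-arm forecasts (sliders on \[0, 1\]) of the mean
#' donation and emotion scores. Within-forecaster relative changes and
#' mitigation shares are aggregated by the median of the individual ratios —
#' deliberately not the ratio of medians, which can disagree on asymmetric
#' data — and set side by side with the realized ratio-of-averages from the
#' experiment when an `arm_summary` is supplied.
#'
#' @param predictions data.frame with columns `activist_id`, `pred_don_NS`,
#'   `pred_don_VS`, `pred_don_VL`, `pred_emo_NS`, `pred_emo_VS`,
#'   `pred_emo_VL`, all predictions in \[0, 1\].
#' @param realized optional `arm_summary` of the realized experiment.
#' @return a `prediction_comparison`: per-arm median predictions, medians of
#'   the within-forecaster ratios (relative donation change, relative emotion
#'   change, donation and emotion mitigation shares), the share of
#'   forecasters whose implied mediated effect is positive, and the realized
#'   ratio-of-averages counterparts (when supplied).
#' @export
aggregate_predictions <- function(predictions, realized = NULL) {
  cols <- c("pred_don_NS", "pred_don_VS", "pred_don_VL",
            "pred_emo_NS", "pred_emo_VS", "pred_emo_VL")
  miss <- setdiff(cols, names(predictions))
  if (length(miss))
    cm_stop(paste("missing prediction columns:",
                  paste(miss, collapse = ", ")), "schema_error")
  if (nrow(predictions) < 1)
    cm_stop("at least one prediction record is required", "invalid_argument")
  p <- predictions
  if (any(as.matrix(p[cols]) < 0 | as.matrix(p[cols]) > 1))
    cm_stop("slider predictions must lie in [0, 1]", "invalid_argument")
  rel_don <- (p$pred_don_VS - p$pred_don_NS) / p$pred_don_NS
  rel_emo <- (p$pred_emo_VS - p$pred_emo_NS) / p$pred_emo_NS
  mit_don <- (p$pred_don_VS - p$pred_don_VL) / (p$pred_don_VS - p$pred_don_NS)
  mit_emo <- (p$pred_emo_VS - p$pred_emo_VL) / (p$pred_emo_VS - p$pred_emo_NS)
  implied_mediated <- (p$pred_don_VS - p$pred_don_VL) / mit_emo
  med <- function(x) median(x[is.finite(x)])
  realized_ratios <- NULL
  if (!is.null(realized)) {
    y <- function(arm) arm_value(realized, arm, "mean_donation_score")
    m <- function(arm) arm_value(realized, arm, "mean_neg_emotion_score")
    realized_ratios <- list(
      rel_donation_change = (y("Vid-Short") - y("Novid-Short")) / y("Novid-Short"),
      rel_emotion_change = (m("Vid-Short") - m("Novid-Short")) / m("Novid-Short"),
      donation_mitigation = (y("Vid-Short") - y("Vid-Long")) /
        (y("Vid-Short") - y("Novid-Short")),
      emotion_mitigation = (m("Vid-Short") - m("Vid-Long")) /
        (m("Vid-Short") - m("Novid-Short")))
  }
  structure(list(
    n_activists = nrow(p),
    median_predictions = vapply(p[cols], median, numeric(1)),
    median_ratios = c(rel_donation_change = med(rel_don),
                      rel_emotion_change = med(rel_emo),
                      donation_mitigation = med(mit_don),
                      emotion_mitigation = med(mit_emo)),
    positive_mediation_share = mean(implied_mediated[is.finite(implied_mediated)] > 0),
    n_degenerate = sum(!is.finite(implied_mediated)),
    realized_ratios = realized_ratios),
    class = "prediction_comparison")
}

#' @export
print.prediction_comparison <- function(x, ...) {
  cat(sprintf("Forecast aggregation (%d forecasters, median-of-ratios):\n",
              x$n_activists))
  mr <- x$median_ratios
  cat(sprintf("  rel. donation change %+.1f%% | rel. emotion change %+.1f%%\n",
              100 * mr[["rel_donation_change"]],
              100 * mr[["rel_emotion_change"]]))
  cat(sprintf("  mitigation shares: donations %.1f%% | emotions %.1f%%\n",
              100 * mr[["donation_mitigation"]],
              100 * mr[["emotion_mitigation"]]))
  cat(sprintf("  share predicting positive mediation: %.0f%%\n",
              100 * x$positive_mediation_share))
  if (!is.null(x$realized_ratios)) {
    rr <- x$realized_ratios
    cat(sprintf("  realized (ratio of averages): don %+.1f%%, emo %+.1f%%, mitigation %.1f%% / %.1f%%\n",
                100 * rr$rel_donation_change, 100 * rr$rel_emotion_change,
                100 * rr$donation_mitigation, 100 * rr$emotion_mitigation))
  }
  invisible(x)
}
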