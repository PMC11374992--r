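#' Per-arm summaries of the two outcome scores
#'
#' @param scored data.frame from [score_participants()] (columns `D`, `C`,
#'   `donation_score`, `neg_emotion_score`).
#' @return `arm_summary` data.frame: `arm`, `n`, `mean_donation_score`,
#'   `mean_neg_emotion_score`, one row per arm.
#' @export
summarize_arms <- function(scored) {
  need <- c("D", "C", "donation_score", "neg_emotion_score")
  miss <- setdiff(need, names(scored))
  if (length(miss))
    cm_stop(paste("missing columns:", paste(miss, collapse = ", ")),
            "schema_error")
  arms <- arm_label(scored$D, scored$C)
  if (!all(ARM_LEVELS %in% arms))
    cm_stop(paste("arms missing from the data:",
                  paste(setdiff(ARM_LEVELS, arms), collapse = ", ")),
            "incomplete_design")
  out <- data.frame(
    arm = factor(ARM_LEVELS, levels = ARM_LEVELS),
    n = as.integer(table(arms)[ARM_LEVELS]),
    mean_donation_score =
      tapply(scored$donation_score, arms, mean)[ARM_LEVELS],
    mean_neg_emotion_score =
      tapply(scored$neg_emotion_score, arms, mean)[ARM_LEVELS],
    row.names = NULL)
  class(out) <- c("arm_summary", "data.frame")
  out
}

arm_value <- function(summaries, arm, col) {
  i <- match(arm, as.character(summaries$arm))
  if (is.na(i)) cm_stop(paste("arm missing:", arm), "incomplete_design")
  summaries[[col]][i]
}

#' Plug-in total treatment effect
#'
#' Difference in mean donation scores between the video arm and the control
#' arm without cooling-off: `Ybar(Vid-Short) - Ybar(Novid-Short)`. Under
#' random assignment this estimates the total effect of the video on the
#' treated.
#'
#' @param summaries an `arm_summary` (or any data.frame with its columns).
#' @return scalar effect in donation-score units.
#' @export
estimate_total_effect <- function(summaries) {
  arm_value(summaries, "Vid-Short", "mean_donation_score") -
    arm_value(summaries, "Novid-Short", "mean_donation_score")
}

#' Plug-in cooling-off compliance share
#'
#' `q_hat = (Mbar_VS - Mbar_VL) / (Mbar_VS - Mbar_NS)`: the drop in the mean
#' negative-emotion score induced by the cooling-off period, relative to the
#' rise induced by the video. Under the strata model this identifies the
#' share of compliers whose emotional state returns to low during the
#' cooling-off period.
#'
#' @param summaries an `arm_summary`.
#' @param tol degeneracy tolerance for the denominator.
#' @return scalar `q_hat`; warns if outside \[0, 1\].
#' @export
estimate_q <- function(summaries, tol = 1e-9) {
  m_vs <- arm_value(summaries, "Vid-Short", "mean_neg_emotion_score")
  m_vl <- arm_value(summaries, "Vid-Long", "mean_neg_emotion_score")
  m_ns <- arm_value(summaries, "Novid-Short", "mean_neg_emotion_score")
  den <- m_vs - m_ns
  if (abs(den) <= tol)
    cm_stop("video did not move the emotion score: q is not identified",
            "degenerate_mediator")
  q <- (m_vs - m_vl) / den
  if (q < 0 || q > 1)
    warning(sprintf("q_hat = %.4f lies outside [0, 1]", q))
  q
}

#' Plug-in estimate set: total, arm-contrast and mediated effects
#'
#' Computes the full set of plug-in estimates from the four arm means:
#' the total effect `delta_TT`, the video-arm contrast
#' `delta = Ybar_VS - Ybar_VL`, the compliance share `q_hat` and the mediated
#' effect `delta_M = delta / q_hat` — the portion of the video's effect on
#' donations that operates through the elevated negative-emotion state.
#'
#' @param summaries an `arm_summary`.
#' @param tol degeneracy tolerance for `q_hat` and its denominator.
#' @return an `estimate_set`: list with `delta_TT`, `delta`, `q_hat`,
#'   `delta_M`.
#' @export
estimate_mediated_effect <- function(summaries, tol = 1e-9) {
  q <- estimate_q(summaries, tol)
  if (abs(q) <= tol)
    cm_stop("q_hat is zero: the mediated effect is not identified",
            "degenerate_mediator")
  delta <- arm_value(summaries, "Vid-Short", "mean_donation_score") -
    arm_value(summaries, "Vid-Long", "mean_donation_score")
  structure(list(delta_TT = estimate_total_effect(summaries),
                 delta = delta, q_hat = q, delta_M = delta / q),
            class = "estimate_set")
}

#' @export
print.estimate_set <- function(x, ...) {
  cat("Plug-in estimates (donation-score units):\n")
  cat(sprintf("  total effect      delta_TT = %+.4f\n", x$delta_TT))
  cat(sprintf("  video-arm contrast   delta = %+.4f\n", x$delta))
  cat(sprintf("  compliance share     q_hat = %.4f\n", x$q_hat))
  cat(sprintf("  mediated effect    delta_M = %+.4f\n", x$delta_M))
  invisible(x)
}

# Shared within-arm resampling: for each arm, B resampled means of both
# scores using the same participant draws (so donation and emotion means stay
# paired within a bootstrap replicate).
boot_arm_stats <- function(scored, B, seed) {
  arms <- arm_label(scored$D, scored$C)
  if (!all(ARM_LEVELS %in% arms))
    cm_stop("all four arms are required for bootstrap inference",
            "incomplete_design")
  set.seed(child_seed(seed, "bootstrap"))
  res <- list()
  for (a in ARM_LEVELS) {
    y <- scored$donation_score[arms == a]
    m <- scored$neg_emotion_score[arms == a]
    n <- length(y)
    idx <- sample.int(n, n * B, replace = TRUE)
    res[[a]] <- list(ybar = colMeans(matrix(y[idx], n, B)),
                     mbar = colMeans(matrix(m[idx], n, B)))
  }
  res
}

make_bootstrap_result <- function(statistic, draws, B, seed, point_estimate,
                                  econ_threshold) {
  valid <- draws[!is.na(draws)]
  n_invalid <- B - length(valid)
  if (n_invalid > 0.01 * B)
    cm_stop(sprintf(
      "%d of %d bootstrap draws hit a degenerate mediator denominator",
      n_invalid, B), "inference_unstable")
  structure(list(
    statistic = statistic, B = B, draws = draws, n_invalid = n_invalid,
    point_estimate = point_estimate, draw_mean = mean(valid),
    pct_2_5 = boot_percentile(valid, 0.025),
    pct_5 = boot_percentile(valid, 0.05),
    pct_95 = boot_percentile(valid, 0.95),
    pct_97_5 = boot_percentile(valid, 0.975),
    share_nonpositive = mean(valid <= 0),
    share_ge_threshold = mean(valid >= econ_threshold),
    econ_threshold = econ_threshold, seed = seed),
    class = "bootstrap_result")
}

#' Bootstrap distribution of a treatment-effect statistic
#'
#' Resamples participants with replacement within each arm (arm sizes
#' preserved, since treatment assignment is fixed by design), recomputes the
#' plug-in statistic per draw, and summarizes the draws by the fixed
#' percentile convention of [boot_percentile()]. Draws in which the mediator
#' denominator or `q_hat` is degenerate are recorded as invalid and excluded
#' from the summaries; more than 1\% invalid draws raises an
#' `inference_unstable` error.
#'
#' @param scored data.frame from [score_participants()].
#' @param statistic `"delta_TT"` or `"delta_M"`.
#' @param B number of bootstrap draws (the registered analysis used 1000).
#' @param seed integer seed; draws are deterministic given the seed, and two
#'   calls with the same seed use identical resamples (so `delta_TT` and
#'   `delta_M` draws are paired).
#' @param econ_threshold threshold for `share_ge_threshold` (default the
#'   registered 3-percentage-point economic-significance bound).
#' @param tol degeneracy tolerance for the mediator denominator.
#' @return a `bootstrap_result`: draws, the 2.5/5/95/97.5 percentiles, the
#'   share of draws at or below zero, the share at or above the threshold,
#'   the plug-in point estimate and the mean of the draws.
#' @export
bootstrap_statistic <- function(scored, statistic = c("delta_TT", "delta_M"),
                                B = 1000L, seed = 1L, econ_threshold = 0.03,
                                tol = 1e-9) {
  statistic <- match.arg(statistic)
  if (B < 1) cm_stop("B must be at least 1", "invalid_argument")
  res <- boot_arm_stats(scored, B, seed)
  summ <- summarize_arms(scored)
  if (statistic == "delta_TT") {
    draws <- res[["Vid-Short"]]$ybar - res[["Novid-Short"]]$ybar
    point <- estimate_total_effect(summ)
  } else {
    den <- res[["Vid-Short"]]$mbar - res[["Novid-Short"]]$mbar
    q <- (res[["Vid-Short"]]$mbar - res[["Vid-Long"]]$mbar) / den
    draws <- (res[["Vid-Short"]]$ybar - res[["Vid-Long"]]$ybar) / q
    draws[abs(den) <= tol | abs(q) <= tol] <- NA_real_
    point <- estimate_mediated_effect(summ, tol)$delta_M
  }
  make_bootstrap_result(statistic, draws, as.integer(B), as.integer(seed),
                        point, econ_threshold)
}

#' Paired bootstrap of the total and mediated effects
#'
#' Convenience wrapper running both statistics on one shared set of
#' within-arm resamples, so the returned draw vectors are paired (as needed
#' by [mediated_share()]).
#'
#' @inheritParams bootstrap_statistic
#' @return list with elements `tt` and `m`, both `bootstrap_result`s.
#' @export
bootstrap_effects <- function(scored, B = 1000L, seed = 1L,
                              econ_threshold = 0.03, tol = 1e-9) {
  list(tt = bootstrap_statistic(scored, "delta_TT", B, seed, econ_threshold,
                                tol),
       m = bootstrap_statistic(scored, "delta_M", B, seed, econ_threshold,
                               tol))
}

#' @export
print.bootstrap_result <- function(x, ...) {
  cat(sprintf("Bootstrap of %s (B = %d, seed = %d):\n",
              x$statistic, x$B, x$seed))
  cat(sprintf("  plug-in %+.4f | draw mean %+.4f\n",
              x$point_estimate, x$draw_mean))
  cat(sprintf("  pct  2.5/5/95/97.5: %+.4f %+.4f %+.4f %+.4f\n",
              x$pct_2_5, x$pct_5, x$pct_95, x$pct_97_5))
  cat(sprintf("  share <= 0: %.3f | share >= %.3g: %.3f | invalid draws: %d\n",
              x$share_nonpositive, x$econ_threshold, x$share_ge_threshold,
              x$n_invalid))
  invisible(x)
}

#' Apply the registered decision rules
#'
#' The pre-registered rules: reject the null of a non-positive total effect
#' (`H1`) iff the 5th bootstrap percentile of `delta_TT` is strictly above 0;
#' reject the null of a non-positive mediated effect (`H2`) iff the 5th
#' percentile of `delta_M` is strictly above 0. If `H1` is rejected but `H2`
#' is not, the mediated effect is declared economically insignificant iff the
#' 95th percentile of `delta_M` is strictly below the economic-significance
#' threshold (registered at 3 percentage points); otherwise the study is
#' inconclusive about mediation. One-sided p-values are reported as the share
#' of draws at or below zero.
#'
#' @param tt `bootstrap_result` for `delta_TT`.
#' @param m `bootstrap_result` for `delta_M`, computed with the same `B`.
#' @param econ_threshold economic-significance threshold (score units).
#' @param gates optional `validity_report` to attach.
#' @return a `decision_report`.
#' @export
decide_hypotheses <- function(tt, m, econ_threshold = 0.03, gates = NULL) {
  stopifnot(inherits(tt, "bootstrap_result"), inherits(m, "bootstrap_result"))
  if (tt$B != m$B)
    cm_stop("both bootstrap results must use the same B", "invalid_argument")
  h1 <- tt$pct_5 > 0
  h2 <- m$pct_5 > 0
  econ_insig <- h1 && !h2 && m$pct_95 < econ_threshold
  inconclusive <- h1 && !h2 && !econ_insig
  structure(list(
    h1_rejected = h1, h2_rejected = h2,
    h2_economically_insignificant = econ_insig,
    h2_inconclusive = inconclusive,
    p_h1 = tt$share_nonpositive, p_h2 = m$share_nonpositive,
    econ_threshold = econ_threshold,
    tt_pct_5 = tt$pct_5, m_pct_5 = m$pct_5, m_pct_95 = m$pct_95,
    gates = gates),
    class = "decision_report")
}

#' @export
print.decision_report <- function(x, ...) {
  cat("Registered decision report:\n")
  cat(sprintf("  H1 (total effect <= 0): %s (5th pct %+.4f, p = %.3f)\n",
              if (x$h1_rejected) "rejected" else "not rejected",
              x$tt_pct_5, x$p_h1))
  cat(sprintf("  H2 (mediated effect <= 0): %s (5th pct %+.4f, p = %.3f)\n",
              if (x$h2_rejected) "rejected" else "not rejected",
              x$m_pct_5, x$p_h2))
  if (x$h1_rejected && !x$h2_rejected) {
    verdict <- if (x$h2_economically_insignificant)
      "economically insignificant" else "inconclusive"
    cat(sprintf("  mediation verdict: %s (95th pct %+.4f vs threshold %.3g)\n",
                verdict, x$m_pct_95, x$econ_threshold))
  }
  if (!is.null(x$gates)) {
    cat(sprintf("  validity gates: %s\n",
                if (all(unlist(x$gates$gates))) "all passed" else "FAILED"))
  }
  invisible(x)
}
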