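#' Donation score
#'
#' The propensity-to-engage score: the average of the seven donation amounts
#' (cents, 0-100 each) divided by 100, so the score lies in \[0, 1\] with
#' higher values meaning a larger share of the endowment donated.
#'
#' @param donations numeric vector of exactly 7 amounts in cents, each in
#'   \[0, 100\].
#' @return scalar in \[0, 1\].
#' @export
donation_score <- function(donations) {
  if (length(donations) != 7L)
    cm_stop("exactly 7 donation amounts required", "invalid_argument")
  if (anyNA(donations) || any(donations < 0 | donations > 100))
    cm_stop("donation amounts must lie in [0, 100]", "invalid_argument")
  mean(donations) / 100
}

#' Negative-emotion score
#'
#' Aggregates six primary-emotion Likert ratings (1-7) into a single score on
#' \[0, 1\]: the five negative-valence emotions enter positively, happiness is
#' reverse-coded (subtracted), and the sum is normalized by adding 2 and
#' dividing by 36. The minimum 0 is attained at all negatives 1 and happiness
#' 7, the maximum 1 at all negatives 7 and happiness 1; each Likert point
#' moves the score by 1/36.
#'
#' @param ratings named numeric vector of 6 ratings in \[1, 7\] with names
#'   `emo_anger`, `emo_disgust`, `emo_fear`, `emo_sadness`, `emo_happiness`,
#'   `emo_surprise` (an unnamed vector is taken in that order).
#' @return scalar in \[0, 1\].
#' @export
negative_emotion_score <- function(ratings) {
  if (length(ratings) != 6L)
    cm_stop("exactly 6 emotion ratings required", "invalid_argument")
  if (is.null(names(ratings))) names(ratings) <- EMOTION_COLS
  if (!all(EMOTION_COLS %in% names(ratings)))
    cm_stop("ratings must be keyed by the six emotion items", "invalid_argument")
  if (anyNA(ratings) || any(ratings < 1 | ratings > 7))
    cm_stop("emotion ratings must lie in [1, 7]", "invalid_argument")
  (sum(ratings[NEGATIVE_EMOTIONS]) - ratings[["emo_happiness"]] + 2) / 36
}

#' Cronbach's alpha
#'
#' Internal-consistency reliability of a k-item scale:
#' `alpha = k/(k-1) * (1 - sum(item variances) / variance(row sums))`,
#' with population (n-denominator) variances used consistently in numerator
#' and denominator. For the emotion scale, reverse-code happiness as
#' `8 - rating` before calling so all items share a common direction.
#'
#' @param items n x k numeric matrix (rows respondents, columns items),
#'   n >= 2, k >= 2.
#' @return scalar alpha (at most 1; can be negative for discordant items).
#' @export
cronbach_alpha <- function(items) {
  items <- as.matrix(items)
  n <- nrow(items); k <- ncol(items)
  if (n < 2 || k < 2)
    cm_stop("need at least 2 respondents and 2 items", "invalid_argument")
  if (anyNA(items)) cm_stop("items must be complete", "invalid_argument")
  pvar <- function(x) mean((x - mean(x))^2)
  total <- pvar(rowSums(items))
  if (total <= 0)
    cm_stop("zero total variance: reliability undefined",
            "undefined_reliability")
  k / (k - 1) * (1 - sum(apply(items, 2, pvar)) / total)
}

#' Pro-meat justification (PMJ) score
#'
#' Mean of the 10 PMJ items rescaled to \[0, 1\] by the scale bounds.
#'
#' @param items numeric vector of exactly 10 ratings on a common scale.
#' @param scale_min,scale_max bounds of the response scale (default 1-7).
#' @return scalar in \[0, 1\].
#' @export
pmj_score <- function(items, scale_min = 1, scale_max = 7) {
  if (length(items) != 10L)
    cm_stop("exactly 10 PMJ items required", "invalid_argument")
  if (anyNA(items) || any(items < scale_min | items > scale_max))
    cm_stop("PMJ items must lie within the scale bounds", "invalid_argument")
  (mean(items) - scale_min) / (scale_max - scale_min)
}

#' Score a participant table
#'
#' Adds `donation_score` and `neg_emotion_score` columns to a participant
#' table. Records flagged as failing the exclusion rules
#' (`passed_checks == 0`) are dropped before scoring; the scorer never
#' imputes.
#'
#' @param table participant data.frame with the 7 `don_*` and 6 `emo_*`
#'   columns (see [simulate_experiment()] for the schema).
#' @return the filtered table with the two score columns appended.
#' @export
score_participants <- function(table) {
  need <- c(DONATION_COLS, EMOTION_COLS)
  miss <- setdiff(need, names(table))
  if (length(miss))
    cm_stop(paste("missing columns:", paste(miss, collapse = ", ")),
            "schema_error")
  if ("passed_checks" %in% names(table))
    table <- table[table$passed_checks == 1, , drop = FALSE]
  don <- as.matrix(table[DONATION_COLS])
  if (any(don < 0 | don > 100))
    cm_stop("donation amounts must lie in [0, 100]", "invalid_argument")
  emo <- as.matrix(table[EMOTION_COLS])
  if (any(emo < 1 | emo > 7))
    cm_stop("emotion ratings must lie in [1, 7]", "invalid_argument")
  table$donation_score <- rowMeans(don) / 100
  table$neg_emotion_score <-
    (rowSums(emo[, NEGATIVE_EMOTIONS, drop = FALSE]) -
       emo[, "emo_happiness"] + 2) / 36
  table
}

#' Scale reliability of the two outcome scales
#'
#' Cronbach's alpha for the 7-option donation scale and for the 6-item
#' emotion scale with happiness reverse-coded as `8 - rating`.
#'
#' @param table participant data.frame with raw item columns.
#' @return list with `alpha_donations` and `alpha_emotions`.
#' @export
outcome_reliability <- function(table) {
  emo <- as.matrix(table[EMOTION_COLS])
  emo[, "emo_happiness"] <- 8 - emo[, "emo_happiness"]
  list(alpha_donations = cronbach_alpha(as.matrix(table[DONATION_COLS])),
       alpha_emotions = cronbach_alpha(emo))
}
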