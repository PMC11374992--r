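#' Exact-count arm assignment
#'
#' Assigns exactly `n_per_arm` participants to each of the four cells of the
#' 2x2 design (video yes/no x cooling-off yes/no), then permutes the order.
#' Stratified exact counts, rather than Bernoulli draws, mirror equal
#' randomization across branches and remove design noise from simulations.
#'
#' @param n_per_arm participants per arm (positive integer).
#' @param seed integer seed; assignment is deterministic given the seed.
#' @return data.frame with columns `D`, `C` and `4 * n_per_arm` rows.
#' @export
assign_arms <- function(n_per_arm, seed = 1L) {
  if (length(n_per_arm) != 1L || is.na(n_per_arm) || n_per_arm < 1)
    cm_stop("n_per_arm must be a positive integer", "invalid_argument")
  n_per_arm <- as.integer(n_per_arm)
  cells <- expand.grid(D = 0:1, C = 0:1)
  out <- cells[rep(seq_len(4), each = n_per_arm), ]
  set.seed(child_seed(seed, "arms"))
  out <- out[sample.int(nrow(out)), ]
  rownames(out) <- NULL
  out
}

#' Draw principal-stratum labels
#'
#' @param n number of draws.
#' @param p_a,p_n,p_c strata shares; must sum to 1 (tolerance 1e-12).
#' @return character vector of labels in `{"a", "n", "c"}`. Uses the current
#'   RNG state; seed upstream for reproducibility.
#' @export
draw_stratum <- function(n, p_a, p_n, p_c) {
  if (abs(p_a + p_n + p_c - 1) > 1e-12 || min(p_a, p_n, p_c) < 0)
    cm_stop("strata shares must be nonnegative and sum to 1",
            "invalid_argument")
  sample(c("a", "n", "c"), n, replace = TRUE, prob = c(p_a, p_n, p_c))
}

#' Realize the binary mediator state
#'
#' Deterministic for always-takers (always high) and never-takers (always
#' low). Compliers are low without the video, high with the video and no
#' cooling-off, and revert to low with probability `q` when the video is
#' followed by the cooling-off period.
#'
#' @param stratum character vector of labels `a`/`n`/`c`.
#' @param D,C 0/1 treatment indicators, recycled against `stratum`.
#' @param q reversion probability for exposed compliers under cooling-off.
#' @return integer vector of 0/1 mediator states; uses the current RNG state.
#' @export
realize_mediator <- function(stratum, D, C, q) {
  if (!all(stratum %in% c("a", "n", "c")))
    cm_stop("stratum labels must be a/n/c", "invalid_argument")
  n <- length(stratum)
  D <- rep_len(D, n); C <- rep_len(C, n)
  m <- integer(n)
  m[stratum == "a"] <- 1L
  exposed_c <- stratum == "c" & D == 1
  m[exposed_c & C == 0] <- 1L
  cool <- which(exposed_c & C == 1)
  if (length(cool)) m[cool] <- 1L - rbinom(length(cool), 1, q)
  m
}

# Vectorized outcome draws: donations and emotion items given latent state.
draw_outcomes <- function(stratum, D, M, config) {
  n <- length(stratum)
  mu <- config$mu_y[cbind(stratum, as.character(D), as.character(M))]
  if (anyNA(mu) || any(mu < 0 | mu > 1))
    cm_stop("mu_y undefined or outside [0, 1] for a realized state",
            "invalid_argument")
  pi0 <- config$zero_inflation
  gives <- rbinom(n, 1, 1 - pi0)
  p_opt <- mu / (1 - pi0)  # conditional per-option mean on the 0-1 scale
  don <- matrix(0L, n, 7, dimnames = list(NULL, DONATION_COLS))
  idx <- which(gives == 1)
  if (length(idx)) {
    # one generosity level per giver, shared across the 7 options: keeps the
    # unconditional mean exact and correlates options within participant
    p_i <- if (config$donation_noise > 0) {
      nu <- 1 / config$donation_noise - 1
      rbeta(length(idx), p_opt[idx] * nu, (1 - p_opt[idx]) * nu)
    } else p_opt[idx]
    don[idx, ] <- rbinom(length(idx) * 7, 100, rep(p_i, 7))
  }
  emo <- matrix(NA_integer_, n, 6, dimnames = list(NULL, EMOTION_COLS))
  for (item in EMOTION_COLS) {
    anchor <- ifelse(M == 1, config$emo_anchor_high[[item]],
                     config$emo_anchor_low[[item]])
    emo[, item] <- 1L + rbetabinom(n, 6, (anchor - 1) / 6, config$likert_noise)
  }
  list(donations = don, emotions = emo)
}

#' Emit a single participant record
#'
#' Draws the observed donations and emotion ratings of one participant given
#' the latent stratum, treatment cell and realized mediator state. The
#' expected donation score equals `mu_y(stratum, D, M)` exactly: with
#' zero-inflation mass `pi`, non-zero donors draw per-option amounts from a
#' beta-binomial on 0..100 with mean `100 * mu / (1 - pi)`.
#'
#' @param stratum one of `a`/`n`/`c`.
#' @param D,C 0/1 treatment indicators.
#' @param M_realized 0/1 mediator state.
#' @param config a `strata_config`.
#' @param id record id.
#' @return one-row data.frame in the participant schema.
#' @export
emit_record <- function(stratum, D, C, M_realized, config, id = 1L) {
  validate_strata_config(config)
  out <- draw_outcomes(stratum, D, M_realized, config)
  cbind(data.frame(id = id, D = D, C = C),
        as.data.frame(out$donations), as.data.frame(out$emotions),
        data.frame(stratum = stratum, m_realized = M_realized,
                   passed_checks = 1L))
}

#' Simulate a full four-arm experiment
#'
#' Generates `4 * n_per_arm` participant records with the principal-strata
#' structure the estimator assumes: exact-count arm assignment, latent strata
#' with shares `(p_a, p_n, p_c)`, mediator states realized per stratum and
#' arm (reversion share `q` for exposed compliers under cooling-off),
#' zero-inflated integer donations and Likert emotion items anchored on the
#' mediator state. Each stage draws from an independent child stream of the
#' master seed. The exclusion restriction holds by construction: neither
#' donations nor emotions depend on `C` given the realized mediator state.
#'
#' @param config a `strata_config`.
#' @param blinded drop the latent `stratum` and `m_realized` columns.
#' @param attrition_rates optional named vector (arm label -> rate in \[0,1\))
#'   of per-arm probabilities that a completer fails the checks
#'   (`passed_checks = 0`); default no attrition.
#' @return data.frame in the participant schema: `id`, `D`, `C`,
#'   `don_1..don_7`, six `emo_*` columns, `stratum`, `m_realized`,
#'   `passed_checks`.
#' @export
simulate_experiment <- function(config, blinded = FALSE,
                                attrition_rates = NULL) {
  validate_strata_config(config)
  arms <- assign_arms(config$n_per_arm, config$seed)
  n <- nrow(arms)
  set.seed(child_seed(config$seed, "strata"))
  stratum <- draw_stratum(n, config$p_a, config$p_n, config$p_c)
  set.seed(child_seed(config$seed, "mediators"))
  m <- realize_mediator(stratum, arms$D, arms$C, config$q)
  set.seed(child_seed(config$seed, "outcomes"))
  out <- draw_outcomes(stratum, arms$D, m, config)
  passed <- rep(1L, n)
  if (!is.null(attrition_rates)) {
    set.seed(child_seed(config$seed, "attrition"))
    lab <- as.character(arm_label(arms$D, arms$C))
    rate <- ifelse(lab %in% names(attrition_rates),
                   attrition_rates[lab], 0)
    passed <- 1L - rbinom(n, 1, rate)
  }
  tab <- cbind(data.frame(id = seq_len(n), D = arms$D, C = arms$C),
               as.data.frame(out$donations), as.data.frame(out$emotions),
               data.frame(stratum = stratum, m_realized = m,
                          passed_checks = passed))
  if (blinded) tab$stratum <- tab$m_realized <- NULL
  tab
}

#' Closed-form true estimands of a configuration
#'
#' The total effect on the treated is the strata-share-weighted contrast of
#' expected donation scores between exposure states at each stratum's
#' realized mediator state; the mediated effect is the complier share times
#' the complier donation contrast across mediator states under exposure,
#' `delta_M = p_c * (mu_y(c,1,1) - mu_y(c,1,0))`. Also returns the implied
#' arm contrast `delta = q * delta_M` and `q` itself.
#'
#' @param config a `strata_config`.
#' @return list with `delta_TT`, `delta_M`, `delta`, `q`.
#' @export
true_estimands <- function(config) {
  validate_strata_config(config)
  g <- function(s, d, m) mu_cell(config, s, d, m)
  delta_TT <- config$p_a * (g("a", 1, 1) - g("a", 0, 1)) +
    config$p_n * (g("n", 1, 0) - g("n", 0, 0)) +
    config$p_c * (g("c", 1, 1) - g("c", 0, 0))
  delta_M <- config$p_c * (g("c", 1, 1) - g("c", 1, 0))
  list(delta_TT = delta_TT, delta_M = delta_M,
       delta = config$q * delta_M, q = config$q)
}

#' Population (expected) arm means of a configuration
#'
#' Exact expected per-arm means of the donation score and the
#' negative-emotion score, computed from the strata shares, `q`, the `mu_y`
#' map and the emotion anchors — no simulation. Returned in the
#' `arm_summary` shape so the plug-in estimators can run on the population
#' directly (the basis of the oracle-equivalence check between the
#' strata-level truth and the arm-contrast estimator).
#'
#' @param config a `strata_config`.
#' @return `arm_summary` data.frame with one row per arm.
#' @export
population_arm_means <- function(config) {
  validate_strata_config(config)
  g <- function(s, d, m) mu_cell(config, s, d, m)
  e_high <- anchor_score(config$emo_anchor_high)
  e_low <- anchor_score(config$emo_anchor_low)
  p_high <- c("Novid-Short" = config$p_a,
              "Novid-Long" = config$p_a,
              "Vid-Short" = config$p_a + config$p_c,
              "Vid-Long" = config$p_a + config$p_c * (1 - config$q))
  y0 <- config$p_a * g("a", 0, 1) + config$p_n * g("n", 0, 0) +
    config$p_c * g("c", 0, 0)
  y_vs <- config$p_a * g("a", 1, 1) + config$p_n * g("n", 1, 0) +
    config$p_c * g("c", 1, 1)
  y_vl <- config$p_a * g("a", 1, 1) + config$p_n * g("n", 1, 0) +
    config$p_c * ((1 - config$q) * g("c", 1, 1) + config$q * g("c", 1, 0))
  out <- data.frame(
    arm = factor(ARM_LEVELS, levels = ARM_LEVELS),
    n = rep(config$n_per_arm, 4L),
    mean_donation_score = c(y0, y0, y_vs, y_vl),
    mean_neg_emotion_score = e_low + (e_high - e_low) * p_high[ARM_LEVELS],
    row.names = NULL)
  class(out) <- c("arm_summary", "data.frame")
  out
}

#' Write / read participant tables as CSV
#'
#' Plain UTF-8 comma-separated files with a header row and "." decimals; the
#' blinded export omits the latent `stratum` and `m_realized` columns.
#'
#' @param table participant data.frame.
#' @param path file path.
#' @param blinded drop latent columns on write.
#' @return `read_participants()` returns the data.frame.
#' @export
write_participants <- function(table, path, blinded = FALSE) {
  if (blinded) table$stratum <- table$m_realized <- NULL
  write.csv(table, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_participants
#' @export
read_participants <- function(path) {
  tab <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("id", "D", "C", DONATION_COLS, EMOTION_COLS)
  miss <- setdiff(need, names(tab))
  if (length(miss))
    cm_stop(paste("missing participant columns:",
                  paste(miss, collapse = ", ")), "schema_error")
  tab
}
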