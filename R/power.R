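#' Configuration of the simulation-based power planner
#'
#' @param n_grid per-arm sample sizes to scan.
#' @param S simulated samples per size (the registered plan used 1000).
#' @param B bootstrap draws per simulated sample (registered: 1000).
#' @param assumed_effect effect size assumed for rejection (registered: 0.05,
#'   i.e. 5 percentage points; the pilot effect size is deliberately not used,
#'   to avoid follow-up bias).
#' @param alpha one-sided type-1 error rate (registered: 0.05).
#' @param target_power target power for the minimum detectable effect
#'   (registered: 0.95).
#' @param seed integer seed.
#' @return a `power_config`.
#' @export
power_config <- function(n_grid, S = 1000L, B = 1000L, assumed_effect = 0.05,
                         alpha = 0.05, target_power = 0.95, seed = 1L) {
  if (alpha <= 0 || alpha >= 1 || target_power <= 0 || target_power >= 1)
    cm_stop("alpha and target_power must lie in (0, 1)", "invalid_argument")
  if (S < 1 || B < 1) cm_stop("S and B must be at least 1", "invalid_argument")
  if (length(n_grid) < 1 || any(n_grid < 1))
    cm_stop("n_grid must contain positive sizes", "invalid_argument")
  structure(list(n_grid = as.integer(n_grid), S = as.integer(S),
                 B = as.integer(B), assumed_effect = assumed_effect,
                 alpha = alpha, target_power = target_power,
                 seed = as.integer(seed)),
            class = "power_config")
}

#' Critical bootstrap standard error for one-sided rejection
#'
#' Under a normal approximation to the bootstrap distribution, the one-sided
#' percentile rule rejects when the assumed effect exceeds
#' `z_(1-alpha) * SE`; rejection is therefore equivalent to
#' `SE < effect / z_(1-alpha)` (about 0.030 for a 5-percentage-point effect
#' at alpha = 0.05).
#'
#' @param effect assumed effect size (score units).
#' @param alpha one-sided type-1 error rate.
#' @return the largest SE at which the effect is still rejected.
#' @export
critical_se <- function(effect, alpha = 0.05) {
  effect / qnorm(1 - alpha)
}

#' Minimum detectable effect under the normal approximation
#'
#' `(z_(1-alpha) + z_(target_power)) * SE`: the smallest true effect detected
#' with probability `target_power` by a one-sided level-`alpha` test whose
#' estimator is normal with standard error `SE`. Homogeneous of degree 1 in
#' the SE (about 3.29 x SE at alpha = 0.05, power 0.95).
#'
#' @param SE_at_N bootstrap standard error of the mediated effect at the
#'   sample size of interest (nonnegative).
#' @param alpha one-sided type-1 error rate.
#' @param target_power target detection probability.
#' @return the minimum detectable effect in score units.
#' @export
minimal_detectable_effect <- function(SE_at_N, alpha = 0.05,
                                      target_power = 0.95) {
  if (any(SE_at_N < 0)) cm_stop("SE must be nonnegative", "invalid_argument")
  (qnorm(1 - alpha) + qnorm(target_power)) * SE_at_N
}

#' Simulation-based power curve for the mediated effect
#'
#' For each per-arm size `n` in the grid, draws `S` simulated experiments by
#' resampling the pilot-like table with replacement within arm (assuming the
#' pilot is representative of the population), computes the bootstrap
#' standard error of the mediated effect (`B` inner draws, SE = standard
#' deviation of the valid draws) per simulated sample, and applies the
#' normal-approximation rejection rule: reject iff
#' `assumed_effect > z_(1-alpha) * SE`. Power at `n` is the rejection share;
#' `mean_SE` tracks precision. Deterministic given the seed.
#'
#' @param pilot scored pilot-like table with all four arms.
#' @param config a [power_config()].
#' @return a `power_curve` data.frame: `n`, `power`, `mean_SE`,
#'   `se_power` (Monte-Carlo SE of the power estimate), with the config
#'   attached as attribute `config`.
#' @export
simulate_power <- function(pilot, config) {
  stopifnot(inherits(config, "power_config"))
  arms <- arm_label(pilot$D, pilot$C)
  if (!all(ARM_LEVELS %in% arms))
    cm_stop("pilot table must contain all four arms", "incomplete_design")
  ys <- split(pilot$donation_score, arms)
  ms <- split(pilot$neg_emotion_score, arms)
  if (any(config$n_grid > max(lengths(ys))))
    warning("requested sizes exceed the pilot arm sizes; ",
            "resampling with replacement extrapolates the pilot")
  z <- qnorm(1 - config$alpha)
  set.seed(child_seed(config$seed, "power"))
  rows <- lapply(config$n_grid, function(n) {
    se <- vapply(seq_len(config$S), function(s) {
      draw_arm <- lapply(ARM_LEVELS, function(a) {
        i <- sample.int(length(ys[[a]]), n, replace = TRUE)
        list(y = ys[[a]][i], m = ms[[a]][i])
      })
      names(draw_arm) <- ARM_LEVELS
      boot <- lapply(draw_arm, function(d) {
        idx <- sample.int(n, n * config$B, replace = TRUE)
        list(ybar = colMeans(matrix(d$y[idx], n, config$B)),
             mbar = colMeans(matrix(d$m[idx], n, config$B)))
      })
      den <- boot[["Vid-Short"]]$mbar - boot[["Novid-Short"]]$mbar
      q <- (boot[["Vid-Short"]]$mbar - boot[["Vid-Long"]]$mbar) / den
      dm <- (boot[["Vid-Short"]]$ybar - boot[["Vid-Long"]]$ybar) / q
      dm[abs(den) <= 1e-9 | abs(q) <= 1e-9] <- NA_real_
      sd(dm[!is.na(dm)])
    }, numeric(1))
    rejected <- config$assumed_effect > z * se
    p <- mean(rejected)
    data.frame(n = n, power = p, mean_SE = mean(se),
               se_power = sqrt(p * (1 - p) / config$S))
  })
  out <- do.call(rbind, rows)
  attr(out, "config") <- config
  class(out) <- c("power_curve", "data.frame")
  out
}

#' @export
print.power_curve <- function(x, ...) {
  cfg <- attr(x, "config")
  cat(sprintf("Power curve (S = %d, B = %d, assumed effect = %.3f, one-sided alpha = %.2f):\n",
              cfg$S, cfg$B, cfg$assumed_effect, cfg$alpha))
  print.data.frame(x, row.names = FALSE)
  invisible(x)
}
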