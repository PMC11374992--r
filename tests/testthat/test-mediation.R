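test_that("arm summaries aggregate scores per arm and demand a full design", {
  sc <- scored_table(n = 3)
  summ <- summarize_arms(sc)
  expect_equal(as.character(summ$arm),
               c("Novid-Short", "Novid-Long", "Vid-Short", "Vid-Long"))
  expect_equal(summ$n, rep(3L, 4))
  expect_equal(summ$mean_donation_score, c(0.164, 0.164, 0.202, 0.191))
  expect_equal(summ$mean_neg_emotion_score, c(0.257, 0.257, 0.660, 0.322))

  zero <- scored_table(y = c(NS = 0, NL = 0, VS = 0, VL = 0), n = 2)
  expect_equal(summarize_arms(zero)$mean_donation_score, rep(0, 4))

  expect_error(summarize_arms(sc[sc$D == 1, ]), class = "incomplete_design")
})

test_that("plug-in estimators reproduce the published arm-mean arithmetic", {
  summ <- summarize_arms(scored_table())
  expect_equal(estimate_total_effect(summ), 0.202 - 0.164)
  expect_equal(estimate_q(summ), (0.660 - 0.322) / (0.660 - 0.257))
  est <- estimate_mediated_effect(summ)
  expect_equal(est$delta, 0.202 - 0.191)
  expect_equal(est$delta_M, (0.202 - 0.191) / ((0.660 - 0.322) / (0.660 - 0.257)))

  # sign convention and degenerate cases
  down <- summarize_arms(scored_table(y = c(NS = 0.15, NL = 0.15,
                                            VS = 0.10, VL = 0.10)))
  expect_equal(estimate_total_effect(down), -0.05)

  full <- summarize_arms(scored_table(m = c(NS = 0.2, NL = 0.2,
                                            VS = 0.6, VL = 0.2)))
  expect_equal(estimate_q(full), 1)      # cool-off fully restores baseline
  none <- summarize_arms(scored_table(m = c(NS = 0.2, NL = 0.2,
                                            VS = 0.6, VL = 0.6)))
  expect_equal(estimate_q(none), 0)      # cool-off does nothing

  flat <- summarize_arms(scored_table(m = c(NS = 0.3, NL = 0.3,
                                            VS = 0.3, VL = 0.3)))
  expect_error(estimate_q(flat), class = "degenerate_mediator")
  expect_error(estimate_mediated_effect(none), class = "degenerate_mediator")

  # identity when compliance is full
  sf <- summarize_arms(scored_table(y = c(NS = 0.10, NL = 0.10,
                                          VS = 0.20, VL = 0.15),
                                    m = c(NS = 0.2, NL = 0.2,
                                          VS = 0.6, VL = 0.2)))
  expect_equal(estimate_mediated_effect(sf)$delta_M, 0.05)
})

test_that("the plug-in identity delta_M * q_hat = delta holds", {
  set.seed(21)
  for (i in 1:20) {
    y <- runif(4, 0, 0.5); m <- c(0.2, 0.2, 0.7, runif(1, 0.25, 0.65))
    summ <- summarize_arms(scored_table(
      y = c(NS = y[1], NL = y[2], VS = y[3], VL = y[4]),
      m = c(NS = m[1], NL = m[2], VS = m[3], VL = m[4])))
    est <- suppressWarnings(estimate_mediated_effect(summ))
    expect_lt(abs(est$delta_M * est$q_hat - est$delta), 1e-12)
  }
})

test_that("bootstrap draws are deterministic, arm-size preserving and collapse
          under constant outcomes", {
  cfg <- default_strata_config(n_per_arm = 120, seed = 3)
  sc <- score_participants(simulate_experiment(cfg))

  b1 <- bootstrap_statistic(sc, "delta_TT", B = 50, seed = 42)
  b2 <- bootstrap_statistic(sc, "delta_TT", B = 50, seed = 42)
  expect_identical(b1$draws, b2$draws)
  expect_false(identical(
    b1$draws, bootstrap_statistic(sc, "delta_TT", B = 50, seed = 43)$draws))

  # degenerate data: constant outcomes within arms -> every draw equals the
  # plug-in point estimate
  const <- scored_table(n = 30)
  bc <- bootstrap_statistic(const, "delta_TT", B = 40, seed = 1)
  expect_true(all(bc$draws == bc$point_estimate))
  bm <- bootstrap_statistic(const, "delta_M", B = 40, seed = 1)
  expect_true(all(abs(bm$draws - bm$point_estimate) < 1e-12))

  # percentile ordering invariant
  expect_true(bm$pct_2_5 <= bm$pct_5 && bm$pct_5 <= bm$pct_95 &&
                bm$pct_95 <= bm$pct_97_5)
})

test_that("bootstrap summaries report shares and percentiles by the fixed
          convention", {
  draws <- c(rep(-0.01, 175), seq(0.001, 0.05, length.out = 825))
  b <- boot_result_from_draws(draws)
  expect_equal(b$share_nonpositive, 0.175)
  expect_equal(b$pct_5, sort(draws)[ceiling(0.05 * 1000)])
  expect_equal(boot_percentile(1:100, 0.05), 5)
  expect_equal(boot_percentile(1:100, 1), 100)
  expect_error(boot_percentile(1:10, 0), class = "invalid_argument")

  # invalid draws beyond 1% trip the stability guard
  bad <- c(rep(NA_real_, 20), rnorm(980))
  expect_error(boot_result_from_draws(bad), class = "inference_unstable")
})

test_that("registered decision rules resolve every hypothesis pattern", {
  tt_pos <- boot_result_from_draws(seq(0.01, 0.06, length.out = 200))
  m_big <- boot_result_from_draws(seq(0.031, 0.08, length.out = 200))
  d1 <- decide_hypotheses(tt_pos, m_big)
  expect_true(d1$h1_rejected && d1$h2_rejected)
  expect_false(d1$h2_economically_insignificant || d1$h2_inconclusive)

  # the published pattern: 5th pct of the total effect +2.1pp, mediated
  # effect 5th pct -0.009 and 95th pct 0.035 -> H1 rejected, H2 inconclusive
  tt_paper <- boot_result_from_draws(qnorm(
    seq(0.0005, 0.9995, length.out = 1000), mean = 0.038, sd = 0.0103))
  m_paper <- boot_result_from_draws(qnorm(
    seq(0.0005, 0.9995, length.out = 1000), mean = 0.0131, sd = 0.0134))
  expect_equal(tt_paper$pct_5, 0.021, tolerance = 0.01)
  d2 <- decide_hypotheses(tt_paper, m_paper)
  expect_true(d2$h1_rejected)
  expect_false(d2$h2_rejected)
  expect_true(d2$h2_inconclusive)
  expect_false(d2$h2_economically_insignificant)

  # small but uniformly positive mediated draws: H2 rejected per the rule
  m_small <- boot_result_from_draws(seq(0.001, 0.009, length.out = 200))
  d3 <- decide_hypotheses(tt_pos, m_small)
  expect_true(d3$h2_rejected)

  # tiny upper bound: economically insignificant
  m_tiny <- boot_result_from_draws(c(rep(-0.002, 15),
                                     seq(0.0001, 0.01, length.out = 185)))
  d4 <- decide_hypotheses(tt_pos, m_tiny)
  expect_false(d4$h2_rejected)
  expect_true(d4$h2_economically_insignificant)

  # exactly one verdict when H1 is rejected
  for (d in list(d1, d2, d3, d4)) {
    expect_equal(sum(d$h2_rejected, d$h2_economically_insignificant,
                     d$h2_inconclusive), 1L)
  }
  expect_error(decide_hypotheses(tt_pos, boot_result_from_draws(rnorm(10))),
               class = "invalid_argument")
})

test_that("paired bootstrap of both effects shares resamples", {
  cfg <- default_strata_config(n_per_arm = 100, seed = 8)
  sc <- score_participants(simulate_experiment(cfg))
  eff <- bootstrap_effects(sc, B = 60, seed = 9)
  solo_tt <- bootstrap_statistic(sc, "delta_TT", B = 60, seed = 9)
  expect_identical(eff$tt$draws, solo_tt$draws)
})
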