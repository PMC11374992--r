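test_that("arm assignment gives exact counts per cell and is deterministic", {
  one <- assign_arms(1, seed = 3)
  expect_equal(nrow(one), 4L)
  expect_equal(sort(paste(one$D, one$C)), c("0 0", "0 1", "1 0", "1 1"))

  big <- assign_arms(800, seed = 5)
  expect_equal(nrow(big), 3200L)
  expect_true(all(table(big$D, big$C) == 800))
  expect_identical(big, assign_arms(800, seed = 5))
  expect_false(identical(big, assign_arms(800, seed = 6)))

  expect_error(assign_arms(0), class = "invalid_argument")
  expect_error(assign_arms(-3), class = "invalid_argument")
})

test_that("stratum draws respect degenerate and stochastic shares", {
  set.seed(1)
  expect_true(all(draw_stratum(50, 1, 0, 0) == "a"))
  expect_true(all(draw_stratum(50, 0, 0, 1) == "c"))
  expect_error(draw_stratum(10, 0.5, 0.2, 0.2), class = "invalid_argument")

  # binomial SE oracle: empirical shares within 3 SE at n = 1e5
  set.seed(42)
  n <- 100000
  s <- draw_stratum(n, 0.2, 0.3, 0.5)
  for (pair in list(c("a", 0.2), c("n", 0.3), c("c", 0.5))) {
    p <- as.numeric(pair[2])
    se <- sqrt(p * (1 - p) / n)
    expect_lt(abs(mean(s == pair[1]) - p), 3 * se)
  }
})

test_that("mediator realization follows the strata model", {
  set.seed(1)
  expect_equal(realize_mediator(rep("a", 10), 0, 1, 0.5), rep(1L, 10))
  expect_equal(realize_mediator(rep("n", 10), 1, 0, 0.5), rep(0L, 10))
  expect_equal(realize_mediator(rep("c", 10), 0, 0, 0.5), rep(0L, 10))
  expect_equal(realize_mediator(rep("c", 10), 1, 0, 0.5), rep(1L, 10))
  expect_error(realize_mediator("x", 1, 1, 0.5), class = "invalid_argument")

  # exposed compliers under cool-off revert with probability q
  set.seed(7)
  n <- 100000; q <- 0.839
  m <- realize_mediator(rep("c", n), 1, 1, q)
  se <- sqrt(q * (1 - q) / n)
  expect_lt(abs(mean(m == 0) - q), 3 * se)
})

test_that("emitted records honor the outcome model extremes", {
  # a flat-zero outcome map forces all-zero donations
  cfg_all0 <- default_strata_config(n_per_arm = 10, seed = 1)
  cfg_all0$mu_y[] <- 0
  set.seed(1)
  rec0 <- emit_record("c", 1, 0, 1, cfg_all0)
  expect_true(all(rec0[paste0("don_", 1:7)] == 0))

  # no Likert noise with saturated anchors pins the emotion score at 1
  cfg_max <- default_strata_config(
    n_per_arm = 10, seed = 1,
    emo_anchor_high = c(emo_anger = 7, emo_disgust = 7, emo_fear = 7,
                        emo_sadness = 7, emo_happiness = 1, emo_surprise = 7))
  cfg_max$likert_noise <- 0
  set.seed(1)
  rec1 <- emit_record("c", 1, 0, 1, cfg_max)
  sc <- score_participants(rec1)
  expect_equal(sc$neg_emotion_score, 1)

  expect_true(all(rec1[paste0("don_", 1:7)] >= 0 & rec1[paste0("don_", 1:7)] <= 100))
})

test_that("true estimands follow the strata algebra", {
  cfg <- default_strata_config()

  cfg_nc <- cfg
  cfg_nc$p_c <- 0; cfg_nc$p_a <- 0.4; cfg_nc$p_n <- 0.6
  expect_equal(true_estimands(cfg_nc)$delta_M, 0)

  # hand arithmetic: p_c = 0.5, complier contrast 0.30 - 0.20
  cfg_h <- cfg
  cfg_h$p_a <- 0.25; cfg_h$p_n <- 0.25; cfg_h$p_c <- 0.5
  cfg_h$mu_y["c", "1", "1"] <- 0.30
  cfg_h$mu_y["c", "1", "0"] <- 0.20
  expect_equal(true_estimands(cfg_h)$delta_M, 0.05)

  # flat outcome map: no effects at all
  cfg_f <- cfg
  cfg_f$mu_y[!is.na(cfg_f$mu_y)] <- 0.2
  te <- true_estimands(cfg_f)
  expect_equal(te$delta_TT, 0)
  expect_equal(te$delta_M, 0)
})

test_that("generated tables satisfy no-defiers and field invariants", {
  cfg <- default_strata_config(n_per_arm = 500, seed = 11)
  tab <- simulate_experiment(cfg)
  expect_equal(nrow(tab), 2000L)
  don <- as.matrix(tab[paste0("don_", 1:7)])
  emo <- as.matrix(tab[c("emo_anger", "emo_disgust", "emo_fear",
                         "emo_sadness", "emo_happiness", "emo_surprise")])
  expect_true(all(don >= 0 & don <= 100))
  expect_true(all(emo >= 1 & emo <= 7))
  expect_true(all(tab$m_realized[tab$stratum == "a"] == 1))
  expect_true(all(tab$m_realized[tab$stratum == "n"] == 0))
  expect_true(all(tab$m_realized[tab$stratum == "c" & tab$D == 0] == 0))
  expect_true(all(tab$m_realized[tab$stratum == "c" & tab$D == 1 &
                                   tab$C == 0] == 1))
  # determinism under the master seed
  expect_identical(tab, simulate_experiment(cfg))
})

test_that("exclusion restriction holds: no cool-off effect without the video", {
  cfg <- default_strata_config(n_per_arm = 20000, seed = 19)
  sc <- score_participants(simulate_experiment(cfg))
  arms <- arm_label(sc$D, sc$C)
  for (col in c("donation_score", "neg_emotion_score")) {
    a <- sc[[col]][arms == "Novid-Short"]
    b <- sc[[col]][arms == "Novid-Long"]
    se <- sqrt(var(a) / length(a) + var(b) / length(b))
    expect_lt(abs(mean(a) - mean(b)), 3 * se)
  }
})

test_that("plug-in estimates recover the true estimands at large n", {
  cfg <- default_strata_config(n_per_arm = 20000, seed = 23)
  sc <- score_participants(simulate_experiment(cfg))
  est <- estimate_mediated_effect(summarize_arms(sc))
  te <- true_estimands(cfg)
  eff <- bootstrap_effects(sc, B = 200, seed = 23)
  expect_lt(abs(est$delta_TT - te$delta_TT),
            3 * sd(eff$tt$draws, na.rm = TRUE))
  expect_lt(abs(est$delta_M - te$delta_M),
            3 * sd(eff$m$draws, na.rm = TRUE))
})

test_that("configuration validation and JSON round-trip", {
  expect_error(strata_config(0.5, 0.4, 0.2, 0.5, coolmediate:::empty_mu_y()),
               class = "invalid_argument")
  cfg <- default_strata_config(n_per_arm = 7, seed = 99)
  bad <- cfg; bad$mu_y["c", "1", "1"] <- 1.5
  expect_error(coolmediate:::validate_strata_config(bad),
               class = "invalid_argument")

  path <- tempfile(fileext = ".json")
  write_strata_config(cfg, path)
  back <- read_strata_config(path)
  expect_equal(back$mu_y, cfg$mu_y)
  expect_equal(back$seed, cfg$seed)
  expect_equal(back$emo_anchor_high, cfg$emo_anchor_high)
  # identical seeds produce identical simulated tables through the round-trip
  expect_identical(simulate_experiment(cfg), simulate_experiment(back))
})

test_that("attrition simulation flags completers at the configured rates", {
  cfg <- default_strata_config(n_per_arm = 4000, seed = 31)
  tab <- simulate_experiment(cfg, attrition_rates = c("Vid-Short" = 0.2))
  arms <- arm_label(tab$D, tab$C)
  fail_vs <- mean(tab$passed_checks[arms == "Vid-Short"] == 0)
  expect_lt(abs(fail_vs - 0.2), 3 * sqrt(0.2 * 0.8 / 4000))
  expect_true(all(tab$passed_checks[arms != "Vid-Short"] == 1))
})
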