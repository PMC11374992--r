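#' Generator configuration for the four-arm cooling-off experiment
#'
#' A `strata_config` bundles every parameter of the synthetic experiment:
#' principal-strata shares, the cooling-off compliance share, the map from
#' latent state to expected donation score, the zero-inflation mass, the
#' Likert and donation dispersion, the per-arm sample size and the master
#' seed. The latent-state model is the standard principal-strata typology for
#' a binary mediator: always-takers (`a`) are in the high emotional state in
#' every arm, never-takers (`n`) never are, and compliers (`c`) switch to the
#' high state when exposed to the video; a share `q` of exposed compliers
#' returns to the low state during the cooling-off period. Defiers are
#' excluded by construction.
#'
#' @param p_a,p_n,p_c shares of always-takers, never-takers and compliers;
#'   must sum to 1 (tolerance 1e-12).
#' @param q share of compliers whose emotional state returns to low under the
#'   cooling-off period, in \[0, 1\].
#' @param mu_y 3-d numeric array (stratum `a`/`n`/`c` x exposure `0`/`1` x
#'   mediator state `0`/`1`) of expected donation scores in \[0, 1\]. Only the
#'   cells reachable under the strata model are used (e.g. always-takers are
#'   never in state 0); unreachable cells may be `NA`.
#' @param zero_inflation probability that a participant donates 0 to every
#'   option, in \[0, 1). Conditional on donating, per-option amounts are
#'   beta-binomial on 0..100 with mean chosen so the unconditional expected
#'   donation score equals the `mu_y` cell exactly.
#' @param likert_noise beta-binomial overdispersion of the emotion items
#'   around their state anchors, in \[0, 1); 0 gives plain binomial draws.
#' @param donation_noise beta-binomial overdispersion of the per-option
#'   donation amounts, in \[0, 1).
#' @param n_per_arm participants per arm (positive integer).
#' @param seed master seed; independent child streams are derived per stage.
#' @param emo_anchor_high,emo_anchor_low named length-6 vectors of expected
#'   Likert means (scale 1-7) for the six emotion items in the high and low
#'   mediator state. Names must be the `emo_*` item columns.
#' @return an object of class `strata_config`.
#' @seealso [default_strata_config()] for the calibrated defaults,
#'   [true_estimands()], [simulate_experiment()].
#' @export
strata_config <- function(p_a, p_n, p_c, q, mu_y,
                          zero_inflation = 0.3,
                          likert_noise = 0.15,
                          donation_noise = 0.3,
                          n_per_arm = 800L,
                          seed = 1L,
                          emo_anchor_high = c(emo_anger = 6.1, emo_disgust = 6.1,
                                              emo_fear = 6.1, emo_sadness = 6.1,
                                              emo_happiness = 1.9, emo_surprise = 6.1),
                          emo_anchor_low = c(emo_anger = 1.8, emo_disgust = 1.8,
                                             emo_fear = 1.8, emo_sadness = 1.8,
                                             emo_happiness = 5.6, emo_surprise = 1.8)) {
  cfg <- structure(
    list(p_a = p_a, p_n = p_n, p_c = p_c, q = q, mu_y = mu_y,
         zero_inflation = zero_inflation, likert_noise = likert_noise,
         donation_noise = donation_noise,
         n_per_arm = as.integer(n_per_arm), seed = as.integer(seed),
         emo_anchor_high = emo_anchor_high[EMOTION_COLS],
         emo_anchor_low = emo_anchor_low[EMOTION_COLS]),
    class = "strata_config")
  validate_strata_config(cfg)
  cfg
}

# Cells of mu_y reachable under the no-defiers strata model.
reachable_cells <- function() {
  rbind(c("a", "0", "1"), c("a", "1", "1"),
        c("n", "0", "0"), c("n", "1", "0"),
        c("c", "0", "0"), c("c", "1", "0"), c("c", "1", "1"))
}

mu_cell <- function(cfg, stratum, d, m) {
  cfg$mu_y[stratum, as.character(d), as.character(m)]
}

validate_strata_config <- function(cfg) {
  with(cfg, {
    if (abs(p_a + p_n + p_c - 1) > 1e-12)
      cm_stop("strata shares must sum to 1", "invalid_argument")
    if (any(c(p_a, p_n, p_c) < 0) || q < 0 || q > 1)
      cm_stop("shares and q must lie in [0, 1]", "invalid_argument")
    if (!is.array(mu_y) || !identical(dim(mu_y), c(3L, 2L, 2L)))
      cm_stop("mu_y must be a 3 x 2 x 2 array", "invalid_argument")
    if (zero_inflation < 0 || zero_inflation >= 1)
      cm_stop("zero_inflation must be in [0, 1)", "invalid_argument")
    if (likert_noise < 0 || likert_noise >= 1 ||
        donation_noise < 0 || donation_noise >= 1)
      cm_stop("dispersion parameters must be in [0, 1)", "invalid_argument")
    if (n_per_arm < 1) cm_stop("n_per_arm must be positive", "invalid_argument")
    if (any(emo_anchor_high < 1 | emo_anchor_high > 7, na.rm = TRUE) ||
        any(emo_anchor_low < 1 | emo_anchor_low > 7, na.rm = TRUE))
      cm_stop("emotion anchors must lie on the 1-7 scale", "invalid_argument")
  })
  cells <- reachable_cells()
  mus <- apply(cells, 1, function(r) cfg$mu_y[r[1], r[2], r[3]])
  if (anyNA(mus) || any(mus < 0 | mus > 1))
    cm_stop("reachable mu_y cells must be defined and in [0, 1]",
            "invalid_argument")
  # the conditional per-option mean must stay on the 0..100 cent scale
  if (any(mus / (1 - cfg$zero_inflation) > 1))
    cm_stop("mu_y incompatible with zero_inflation: conditional mean exceeds 1",
            "invalid_argument")
  invisible(cfg)
}

# Expected negative-emotion score implied by a set of item anchors.
anchor_score <- function(anchor) {
  (sum(anchor[NEGATIVE_EMOTIONS]) - anchor[["emo_happiness"]] + 2) / 36
}

empty_mu_y <- function() {
  array(NA_real_, dim = c(3, 2, 2),
        dimnames = list(stratum = c("a", "n", "c"), d = c("0", "1"),
                        m = c("0", "1")))
}

#' Calibrate a generator configuration to target arm means
#'
#' Solves, in closed form, for strata shares, the compliance share `q` and the
#' complier donation means so that the population arm means of the generated
#' data equal the supplied targets exactly. Identification follows the
#' estimator's own algebra: the emotion-score means pin down the share in the
#' high state per arm (given the two state anchors), hence `p_a`, `p_c`, `p_n`
#' and `q`; the donation means then pin down the complier cells given
#' baseline donation levels for always- and never-takers and their direct
#' (unmediated) video effects, which are not identified by arm means and must
#' be supplied as structural choices.
#'
#' @param donation_means named vector with entries `NS`, `VS`, `VL`: target
#'   mean donation scores for Novid-Short, Vid-Short and Vid-Long.
#' @param emotion_means named vector with entries `NS`, `VS`, `VL`: target
#'   mean negative-emotion scores for the same arms.
#' @param mu_n0,mu_a0 baseline expected donation scores of never-takers and
#'   always-takers without the video.
#' @param direct_n,direct_a,direct_c direct (mediator-held-fixed) video
#'   effects on the donation score per stratum.
#' @param ... further arguments passed to [strata_config()] (sample size,
#'   seed, dispersion, anchors).
#' @return a validated `strata_config` whose [population_arm_means()] equal
#'   the targets.
#' @export
calibrate_strata_config <- function(donation_means, emotion_means,
                                    mu_n0 = 0.10, mu_a0 = 0.26,
                                    direct_n = 0.02, direct_a = 0.03,
                                    direct_c = 0.0258, ...) {
  stopifnot(all(c("NS", "VS", "VL") %in% names(donation_means)),
            all(c("NS", "VS", "VL") %in% names(emotion_means)))
  dots <- list(...)
  anchor_high <- if (is.null(dots$emo_anchor_high))
    eval(formals(strata_config)$emo_anchor_high) else dots$emo_anchor_high
  anchor_low <- if (is.null(dots$emo_anchor_low))
    eval(formals(strata_config)$emo_anchor_low) else dots$emo_anchor_low
  e_high <- anchor_score(anchor_high)
  e_low <- anchor_score(anchor_low)

  span <- e_high - e_low
  p_a <- (emotion_means[["NS"]] - e_low) / span
  p_high_vs <- (emotion_means[["VS"]] - e_low) / span
  p_c <- p_high_vs - p_a
  p_n <- 1 - p_high_vs
  q <- (emotion_means[["VS"]] - emotion_means[["VL"]]) /
    (emotion_means[["VS"]] - emotion_means[["NS"]])
  if (min(p_a, p_c, p_n) < 0 || q < 0 || q > 1)
    cm_stop("targets are not attainable with the given anchors",
            "invalid_argument")

  mu <- empty_mu_y()
  mu["n", "0", "0"] <- mu_n0
  mu["n", "1", "0"] <- mu_n0 + direct_n
  mu["a", "0", "1"] <- mu_a0
  mu["a", "1", "1"] <- mu_a0 + direct_a
  mu["c", "0", "0"] <-
    (donation_means[["NS"]] - p_a * mu["a", "0", "1"] -
       p_n * mu["n", "0", "0"]) / p_c
  mu["c", "1", "1"] <-
    (donation_means[["VS"]] - p_a * mu["a", "1", "1"] -
       p_n * mu["n", "1", "0"]) / p_c
  delta <- donation_means[["VS"]] - donation_means[["VL"]]
  mu["c", "1", "0"] <- mu["c", "1", "1"] - delta / (p_c * q)

  strata_config(p_a = p_a, p_n = p_n, p_c = p_c, q = q, mu_y = mu, ...)
}

#' Default configuration: the published arm means
#'
#' The calibrated study conditions: population arm means equal to the
#' published donation scores (16.4/20.2/19.1 percent) and negative-emotion
#' scores (25.7/66.0/32.2 percent) for Novid-Short, Vid-Short and Vid-Long;
#' the cooling-off arm without video mirrors Novid-Short by the exclusion
#' restriction. Zero-inflation defaults to 0.3, between the pilot's
#' zero-donation shares with and without the video.
#'
#' @param n_per_arm participants per arm; the study's planned size was 800.
#' @param seed master seed.
#' @param ... overrides passed on to [calibrate_strata_config()].
#' @return a `strata_config`.
#' @export
default_strata_config <- function(n_per_arm = 800L, seed = 1L, ...) {
  calibrate_strata_config(
    donation_means = c(NS = 0.164, VS = 0.202, VL = 0.191),
    emotion_means = c(NS = 0.257, VS = 0.660, VL = 0.322),
    n_per_arm = n_per_arm, seed = seed, ...)
}

#' Variant of a configuration with a prescribed true mediated effect
#'
#' Rescales the complier donation contrast so the true mediated effect equals
#' `delta_M`, holding `mu_y(c,1,0)`, the strata shares and `q` fixed. Used for
#' recovery and null-calibration experiments where the truth must be known.
#'
#' @param delta_M target true mediated effect (donation-score units).
#' @param config base configuration (default [default_strata_config()]).
#' @return a `strata_config` whose [true_estimands()] report `delta_M`.
#' @export
config_with_mediated_effect <- function(delta_M,
                                        config = default_strata_config()) {
  mu <- config$mu_y
  mu["c", "1", "1"] <- mu["c", "1", "0"] + delta_M / config$p_c
  config$mu_y <- mu
  validate_strata_config(config)
  config
}

#' @export
print.strata_config <- function(x, ...) {
  cat("strata_config:\n")
  cat(sprintf("  shares     p_a=%.4f  p_n=%.4f  p_c=%.4f\n", x$p_a, x$p_n, x$p_c))
  cat(sprintf("  cool-off   q=%.4f\n", x$q))
  te <- true_estimands(x)
  cat(sprintf("  estimands  delta_TT=%.4f  delta_M=%.4f\n",
              te$delta_TT, te$delta_M))
  cat(sprintf("  sampling   n_per_arm=%d  seed=%d  zero_inflation=%.2f\n",
              x$n_per_arm, x$seed, x$zero_inflation))
  invisible(x)
}

#' Serialize / read a generator configuration as JSON
#'
#' @param config a `strata_config`.
#' @param path file path.
#' @return `read_strata_config()` returns a validated `strata_config`.
#' @export
write_strata_config <- function(config, path) {
  x <- unclass(config)
  x$mu_y <- as.vector(x$mu_y)
  x$emo_anchor_high <- as.list(x$emo_anchor_high)
  x$emo_anchor_low <- as.list(x$emo_anchor_low)
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname write_strata_config
#' @export
read_strata_config <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  mu <- empty_mu_y()
  mu[] <- x$mu_y
  strata_config(p_a = x$p_a, p_n = x$p_n, p_c = x$p_c, q = x$q, mu_y = mu,
                zero_inflation = x$zero_inflation,
                likert_noise = x$likert_noise,
                donation_noise = x$donation_noise,
                n_per_arm = x$n_per_arm, seed = x$seed,
                emo_anchor_high = unlist(x$emo_anchor_high),
                emo_anchor_low = unlist(x$emo_anchor_low))
}
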