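#' @importFrom stats rbinom rbeta sd median quantile var qnorm setNames
#' @importFrom utils head write.csv read.csv packageVersion
NULL

# Classed conditions so callers can distinguish design errors from bugs.
cm_stop <- function(msg, class) {
  stop(errorCondition(msg, class = c(class, "coolmediate_error")))
}

ARM_LEVELS <- c("Novid-Short", "Novid-Long", "Vid-Short", "Vid-Long")

DONATION_COLS <- paste0("don_", 1:7)
EMOTION_COLS <- c("emo_anger", "emo_disgust", "emo_fear", "emo_sadness",
                  "emo_happiness", "emo_surprise")
NEGATIVE_EMOTIONS <- setdiff(EMOTION_COLS, "emo_happiness")

#' Arm label from treatment indicators
#'
#' Maps the video indicator `D` and the cooling-off indicator `C` to the
#' four arm labels: `Novid-Short` (D=0,C=0), `Novid-Long` (D=0,C=1),
#' `Vid-Short` (D=1,C=0), `Vid-Long` (D=1,C=1).
#'
#' @param D integer vector of 0/1 video-exposure indicators.
#' @param C integer vector of 0/1 cooling-off (long survey) indicators.
#' @return factor with levels in the canonical arm order.
#' @export
arm_label <- function(D, C) {
  stopifnot(all(D %in% 0:1), all(C %in% 0:1))
  factor(ifelse(D == 0,
                ifelse(C == 0, "Novid-Short", "Novid-Long"),
                ifelse(C == 0, "Vid-Short", "Vid-Long")),
         levels = ARM_LEVELS)
}

#' Empirical percentile of bootstrap draws
#'
#' Fixed empirical-quantile convention: the draws are sorted and the value at
#' rank `ceiling(p * B)` is returned. The registered decision rules compare a
#' percentile to zero, so the convention must be deterministic and documented;
#' this is the conservative order-statistic reading of "the 5th percentile of
#' the bootstrap distribution".
#'
#' @param draws numeric vector of bootstrap draws (NAs dropped).
#' @param p probability in (0, 1].
#' @return the order statistic at rank `ceiling(p * length(draws))`.
#' @export
boot_percentile <- function(draws, p) {
  draws <- draws[!is.na(draws)]
  if (length(draws) == 0L) cm_stop("no valid draws", "invalid_argument")
  if (any(p <= 0 | p > 1)) cm_stop("p must be in (0, 1]", "invalid_argument")
  s <- sort(draws)
  s[pmax(1L, ceiling(p * length(s)))]
}

# Beta-binomial draws on 0..size with exact mean size*mu and overdispersion
# rho in [0, 1); rho = 0 degenerates to the plain binomial.
rbetabinom <- function(n, size, mu, rho = 0) {
  stopifnot(all(mu >= 0 & mu <= 1), rho >= 0, rho < 1)
  if (rho == 0) return(rbinom(n, size, mu))
  nu <- 1 / rho - 1
  p <- rbeta(n, mu * nu, (1 - mu) * nu)
  rbinom(n, size, p)
}

# Independent child seed per pipeline stage, derived from one master seed.
# Kept below 2^31 so set.seed() always accepts it.
child_seed <- function(seed, stage) {
  stages <- c(arms = 1, strata = 2, mediators = 3, outcomes = 4,
              attrition = 5, bootstrap = 6, power = 7)
  off <- stages[[stage]]
  as.integer((as.numeric(seed) %% 1e6) * 1009 + off * 101)
}
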