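# Exact two-sided permutation p-value for the rank-sum statistic (midranks):
# enumerates every assignment of the pooled ranks to the first sample.
# Independent of the package's normal-approximation path.
exact_wilcoxon_p <- function(a, b) {
  r <- rank(c(a, b))
  n1 <- length(a)
  combs <- utils::combn(length(r), n1)
  sums <- colSums(matrix(r[combs], nrow = n1))
  mu <- n1 * (length(r) + 1) / 2
  w_obs <- sum(r[seq_len(n1)])
  mean(abs(sums - mu) >= abs(w_obs - mu) - 1e-12)
}

# Minimal scored table with one known score pair per arm cell, n rows per arm.
scored_table <- function(y = c(NS = 0.164, NL = 0.164, VS = 0.202, VL = 0.191),
                         m = c(NS = 0.257, NL = 0.257, VS = 0.660, VL = 0.322),
                         n = 1L) {
  cells <- data.frame(D = c(0, 0, 1, 1), C = c(0, 1, 0, 1),
                      donation_score = as.numeric(y[c("NS", "NL", "VS", "VL")]),
                      neg_emotion_score = as.numeric(m[c("NS", "NL", "VS", "VL")]))
  out <- cells[rep(1:4, each = n), ]
  out$id <- seq_len(nrow(out))
  rownames(out) <- NULL
  out
}

# Bootstrap-result stub around a given draw vector (uses the package's own
# summary constructor so percentile/share conventions match).
boot_result_from_draws <- function(draws, statistic = "delta_M",
                                   econ_threshold = 0.03) {
  coolmediate:::make_bootstrap_result(statistic, draws, length(draws), 1L,
                                      mean(draws), econ_threshold)
}
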