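# Shared fixtures and small independent oracles used across test files.

make_matrix <- function(values, nrow, probes = sprintf("cg%02d", seq_len(nrow)),
                        samples = sprintf("s%02d", seq_len(length(values) / nrow))) {
  matrix(values, nrow = nrow, dimnames = list(probes, samples))
}

small_cohort <- function(seed = 7, ...) {
  args <- list(n_normal = 15, n_dcis = 10, n_ibc = 15, n_cpgs = 200,
               n_diff_normal_dcis = 15, n_diff_dcis_ibc = 5,
               n_eqtm = 15, n_signature = 4, seed = seed)
  args[names(list(...))] <- list(...)
  simulate_cohort(do.call(simulate_config, args))
}

# independent Pearson r/p via explicit sums (no cor()/cor.test())
pearson_oracle <- function(x, y) {
  n <- length(x)
  sx <- sum(x); sy <- sum(y)
  num <- n * sum(x * y) - sx * sy
  den <- sqrt(n * sum(x^2) - sx^2) * sqrt(n * sum(y^2) - sy^2)
  r <- num / den
  tt <- r * sqrt((n - 2) / (1 - r^2))
  list(r = r, p = 2 * stats::pt(-abs(tt), n - 2))
}

# independent two-class SAM d via the plain formula
sam_d_oracle <- function(values, labels, s0 = 0) {
  labs <- unique(labels)
  apply(values, 1, function(v) {
    a <- v[labels == labs[1]]; b <- v[labels == labs[2]]
    sp <- sqrt((1 / length(a) + 1 / length(b)) *
                 (sum((a - mean(a))^2) + sum((b - mean(b))^2)) /
                 (length(a) + length(b) - 2))
    (mean(b) - mean(a)) / (sp + s0)
  })
}

# survival times with a piecewise-constant hazard that switches at t_switch
# (used to plant a time-varying covariate effect)
rpiecewise <- function(n, h_early, h_late, t_switch) {
  u <- stats::runif(n)
  t1 <- -log(u) / h_early
  ifelse(t1 <= t_switch, t1, t_switch - (log(u) + h_early * t_switch) / h_late)
}
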