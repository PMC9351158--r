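# shared fixtures, built in code

# central finite-difference gradient for checking analytic scores
num_grad <- function(f, par, eps = 1e-6) {
  vapply(seq_along(par), function(i) {
    p1 <- par; p2 <- par
    p1[i] <- p1[i] + eps
    p2[i] <- p2[i] - eps
    (f(p1) - f(p2)) / (2 * eps)
  }, numeric(1))
}

# a fixed small dataset per family, deterministic
small_data <- function(family, n = 100, seed = 404) {
  sim_counts(
    family = family,
    alpha = if (family %in% c("nb", "zinb")) 1,
    phi = if (family %in% c("zip", "zinb")) 0.3,
    n = n, seed = seed
  )
}

# two-sample chi-square comparison of count samples, pooling the tail
chisq_two_sample <- function(a, b, max_bin = 30) {
  bins <- pmin(c(a, b), max_bin)
  grp <- rep(c("a", "b"), c(length(a), length(b)))
  suppressWarnings(stats::chisq.test(table(grp, bins))$p.value)
}
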