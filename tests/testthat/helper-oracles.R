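# Independent oracles, deliberately naive: direct-summation DFT and
# textbook sums-of-squares ANOVA. They never share code with the package.

dft_amplitude_oracle <- function(x, n_points) {
  x <- c(x - mean(x), rep(0, n_points - length(x)))
  idx <- seq_along(x) - 1
  vapply(seq_len(n_points / 2), function(k)
    Mod(sum(x * exp(-2i * pi * k * idx / n_points))), 0)
}

anova_bruteforce <- function(groups) {
  vals <- unlist(groups)
  k <- length(groups); N <- length(vals)
  grand <- mean(vals)
  ssb <- sum(vapply(groups, function(g) length(g) * (mean(g) - grand)^2, 0))
  ssw <- sum(vapply(groups, function(g) sum((g - mean(g))^2), 0))
  f <- (ssb / (k - 1)) / (ssw / (N - k))
  list(f_stat = f, df_between = k - 1, df_within = N - k,
       p_value = stats::pf(f, k - 1, N - k, lower.tail = FALSE))
}

# quantize a real signal to the nearest EIIP residue, as a test-side check
nearest_residue_oracle <- function(x, entries) {
  e <- entries[order(names(entries))]
  names(e)[which.min(abs(unname(e) - x))]
}
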