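# Fixture builders shared across test files; everything is generated in code.

tiny_table <- function() {
  OtuTable(matrix(c(1, 2,
                    3, 4), 2, byrow = TRUE,
                  dimnames = list(c("s1", "s2"), c("tA", "tB"))))
}

# Random Poisson count table (has plenty of rank ties at small lambda).
rand_table <- function(n_samples, n_taxa, seed, lambda = 3) {
  set.seed(seed)
  m <- matrix(rpois(n_samples * n_taxa, lambda), n_samples, n_taxa,
              dimnames = list(sprintf("s%02d", seq_len(n_samples)),
                              sprintf("t%02d", seq_len(n_taxa))))
  OtuTable(m)
}

# Brute-force Spearman: explicit average ranks, then the Pearson formula.
brute_spearman <- function(m) {
  rk <- apply(m, 2L, rank)
  S <- ncol(m)
  out <- matrix(NA_real_, S, S, dimnames = list(colnames(m), colnames(m)))
  for (i in seq_len(S)) for (j in seq_len(S)) {
    a <- rk[, i]; b <- rk[, j]
    num <- sum((a - mean(a)) * (b - mean(b)))
    den <- sqrt(sum((a - mean(a))^2) * sum((b - mean(b))^2))
    out[i, j] <- if (den == 0) NA_real_ else num / den
  }
  out
}

# Brute-force Bray-Curtis double loop.
brute_bray <- function(m) {
  n <- nrow(m)
  out <- matrix(0, n, n)
  for (i in seq_len(n)) for (j in seq_len(n))
    out[i, j] <- sum(abs(m[i, ] - m[j, ])) / sum(m[i, ] + m[j, ])
  out
}

# Noisy logarithm-model taxa-area curve over the standard nested areas.
noisy_log_curve <- function(seed, z = 50, c0 = 100, sd = 5, levels = 9,
                            n_plots = 3) {
  areas <- rep((0.5 * 2^(seq_len(levels) - 1))^2, n_plots)
  set.seed(seed)
  data.frame(area = areas,
             richness = c0 + z * log10(areas) + rnorm(length(areas), 0, sd),
             plot_id = rep(seq_len(n_plots), each = levels))
}
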