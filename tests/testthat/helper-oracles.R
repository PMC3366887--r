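# Independent brute-force oracles used across the suite. These deliberately
# take the dumbest correct path (pairwise counting, exhaustive enumeration,
# normal equations) so they share no code with the implementation.

# Mann-Whitney U of x vs y by direct pairwise comparison (ties count 1/2).
oracle_u <- function(x, y) {
  u <- 0
  for (xi in x) for (yj in y) {
    u <- u + (xi > yj) + 0.5 * (xi == yj)
  }
  u
}

# Two-sided exact MW p by enumerating every subset of the pooled values as
# "group x", doubling the smaller one-sided tail.
oracle_mw_exact <- function(x, y) {
  pooled <- c(x, y)
  n <- length(x)
  combs <- combn(length(pooled), n)
  u_obs <- oracle_u(x, y)
  u_all <- apply(combs, 2, function(ix) {
    oracle_u(pooled[ix], pooled[-ix])
  })
  eps <- 1e-9
  min(1, 2 * min(mean(u_all <= u_obs + eps), mean(u_all >= u_obs - eps)))
}

# OLS slope/intercept via the closed-form normal equations.
oracle_ols <- function(x, y) {
  sxx <- sum((x - mean(x))^2)
  slope <- sum((x - mean(x)) * (y - mean(y))) / sxx
  c(intercept = mean(y) - slope * mean(x), slope = slope)
}

# LD statistics from an explicit 2x2 haplotype count table.
oracle_ld_from_counts <- function(n_ab, n_aB, n_Ab, n_AB) {
  n <- n_ab + n_aB + n_Ab + n_AB
  p_ab <- n_ab / n
  p_a <- (n_ab + n_aB) / n
  p_b <- (n_ab + n_Ab) / n
  D <- p_ab - p_a * p_b
  d_max <- if (D >= 0) min(p_a * (1 - p_b), (1 - p_a) * p_b)
           else min(p_a * p_b, (1 - p_a) * (1 - p_b))
  list(D = D,
       d_prime = if (d_max == 0) 0 else D / d_max,
       r_squared = if (p_a %in% c(0, 1) || p_b %in% c(0, 1)) 0
                   else D^2 / (p_a * (1 - p_a) * p_b * (1 - p_b)))
}

# Write a replicate table data.frame for tests.
make_replicate_file <- function(df, path = tempfile(fileext = ".tsv"),
                                sep = "\t") {
  write.table(df, path, sep = sep, quote = FALSE, row.names = FALSE)
  path
}

taqman_rows <- function(sample_id, snp_id, template, s1, s2) {
  data.frame(sample_id = sample_id, snp_id = snp_id, template = template,
             platform = "taqman", replicate = seq_along(s1),
             signal_1 = s1, signal_2 = s2, stringsAsFactors = FALSE)
}
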