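# Independent oracles, deliberately written on different paths than the
# package implementation.

# Harmonic number by a literal loop.
harmonic_loop <- function(n) {
  s <- 0
  for (i in seq_len(n)) s <- s + 1 / i
  s
}

# Depth-corrected abundance by direct transcription of the formula.
beta_loop <- function(S, L, D) {
  ((S + 1) / L) / harmonic_loop(floor(D) - 1)
}

# One-sided (over-representation) Fisher p-value by explicit
# hypergeometric tail summation over lchoose terms.
hyper_p_greater <- function(a, b, c_, d) {
  K <- a + c_; n <- a + b; N <- a + b + c_ + d
  ks <- a:min(K, n)
  sum(exp(lchoose(K, ks) + lchoose(N - K, n - ks) - lchoose(N, n)))
}

# Two-sided Fisher p-value: sum of all table probabilities not exceeding
# the observed one (with the usual relative tolerance).
hyper_p_twosided <- function(a, b, c_, d) {
  K <- a + c_; n <- a + b; N <- a + b + c_ + d
  ks <- max(0, n - (N - K)):min(K, n)
  pr <- exp(lchoose(K, ks) + lchoose(N - K, n - ks) - lchoose(N, n))
  p_obs <- pr[ks == a]
  sum(pr[pr <= p_obs * (1 + 1e-7)])
}

# A small, fast study configuration for end-to-end tests.
small_config <- function(...) {
  args <- list(n_contigs = 150, n_genes = 100, n_markers = 80,
               n_samples = 40, rng_seed = 42L)
  override <- list(...)
  args[names(override)] <- override
  do.call(synth_config, args)
}

site_key <- function(df) paste(df$contig_id, df$pos)
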