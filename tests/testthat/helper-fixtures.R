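# Shared fixtures: layouts, small screens, brute-force oracles.

make_layout <- function(n_plates = 1L, prefix = "prey") {
  library_layout(data.frame(
    plate = rep(seq_len(n_plates), each = 96L),
    row = rep(rep(1:8, each = 12L), n_plates),
    col = rep(1:12, 8L * n_plates),
    prey = sprintf("%s%03d", prefix, seq_len(96L * n_plates))))
}

# Brute-force upper-tail hypergeometric probability by enumerating every
# n-subset of a universe of size N: P(|draw ∩ annotated| >= k_obs).
brute_hyper_p <- function(N, annotated, n, k_obs) {
  draws <- utils::combn(N, n)
  mean(apply(draws, 2, function(d) sum(d %in% annotated) >= k_obs))
}

# Interactome table helper for comparison tests.
interactome <- function(prey, density, positive) {
  data.frame(prey = prey, mean_density = density, positive = positive,
             status = "ok")
}
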