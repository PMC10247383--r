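# Independent brute-force oracles used across tests.

# exhaustive rarefaction: mean Hill number over every m-subset of individuals
enum_rarefy <- function(counts, m, q) {
  pool <- rep(seq_along(counts), counts)
  subs <- utils::combn(length(pool), m)
  vals <- apply(subs, 2, function(idx) {
    hill_number(tabulate(pool[idx], nbins = length(counts)), q)
  })
  mean(vals)
}

# Kruskal-Wallis H with tie correction, computed from first principles
kw_H <- function(x, g) {
  g <- factor(g)
  r <- rank(x)
  n <- length(x)
  H <- 12 / (n * (n + 1)) *
    sum(tapply(r, g, function(ri) length(ri) * (mean(ri) - (n + 1) / 2)^2))
  ties <- table(x)
  H / (1 - sum(ties^3 - ties) / (n^3 - n))
}

# small deterministic design + dataset reused by several files
tiny_dataset <- function(seed = 7, ...) {
  design <- build_design(seed = seed)
  simulate_dataset(design, simulation_params(seed = seed, ...))
}
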