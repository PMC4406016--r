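# Shared fixtures, built in code. The medium cohort used by several
# integration tests is cached per session.

.fx <- new.env(parent = emptyenv())

# a small grid: n_chrom chromosomes x probes_per probes at 100 kb pitch
small_grid <- function(n_chrom = 4, probes_per = 30) {
  generate_probe_grid(sim_config(n_probes = n_chrom * probes_per,
                                 n_chromosomes = n_chrom))
}

# single-sample cohort from a ratio vector
one_sample_cohort <- function(grid, ratio, thresholds = state_thresholds()) {
  cna_cohort(grid, matrix(ratio, ncol = 1,
                          dimnames = list(grid$probe, "s1")), thresholds)
}

# a segmented + state-called medium synthetic cohort (cached)
medium_cohort <- function() {
  if (is.null(.fx$medium)) {
    cfg <- sim_config(n_probes = 920, n_chromosomes = 23, seed = 42)
    sim <- generate_cohort(cfg)
    co <- call_states(segment_cohort(sim$cohort, seed = 43))
    .fx$medium <- list(sim = sim, cohort = co)
  }
  .fx$medium
}

# ---- independent brute-force oracles -------------------------------------

# Mann-Whitney two-sided exact p by enumeration of all C(n, na) labelings
mw_enum_p <- function(a, b) {
  x <- c(a, b)
  na <- length(a)
  r <- rank(x)
  u_of <- function(idx) sum(r[idx]) - na * (na + 1) / 2
  obs <- u_of(seq_len(na))
  labelings <- utils::combn(length(x), na)
  us <- apply(labelings, 2, u_of)
  min(1, 2 * min(mean(us <= obs), mean(us >= obs)))
}

# Spearman two-sided exact p by enumeration of all n! orderings
spearman_enum_p <- function(x, y) {
  n <- length(x)
  rx <- rank(x); ry <- rank(y)
  obs <- abs(cor(rx, ry))
  perms <- matrix(0L, factorial(n), n)
  idx <- 1L
  rec <- function(prefix, rest) {
    if (!length(rest)) {
      perms[idx, ] <<- prefix
      idx <<- idx + 1L
      return(invisible())
    }
    for (k in seq_along(rest)) rec(c(prefix, rest[k]), rest[-k])
  }
  rec(integer(0), seq_len(n))
  rhos <- apply(perms, 1, function(p) cor(rx[p], ry))
  mean(abs(rhos) >= obs - 1e-12)
}

# Benjamini-Hochberg step-up, written independently (explicit loop)
bh_oracle <- function(p) {
  m <- length(p)
  o <- order(p)
  q <- numeric(m)
  prev <- Inf
  for (i in m:1) {
    v <- min(prev, p[o[i]] * m / i, 1)
    q[o[i]] <- v
    prev <- v
  }
  q
}
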