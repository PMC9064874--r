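# Shared fixtures for the test suite. Everything is generated in code; the
# only file dependency is the bundled synthetic reference table.

ref_table <- read_reference_table()

# deterministic random symmetric 3x3 tensor
random_sym_tensor <- function(seed, scale = 5) {
  set.seed(seed)
  m <- matrix(stats::rnorm(9, sd = scale), 3, 3)
  (m + t(m)) / 2
}

# brute-force displacement enumeration over a generous translation box
brute_force_displacements <- function(a, b, cell, cutoff, nmax = 6) {
  hits <- list()
  for (l1 in -nmax:nmax) for (l2 in -nmax:nmax) for (l3 in -nmax:nmax) {
    L <- c(l1, l2, l3)
    if (any(L[!cell$periodic] != 0)) next
    p <- b + drop(L %*% cell$vectors)
    d <- sqrt(sum((p - a)^2))
    if (d < cutoff && d > 1e-12) hits[[length(hits) + 1]] <- c(L, d)
  }
  do.call(rbind, hits)
}
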