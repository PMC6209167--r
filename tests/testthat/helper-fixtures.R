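# Shared fixtures: small parameter sets and independent oracles.

# default parameter set used throughout the experiments
base_params <- function(L = 64, allowed_a = c(0, 150), seed = 1, ...) {
  model_params(L = L, allowed_a = allowed_a, seed = seed, ...)
}

pns_comp <- function(a, f = 0.05) {
  lattice_composition(setNames(rep(f, 3), c(cell_state("P", a), "N", "S")))
}

# Build a lattice by hand from a vector/matrix of integer codes
lattice_from_codes <- function(codes, L, allowed_a) {
  spatabx:::new_lattice(as.raw(as.integer(codes)), L, allowed_a)
}

# Brute-force oracle for the antibiotic field: double loop over all sites
# and their 9-site Moore neighbourhoods with explicit torus wrapping.
brute_force_field <- function(lattice, b) {
  L <- lattice$side
  codes <- as.integer(lattice$cells)
  a_of <- function(idx) {
    k <- codes[idx]
    if (k >= 1 && k < 100) lattice$allowed_a[k] else 0
  }
  wrap <- function(i) ((i - 1) %% L) + 1
  field <- matrix(0, L, L)
  for (row in seq_len(L)) {
    for (col in seq_len(L)) {
      tot <- 0
      for (dr in -1:1) for (dc in -1:1) {
        rr <- wrap(row + dr); cc <- wrap(col + dc)
        tot <- tot + a_of((cc - 1) * L + rr)
      }
      field[row, col] <- tot / (9 * b)
    }
  }
  field
}

# Independent bisection root finder (oracle for the production-rate window)
bisect <- function(f, lo, hi, tol = 1e-10) {
  flo <- f(lo)
  stopifnot(sign(flo) != sign(f(hi)))
  while (hi - lo > tol * max(1, abs(hi))) {
    mid <- (lo + hi) / 2
    if (sign(f(mid)) == sign(flo)) lo <- mid else hi <- mid
  }
  (lo + hi) / 2
}
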