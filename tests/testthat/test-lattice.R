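test_that("initialisation hits the requested occupancy fractions", {
  p <- base_params(L = 128)
  lat <- initialize_lattice(p, pns_comp(150), seed = 3)
  conc <- concentrations(lat)
  n <- p$L^2
  tol <- 4 * sqrt(0.05 * 0.95 / n)      # 4 binomial sd
  for (lb in c("P150", "N", "S")) expect_equal(unname(conc[lb]), 0.05, tolerance = tol / 0.05)
  expect_equal(sum(conc), 1)
  # edge compositions
  expect_identical(concentrations(initialize_lattice(p, lattice_composition())),
                   c(vacant = 1))
  full_S <- initialize_lattice(p, lattice_composition(S = 1))
  expect_identical(concentrations(full_S), c(S = 1))
  expect_error(lattice_composition(S = 0.7, N = 0.7), "sum")
})

test_that("antibiotic field matches single-producer geometry and brute force", {
  p <- base_params(L = 8, allowed_a = c(0, 110))
  # single producer: field is a/(9b) on its 9-site neighbourhood, 0 elsewhere
  codes <- rep(0L, 64)
  codes[3 * 8 + 4] <- 2L        # one P110
  lat <- lattice_from_codes(codes, 8, p$allowed_a)
  f <- antibiotic_field(lat, b = 10)
  expect_equal(sort(unique(as.numeric(f))), c(0, 110 / 90))
  expect_identical(sum(f > 0), 9L)
  # all-sensitive lattice: zero field
  latS <- initialize_lattice(p, lattice_composition(S = 1))
  expect_true(all(antibiotic_field(latS, 10) == 0))
  # uniform producers: field = a/b everywhere (matches well-mixed A = aP/b at P = 1)
  latP <- initialize_lattice(p, lattice_composition(P110 = 1))
  expect_true(all(abs(antibiotic_field(latP, 10) - 11) < 1e-12))
  # random heterogeneous lattices against the double-loop oracle
  p2 <- base_params(L = 11, allowed_a = c(0, 50, 110, 200))
  set.seed(9)
  for (i in 1:3) {
    codes <- sample(c(0L, 1L, 2L, 3L, 4L, 100L, 101L), 121, replace = TRUE)
    lat <- lattice_from_codes(codes, 11, p2$allowed_a)
    expect_equal(antibiotic_field(lat, 10), brute_force_field(lat, 10))
  }
})

test_that("kernel antibiotic coupling agrees with the R field", {
  # a sensitive cell surrounded by producers has birth probability
  # max(0, r2 - A_loc)*dt; verify through event counts with death disabled
  p <- model_params(L = 8, allowed_a = c(0, 150), v = 1e-9, seed = 1)
  codes <- rep(0L, 64)
  centre <- 3 * 8 + 4
  codes[centre + 1] <- 100L
  for (d in c(-9, -8, -7, -1, 1, 7, 8, 9)) codes[centre + d + 1] <- 2L
  lat <- lattice_from_codes(codes, 8, p$allowed_a)
  # the S cell sees its 8 producer neighbours (it occupies the centre itself)
  expect_equal(max(antibiotic_field(lat, p$b)), 150 * 8 / 90)
  # r_S = 2.5 - 13.3 < 0 so the S cell must never reproduce
  res <- sweep_lattice(lat, p, n_sweeps = 200, sweep_rng(4))
  expect_identical(res$counts[100 + 1], 1L)           # still exactly one S
})

test_that("identical seed and config give bit-identical runs", {
  p <- base_params(L = 48, seed = 5)
  comp <- pns_comp(150)
  r1 <- run_lattice(p, comp, t_end = 30)
  r2 <- run_lattice(p, comp, t_end = 30)
  expect_identical(r1$series, r2$series)
  expect_identical(r1$final$cells, r2$final$cells)
  r3 <- run_lattice(p, comp, t_end = 30, seed = 6)
  expect_false(identical(r1$final$cells, r3$final$cells))
})

test_that("fractions are conserved and bounded through a run", {
  p <- base_params(L = 48, seed = 2)
  r <- run_lattice(p, pns_comp(150), t_end = 50)
  sums <- rowSums(r$series[, -1])
  expect_true(all(abs(sums - 1) < 1e-12))
  expect_true(all(r$series[, -1] >= 0 & r$series[, -1] <= 1))
  # with u = 0 no new strain can appear: R column must stay 0
  expect_true(all(r$series$R == 0))
})

test_that("occupancy changes only through recorded birth and death events", {
  p <- base_params(L = 48, seed = 13)
  lat <- initialize_lattice(p, pns_comp(150), seed = 13)
  n_before <- sum(as.integer(lat$cells) > 0)
  res <- sweep_lattice(lat, p, n_sweeps = 500, sweep_rng(13))
  n_after <- sum(res$counts[-1])
  expect_identical(n_after - n_before, as.integer(res$births - res$deaths))
})

test_that("single-type absorbing states persist", {
  p <- base_params(L = 32, seed = 8)
  latS <- initialize_lattice(p, lattice_composition(S = 0.4))
  res <- sweep_lattice(latS, p, n_sweeps = 2000, sweep_rng(8))
  cnt <- res$counts
  expect_identical(sum(cnt[-1] > 0), 1L)   # only one type left besides vacancy
  expect_gt(cnt[100 + 1], 0)               # and it is S
  # the run driver stops immediately on a single-type start with u = 0
  r <- run_lattice(p, lattice_composition(S = 0.4), t_end = 500)
  expect_true(r$stopped_early)
  expect_identical(classify_outcome(r)$label, "S_only")
})

test_that("with no births, occupancy decays as pure death at rate v", {
  # r*dt ~ 0: the lattice is a set of independent exponential clocks
  p <- model_params(L = 96, r1 = 1e-9, r2 = 1e-9, seed = 10,
                    allowed_a = c(0, 150))
  lat <- initialize_lattice(p, lattice_composition(S = 0.9))
  n0 <- sum(as.integer(lat$cells) > 0)
  t_run <- 2
  res <- sweep_lattice(lat, p, n_sweeps = t_run / p$dt, sweep_rng(10))
  expected <- n0 * exp(-p$v * t_run)
  observed <- sum(res$counts[-1])
  expect_lt(abs(observed - expected), 4 * sqrt(expected))
})

test_that("birth and death probabilities match r*dt and v*dt", {
  # single S cell, r2 = 2.5, v = 1, dt = 0.01: birth w.p. 0.025, death 0.01
  p <- model_params(L = 8, allowed_a = c(0, 150), seed = 1)
  codes <- rep(0L, 64); codes[28] <- 100L
  lat <- lattice_from_codes(codes, 8, p$allowed_a)
  nb <- nd <- 0L
  n_rep <- 4000
  for (i in seq_len(n_rep)) {
    res <- sweep_lattice(lat, p, 1L, sweep_rng(i))
    nb <- nb + as.integer(res$births)
    nd <- nd + as.integer(res$deaths)
  }
  expect_lt(abs(nb / n_rep - 0.025), 4 * sqrt(0.025 * 0.975 / n_rep))
  expect_lt(abs(nd / n_rep - 0.010), 4 * sqrt(0.010 * 0.990 / n_rep))
})

test_that("mutation redraws production rates uniformly over the active set", {
  # u = 0: offspring always identical
  p0 <- base_params(allowed_a = c(0, 110), u = 0)
  set.seed(1)
  expect_true(all(replicate(50, mutate_offspring("P110", p0)) == "P110"))
  expect_error(mutate_offspring("vacant", p0), "contract violation")
  # u = 1, two strains: deterministic P <-> N flip
  p1 <- base_params(allowed_a = c(0, 110), u = 1)
  set.seed(2)
  expect_true(all(replicate(20, mutate_offspring("P110", p1)) == "N"))
  expect_true(all(replicate(20, mutate_offspring("N", p1)) == "P110"))
  # u = 1, 21 strains: uniform over the 20 other values
  p21 <- base_params(allowed_a = seq(0, 200, 10), u = 1)
  set.seed(3)
  draws <- replicate(4000, mutate_offspring("P110", p21))
  expect_false(any(draws == "P110"))
  freq <- table(draws) / length(draws)
  expect_identical(length(freq), 20L)
  expect_true(all(abs(freq - 1 / 20) < 4 * sqrt(0.05 * 0.95 / 4000)))
  # species is never changed; S <-> R only when enabled
  expect_true(all(replicate(50, mutate_offspring("S", p21)) == "S"))
  pR <- base_params(allowed_a = c(0, 110), u = 1, mutate_resistance = TRUE)
  set.seed(4)
  expect_true(all(replicate(20, mutate_offspring("S", pR)) == "R"))
  expect_true(all(replicate(20, mutate_offspring("R", pR)) == "S"))
})

test_that("kernel mutation creates the expected strain flow", {
  # P <-> N flip at u = 1e-2 on a producer-only lattice: N appears quickly
  p <- model_params(L = 32, allowed_a = c(0, 150), u = 1e-2, seed = 6)
  lat <- initialize_lattice(p, lattice_composition(P150 = 0.3))
  res <- sweep_lattice(lat, p, n_sweeps = 2000, sweep_rng(6))
  expect_gt(res$counts[1 + 1], 0)    # code 1 = non-producer
  # resistance mutation disabled: R never appears from S
  expect_identical(res$counts[101 + 1], 0L)
})

test_that("species-1 and species-2 labels are exchangeable in the neutral model", {
  # a = 0 for all producers, c_R = 0, r1 = r2: the two species differ only
  # by label, so their occupancy fractions have the same distribution
  p <- model_params(L = 32, r1 = 2, r2 = 2, allowed_a = 0, seed = 1)
  f1 <- f2 <- numeric(16)
  for (i in seq_len(16)) {
    r <- run_lattice(p, lattice_composition(N = 0.2, S = 0.2), t_end = 25,
                     seed = 100 + i)
    last <- r$series[nrow(r$series), ]
    f1[i] <- last$N; f2[i] <- last$S
  }
  ks <- suppressWarnings(stats::ks.test(f1, f2))
  expect_gt(ks$p.value, 0.01)
})

test_that("snapshots round-trip bit-exactly", {
  p <- base_params(L = 16, allowed_a = c(0, 50, 110))
  lat <- initialize_lattice(p, lattice_composition(P110 = .1, P50 = .1,
                                                   N = .1, S = .1, R = .1))
  path <- withr::local_tempfile(fileext = ".txt")
  write_snapshot(lat, path, time = 123.5, seed = 42L)
  snap <- read_snapshot(path)
  expect_identical(snap$lattice$cells, lat$cells)
  expect_identical(snap$lattice$side, lat$side)
  expect_identical(snap$lattice$allowed_a, lat$allowed_a)
  expect_identical(snap$time, 123.5)
  expect_identical(snap$seed, 42L)
  # PPM render: valid plain-text header, one pixel per site
  ppm <- withr::local_tempfile(fileext = ".ppm")
  render_snapshot(lat, ppm)
  lines <- readLines(ppm)
  expect_identical(lines[1], "P3")
  expect_identical(lines[2], "16 16")
})
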