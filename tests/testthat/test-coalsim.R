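tree_height <- function(phy) max(ape::node.depth.edgelength(phy))

test_that("no recombination yields exactly one genealogy segment", {
  spec <- scenario_spec(N_e = 500, pair_ages = 1000, samples_per_species = 3,
                        seq_length_bp = 5000, mu = 0, rec = 0)
  segs <- simulate_pair(spec, 1000, seed = 1)
  expect_equal(nrow(segs), 1)
  expect_equal(segs$start_bp, 0)
  expect_equal(segs$end_bp, 5000)
  phy <- segs$tree[[1]]
  expect_equal(length(phy$tip.label), 6)
  expect_true(all(phy$edge.length >= 0))
})

test_that("segments partition the sequence and trees have all tips", {
  spec <- scenario_spec(N_e = 500, pair_ages = 2000, samples_per_species = 4,
                        seq_length_bp = 10000, mu = 0, rec = 5e-6)
  segs <- simulate_pair(spec, 2000, seed = 2)
  expect_gt(nrow(segs), 1)
  expect_equal(segs$start_bp[1], 0)
  expect_equal(segs$end_bp[nrow(segs)], 10000)
  expect_equal(segs$start_bp[-1], segs$end_bp[-nrow(segs)])
  expect_true(all(vapply(segs$tree, function(p)
    length(p$tip.label) == 8 && all(p$edge.length >= -1e-9), logical(1))))
})

test_that("simulation is deterministic given (spec, seed) and varies by seed", {
  spec <- scenario_spec(N_e = 300, pair_ages = c(600, 1200),
                        samples_per_species = 3, seq_length_bp = 2000,
                        mu = 1e-5, rec = 1e-6)
  a1 <- simulate_pair_alignment(spec, 600, seed = 11)
  a2 <- simulate_pair_alignment(spec, 600, seed = 11)
  expect_identical(a1, a2)
  r1 <- simulate_replicate(spec, seed = 5)
  r2 <- simulate_replicate(spec, seed = 5)
  expect_identical(r1, r2)
  # different seeds give a different first tree with probability ~ 1
  diff <- vapply(1:10, function(i) {
    s1 <- simulate_pair(spec, 600, seed = i)
    s2 <- simulate_pair(spec, 600, seed = i + 1000)
    !isTRUE(all.equal(s1$tree[[1]], s2$tree[[1]]))
  }, logical(1))
  expect_true(all(diff))
})

test_that("a replicate maps every pair age", {
  spec <- scenario_spec(N_e = 100, samples_per_species = 2,
                        seq_length_bp = 500, mu = 1e-5, rec = 0)
  rep <- simulate_replicate(spec, seed = 3)
  expect_equal(nrow(rep), 8)
  expect_equal(rep$pair_age, seq(2, 16, 2) * 100)
  expect_error(simulate_pair(spec, 12345, seed = 1), "pair_ages")
})

test_that("panmictic limit: mean pairwise coalescence approaches 2N", {
  # pair_age -> 0: one deme; mean TMRCA of two lineages = 2N generations
  spec <- scenario_spec(N_e = 1000, pair_ages = 1e-9,
                        samples_per_species = 1, seq_length_bp = 100,
                        mu = 0, rec = 0)
  h <- vapply(1:800, function(i)
    tree_height(simulate_pair(spec, 1e-9, seed = i)$tree[[1]]),
    numeric(1))
  expect_equal(mean(h), 2000, tolerance = 3 * sd(h) / sqrt(800) / 2000)
})

test_that("isolation model: cross-species coalescence averages T + 2N", {
  N <- 1000; T <- 4000
  spec <- scenario_spec(N_e = N, pair_ages = T, samples_per_species = 1,
                        seq_length_bp = 100, mu = 0, rec = 0)
  h <- vapply(1:1000, function(i)
    tree_height(simulate_pair(spec, T, seed = i)$tree[[1]]), numeric(1))
  expect_equal(mean(h), T + 2 * N,
               tolerance = 3 * sd(h) / sqrt(1000) / (T + 2 * N))
})

test_that("pairwise TMRCA distribution matches an independent oracle (KS)", {
  # 2+2 samples, no recombination, with a recent migration epoch
  N <- 500; T <- 3000
  spec <- scenario_spec(N_e = N, pair_ages = T, samples_per_species = 2,
                        seq_length_bp = 100, mu = 0, rec = 0,
                        gene_flow_mode = "recent", migration_4Nm = 1)
  n_sim <- 1500
  ours <- vapply(seq_len(n_sim), function(i)
    tree_height(simulate_pair(spec, T, seed = i)$tree[[1]]), numeric(1))
  set.seed(42)
  theirs <- replicate(n_sim,
    oracle_tmrca(2, 2, N, T, m_epoch = c(0, 2 * N), m1 = 1 / (4 * N)))
  expect_gt(stats::ks.test(ours, theirs)$p.value, 0.01)
})

test_that("d_xy grows as 2 mu T + 4 N mu without gene flow", {
  N <- 500; mu <- 2e-5; L <- 20000
  spec <- scenario_spec(N_e = N, pair_ages = c(2, 6, 10) * N,
                        samples_per_species = 2, seq_length_bp = L,
                        mu = mu, rec = 1e-5)
  obs <- vapply(c(2, 6, 10) * N, function(T) {
    mean(vapply(1:8, function(i)
      dxy(simulate_pair_alignment(spec, T, seed = 100 * T + i)),
      numeric(1)))
  }, numeric(1))
  # JC correction: observed p-distance slightly below expected divergence
  raw <- 2 * mu * c(2, 6, 10) * N + 4 * N * mu
  expected <- 0.75 * (1 - exp(-4 * raw / 3))
  expect_equal(obs, expected, tolerance = 0.08)
  # linearity of the underlying divergence in T
  d <- diff(-0.75 * log(1 - 4 * obs / 3))  # invert JC
  expect_equal(d[1], d[2], tolerance = 0.15)
})

test_that("downstream statistics are invariant to coalescent rescaling", {
  # c = 10 rescaling: N/10, rates x10, ages/10 — compare segregating sites
  # and global F_ST distributions of the two parameterisations
  base <- scenario_spec(N_e = 2000, pair_ages = 8000,
                        samples_per_species = 5, seq_length_bp = 10000,
                        mu = 2.5e-6, rec = 5e-6)
  scaled <- scale_scenario(base, 10)
  stat <- function(spec, seeds) {
    vapply(seeds, function(i) {
      a <- simulate_pair_alignment(spec, spec$pair_ages, seed = i)
      attr(window_table(a, 500, spec$pair_ages), "global_fst")
    }, numeric(1))
  }
  f1 <- stat(base, 1:60)
  f2 <- stat(scaled, 61:120)
  expect_gt(stats::ks.test(f1, f2)$p.value, 0.01)
})

test_that("high sustained recent gene flow pins F_ST to a plateau", {
  # recent gene flow 4Nm = 10: differentiation stays flat in T
  N <- 1000
  spec <- scenario_spec(N_e = N, pair_ages = c(4, 16) * N,
                        samples_per_species = 5, seq_length_bp = 10000,
                        mu = 5e-6, rec = 1e-5,
                        gene_flow_mode = "recent", migration_4Nm = 10)
  gf <- function(T) mean(vapply(1:15, function(i) {
    a <- simulate_pair_alignment(spec, T, seed = 7000 + 17 * T + i)
    attr(window_table(a, 500, T), "global_fst")
  }, numeric(1)))
  f4 <- gf(4 * N); f16 <- gf(16 * N)
  expect_lt(abs(f16 - f4), 0.1)
  expect_lt(f16, 0.5)
})
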