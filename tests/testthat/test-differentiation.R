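# Weir-Cockerham components, theta estimators, gene flow transform.

test_that("theta is 1 on fixed differences and near 0 on identical populations", {
  fx <- fixed_difference_dataset(n = 10, L = 3)
  g <- fst_global(wc_components(allele_frequencies(fx)))
  expect_equal(g$theta, 1)
  expect_equal(g$percent_among, 100)
  expect_equal(g$percent_among + g$percent_within, 100)

  # the same genotype list duplicated into two populations
  set.seed(2)
  half <- random_dataset(n_per_pop = 50, L = 5, seed = 2)
  ds <- genotype_dataset(rbind(half$a1, half$a1), rbind(half$a2, half$a2),
                         pop = rep(c("A", "B"), each = 50),
                         individuals = sprintf("i%d", 1:100))
  th <- fst_global(wc_components(allele_frequencies(ds)))$theta
  expect_lt(abs(th), 0.02)
  expect_lte(th, 0)   # duplicated samples: no among-population variance
})

test_that("components match the hand-evaluated 2-population, 1-locus case", {
  # pop1: 8 x A1A1 + 2 x A1A2 ; pop2: 3 x A1A1 + 7 x A2A2
  a1 <- c(rep(1L, 10), rep(1L, 3), rep(2L, 7))
  a2 <- c(rep(1L, 8), rep(2L, 2), rep(1L, 3), rep(2L, 7))
  ds <- genotype_dataset(matrix(a1), matrix(a2),
                         pop = rep(c("p1", "p2"), each = 10))
  comp <- wc_components(allele_frequencies(ds))
  # hand evaluation: nbar = 10, nc = 10, pbar = 0.6, s2 = 0.18, hbar = 0.1
  # a = 0.18 - (0.24 - 0.09 - 0.025)/9 ; b = (10/9)(0.15 - 0.0475) ; c = 0.05
  expect_equal(comp$a[comp$allele == 1], 0.18 - 0.125 / 9, tolerance = 1e-12)
  expect_equal(comp$b[comp$allele == 1], (10 / 9) * 0.1025, tolerance = 1e-12)
  expect_equal(comp$c[comp$allele == 1], 0.05, tolerance = 1e-12)
  th <- fst_global(comp)$theta
  expect_equal(th, sum(comp$a) / sum(comp$a + comp$b + comp$c),
               tolerance = 1e-12)
})

test_that("theta is invariant to allele relabeling and population order", {
  ds <- random_dataset(n_per_pop = c(8, 8, 8), L = 4, seed = 9)
  th1 <- fst_global(wc_components(allele_frequencies(ds)))$theta
  # relabel alleles (order-preserving shift) and reverse population order
  ds2 <- genotype_dataset(ds$a1 + 50L, ds$a2 + 50L,
                          pop = as.character(ds$pop), loci = ds$loci)
  rev_idx <- rev(seq_len(n_individuals(ds)))
  ds3 <- genotype_dataset(ds$a1[rev_idx, ], ds$a2[rev_idx, ],
                          pop = as.character(ds$pop)[rev_idx],
                          individuals = ds$individuals[rev_idx],
                          loci = ds$loci)
  expect_equal(fst_global(wc_components(allele_frequencies(ds2)))$theta, th1)
  expect_equal(fst_global(wc_components(allele_frequencies(ds3)))$theta, th1)
})

test_that("pairwise theta equals the two-population component computation", {
  ds <- random_dataset(n_per_pop = c(10, 10, 10), L = 5, seed = 4)
  freqs <- allele_frequencies(ds)
  m <- fst_pairwise(freqs)
  expect_equal(unclass(m), t(unclass(m)))
  expect_equal(diag(unclass(m)), setNames(rep(0, 3), freqs$pops))
  for (pair in list(c(1, 2), c(1, 3), c(2, 3))) {
    th <- fst_global(wc_components(freqs, freqs$pops[pair]))$theta
    expect_equal(m[pair[1], pair[2]], th)
  }
  # complete fixation
  expect_equal(fst_pairwise(allele_frequencies(
    fixed_difference_dataset()))["A", "B"], 1)
})

test_that("island-model gene flow transform follows (1 - F)/(4 F)", {
  expect_equal(nm_from_fst(0.25), 0.75)
  expect_equal(nm_from_fst(1), 0)
  expect_equal(nm_from_fst(0.005), 49.75)
  expect_warning(res <- nm_from_fst(-0.01), "non-positive")
  expect_equal(res, Inf)
  m <- pairwise_matrix(matrix(c(0, 0.25, 0.25, 0), 2,
                              dimnames = list(c("A", "B"), c("A", "B"))),
                       statistic = "FST")
  nm <- nm_from_fst(m)
  expect_equal(nm["A", "B"], 0.75)
  expect_true(is.na(nm["A", "A"]))
})

test_that("pairwise theta decreases with migration rate on island simulations", {
  # expectation over replicates: theta(m = 0) > theta(m = 0.01) > theta(m = 0.1)
  mean_theta <- function(m) {
    vals <- sapply(1:5, function(s) {
      cfg <- sim_config(split_node(150, leaf_pop("A"), leaf_pop("B")),
                        N_e = 60L, beta = 5e-3, L = 8L, sample_sizes = 30L,
                        migration = m, burnin = 300L, seed = 100L + s)
      fst_pairwise(allele_frequencies(simulate_smm(cfg)))["A", "B"]
    })
    mean(vals)
  }
  th <- c(mean_theta(0), mean_theta(0.02), mean_theta(0.4))
  expect_true(all(diff(th) < 0))
  expect_lt(th[3], 0.05)   # near panmixia at high migration (Nm = 24)
})

test_that("leave-group-out recomputation changes the global theta", {
  ds <- random_dataset(n_per_pop = c(10, 10, 10), L = 4, seed = 21)
  # make pop3 strongly divergent
  idx <- ds$pop == "pop3"
  ds$a1[idx, ] <- ds$a1[idx, ] + 40L
  ds$a2[idx, ] <- ds$a2[idx, ] + 40L
  ds <- genotype_dataset(ds$a1, ds$a2, pop = as.character(ds$pop),
                         individuals = ds$individuals, loci = ds$loci)
  res <- fst_leave_group_out(allele_frequencies(ds), drop = "pop3")
  expect_false(isTRUE(all.equal(res$full$theta, res$reduced$theta)))
  expect_lt(res$reduced$theta, res$full$theta)
})

test_that("permutation test calls strong differentiation significant", {
  ds <- fixed_difference_dataset(n = 8, L = 3)
  res <- fst_permutation_test(ds, n_perm = 49, seed = 3)
  expect_lt(res$p_value["A", "B"], 0.05)
  expect_equal(res$fst["A", "B"], 1)
})
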