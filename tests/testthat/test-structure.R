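# Admixture-model Gibbs sampler, Evanno Delta-K, and label alignment.

test_that("K = 1 gives unit ancestry and the conjugate posterior mean for P", {
  ds <- random_dataset(n_per_pop = 15, L = 3, seed = 41)
  lambda <- 1.0
  run <- admixture_gibbs(ds, K = 1, lambda = lambda, burn_in = 100,
                         iterations = 1100, thin = 2, seed = 5)
  expect_true(all(run$Q == 1))
  # with K = 1 the allele counts are fixed, so P sweeps are iid
  # Dirichlet(lambda + counts) draws: posterior mean is closed-form
  freqs <- allele_frequencies(genotype_dataset(
    ds$a1, ds$a2, pop = rep("all", 15), individuals = ds$individuals,
    loci = ds$loci))
  n_rec <- length(run$lnL_trace)
  for (l in 1:3) {
    counts <- colSums(freqs$tables[[l]]$counts)
    A <- length(counts); tot <- sum(counts) + A * lambda
    m <- (counts + lambda) / tot
    se <- sqrt(m * (1 - m) / (tot + 1)) / sqrt(n_rec)
    expect_true(all(abs(run$P[[l]][1, ] - m) < 3 * se + 1e-8))
  }
})

test_that("disjoint two-cluster structure is recovered for every individual", {
  sim <- simulate_admixture(K = 2, sample_sizes = 50, L = 10, alpha = 0,
                            profiles = "disjoint", n_alleles = 3, seed = 5)
  run <- admixture_gibbs(sim$dataset, K = 2, alpha = 0.1, burn_in = 300,
                         iterations = 1300, thin = 5, seed = 9)
  truth <- structure(list(K = 2L, Q = sim$Q,
                          P = replicate(10, matrix(0.5, 2, 2),
                                        simplify = FALSE)),
                     class = "cluster_run")
  al <- align_runs(truth, run)
  own <- al$Q[cbind(seq_len(100), rep(1:2, each = 50))]
  expect_true(all(own >= 0.95))
  expect_lte(mean(abs(al$Q - sim$Q)), 0.05)
})

test_that("the sampler is deterministic under a fixed seed", {
  ds <- random_dataset(n_per_pop = c(8, 8), L = 4, seed = 2)
  r1 <- admixture_gibbs(ds, K = 2, burn_in = 50, iterations = 150, seed = 77)
  r2 <- admixture_gibbs(ds, K = 2, burn_in = 50, iterations = 150, seed = 77)
  expect_identical(r1$Q, r2$Q)
  expect_identical(r1$lnL_trace, r2$lnL_trace)
})

test_that("recorded ancestry and frequency estimates are simplex-valid", {
  ds <- random_dataset(n_per_pop = c(10, 10), L = 3, miss_rate = 0.1, seed = 6)
  run <- admixture_gibbs(ds, K = 3, burn_in = 100, iterations = 400, seed = 3)
  expect_equal(unname(rowSums(run$Q)), rep(1, 20), tolerance = 1e-9)
  for (p in run$P) expect_equal(rowSums(p), rep(1, 3), tolerance = 1e-9)
  expect_true(is.finite(run$L_hat))
})

test_that("Evanno table matches hand arithmetic and flags degenerate SD", {
  fake <- function(K, L) structure(list(K = as.integer(K), L_hat = L),
                                   class = "cluster_run")
  means <- c(-5000, -4000, -3900, -3890)
  runs <- list()
  for (i in seq_along(means))
    for (d in c(-10, 0, 10))     # mean = means[i], sd = 10
      runs[[length(runs) + 1]] <- fake(i, means[i] + d)
  ev <- evanno_delta_k(runs)
  expect_equal(ev$ddL[ev$K == 2], 900)      # |100 - 1000|
  expect_equal(ev$delta_K[ev$K == 2], 90)
  expect_equal(attr(ev, "selected_K"), 2)
  expect_true(is.na(ev$delta_K[ev$K == 1]) && is.na(ev$delta_K[ev$K == 4]))

  # L linear in K: no curvature anywhere
  lin <- list()
  for (i in 1:4) for (d in c(-1, 0, 1))
    lin[[length(lin) + 1]] <- fake(i, -1000 + 50 * i + d)
  evl <- evanno_delta_k(lin)
  expect_true(all(abs(evl$ddL[c(2, 3)]) < 1e-9))

  # zero SD: delta-K undefined there
  z <- list()
  for (i in 1:3) for (r in 1:3) z[[length(z) + 1]] <- fake(i, -100 * i)
  expect_true(is.na(evanno_delta_k(z)$delta_K[2]))
  expect_error(evanno_delta_k(list(fake(1, -1), fake(3, -2))), "consecutive")
})

test_that("Evanno Delta-K selects the generating K on a 3-cluster fixture", {
  sim <- simulate_admixture(K = 3, sample_sizes = 25, L = 12, alpha = 0.02,
                            profiles = "disjoint", n_alleles = 3, seed = 8)
  runs <- list()
  for (K in 1:5) for (r in 1:5)
    runs[[length(runs) + 1]] <- admixture_gibbs(
      sim$dataset, K, alpha = 0.1, burn_in = 200, iterations = 700,
      thin = 5, seed = 1000L + K * 10L + r)
  ev <- evanno_delta_k(runs)
  expect_equal(attr(ev, "selected_K"), 3)
})

test_that("label alignment recovers permutations and matches the exhaustive optimum", {
  ds <- random_dataset(n_per_pop = c(10, 10), L = 4, seed = 19)
  run <- admixture_gibbs(ds, K = 3, burn_in = 50, iterations = 250, seed = 4)
  # identity
  self <- align_runs(run, run)
  expect_equal(attr(self, "perm"), 1:3)
  # column swap is undone
  sw <- run; sw$Q <- run$Q[, c(2, 3, 1)]; sw$P <- lapply(run$P, function(p) p[c(2, 3, 1), ])
  al <- align_runs(run, sw)
  expect_equal(al$Q, run$Q)
  # exhaustive oracle on random Q pairs, K <= 4
  set.seed(23)
  for (rep in 1:10) {
    K <- sample(2:4, 1)
    qa <- t(replicate(12, rdirichlet_test(K)))
    qb <- t(replicate(12, rdirichlet_test(K)))
    ra <- structure(list(K = K, Q = qa, P = list()), class = "cluster_run")
    rb <- structure(list(K = K, Q = qb, P = list()), class = "cluster_run")
    got <- align_runs(ra, rb)
    best <- -Inf
    perms <- msatpop:::.permutations(K)
    for (r in seq_len(nrow(perms)))
      best <- max(best, sum(qa * qb[, perms[r, ]]))
    expect_equal(sum(qa * got$Q), best, tolerance = 1e-12)
    expect_gte(sum(qa * got$Q), sum(qa * qb) - 1e-12)  # never worse
  }
  # K mismatch errors
  r2 <- admixture_gibbs(ds, K = 2, burn_in = 20, iterations = 60, seed = 1)
  expect_error(align_runs(run, r2), "K mismatch")
})

test_that("Q-matrix export is population-ordered with simplex rows", {
  ds <- random_dataset(n_per_pop = c(5, 5), L = 3, seed = 3)
  run <- admixture_gibbs(ds, K = 2, burn_in = 20, iterations = 120, seed = 2)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_q_matrix(run, path)
  tab <- read.delim(path)
  expect_equal(names(tab), c("individual", "population", "q_1", "q_2"))
  expect_equal(tab$population, sort(tab$population))
  expect_equal(unname(rowSums(tab[, 3:4])), rep(1, 10), tolerance = 1e-6)
})
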