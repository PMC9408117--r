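# The Wright-Fisher SMM simulator and the admixture-model generator.

test_that("no mutation and a single population stays fixed at the founder", {
  cfg <- sim_config(leaf_pop("A"), N_e = 20L, beta = 0, L = 3L,
                    founder_allele = 50L, sample_sizes = 10L, burnin = 50L,
                    seed = 2)
  ds <- simulate_smm(cfg)
  expect_true(all(ds$a1 == 50L) && all(ds$a2 == 50L))
})

test_that("simulation is bit-reproducible under a fixed seed", {
  tree <- split_node(50, leaf_pop("A"), leaf_pop("B"))
  cfg <- sim_config(tree, N_e = 30L, beta = 5e-3, L = 5L, sample_sizes = 15L,
                    burnin = 100L, seed = 11)
  d1 <- simulate_smm(cfg); d2 <- simulate_smm(cfg)
  expect_identical(d1$a1, d2$a1)
  expect_identical(d1$a2, d2$a2)
})

test_that("per-lineage mutation counts behave as Binomial(t, beta)", {
  # drive the mutation kernel directly over independent lineages
  set.seed(6)
  t_gen <- 50; beta <- 0.02; n_lineage <- 1500
  M <- matrix(1000L, n_lineage, 1)
  changes <- 0
  for (g in seq_len(t_gen)) {
    M2 <- msatpop:::smm_mutate(M, beta)
    changes <- changes + sum(M2 != M)
    M <- M2
  }
  # mean mutation events per lineage vs Binomial mean t*beta, 3 SE band
  expected <- t_gen * beta
  se <- sqrt(t_gen * beta * (1 - beta) / n_lineage)
  expect_lt(abs(changes / n_lineage - expected), 3 * se)
})

test_that("heterozygosity decays by about 1 - 1/(2N) per generation under drift", {
  # polymorphic founders, no mutation: E[He_t] = He_0 (1 - 1/(2N))^t
  set.seed(14)
  N <- 30L; t_gen <- 60
  ratios <- replicate(40, {
    M <- matrix(sample(95:104, 2 * N * 5, TRUE), 2 * N, 5)
    h0 <- mean(apply(M, 2, function(x) 1 - sum((table(x) / length(x))^2)))
    for (g in seq_len(t_gen)) M <- msatpop:::.wf_generation(M, 0)
    h1 <- mean(apply(M, 2, function(x) 1 - sum((table(x) / length(x))^2)))
    h1 / h0
  })
  expect_equal(mean(ratios), (1 - 1 / (2 * N))^t_gen, tolerance = 0.08)
})

test_that("pairwise F_ST grows with divergence time without migration", {
  mean_theta <- function(tau) {
    vals <- sapply(1:4, function(s) {
      cfg <- sim_config(split_node(tau, leaf_pop("A"), leaf_pop("B")),
                        N_e = 50L, beta = 5e-3, L = 10L, sample_sizes = 25L,
                        burnin = 250L, seed = 500L + s)
      fst_pairwise(allele_frequencies(simulate_smm(cfg)))["A", "B"]
    })
    mean(vals)
  }
  th <- c(mean_theta(5), mean_theta(50), mean_theta(250))
  expect_true(all(diff(th) > 0))
})

test_that("reflecting size bounds keep the allele walk inside the window", {
  cfg <- sim_config(leaf_pop("A"), N_e = 30L, beta = 0.05, L = 4L,
                    founder_allele = 100L, sample_sizes = 20L, burnin = 400L,
                    size_bounds = cbind(rep(95, 4), rep(105, 4)), seed = 21)
  ds <- simulate_smm(cfg)
  expect_true(all(ds$a1 >= 95 & ds$a2 <= 105))
})

test_that("a YAML config builds the same sim_config as the programmatic call", {
  path <- withr::local_tempfile(fileext = ".yaml")
  writeLines(c(
    "split_tree:",
    "  time: 80",
    "  left: {name: A}",
    "  right:",
    "    time: 40",
    "    left: {name: B}",
    "    right: {name: C}",
    "N_e: 40",
    "beta: 0.002",
    "L: 6",
    "burnin: 100",
    "seed: 13",
    "sample_sizes: {A: 10, B: 12, C: 8}"), path)
  cfg <- read_sim_config(path)
  ref <- sim_config(split_node(80, leaf_pop("A"),
                               split_node(40, leaf_pop("B"), leaf_pop("C"))),
                    N_e = 40L, beta = 0.002, L = 6L, burnin = 100L,
                    seed = 13L, sample_sizes = c(A = 10L, B = 12L, C = 8L))
  expect_equal(cfg$sample_sizes, ref$sample_sizes)
  expect_equal(cfg$beta, ref$beta)
  expect_identical(simulate_smm(cfg)$a1, simulate_smm(ref)$a1)
})

test_that("tree validation rejects non-decreasing split times", {
  expect_error(sim_config(split_node(100, leaf_pop("A"),
                                     split_node(150, leaf_pop("B"),
                                                leaf_pop("C")))),
               "strictly decrease")
  expect_error(sim_config(split_node(100, leaf_pop("A"), leaf_pop("B")),
                          N_e = 10L, sample_sizes = 50L),
               "exceed N_e")
})

test_that("admixture generator honours purity, K = 1, and profiles", {
  # alpha -> 0: near-pure individuals
  sim <- simulate_admixture(K = 2, sample_sizes = 20, L = 5, alpha = 0.01,
                            seed = 31)
  expect_gte(mean(apply(sim$Q, 1, max)), 0.99)
  expect_equal(rowSums(sim$Q), rep(1, 40), tolerance = 1e-12)
  # group labels match the dominant component
  grp <- as.integer(factor(as.character(sim$dataset$pop),
                           paste0("cluster_", 1:2)))
  expect_equal(unname(apply(sim$Q, 1, which.max)), grp)
  # K = 1: all Q = 1
  s1 <- simulate_admixture(K = 1, sample_sizes = 10, L = 3, seed = 2)
  expect_true(all(s1$Q == 1))
  # disjoint profiles keep cluster allele sets disjoint
  sd2 <- simulate_admixture(K = 2, sample_sizes = 15, L = 4, alpha = 0.01,
                            profiles = "disjoint", n_alleles = 3, seed = 7)
  pop1 <- sd2$dataset$pop == "cluster_1"
  a_1 <- unique(c(sd2$dataset$a1[pop1, ], sd2$dataset$a2[pop1, ]))
  a_2 <- unique(c(sd2$dataset$a1[!pop1, ], sd2$dataset$a2[!pop1, ]))
  expect_length(intersect(a_1, a_2), 0)
})

test_that("the study-shaped fixture matches the published panel shape", {
  ds <- make_study_fixture(seed = 1)
  expect_equal(n_individuals(ds), 975)
  expect_equal(n_populations(ds), 11)
  expect_equal(n_loci(ds), 17)
  expect_equal(sort(as.integer(table(as.character(ds$pop)))),
               sort(c(64L, 41L, 30L, 28L, 45L, 41L, 250L, 186L, 118L, 141L,
                      31L)))
  # alleles inside the published windows
  for (l in seq_len(17)) {
    expect_true(all(ds$a1[, l] >= ds$loci$size_min[l] &
                    ds$a2[, l] <= ds$loci$size_max[l]))
  }
  # pooled allele counts in a plausible band around the published 16-38
  tna <- sapply(allele_frequencies(ds)$tables,
                function(tb) sum(colSums(tb$counts) > 0))
  expect_gte(sum(tna >= 10 & tna <= 45), 15)
  # determinism
  ds2 <- make_study_fixture(seed = 1)
  expect_identical(ds$a1, ds2$a1)
})
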