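# Coancestry, Nei's Ds, (delta-mu)^2, and the locus bootstrap.

test_that("coancestry matches direct arithmetic and its bounds", {
  # one locus, 4 equifrequent alleles: within-population identity 0.25
  f <- matrix(0.25, 2, 4, dimnames = list(c("X", "Y"), 100:103))
  fij <- coancestry_fij(exact_freqs(list(f)))
  expect_equal(fij["X", "X"], 0.25)
  # p_X = (0.8, 0.2), p_Y = (0.5, 0.5): f = 0.8*0.5 + 0.2*0.5 = 0.5
  f2 <- rbind(X = c(0.8, 0.2), Y = c(0.5, 0.5))
  colnames(f2) <- c("100", "102")
  fij2 <- coancestry_fij(exact_freqs(list(f2)))
  expect_equal(fij2["X", "Y"], 0.5)
  # disjoint allele sets: f = 0
  f3 <- rbind(X = c(1, 0, 0, 0), Y = c(0, 0, 0.5, 0.5))
  colnames(f3) <- 100:103
  expect_equal(coancestry_fij(exact_freqs(list(f3)))["X", "Y"], 0)
  # Cauchy-Schwarz: f_ii >= f_ij when both populations share a profile
  set.seed(8)
  for (rep in 1:10) {
    p <- rdirichlet_test(4); q <- rdirichlet_test(4)
    fm <- rbind(X = p, Y = q); colnames(fm) <- 100:103
    m <- coancestry_fij(exact_freqs(list(fm)))
    expect_gte(sqrt(m["X", "X"] * m["Y", "Y"]), m["X", "Y"] - 1e-12)
  }
})

test_that("Nei's Ds matches direct arithmetic and flags disjoint profiles", {
  # X fixed, Y equifrequent on 2 alleles: Ds = -ln(0.5/sqrt(0.5)) = 0.3466
  f <- rbind(X = c(1, 0), Y = c(0.5, 0.5)); colnames(f) <- c(100, 102)
  d <- nei_ds(exact_freqs(list(f)))
  expect_equal(d["X", "Y"], -log(0.5 / sqrt(0.5)), tolerance = 1e-12)
  expect_equal(d["X", "X"], 0)
  # identical profiles: 0
  f2 <- rbind(X = c(0.3, 0.7), Y = c(0.3, 0.7)); colnames(f2) <- c(100, 102)
  expect_equal(nei_ds(exact_freqs(list(f2)))["X", "Y"], 0)
  # disjoint allele sets: finite sentinel with warning
  f3 <- rbind(X = c(1, 0), Y = c(0, 1)); colnames(f3) <- c(100, 102)
  expect_warning(d3 <- nei_ds(exact_freqs(list(f3))), "sentinel")
  expect_gte(d3["X", "Y"], 1e8)
})

test_that("(delta-mu)^2 matches direct arithmetic on mean sizes", {
  # X fixed at size 10, Y fixed at size 12: (10 - 12)^2 = 4
  f <- rbind(X = c(1, 0), Y = c(0, 1)); colnames(f) <- c(10, 12)
  expect_equal(delta_mu2(exact_freqs(list(f)))["X", "Y"], 4)
  # two loci with mean-size gaps 1 and 3: (1 + 9)/2 = 5
  fa <- rbind(X = c(1, 0), Y = c(0, 1)); colnames(fa) <- c(10, 11)
  fb <- rbind(X = c(1, 0), Y = c(0, 1)); colnames(fb) <- c(10, 13)
  expect_equal(delta_mu2(exact_freqs(list(fa, fb)))["X", "Y"], 5)
  # identical populations: 0
  f2 <- rbind(X = c(0.5, 0.5), Y = c(0.5, 0.5)); colnames(f2) <- c(10, 12)
  expect_equal(delta_mu2(exact_freqs(list(f2)))["X", "Y"], 0)
})

test_that("size maps convert bp to repeat units and reject unmapped loci", {
  ds <- genotype_dataset(matrix(c(100L, 104L)), matrix(c(100L, 104L)),
                         pop = c("X", "Y"))
  freqs <- allele_frequencies(ds)
  # identity coding: gap (100 - 104)^2 = 16
  expect_equal(delta_mu2(freqs)["X", "Y"], 16)
  # dinucleotide in bp: (50 - 52)^2 = 4
  sizes <- allele_size_map("locus_1", offset = 0, motif_length = 2)
  expect_equal(delta_mu2(freqs, sizes)["X", "Y"], 4)
  bad <- allele_size_map("other_locus")
  expect_error(delta_mu2(freqs, bad), "no size mapping")
  # offsets must keep scores positive
  neg <- allele_size_map("locus_1", offset = 200)
  expect_error(delta_mu2(freqs, neg), "non-positive")
})

test_that("distance matrices are symmetric and invariant to population order", {
  ds <- random_dataset(n_per_pop = c(8, 8, 8), L = 4, seed = 13)
  rev_idx <- rev(seq_len(n_individuals(ds)))
  ds_rev <- genotype_dataset(ds$a1[rev_idx, ], ds$a2[rev_idx, ],
                             pop = as.character(ds$pop)[rev_idx],
                             individuals = ds$individuals[rev_idx],
                             loci = ds$loci)
  bare <- function(m) matrix(as.numeric(m), nrow(m), dimnames = dimnames(m))
  for (fn in list(nei_ds, delta_mu2, coancestry_fij)) {
    m1 <- fn(allele_frequencies(ds))
    m2 <- fn(allele_frequencies(ds_rev))
    expect_equal(unclass(m1), t(unclass(m1)))
    expect_equal(bare(m2)[rownames(m1), colnames(m1)], bare(m1))
  }
})

test_that("matrix writers round-trip CSV and emit triangle/PHYLIP layouts", {
  ds <- random_dataset(n_per_pop = c(5, 5, 5), L = 3, seed = 29)
  m <- nei_ds(allele_frequencies(ds))
  csv <- withr::local_tempfile(fileext = ".csv")
  write_pairwise_csv(m, csv)
  back <- read_pairwise_csv(csv, "Ds")
  expect_equal(unclass(back), unclass(m), tolerance = 1e-12)
  tri <- withr::local_tempfile(fileext = ".txt")
  write_pairwise_triangle(m, tri)
  lines <- readLines(tri)
  expect_length(lines, 4)                       # header + one row per pop
  expect_equal(length(strsplit(lines[4], "\t")[[1]]), 3)  # label + 2 values
  phy <- withr::local_tempfile(fileext = ".phy")
  write_pairwise_phylip(m, phy)
  expect_equal(as.integer(trimws(readLines(phy)[1])), 3)
})

test_that("locus bootstrap is seeded, deterministic, and degenerate-safe", {
  ds <- random_dataset(n_per_pop = c(6, 6), L = 5, seed = 17)
  b1 <- bootstrap_distance(ds, "Ds", B = 7, seed = 42)
  b2 <- bootstrap_distance(ds, "Ds", B = 7, seed = 42)
  expect_identical(b1$indices, b2$indices)
  for (b in seq_len(7))
    expect_equal(unclass(b1$matrices[[b]]), unclass(b2$matrices[[b]]))

  # all loci identical copies of one locus: every replicate = point estimate
  dsc <- genotype_dataset(ds$a1[, rep(1, 4)], ds$a2[, rep(1, 4)],
                          pop = as.character(ds$pop),
                          loci = sprintf("L%d", 1:4))
  point <- nei_ds(allele_frequencies(dsc))
  reps <- bootstrap_distance(dsc, "Ds", B = 5, seed = 1)
  for (b in 1:5)
    expect_equal(unclass(reps$matrices[[b]]), unclass(point))

  # an identity-permutation resample reproduces the point estimate
  b3 <- bootstrap_distance(ds, "dmu2", B = 1, seed = 5)
  ing_point <- delta_mu2(allele_frequencies(ds))
  manual <- msatpop:::.dist_from_ingredients(
    msatpop:::.distance_ingredients(allele_frequencies(ds)), "dmu2",
    seq_len(n_loci(ds)))
  expect_equal(unclass(manual), unclass(ing_point))
  expect_error(bootstrap_distance(ds, "Ds", B = 0), "B must be")
})
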