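# Small programmatic fixtures shared across test files.

# n individuals per population, random genotypes over `alleles`
random_dataset <- function(n_per_pop = c(5, 5), L = 3, alleles = 100:105,
                           miss_rate = 0, seed = 1) {
  set.seed(seed)
  n <- sum(n_per_pop)
  a1 <- matrix(sample(alleles, n * L, TRUE), n, L)
  a2 <- matrix(sample(alleles, n * L, TRUE), n, L)
  if (miss_rate > 0) {
    m <- matrix(runif(n * L) < miss_rate, n, L)
    a1[m] <- NA; a2[m] <- NA
  }
  genotype_dataset(a1, a2,
                   pop = rep(paste0("pop", seq_along(n_per_pop)), n_per_pop))
}

# two populations fixed for different alleles at every locus
fixed_difference_dataset <- function(n = 10, L = 4) {
  a <- matrix(rep(c(10L, 20L), each = n), 2 * n, L)
  genotype_dataset(a, a, pop = rep(c("A", "B"), each = n))
}

# dataset built directly from per-population allele frequency profiles:
# pop i genotypes drawn from profile freqs[[i]] (named numeric vectors)
profile_dataset <- function(profiles, n = 50, L = 1, seed = 1) {
  set.seed(seed)
  draws <- lapply(profiles, function(p) {
    al <- as.integer(names(p))
    cbind(sample(al, n * L, TRUE, prob = p), sample(al, n * L, TRUE, prob = p))
  })
  a1 <- do.call(rbind, lapply(draws, function(d) matrix(d[, 1], n, L)))
  a2 <- do.call(rbind, lapply(draws, function(d) matrix(d[, 2], n, L)))
  genotype_dataset(a1, a2,
                   pop = rep(paste0("pop", seq_along(profiles)), each = n))
}

# one random point on the k-simplex
rdirichlet_test <- function(k) { x <- rgamma(k, 1); x / sum(x) }

# exact-frequency single-locus table for distance arithmetic: build an
# allele_freqs object directly (2 populations, L loci, given p vectors)
exact_freqs <- function(freq_list, alleles_list = NULL) {
  # freq_list: list per locus of matrices (pops x alleles, rows sum to 1)
  pops <- rownames(freq_list[[1]])
  tables <- lapply(seq_along(freq_list), function(l) {
    f <- freq_list[[l]]
    alleles <- if (is.null(alleles_list)) as.integer(colnames(f)) else
      alleles_list[[l]]
    n <- rep(100L, nrow(f))
    list(alleles = alleles, freq = f, counts = f * 100, het = f * 0,
         n = n, n_ind = n / 2L, empty = rep(FALSE, nrow(f)))
  })
  structure(list(pops = pops, loci = paste0("L", seq_along(freq_list)),
                 tables = tables), class = "allele_freqs")
}
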