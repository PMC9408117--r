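# Per-population, per-locus allele frequencies: the substrate of every
# downstream statistic. Denominators exclude missing genotypes; alleles are
# canonicalised in ascending size order so all matrices reproduce exactly.

#' Allele frequency tables
#'
#' Computes, for every (population, locus) cell: the shared allele set of
#' the locus (ascending by integer code), allele frequencies over non-missing
#' gene copies, the gene-copy count (2 x non-missing individuals), allele
#' copy counts, and the observed heterozygote frequency per allele (the
#' fraction of non-missing individuals heterozygous and carrying that
#' allele), as required by the Weir-Cockerham variance components.
#'
#' @param ds A [genotype_dataset()].
#' @return An object of class `allele_freqs`: a list with `pops`, `loci`
#'   and per-locus tables. Each table holds `alleles` (sorted codes),
#'   matrices `freq`, `counts`, `het` (populations x alleles), vectors
#'   `n` (gene copies) and `n_ind` (non-missing individuals), and `empty`
#'   (logical per population: no data at this locus).
#' @export
allele_frequencies <- function(ds) {
  pops <- levels(ds$pop)
  P <- length(pops); L <- n_loci(ds)
  tables <- vector("list", L)
  names(tables) <- ds$loci$name
  pop_idx <- as.integer(ds$pop)
  for (l in seq_len(L)) {
    x1 <- ds$a1[, l]; x2 <- ds$a2[, l]
    ok <- !is.na(x1)
    alleles <- sort(unique(c(x1[ok], x2[ok])))
    A <- length(alleles)
    counts <- matrix(0, P, A, dimnames = list(pops, alleles))
    het <- matrix(0, P, A, dimnames = list(pops, alleles))
    n_ind <- integer(P)
    if (A > 0L) {
      i1 <- match(x1[ok], alleles); i2 <- match(x2[ok], alleles)
      pp <- pop_idx[ok]
      counts[] <- tabulate(pp + (i1 - 1L) * P, nbins = P * A) +
                  tabulate(pp + (i2 - 1L) * P, nbins = P * A)
      hh <- i1 != i2
      het[] <- tabulate(pp[hh] + (i1[hh] - 1L) * P, nbins = P * A) +
               tabulate(pp[hh] + (i2[hh] - 1L) * P, nbins = P * A)
      n_ind <- as.integer(tabulate(pp, nbins = P))
    }
    n <- 2L * n_ind
    freq <- counts
    hfrq <- het
    nz <- n_ind > 0L
    freq[nz, ] <- counts[nz, , drop = FALSE] / n[nz]
    hfrq[nz, ] <- het[nz, , drop = FALSE] / n_ind[nz]
    freq[!nz, ] <- NA_real_
    hfrq[!nz, ] <- NA_real_
    tables[[l]] <- list(alleles = alleles, freq = freq, counts = counts,
                        het = hfrq, n = n, n_ind = n_ind, empty = !nz)
  }
  structure(list(pops = pops, loci = ds$loci$name, tables = tables),
            class = "allele_freqs")
}

#' @export
print.allele_freqs <- function(x, ...) {
  cat("allele_freqs:", length(x$pops), "populations,",
      length(x$loci), "loci\n")
  invisible(x)
}

# Pooled (all populations combined) allele counts and frequencies per locus.
# Returns list per locus: alleles, counts, freq, n (total gene copies).
pooled_frequencies <- function(freqs) {
  lapply(freqs$tables, function(tb) {
    cnt <- colSums(tb$counts)
    n <- sum(tb$n)
    list(alleles = tb$alleles, counts = cnt,
         freq = if (n > 0) cnt / n else cnt * NA_real_, n = n)
  })
}
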