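# Per-locus marker diversity summaries: allele counts, rarefied allelic
# richness, PIC, observed and unbiased expected heterozygosity.

#' Polymorphism information content
#'
#' Botstein's PIC for a co-dominant marker:
#' \deqn{PIC = 1 - \sum_a p_a^2 - \sum_{a<b} 2 p_a^2 p_b^2}
#' computed here via the power-sum identity
#' `1 - s2 - s2^2 + s4` with `s2 = sum(p^2)`, `s4 = sum(p^4)`.
#'
#' @param p Numeric allele frequency vector summing to 1.
#' @return PIC in `[0, 1)`; 0 for a monomorphic locus.
#' @export
pic <- function(p) {
  if (any(p < 0)) stop("negative allele frequency")
  if (abs(sum(p) - 1) > 1e-8) stop("allele frequencies must sum to 1")
  s2 <- sum(p^2); s4 <- sum(p^4)
  1 - s2 - s2^2 + s4
}

#' Rarefied allelic richness
#'
#' Expected number of distinct alleles in a random subsample of `g` gene
#' copies drawn without replacement from a sample of `N` copies, by the
#' hypergeometric expectation
#' \deqn{AR(g) = \sum_a \left[1 - \binom{N - N_a}{g} / \binom{N}{g}\right]}
#' where `N_a` is the copy count of allele `a`. `AR(1) = 1` and
#' `AR(N) = ` the observed allele count, exactly.
#'
#' @param counts Integer vector of allele copy counts (`N_a`).
#' @param g Rarefaction size in gene copies, `1 <= g <= sum(counts)`.
#' @return Expected allele count (real, `>= 1` for any polymorphic sample).
#' @export
allelic_richness <- function(counts, g) {
  counts <- counts[counts > 0]
  N <- sum(counts)
  if (g < 1 || g > N) stop("rarefaction size g = ", g,
                           " outside [1, ", N, "]")
  # lchoose(N - Na, g) is -Inf (prob 0) when N - Na < g
  sum(1 - exp(lchoose(N - counts, g) - lchoose(N, g)))
}

#' Observed and expected heterozygosity
#'
#' `Ho` is the fraction of non-missing individuals that are heterozygous.
#' `He` is Nei's unbiased expected heterozygosity
#' `n/(n-1) * (1 - sum(p^2))` with `n` the gene-copy count. Computed on the
#' pooled sample by default, or per population.
#'
#' @param freqs An [allele_frequencies()] table.
#' @param per_population If `TRUE`, return one row per (locus, population).
#' @return A `data.frame` with columns `locus` (, `population`), `Ho`, `He`,
#'   `n` (gene copies). `He` is `NA` when fewer than 2 gene copies.
#' @export
heterozygosities <- function(freqs, per_population = FALSE) {
  if (!per_population) {
    rows <- lapply(seq_along(freqs$tables), function(l) {
      tb <- freqs$tables[[l]]
      n <- sum(tb$n); n_ind <- sum(tb$n_ind)
      if (n_ind == 0L)
        return(data.frame(locus = freqs$loci[l], Ho = NA_real_,
                          He = NA_real_, n = 0L))
      # per-allele het fractions count each heterozygote twice
      ho_cnt <- sum(tb$het[!tb$empty, , drop = FALSE] *
                      tb$n_ind[!tb$empty]) / 2
      p <- colSums(tb$counts) / n
      he <- if (n >= 2) n / (n - 1) * (1 - sum(p^2)) else NA_real_
      data.frame(locus = freqs$loci[l], Ho = ho_cnt / n_ind, He = he, n = n)
    })
    return(do.call(rbind, rows))
  }
  rows <- list()
  for (l in seq_along(freqs$tables)) {
    tb <- freqs$tables[[l]]
    for (i in seq_along(freqs$pops)) {
      n <- tb$n[i]
      if (tb$empty[i]) { ho <- NA_real_; he <- NA_real_ }
      else {
        ho <- sum(tb$het[i, ]) / 2
        p <- tb$freq[i, ]
        he <- if (n >= 2) n / (n - 1) * (1 - sum(p^2)) else NA_real_
      }
      rows[[length(rows) + 1L]] <- data.frame(
        locus = freqs$loci[l], population = freqs$pops[i],
        Ho = ho, He = he, n = n)
    }
  }
  do.call(rbind, rows)
}

#' Per-locus diversity summary table
#'
#' One row per locus over the pooled sample: total number of alleles (TNA),
#' rarefied allelic richness (AR), PIC, observed and unbiased expected
#' heterozygosity, plus trailing `Average` and `SD` rows (arithmetic mean
#' and sample SD, n-1 denominator) mirroring the usual marker-panel report.
#'
#' @param freqs An [allele_frequencies()] table.
#' @param rarefaction_g Gene-copy subsample size for AR, or `"auto"`: the
#'   smallest per-population gene-copy count observed at each locus (a
#'   per-locus `g`, reported in the `g` column).
#' @return A `data.frame` with columns `locus, TNA, AR, PIC, Ho, He, g`,
#'   with two final summary rows (`Average`, `SD`).
#' @export
locus_summary <- function(freqs, rarefaction_g = "auto") {
  het <- heterozygosities(freqs)
  pooled <- pooled_frequencies(freqs)
  L <- length(freqs$loci)
  rows <- vector("list", L)
  for (l in seq_len(L)) {
    pl <- pooled[[l]]
    tb <- freqs$tables[[l]]
    tna <- sum(pl$counts > 0)
    if (identical(rarefaction_g, "auto")) {
      with_data <- tb$n[!tb$empty]
      g <- if (length(with_data)) min(with_data) else NA_integer_
    } else g <- rarefaction_g
    if (!is.na(g) && g > pl$n)
      stop("rarefaction size g = ", g, " exceeds pooled gene copies (",
           pl$n, ") at locus '", freqs$loci[l], "'")
    ar <- if (is.na(g) || pl$n == 0) NA_real_ else
      allelic_richness(pl$counts, g)
    p <- pl$freq[pl$counts > 0]
    pic_l <- if (pl$n > 0) pic(p) else NA_real_
    rows[[l]] <- data.frame(locus = freqs$loci[l], TNA = tna, AR = ar,
                            PIC = pic_l, Ho = het$Ho[l], He = het$He[l],
                            g = as.numeric(g))
  }
  out <- do.call(rbind, rows)
  num <- c("TNA", "AR", "PIC", "Ho", "He")
  avg <- data.frame(locus = "Average", t(colMeans(out[num], na.rm = TRUE)),
                    g = NA_real_)
  sdr <- data.frame(locus = "SD", t(apply(out[num], 2, stats::sd, na.rm = TRUE)),
                    g = NA_real_)
  names(avg) <- names(sdr) <- names(out)
  rbind(out, avg, sdr)
}

#' Summarise printed per-locus diversity columns
#'
#' Recomputes the panel-level summary statistics (total allele count, means
#' and sample SDs) from a published per-locus characteristics table with
#' columns `TNA`, `AR`, `PIC` — useful to check a reported marker panel
#' without the raw genotypes.
#'
#' @param tab A `data.frame` with numeric columns `TNA`, `AR`, `PIC` (one
#'   row per locus, no summary rows).
#' @return A list with `total_alleles`, and per column `mean` and `sd`
#'   (named vectors).
#' @export
summarize_locus_table <- function(tab) {
  num <- c("TNA", "AR", "PIC")
  if (!all(num %in% names(tab)))
    stop("table must contain columns ", paste(num, collapse = ", "))
  list(total_alleles = sum(tab$TNA),
       mean = vapply(tab[num], mean, numeric(1)),
       sd = vapply(tab[num], stats::sd, numeric(1)))
}
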