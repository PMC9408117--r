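# Weir-Cockerham F_ST: per-(locus, allele) variance components, global and
# pairwise ratio estimators, permutation significance, and Wright's
# island-model gene-flow transform.

#' Labelled symmetric pairwise-statistic matrix
#'
#' Thin wrapper holding a symmetric population-by-population matrix with a
#' statistic tag (`"FST"`, `"Nm"`, `"fij"`, `"Ds"`, `"dmu2"`, `"generations"`,
#' `"years"`).
#'
#' @param values Square numeric matrix.
#' @param labels Population labels (row/column names).
#' @param statistic Statistic tag.
#' @return A `pairwise_matrix` (a classed matrix with a `statistic`
#'   attribute).
#' @export
pairwise_matrix <- function(values, labels = rownames(values), statistic) {
  values <- as.matrix(values)
  if (nrow(values) != ncol(values)) stop("matrix must be square")
  if (is.null(labels)) stop("labels required")
  dimnames(values) <- list(labels, labels)
  finite <- is.finite(values)
  asym <- abs(values - t(values))
  if (any(asym[finite & t(finite)] > 1e-12))
    stop("matrix is not symmetric")
  structure(values, class = c("pairwise_matrix", "matrix", "array"),
            statistic = statistic)
}

#' @export
print.pairwise_matrix <- function(x, digits = 4, ...) {
  cat("pairwise_matrix [", attr(x, "statistic"), "], ",
      nrow(x), " populations\n", sep = "")
  print(round(unclass(x), digits))
  invisible(x)
}

#' Weir-Cockerham variance components
#'
#' For each (locus, allele) combination over `r` populations, the three
#' moment components of the allele-frequency variance: `a` among
#' populations, `b` among individuals within populations, `c` within
#' individuals. With per-population sample sizes `n_i` (non-missing
#' individuals), allele frequencies `p_i`, and observed heterozygote
#' frequencies `h_i`:
#' \deqn{a = (\bar n / n_c)[s^2 - (1/(\bar n - 1))(\bar p(1-\bar p) -
#'   s^2 (r-1)/r - \bar h/4)]}
#' \deqn{b = (\bar n/(\bar n - 1))[\bar p (1-\bar p) - s^2 (r-1)/r -
#'   \bar h (2\bar n - 1)/(4 \bar n)]}
#' \deqn{c = \bar h / 2}
#' with the usual weighted means and `n_c` the variance-corrected average
#' sample size. Loci where any selected population has no data are dropped
#' with a warning.
#'
#' @param freqs An [allele_frequencies()] table.
#' @param populations Optional subset (character) of populations; default
#'   all.
#' @return An object of class `wc_components`: a `data.frame` with columns
#'   `locus`, `allele`, `a`, `b`, `c`.
#' @export
wc_components <- function(freqs, populations = NULL) {
  pops <- if (is.null(populations)) freqs$pops else populations
  if (!all(pops %in% freqs$pops))
    stop("unknown population(s): ",
         paste(setdiff(pops, freqs$pops), collapse = ", "))
  r <- length(pops)
  if (r < 2) stop("need at least 2 populations")
  pi_ <- match(pops, freqs$pops)
  out <- vector("list", length(freqs$tables))
  dropped <- character(0)
  for (l in seq_along(freqs$tables)) {
    tb <- freqs$tables[[l]]
    if (any(tb$empty[pi_])) { dropped <- c(dropped, freqs$loci[l]); next }
    n_i <- tb$n_ind[pi_]
    nbar <- mean(n_i)
    if (nbar <= 1) { dropped <- c(dropped, freqs$loci[l]); next }
    nc <- (r * nbar - sum(n_i^2) / (r * nbar)) / (r - 1)
    A <- length(tb$alleles)
    a <- b <- cc <- numeric(A)
    for (j in seq_len(A)) {
      p_i <- tb$freq[pi_, j]
      h_i <- tb$het[pi_, j]
      pbar <- sum(n_i * p_i) / (r * nbar)
      s2 <- sum(n_i * (p_i - pbar)^2) / ((r - 1) * nbar)
      hbar <- sum(n_i * h_i) / (r * nbar)
      inner <- pbar * (1 - pbar) - s2 * (r - 1) / r
      a[j] <- (nbar / nc) * (s2 - (inner - hbar / 4) / (nbar - 1))
      b[j] <- (nbar / (nbar - 1)) * (inner - hbar * (2 * nbar - 1) / (4 * nbar))
      cc[j] <- hbar / 2
    }
    out[[l]] <- data.frame(locus = freqs$loci[l], allele = tb$alleles,
                           a = a, b = b, c = cc)
  }
  if (length(dropped))
    warning("loci dropped (population without data or n <= 1): ",
            paste(dropped, collapse = ", "))
  res <- do.call(rbind, out)
  if (is.null(res) || nrow(res) == 0) stop("no usable loci")
  class(res) <- c("wc_components", "data.frame")
  res
}

#' Global multi-locus F_ST (theta) and variance partition
#'
#' The ratio-of-sums estimator \eqn{\theta = \sum a / \sum (a + b + c)} over
#' all loci and alleles, with the corresponding among/within percentage
#' partition of the total variance.
#'
#' @param components A [wc_components()] table.
#' @return A list with `theta`, `percent_among` (`100 * theta`) and
#'   `percent_within`.
#' @export
fst_global <- function(components) {
  tot <- sum(components$a + components$b + components$c)
  if (tot == 0) stop("all loci monomorphic: F_ST undefined")
  theta <- sum(components$a) / tot
  list(theta = theta, percent_among = 100 * theta,
       percent_within = 100 * (1 - theta))
}

#' Pairwise F_ST matrix
#'
#' Weir-Cockerham theta for every population pair (each pair analysed with
#' `r = 2`), as a symmetric [pairwise_matrix()] with zero diagonal.
#'
#' @param freqs An [allele_frequencies()] table.
#' @return A `pairwise_matrix` tagged `"FST"`. Negative estimates are
#'   reported as computed (not truncated).
#' @export
fst_pairwise <- function(freqs) {
  pops <- freqs$pops
  P <- length(pops)
  m <- matrix(0, P, P, dimnames = list(pops, pops))
  for (i in seq_len(P - 1)) for (j in (i + 1):P) {
    comp <- suppressWarnings(wc_components(freqs, populations = pops[c(i, j)]))
    m[i, j] <- m[j, i] <- fst_global(comp)$theta
  }
  pairwise_matrix(m, pops, "FST")
}

#' Gene flow from F_ST under Wright's island model
#'
#' `Nm = (1 - F_ST) / (4 F_ST)`, the effective number of migrants per
#' generation. Non-positive F_ST values (no measurable differentiation)
#' map to `Inf` with a warning.
#'
#' @param fst A `pairwise_matrix` tagged `"FST"`, or a numeric scalar.
#' @return Matching `pairwise_matrix` tagged `"Nm"` (diagonal `NA`), or a
#'   scalar.
#' @export
nm_from_fst <- function(fst) {
  transform1 <- function(f) {
    if (!is.finite(f)) return(NA_real_)
    if (f <= 0) return(Inf)
    if (f >= 1) return(0)
    (1 - f) / (4 * f)
  }
  if (is.matrix(fst)) {
    v <- unclass(fst)
    out <- apply(v, c(1, 2), transform1)
    if (any(v[upper.tri(v)] <= 0))
      warning("non-positive F_ST entries mapped to Nm = Inf")
    diag(out) <- NA_real_
    # rebuild without symmetry re-check on the NA diagonal
    structure(out, class = c("pairwise_matrix", "matrix", "array"),
              statistic = "Nm")
  } else {
    if (fst <= 0) warning("non-positive F_ST mapped to Nm = Inf")
    transform1(fst)
  }
}

#' Global F_ST with a group left out
#'
#' Recomputes the global theta after removing a set of populations — the
#' usual check of how much one divergent group drives the variance
#' partition.
#'
#' @param freqs An [allele_frequencies()] table.
#' @param drop Character vector of population labels to remove.
#' @return A list with the full and reduced [fst_global()] results and the
#'   dropped labels.
#' @export
fst_leave_group_out <- function(freqs, drop) {
  keep <- setdiff(freqs$pops, drop)
  if (length(keep) < 2) stop("fewer than 2 populations remain")
  full <- fst_global(suppressWarnings(wc_components(freqs)))
  reduced <- fst_global(suppressWarnings(wc_components(freqs, populations = keep)))
  list(full = full, reduced = reduced, dropped = drop)
}

#' Permutation test for pairwise F_ST
#'
#' For each population pair, individuals are permuted between the two
#' populations and theta recomputed, giving the null distribution of
#' no differentiation. The p-value is the fraction of permuted thetas
#' greater than or equal to the observed one (with the +1 continuity
#' correction).
#'
#' @param ds A [genotype_dataset()].
#' @param n_perm Number of permutations per pair.
#' @param seed Integer RNG seed.
#' @return A list with `fst` (observed pairwise matrix) and `p_value`
#'   (matrix, `NA` diagonal).
#' @export
fst_permutation_test <- function(ds, n_perm = 999, seed = 1L) {
  set.seed(seed)
  pops <- levels(ds$pop)
  P <- length(pops)
  obs <- fst_pairwise(allele_frequencies(ds))
  pmat <- matrix(NA_real_, P, P, dimnames = list(pops, pops))
  for (i in seq_len(P - 1)) for (j in (i + 1):P) {
    sub <- subset_populations(ds, pops[c(i, j)])
    labels <- as.character(sub$pop)
    count <- 0L
    for (b in seq_len(n_perm)) {
      perm <- sample(labels)
      pds <- genotype_dataset(sub$a1, sub$a2, pop = perm,
                              individuals = sub$individuals, loci = sub$loci)
      th <- fst_global(suppressWarnings(wc_components(allele_frequencies(pds))))$theta
      if (th >= obs[i, j]) count <- count + 1L
    }
    pmat[i, j] <- pmat[j, i] <- (count + 1) / (n_perm + 1)
  }
  list(fst = obs, p_value = pmat)
}
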