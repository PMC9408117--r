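# Admixture-model Bayesian clustering: a Gibbs sampler over allele-copy
# cluster origins (Z), cluster allele frequencies (P) and individual
# ancestry proportions (Q), with the Evanno Delta-K model-selection table
# and label alignment across replicate runs.

# Per-locus integer allele indices for both gene copies, with the
# non-missing row subset (missing copies contribute to nothing).
.geno_indices <- function(ds) {
  L <- n_loci(ds)
  out <- vector("list", L)
  for (l in seq_len(L)) {
    ok <- which(!is.na(ds$a1[, l]))
    alleles <- sort(unique(c(ds$a1[ok, l], ds$a2[ok, l])))
    out[[l]] <- list(alleles = alleles, rows = ok,
                     i1 = match(ds$a1[ok, l], alleles),
                     i2 = match(ds$a2[ok, l], alleles))
  }
  out
}

# sample one categorical draw per row of an (n x K) unnormalised weight
# matrix
.sample_rows <- function(W) {
  K <- ncol(W)
  if (K == 1L) return(rep(1L, nrow(W)))
  cs <- W
  for (k in 2:K) cs[, k] <- cs[, k] + cs[, k - 1]
  u <- stats::runif(nrow(W)) * cs[, K]
  1L + as.integer(rowSums(cs < u))
}

#' Admixture-model Gibbs sampler
#'
#' Pritchard-style clustering of multilocus genotypes: each allele copy of
#' individual `i` at locus `l` originates from cluster `k` with probability
#' proportional to `Q[i,k] * P[k,l,a]`; cluster allele frequencies get a
#' `Dirichlet(lambda + counts)` update and ancestry rows a
#' `Dirichlet(alpha + copy counts)` update. `alpha` and `lambda` are fixed.
#' The data log-likelihood `ln P(X | P, Q)` is recorded at every thinned
#' sweep after burn-in; the model evidence estimate is
#' `L_hat = mean(lnL) - var(lnL) / 2`.
#'
#' @param ds A [genotype_dataset()].
#' @param K Number of clusters (`>= 1`).
#' @param alpha Dirichlet concentration of individual ancestry (fixed).
#' @param lambda Dirichlet prior on cluster allele frequencies.
#' @param burn_in,iterations Total sweeps and burn-in sweeps
#'   (`iterations > burn_in`).
#' @param thin Record every `thin`-th post-burn-in sweep.
#' @param seed Integer RNG seed (runs are bit-reproducible).
#' @return A `cluster_run`: list with `K`, `Q` (posterior-mean ancestry,
#'   individuals x K), `P` (list per locus of K x alleles posterior-mean
#'   frequencies), `lnL_trace`, `L_hat`, and the chain settings.
#' @export
admixture_gibbs <- function(ds, K, alpha = 1.0, lambda = 1.0,
                            burn_in = 2000L, iterations = 10000L,
                            thin = 10L, seed = 1L) {
  if (K < 1) stop("K must be >= 1")
  if (iterations <= burn_in) stop("iterations must exceed burn_in")
  n_distinct <- nrow(unique(cbind(ds$a1, ds$a2)))
  if (K > n_distinct)
    warning("K = ", K, " exceeds the number of distinct multilocus genotypes (",
            n_distinct, ")")
  set.seed(seed)
  n <- n_individuals(ds); L <- n_loci(ds)
  gi <- .geno_indices(ds)
  A <- vapply(gi, function(g) length(g$alleles), integer(1))

  # initial state: uniform ancestry, prior-draw frequencies
  Q <- matrix(1 / K, n, K)
  P <- lapply(seq_len(L), function(l)
    .rdirichlet(K, rep(lambda, A[l])))
  Q_acc <- matrix(0, n, K)
  P_acc <- lapply(seq_len(L), function(l) matrix(0, K, A[l]))
  lnL_trace <- numeric(0)
  n_rec <- 0L

  for (sweep in seq_len(iterations)) {
    q_counts <- matrix(0, n, K)
    for (l in seq_len(L)) {
      g <- gi[[l]]
      if (!length(g$rows)) next
      Pt <- t(P[[l]])                          # A x K
      p_counts <- numeric(A[l] * K)
      for (copy in 1:2) {
        ia <- if (copy == 1) g$i1 else g$i2
        W <- Q[g$rows, , drop = FALSE] * Pt[ia, , drop = FALSE]
        z <- .sample_rows(W)
        p_counts <- p_counts + tabulate(ia + (z - 1L) * A[l], A[l] * K)
        q_counts[] <- q_counts + tabulate(g$rows + (z - 1L) * n, n * K)
      }
      cnt <- matrix(p_counts, A[l], K)         # alleles x clusters
      P[[l]] <- .rdirichlet_rows(t(cnt) + lambda)
    }
    Q <- .rdirichlet_rows(q_counts + alpha)
    if (sweep > burn_in && (sweep - burn_in) %% thin == 0L) {
      n_rec <- n_rec + 1L
      Q_acc <- Q_acc + Q
      lnL <- 0
      for (l in seq_len(L)) {
        g <- gi[[l]]
        if (!length(g$rows)) next
        P_acc[[l]] <- P_acc[[l]] + P[[l]]
        Pt <- t(P[[l]])
        Qr <- Q[g$rows, , drop = FALSE]
        lnL <- lnL + sum(log(rowSums(Qr * Pt[g$i1, , drop = FALSE]))) +
                     sum(log(rowSums(Qr * Pt[g$i2, , drop = FALSE])))
      }
      if (!is.finite(lnL)) stop("non-finite data log-likelihood")
      lnL_trace <- c(lnL_trace, lnL)
    }
  }
  Qm <- Q_acc / n_rec
  rownames(Qm) <- ds$individuals
  Pm <- lapply(seq_len(L), function(l) {
    m <- P_acc[[l]] / n_rec
    colnames(m) <- as.character(gi[[l]]$alleles)
    m
  })
  names(Pm) <- ds$loci$name
  L_hat <- mean(lnL_trace) - stats::var(lnL_trace) / 2
  if (length(lnL_trace) == 1L) L_hat <- lnL_trace
  structure(list(K = as.integer(K), Q = Qm, P = Pm,
                 lnL_trace = lnL_trace, L_hat = L_hat,
                 alpha = alpha, lambda = lambda, burn_in = burn_in,
                 iterations = iterations, thin = thin, seed = seed,
                 populations = as.character(ds$pop)),
            class = "cluster_run")
}

# one Dirichlet draw per row of a positive shape matrix
.rdirichlet_rows <- function(shape) {
  x <- matrix(stats::rgamma(length(shape), shape = shape), nrow(shape))
  x / rowSums(x)
}

#' @export
print.cluster_run <- function(x, ...) {
  cat("cluster_run: K =", x$K, ", ", nrow(x$Q), "individuals, L_hat =",
      format(x$L_hat), "\n")
  invisible(x)
}

#' Evanno Delta-K model-selection table
#'
#' From replicate runs over a consecutive range of K: the mean and SD of
#' the evidence estimate `L_hat` per K, the first and second differences,
#' and \deqn{\Delta K = |L''(K)| / SD(K)} defined for interior K with
#' positive SD. The selected K is the arg-max of Delta-K.
#'
#' @param runs List of [admixture_gibbs()] results (>= 3 replicates per K,
#'   consecutive K values).
#' @return An `evanno_table` data.frame with columns `K`, `n_runs`,
#'   `mean_L`, `sd_L`, `dL`, `ddL`, `delta_K`, plus a `selected_K`
#'   attribute.
#' @export
evanno_delta_k <- function(runs) {
  Ks <- vapply(runs, function(r) r$K, integer(1))
  Ls <- vapply(runs, function(r) r$L_hat, numeric(1))
  uK <- sort(unique(Ks))
  if (any(diff(uK) != 1L)) stop("K values must be consecutive")
  reps <- table(factor(Ks, levels = uK))
  if (any(reps < 3))
    stop("need >= 3 replicate runs per K (K = ",
         paste(uK[reps < 3], collapse = ", "), " underfilled)")
  meanL <- tapply(Ls, factor(Ks, levels = uK), mean)
  sdL <- tapply(Ls, factor(Ks, levels = uK), stats::sd)
  m <- length(uK)
  dL <- c(NA, diff(meanL))
  ddL <- rep(NA_real_, m)
  dk <- rep(NA_real_, m)
  for (i in seq_len(m)) {
    if (i == 1 || i == m) next
    ddL[i] <- abs(meanL[i + 1] - 2 * meanL[i] + meanL[i - 1])
    if (sdL[i] > 0) dk[i] <- ddL[i] / sdL[i]
  }
  out <- data.frame(K = uK, n_runs = as.integer(reps), mean_L = as.numeric(meanL),
                    sd_L = as.numeric(sdL), dL = as.numeric(dL),
                    ddL = ddL, delta_K = dk)
  sel <- if (all(is.na(dk))) NA_integer_ else uK[which.max(dk)]
  attr(out, "selected_K") <- sel
  class(out) <- c("evanno_table", "data.frame")
  out
}

#' Align cluster labels between two runs
#'
#' Permutes the cluster columns of `other` to maximise the ancestry
#' agreement `sum_i sum_k Q_ref[i,k] * Q_perm[i,k]` with the reference run.
#' The optimum is found exactly (enumeration) for `K <= 8`, greedily above.
#'
#' @param reference,other Two [admixture_gibbs()] runs with the same K and
#'   individuals.
#' @return `other` with `Q` columns and `P` rows permuted; the permutation
#'   is attached as attribute `perm`.
#' @export
align_runs <- function(reference, other) {
  if (reference$K != other$K) stop("K mismatch")
  if (nrow(reference$Q) != nrow(other$Q)) stop("individual sets differ")
  K <- reference$K
  S <- crossprod(reference$Q, other$Q)   # S[k, k'] = sum_i Qref_ik Qoth_ik'
  if (K <= 8) {
    perms <- .permutations(K)
    scores <- vapply(seq_len(nrow(perms)), function(r)
      sum(S[cbind(seq_len(K), perms[r, ])]), numeric(1))
    perm <- perms[which.max(scores), ]
  } else {
    perm <- integer(K); used <- logical(K)
    Sw <- S
    for (step in seq_len(K)) {
      best <- which(Sw == max(Sw), arr.ind = TRUE)[1, ]
      perm[best[1]] <- best[2]
      Sw[best[1], ] <- -Inf; Sw[, best[2]] <- -Inf
    }
  }
  out <- other
  out$Q <- other$Q[, perm, drop = FALSE]
  out$P <- lapply(other$P, function(p) p[perm, , drop = FALSE])
  attr(out, "perm") <- perm
  out
}

.permutations <- function(K) {
  if (K == 1) return(matrix(1L, 1, 1))
  sub <- .permutations(K - 1L)
  out <- matrix(0L, 0, K)
  for (pos in seq_len(K)) {
    block <- cbind(sub[, seq_len(pos - 1), drop = FALSE], K,
                   sub[, seq(pos, K - 1)[seq_len(K - pos)], drop = FALSE])
    out <- rbind(out, block)
  }
  dimnames(out) <- NULL
  out
}

#' Export a Q-matrix in a cluster-plot-friendly layout
#'
#' Writes `individual, population, q_1 .. q_K`, ordered by population then
#' individual.
#'
#' @param run An [admixture_gibbs()] result.
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_q_matrix <- function(run, path) {
  ord <- order(factor(run$populations, levels = unique(run$populations)),
               rownames(run$Q))
  tab <- data.frame(individual = rownames(run$Q)[ord],
                    population = run$populations[ord],
                    run$Q[ord, , drop = FALSE])
  names(tab)[-(1:2)] <- paste0("q_", seq_len(run$K))
  utils::write.table(tab, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}
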