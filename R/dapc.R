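# Discriminant analysis of principal components on allele-dosage vectors:
# PCA reduction of the centered 0/1/2 dosage matrix followed by linear
# discriminant axes on the group labels.

#' Allele dosage matrix
#'
#' Codes each individual as a vector of per-allele dosages (0, 1 or 2
#' copies), one column per (locus, allele); missing genotypes contribute
#' the population-mean dosage of the column (mean imputation, the standard
#' PCA-friendly choice).
#'
#' @param ds A [genotype_dataset()].
#' @return A numeric matrix, individuals x allele columns, named
#'   `locus.allele`.
#' @export
allele_dosage <- function(ds) {
  L <- n_loci(ds); n <- n_individuals(ds)
  cols <- list()
  for (l in seq_len(L)) {
    x1 <- ds$a1[, l]; x2 <- ds$a2[, l]
    alleles <- sort(unique(c(x1, x2)))
    alleles <- alleles[!is.na(alleles)]
    if (!length(alleles)) next
    m <- matrix(0, n, length(alleles),
                dimnames = list(ds$individuals,
                                paste0(ds$loci$name[l], ".", alleles)))
    for (j in seq_along(alleles))
      m[, j] <- (x1 == alleles[j]) + (x2 == alleles[j])
    miss <- is.na(x1)
    if (any(miss)) {
      cm <- colMeans(m[!miss, , drop = FALSE])
      m[miss, ] <- matrix(cm, sum(miss), length(alleles), byrow = TRUE)
    }
    cols[[length(cols) + 1L]] <- m
  }
  do.call(cbind, cols)
}

#' Discriminant analysis of principal components
#'
#' The centered allele-dosage matrix is reduced to `n_pcs` principal
#' components (`"auto"`: the smallest count explaining at least 90% of the
#' variance, capped at `n - groups`), then linear discriminant axes are fit
#' on the group labels. Individual coordinates on the discriminant axes
#' summarise between-group structure while the PCA step controls
#' overfitting of the many allele columns.
#'
#' @param ds A [genotype_dataset()].
#' @param groups Group label per individual (default: population labels).
#' @param n_pcs Number of retained PCs, or `"auto"`.
#' @param var_threshold Variance fraction targeted by `"auto"`.
#' @return A `dapc_result`: list with `n_pcs`, `pc_scores`, `loadings`
#'   (discriminant axes in PC space), `coords` (individual discriminant
#'   coordinates), `groups`, `var_explained`.
#' @export
dapc_genotypes <- function(ds, groups = NULL, n_pcs = "auto",
                           var_threshold = 0.9) {
  if (is.null(groups)) groups <- as.character(ds$pop)
  groups <- factor(groups)
  if (nlevels(groups) < 2) stop("need at least 2 groups")
  if (any(table(groups) < 2))
    stop("every group needs at least 2 members")
  X <- allele_dosage(ds)
  X <- scale(X, center = TRUE, scale = FALSE)
  pca <- stats::prcomp(X, center = FALSE)
  ev <- pca$sdev^2
  pos <- ev > 1e-12
  cum <- cumsum(ev[pos]) / sum(ev[pos])
  max_pcs <- min(sum(pos), nrow(X) - nlevels(groups))
  if (identical(n_pcs, "auto")) {
    n_pcs <- min(which(cum >= var_threshold), max_pcs)
  } else {
    n_pcs <- min(n_pcs, max_pcs)
  }
  scores <- pca$x[, seq_len(n_pcs), drop = FALSE]
  fit <- MASS::lda(scores, grouping = groups)
  coords <- stats::predict(fit, scores)$x
  structure(list(n_pcs = n_pcs, pc_scores = scores,
                 loadings = fit$scaling, coords = coords, groups = groups,
                 var_explained = cum[n_pcs]),
            class = "dapc_result")
}

#' @export
print.dapc_result <- function(x, ...) {
  cat("dapc_result:", x$n_pcs, "PCs (", round(100 * x$var_explained, 1),
      "% variance ),", nlevels(x$groups), "groups,",
      ncol(x$coords), "discriminant axes\n")
  invisible(x)
}

#' Permutation test of group separation on the first discriminant axis
#'
#' Compares the observed between-group variance fraction of the first
#' discriminant coordinate against refits under permuted group labels —
#' the null of no group structure.
#'
#' @param ds A [genotype_dataset()].
#' @param groups Group labels (default population labels).
#' @param n_perm Number of permutations.
#' @param seed RNG seed.
#' @param ... Passed to [dapc_genotypes()].
#' @return A list with `observed` (between-group variance fraction),
#'   `null` (permuted values), and `p_value`.
#' @export
dapc_permutation_test <- function(ds, groups = NULL, n_perm = 99L,
                                  seed = 1L, ...) {
  if (is.null(groups)) groups <- as.character(ds$pop)
  set.seed(seed)
  stat <- function(g) {
    fit <- dapc_genotypes(ds, groups = g, ...)
    x <- fit$coords[, 1]
    gm <- tapply(x, fit$groups, mean)
    sum(table(fit$groups) * (gm - mean(x))^2) / sum((x - mean(x))^2)
  }
  obs <- stat(groups)
  null <- vapply(seq_len(n_perm), function(b) stat(sample(groups)),
                 numeric(1))
  list(observed = obs, null = null,
       p_value = (sum(null >= obs) + 1) / (n_perm + 1))
}
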