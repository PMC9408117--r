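# Between-population distances on allele frequencies: molecular coancestry
# f_ij, Nei's standard distance Ds, Goldstein's (delta-mu)^2, and locus
# bootstrap of any of them. Per-locus ingredients (gene-identity
# cross-products and mean allele sizes) are precomputed once so bootstrap
# replicates only recombine locus slices.

# Sentinel used when a log-of-zero distance must stay finite for tree building
.DS_INF_SENTINEL <- 1e9

#' Allele size map (fragment size to repeat units)
#'
#' Per-locus affine map `size_score = (code - offset) / motif_length`,
#' converting fragment sizes in bp to repeat counts. The default
#' (`offset = 0`, `motif_length = 1`) is the identity, appropriate when
#' allele codes already are repeat counts (e.g. simulator output).
#'
#' @param loci Character vector of locus names, or a `genotype_dataset`.
#' @param offset Integer offset(s) in bp, recycled.
#' @param motif_length Integer motif length(s) in bp, recycled.
#' @return An `allele_size_map`: data.frame with `locus`, `offset`,
#'   `motif_length`.
#' @export
allele_size_map <- function(loci, offset = 0L, motif_length = 1L) {
  if (inherits(loci, "genotype_dataset")) {
    ml <- loci$loci$motif_length
    ml[is.na(ml)] <- 1L
    out <- data.frame(locus = loci$loci$name, offset = 0L, motif_length = ml,
                      stringsAsFactors = FALSE)
    if (!missing(offset)) out$offset <- as.integer(rep_len(offset, nrow(out)))
    if (!missing(motif_length))
      out$motif_length <- as.integer(rep_len(motif_length, nrow(out)))
  } else {
    out <- data.frame(locus = as.character(loci),
                      offset = as.integer(rep_len(offset, length(loci))),
                      motif_length = as.integer(rep_len(motif_length, length(loci))),
                      stringsAsFactors = FALSE)
  }
  if (any(out$motif_length < 1L)) stop("motif_length must be >= 1")
  class(out) <- c("allele_size_map", "data.frame")
  out
}

# Precompute, per locus: the P x P gene-identity cross-product
# C[i,j] = sum_a p_{i,a} p_{j,a}, validity mask, and mean allele size mu.
.distance_ingredients <- function(freqs, sizes = NULL) {
  P <- length(freqs$pops); L <- length(freqs$tables)
  C <- array(NA_real_, dim = c(P, P, L))
  valid <- matrix(FALSE, P, L)
  mu <- matrix(NA_real_, P, L)
  for (l in seq_len(L)) {
    tb <- freqs$tables[[l]]
    ok <- !tb$empty
    valid[, l] <- ok
    if (!any(ok)) next
    f <- tb$freq
    f[!ok, ] <- 0
    C[, , l] <- f %*% t(f)
    s <- as.numeric(tb$alleles)
    if (!is.null(sizes)) {
      row <- match(freqs$loci[l], sizes$locus)
      if (is.na(row)) stop("no size mapping for locus '", freqs$loci[l], "'")
      s <- (s - sizes$offset[row]) / sizes$motif_length[row]
      if (any(s <= 0))
        stop("non-positive size score at locus '", freqs$loci[l],
             "' (allele ", tb$alleles[which(s <= 0)[1]], ")")
    }
    mu[, l] <- as.vector(f %*% s)
    mu[!ok, l] <- NA_real_
  }
  list(C = C, valid = valid, mu = mu, pops = freqs$pops)
}

# Pairwise matrices from ingredients restricted to a locus subset (with
# replacement allowed: `loci_idx` may repeat indices).
.dist_from_ingredients <- function(ing, statistic, loci_idx = NULL) {
  P <- length(ing$pops)
  if (is.null(loci_idx)) loci_idx <- seq_len(ncol(ing$valid))
  m <- matrix(0, P, P, dimnames = list(ing$pops, ing$pops))
  warn_inf <- FALSE
  for (i in seq_len(P)) for (j in i:P) {
    shared <- loci_idx[ing$valid[i, loci_idx] & ing$valid[j, loci_idx]]
    if (length(shared) == 0)
      stop("no shared loci with data between '", ing$pops[i], "' and '",
           ing$pops[j], "'")
    if (statistic == "fij") {
      v <- mean(ing$C[i, j, shared])
    } else if (statistic == "Ds") {
      jxy <- mean(ing$C[i, j, shared])
      jx <- mean(ing$C[i, i, shared]); jy <- mean(ing$C[j, j, shared])
      if (jxy <= 0) { v <- .DS_INF_SENTINEL; warn_inf <- TRUE }
      else v <- max(0, -log(jxy / sqrt(jx * jy)))
      if (i == j) v <- 0
    } else if (statistic == "dmu2") {
      v <- mean((ing$mu[i, shared] - ing$mu[j, shared])^2)
    } else stop("unknown statistic: ", statistic)
    m[i, j] <- m[j, i] <- v
  }
  if (warn_inf)
    warning("disjoint allele sets: Ds = +Inf replaced by sentinel ",
            format(.DS_INF_SENTINEL))
  pairwise_matrix(m, ing$pops, statistic)
}

#' Between-population molecular coancestry
#'
#' `f_ij`: the probability that two random gene copies, one drawn from each
#' of two populations, are identical in state, averaged over loci:
#' \deqn{f_{ij} = (1/L) \sum_l \sum_a p_{l,i,a} \, p_{l,j,a}.}
#' The diagonal holds the within-population expected homozygosity (same
#' formula with `i = j`).
#'
#' @param freqs An [allele_frequencies()] table.
#' @return A `pairwise_matrix` tagged `"fij"`, values in `[0, 1]`.
#' @export
coancestry_fij <- function(freqs) {
  .dist_from_ingredients(.distance_ingredients(freqs), "fij")
}

#' Nei's standard genetic distance
#'
#' \deqn{D_S = -\ln\left(J_{XY} / \sqrt{J_X J_Y}\right)} with gene
#' identities averaged arithmetically over loci first (Nei 1972 convention):
#' `J_X = mean_l sum_a p_X^2`, `J_XY = mean_l sum_a p_X p_Y`. Disjoint
#' allele sets (`J_XY = 0`) yield a large finite sentinel (`1e9`) with a
#' warning so trees remain constructible.
#'
#' @param freqs An [allele_frequencies()] table.
#' @return A `pairwise_matrix` tagged `"Ds"`, zero diagonal.
#' @export
nei_ds <- function(freqs) {
  .dist_from_ingredients(.distance_ingredients(freqs), "Ds")
}

#' Goldstein's (delta-mu)^2 distance
#'
#' Squared difference of mean allele sizes, averaged over loci:
#' \deqn{(\delta\mu)^2 = (1/L) \sum_l (\mu_{l,X} - \mu_{l,Y})^2,\quad
#'   \mu_{l,i} = \sum_a s_a \, p_{l,i,a}}
#' where `s_a` is the allele size score. Under the stepwise mutation model
#' its expectation grows linearly in divergence time,
#' `E[(delta-mu)^2] = 2 beta tau`, which is what makes it the distance of
#' choice for dating deep splits.
#'
#' @param freqs An [allele_frequencies()] table.
#' @param sizes Optional [allele_size_map()]; by default allele codes are
#'   used as sizes directly (repeat-count coding).
#' @return A `pairwise_matrix` tagged `"dmu2"`, zero diagonal.
#' @export
delta_mu2 <- function(freqs, sizes = NULL) {
  .dist_from_ingredients(.distance_ingredients(freqs, sizes), "dmu2")
}

#' Locus bootstrap of a pairwise distance
#'
#' Draws `B` resamples of the locus set (with replacement), recomputes the
#' chosen statistic on each, and returns the replicate matrices — the raw
#' material for bootstrap supports on a neighbor-joining tree.
#'
#' @param ds A [genotype_dataset()].
#' @param statistic One of `"Ds"`, `"dmu2"`, `"fst"`.
#' @param B Number of replicates (`>= 1`).
#' @param seed Integer RNG seed (replicates are bit-reproducible).
#' @param sizes Optional [allele_size_map()] for `"dmu2"`.
#' @return An object of class `bootstrap_replicates`: list with `B`,
#'   `indices` (B x L matrix of resampled locus indices), `matrices`
#'   (list of `pairwise_matrix`), `statistic`, `seed`.
#' @export
bootstrap_distance <- function(ds, statistic = c("Ds", "dmu2", "fst"),
                               B = 1000L, seed = 1L, sizes = NULL) {
  statistic <- match.arg(statistic)
  if (B < 1) stop("B must be >= 1")
  L <- n_loci(ds)
  if (L < 2) stop("need at least 2 loci to bootstrap")
  set.seed(seed)
  idx <- matrix(sample.int(L, B * L, replace = TRUE), nrow = B)
  freqs <- allele_frequencies(ds)
  mats <- vector("list", B)
  if (statistic == "fst") {
    for (b in seq_len(B)) {
      sub <- .subset_freqs(freqs, idx[b, ])
      mats[[b]] <- fst_pairwise(sub)
    }
  } else {
    ing <- .distance_ingredients(freqs, sizes)
    for (b in seq_len(B))
      mats[[b]] <- .dist_from_ingredients(ing, statistic, idx[b, ])
  }
  structure(list(B = B, indices = idx, matrices = mats,
                 statistic = statistic, seed = seed,
                 labels = freqs$pops),
            class = "bootstrap_replicates")
}

# allele_freqs restricted to (possibly repeated) locus indices
.subset_freqs <- function(freqs, loci_idx) {
  structure(list(pops = freqs$pops,
                 loci = make.unique(freqs$loci[loci_idx]),
                 tables = freqs$tables[loci_idx]),
            class = "allele_freqs")
}

#' Write / read a pairwise matrix as labelled CSV
#'
#' @param m A `pairwise_matrix`.
#' @param path Output path.
#' @return `path` invisibly (writer); a `pairwise_matrix` (reader).
#' @export
write_pairwise_csv <- function(m, path) {
  tab <- data.frame(population = rownames(m), unclass(m),
                    check.names = FALSE)
  utils::write.csv(tab, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_pairwise_csv
#' @param statistic Statistic tag to attach on read.
#' @export
read_pairwise_csv <- function(path, statistic = "unknown") {
  tab <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  labels <- tab[[1]]
  m <- as.matrix(tab[, -1, drop = FALSE])
  pairwise_matrix(m, labels, statistic)
}

#' Write a pairwise matrix as lower-triangle text
#'
#' The publication-style layout: header row of labels, one row per
#' population with values for the earlier populations only.
#'
#' @param m A `pairwise_matrix`.
#' @param path Output path.
#' @param digits Decimal digits (3 mirrors the usual distance tables).
#' @return `path`, invisibly.
#' @export
write_pairwise_triangle <- function(m, path, digits = 3) {
  labs <- rownames(m)
  con <- file(path, "w"); on.exit(close(con))
  writeLines(paste(c("", labs[-length(labs)]), collapse = "\t"), con)
  for (i in seq_along(labs)) {
    vals <- if (i == 1) character(0) else
      formatC(m[i, seq_len(i - 1)], digits = digits, format = "f")
    writeLines(paste(c(labs[i], vals), collapse = "\t"), con)
  }
  invisible(path)
}

#' Write a pairwise matrix in PHYLIP square format
#'
#' @param m A `pairwise_matrix`.
#' @param path Output path.
#' @param digits Decimal digits.
#' @return `path`, invisibly.
#' @export
write_pairwise_phylip <- function(m, path, digits = 6) {
  con <- file(path, "w"); on.exit(close(con))
  writeLines(sprintf("%5d", nrow(m)), con)
  for (i in seq_len(nrow(m))) {
    name <- formatC(substr(rownames(m)[i], 1, 10), width = -10)
    writeLines(paste0(name, paste(formatC(m[i, ], digits = digits,
                                          format = "f"), collapse = "  ")),
               con)
  }
  invisible(path)
}
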