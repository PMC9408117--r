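# Forward-time Wright-Fisher simulator of diploid microsatellite genotypes
# under the single-step stepwise mutation model (SMM), on a configurable
# population-split tree with optional symmetric migration; plus a
# frequency-level admixture generator and the study-shaped fixture.

#' Split-tree node constructors
#'
#' A population history is a rooted tree: internal nodes carry split times
#' in generations before present (strictly decreasing toward the tips),
#' leaves carry population names.
#'
#' @param time Split time in generations before present.
#' @param left,right Child nodes (further [split_node()]s or [leaf_pop()]s).
#' @return A nested-list tree node.
#' @export
split_node <- function(time, left, right) {
  list(time = as.numeric(time), children = list(left, right))
}

#' @rdname split_node
#' @param name Population label.
#' @export
leaf_pop <- function(name) list(name = as.character(name))

.tree_leaves <- function(node) {
  if (!is.null(node$name)) return(node$name)
  unlist(lapply(node$children, .tree_leaves))
}

.check_tree_times <- function(node, parent_time = Inf) {
  if (!is.null(node$name)) return(invisible(TRUE))
  if (node$time >= parent_time)
    stop("split times must strictly decrease toward the present (",
         node$time, " >= ", parent_time, ")")
  if (node$time < 1) stop("split time must be >= 1 generation")
  for (ch in node$children) .check_tree_times(ch, node$time)
  invisible(TRUE)
}

#' Stepwise-mutation-model simulation configuration
#'
#' @param split_tree A tree from [split_node()] / [leaf_pop()]; a single
#'   [leaf_pop()] simulates one unsplit population.
#' @param N_e Diploid population size per branch.
#' @param beta SMM mutation rate per allele copy per generation; each
#'   transmitted copy mutates with probability `beta`, moving one repeat
#'   unit up or down with equal probability.
#' @param L Number of loci.
#' @param founder_allele Founder repeat count (all copies identical at the
#'   start of the burn-in; recycled over loci).
#' @param sample_sizes Named integer vector: diploid individuals sampled per
#'   terminal population (`<= N_e`). Unnamed scalar = same size everywhere.
#' @param migration Symmetric per-generation migration rate between every
#'   pair of coexisting populations (fraction of individuals exchanged).
#' @param burnin Pre-split burn-in generations for the ancestral population
#'   to reach drift-mutation balance; default `10 * N_e` (five relaxation
#'   time constants of the within-population variance, which equilibrates
#'   on a `2 N_e`-generation scale).
#' @param size_bounds Optional L x 2 matrix of reflecting bounds (repeat
#'   units) restricting the allele-size walk.
#' @param motif_length Motif length recorded in the locus metadata.
#' @param seed Integer RNG seed.
#' @return A `sim_config` list.
#' @export
sim_config <- function(split_tree, N_e = 100L, beta = 1e-3, L = 20L,
                       founder_allele = 100L, sample_sizes = 30L,
                       migration = 0, burnin = NULL, size_bounds = NULL,
                       motif_length = 2L, seed = 1L) {
  .check_tree_times(split_tree)
  leaves <- .tree_leaves(split_tree)
  if (anyDuplicated(leaves)) stop("duplicate leaf names in split tree")
  if (beta < 0 || beta > 1) stop("beta must be in [0, 1]")
  if (migration < 0 || migration > 1) stop("migration must be in [0, 1]")
  if (is.null(burnin)) burnin <- 10L * N_e
  if (is.null(names(sample_sizes)))
    sample_sizes <- setNames(rep_len(sample_sizes, length(leaves)), leaves)
  if (!all(leaves %in% names(sample_sizes)))
    stop("sample_sizes must cover every terminal population")
  if (any(sample_sizes[leaves] > N_e))
    stop("sample_sizes must not exceed N_e")
  founder_allele <- rep_len(as.integer(founder_allele), L)
  if (!is.null(size_bounds)) {
    size_bounds <- matrix(as.numeric(size_bounds), ncol = 2)
    if (nrow(size_bounds) == 1) size_bounds <- size_bounds[rep(1, L), , drop = FALSE]
    if (any(founder_allele < size_bounds[, 1] | founder_allele > size_bounds[, 2]))
      stop("founder_allele outside size_bounds")
  }
  structure(list(split_tree = split_tree, N_e = as.integer(N_e), beta = beta,
                 L = as.integer(L), founder_allele = founder_allele,
                 sample_sizes = sample_sizes, migration = migration,
                 burnin = as.integer(burnin), size_bounds = size_bounds,
                 motif_length = as.integer(motif_length),
                 seed = as.integer(seed)),
            class = "sim_config")
}

#' Read a simulation configuration from a YAML file
#'
#' Declarative front end to [sim_config()]: scalar keys match the
#' `sim_config()` arguments; `split_tree` is a nested map of
#' `{time, left, right}` nodes with `{name}` leaves; `sample_sizes` may be
#' a map of population name to count; `size_bounds` a list of `[lo, hi]`
#' pairs.
#'
#' @param path Path to a YAML file.
#' @return A `sim_config`.
#' @export
read_sim_config <- function(path) {
  if (!requireNamespace("yaml", quietly = TRUE))
    stop("the 'yaml' package is required to read YAML configs")
  raw <- yaml::read_yaml(path)
  parse_node <- function(nd) {
    if (!is.null(nd$name)) return(leaf_pop(nd$name))
    split_node(nd$time, parse_node(nd$left), parse_node(nd$right))
  }
  if (is.null(raw$split_tree)) stop("config must define split_tree")
  args <- list(split_tree = parse_node(raw$split_tree))
  for (key in c("N_e", "beta", "L", "founder_allele", "migration",
                "burnin", "motif_length", "seed"))
    if (!is.null(raw[[key]])) args[[key]] <- raw[[key]]
  if (!is.null(raw$sample_sizes)) {
    ss <- unlist(raw$sample_sizes)
    args$sample_sizes <- ss
  }
  if (!is.null(raw$size_bounds))
    args$size_bounds <- do.call(rbind, raw$size_bounds)
  do.call(sim_config, args)
}

# One SMM mutation pass over a gene-copy matrix: each entry mutates with
# probability beta by +/- 1 repeat unit (equal probability), optionally
# reflected at per-locus bounds.
smm_mutate <- function(M, beta, size_bounds = NULL) {
  if (beta <= 0) return(M)
  nm <- stats::rbinom(1L, length(M), beta)
  if (nm == 0L) return(M)
  pos <- sample.int(length(M), nm)
  M[pos] <- M[pos] + sample(c(-1L, 1L), nm, replace = TRUE)
  if (!is.null(size_bounds)) {
    col <- (pos - 1L) %/% nrow(M) + 1L
    lo <- size_bounds[col, 1]; hi <- size_bounds[col, 2]
    v <- M[pos]
    v <- ifelse(v < lo, lo + (lo - v), v)
    v <- ifelse(v > hi, hi - (v - hi), v)
    M[pos] <- v
  }
  M
}

# One Wright-Fisher generation: random union of gametes with selfing
# allowed. Loci are unlinked (microsatellite panels sit on different
# chromosomes), so every locus resamples its parental copies
# independently: offspring copy j at locus l is a uniform random parental
# copy at locus l.
.wf_generation <- function(M, beta, size_bounds = NULL) {
  n2 <- nrow(M); L <- ncol(M)
  lin <- sample.int(n2, n2 * L, replace = TRUE) +
    rep.int((seq_len(L) - 1L) * n2, rep.int(n2, L))
  smm_mutate(matrix(M[lin], n2, L), beta, size_bounds)
}

# symmetric migration: every unordered pair of live populations exchanges
# Binomial(N, m) random individuals
.migrate <- function(pops_M, m) {
  k <- length(pops_M)
  if (k < 2 || m <= 0) return(pops_M)
  for (i in seq_len(k - 1)) for (j in (i + 1):k) {
    N <- min(nrow(pops_M[[i]]), nrow(pops_M[[j]])) %/% 2L
    nmig <- stats::rbinom(1L, N, m)
    if (nmig == 0L) next
    ii <- sample.int(nrow(pops_M[[i]]) %/% 2L, nmig)
    jj <- sample.int(nrow(pops_M[[j]]) %/% 2L, nmig)
    ri <- as.vector(rbind(2L * ii - 1L, 2L * ii))
    rj <- as.vector(rbind(2L * jj - 1L, 2L * jj))
    tmp <- pops_M[[i]][ri, , drop = FALSE]
    pops_M[[i]][ri, ] <- pops_M[[j]][rj, , drop = FALSE]
    pops_M[[j]][rj, ] <- tmp
  }
  pops_M
}

#' Simulate microsatellite genotypes under the SMM
#'
#' Forward-time Wright-Fisher simulation: a founder population (all copies
#' identical) evolves through `burnin` generations of drift-mutation
#' balance, then follows the split tree — each split copies the ancestral
#' gene pool into two daughter populations of size `N_e` — down to the
#' present, with optional symmetric migration between coexisting
#' populations. Terminal samples are drawn without replacement. Allele
#' codes are repeat counts.
#'
#' @param cfg A [sim_config()].
#' @return A [genotype_dataset()] with one population per tree leaf.
#' @export
simulate_smm <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(cfg$seed)
  L <- cfg$L; N <- cfg$N_e
  founder <- matrix(rep(cfg$founder_allele, each = 2L * N), 2L * N, L)
  # live populations: parallel lists of gene-copy matrices and subtrees
  Ms <- list(founder); nodes <- list(cfg$split_tree)
  for (g in seq_len(cfg$burnin))
    Ms[[1]] <- .wf_generation(Ms[[1]], cfg$beta, cfg$size_bounds)
  root_is_leaf <- !is.null(cfg$split_tree$name)
  t <- if (root_is_leaf) 0 else cfg$split_tree$time
  while (t > 0) {
    # split every population whose pending node splits at this time
    repeat {
      due <- which(vapply(nodes, function(nd)
        is.null(nd$name) && nd$time == t, logical(1)))
      if (!length(due)) break
      for (d in due) {
        nd <- nodes[[d]]
        Ms <- c(Ms, Ms[d]); nodes <- c(nodes, nd$children[2])
        nodes[[d]] <- nd$children[[1]]
      }
    }
    for (k in seq_along(Ms))
      Ms[[k]] <- .wf_generation(Ms[[k]], cfg$beta, cfg$size_bounds)
    Ms <- .migrate(Ms, cfg$migration)
    t <- t - 1
  }
  leaf_names <- vapply(nodes, function(nd) nd$name, character(1))
  ord <- match(.tree_leaves(cfg$split_tree), leaf_names)
  a1 <- list(); a2 <- list(); pop <- character(0); ids <- character(0)
  for (k in ord) {
    nm <- leaf_names[k]
    ns <- cfg$sample_sizes[[nm]]
    pick <- sort(sample.int(N, ns))
    M <- Ms[[k]]
    a1[[length(a1) + 1L]] <- M[2L * pick - 1L, , drop = FALSE]
    a2[[length(a2) + 1L]] <- M[2L * pick, , drop = FALSE]
    pop <- c(pop, rep(nm, ns))
    ids <- c(ids, paste0(nm, "_", seq_len(ns)))
  }
  loci <- locus_meta(paste0("locus_", seq_len(L)),
                     motif_length = cfg$motif_length)
  genotype_dataset(do.call(rbind, a1), do.call(rbind, a2), pop = pop,
                   individuals = ids, loci = loci)
}

# symmetric Dirichlet draw
.rdirichlet <- function(n, alpha) {
  x <- matrix(stats::rgamma(n * length(alpha), shape = alpha), n,
              length(alpha), byrow = TRUE)
  x / rowSums(x)
}

#' Simulate genotypes under the admixture model
#'
#' Frequency-level generator matching the Pritchard admixture model: each
#' individual carries ancestry proportions `Q_i` drawn from a symmetric
#' Dirichlet(`alpha`); every allele copy picks an ancestral cluster from
#' `Q_i` and an allele from that cluster's frequency profile. Individuals
#' of labelled group `k` have their ancestry vector rotated so its largest
#' component is cluster `k` (with balanced groups this keeps the symmetric
#' Dirichlet marginal while making labels meaningful). The true `Q` is
#' returned for recovery scoring.
#'
#' @param K Number of ancestral clusters.
#' @param sample_sizes Integer vector (length `K`) of individuals per
#'   labelled group.
#' @param L Number of loci.
#' @param alpha Symmetric Dirichlet concentration of individual ancestry;
#'   small values give near-pure individuals, and `0` gives exactly pure
#'   individuals (ancestry = group indicator).
#' @param profiles `"random"` (per-locus cluster profiles drawn from a
#'   Dirichlet over a shared allele set), `"disjoint"` (each cluster owns a
#'   private allele set — unambiguous structure), or a list of L matrices
#'   (K x alleles, rows summing to 1, integer allele codes as colnames).
#' @param n_alleles Alleles per locus (per cluster, for `"disjoint"`).
#' @param profile_concentration Dirichlet concentration for `"random"`
#'   profiles.
#' @param seed Integer RNG seed.
#' @return A list: `dataset` ([genotype_dataset()]), `Q` (true ancestry,
#'   individuals x K), `profiles` (list of K x alleles matrices).
#' @export
simulate_admixture <- function(K, sample_sizes, L = 10L, alpha = 0.1,
                               profiles = c("random", "disjoint"),
                               n_alleles = 4L, profile_concentration = 1,
                               seed = 1L) {
  set.seed(seed)
  sample_sizes <- rep_len(sample_sizes, K)
  n <- sum(sample_sizes)
  if (is.character(profiles)) {
    profiles <- match.arg(profiles)
    prof <- vector("list", L)
    for (l in seq_len(L)) {
      if (profiles == "disjoint") {
        A <- K * n_alleles
        p <- matrix(0, K, A)
        for (k in seq_len(K))
          p[k, (k - 1) * n_alleles + seq_len(n_alleles)] <- 1 / n_alleles
      } else {
        A <- n_alleles
        p <- .rdirichlet(K, rep(profile_concentration, A))
      }
      colnames(p) <- as.character(100L + seq_len(ncol(p)) - 1L)
      prof[[l]] <- p
    }
  } else prof <- profiles
  group <- rep(seq_len(K), sample_sizes)
  if (alpha == 0) {              # exact-pure limit: Q is the group indicator
    Q <- matrix(0, n, K)
    Q[cbind(seq_len(n), group)] <- 1
  } else {
    Q <- .rdirichlet(n, rep(alpha, K))
    for (i in seq_len(n)) {      # rotate: dominant component at group index
      mx <- which.max(Q[i, ])
      if (mx != group[i]) Q[i, c(mx, group[i])] <- Q[i, c(group[i], mx)]
    }
  }
  a1 <- matrix(NA_integer_, n, L); a2 <- matrix(NA_integer_, n, L)
  for (l in seq_len(L)) {
    p <- prof[[l]]
    codes <- as.integer(colnames(p))
    for (copy in 1:2) {
      z <- apply(Q, 1, function(q) sample.int(K, 1, prob = q))
      al <- vapply(z, function(k)
        codes[sample.int(length(codes), 1, prob = p[k, ])], integer(1))
      if (copy == 1) a1[, l] <- al else a2[, l] <- al
    }
  }
  ds <- genotype_dataset(a1, a2, pop = paste0("cluster_", group),
                         individuals = sprintf("ind_%03d", seq_len(n)),
                         loci = locus_meta(paste0("locus_", seq_len(L)),
                                           motif_length = 1L))
  list(dataset = ds, Q = Q, profiles = prof)
}

#' Study-shaped fixture specification
#'
#' The default preset mirrors the shape of the motivating Mediterranean
#' sheep panel: 11 breeds totalling 975 diploid individuals, 17
#' dinucleotide loci with published fragment-size windows, and pooled
#' per-locus allele counts targeting the published 16-38 range.
#'
#' @return A list with `populations` (named sample sizes), `loci` (a
#'   [locus_meta()] table), and the simulation scale parameters used by
#'   [make_study_fixture()].
#' @export
study_fixture_spec <- function() {
  pops <- c(BAR = 64L, QFO = 41L, CRO = 30L, DM = 28L, SS = 45L, NTH = 41L,
            ALP = 250L, BRO = 186L, FOZ = 118L, LAM = 141L, APP = 31L)
  panel <- utils::read.csv(system.file("extdata", "med_sheep_loci.csv",
                                       package = "msatpop"),
                           stringsAsFactors = FALSE)
  sz <- do.call(rbind, strsplit(panel$Size, "-", fixed = TRUE))
  loci <- locus_meta(panel$Locus, motif_length = 2L,
                     size_min = as.integer(sz[, 1]),
                     size_max = as.integer(sz[, 2]),
                     chromosome = panel$Chr)
  list(populations = pops, loci = loci, N_e = 300L, beta = 6e-3,
       migration = 2e-3)
}

#' Generate the study-shaped synthetic fixture
#'
#' An SMM simulation over an 11-leaf split tree with three depth phases —
#' deep splits (~2750 generations: the D'man, Apennine and Venetian
#' ancestries), intermediate splits (Maghrebian radiation), and recent
#' splits (Venetian breeds) — scaled so pooled per-locus allele counts fall
#' in the published 16-38 range for most loci. Repeat counts are converted
#' to fragment sizes (bp) inside each locus's published window. This is a
#' synthetic stand-in for the study's undeposited raw genotypes: it matches
#' their shape, not their values.
#'
#' @param seed Integer RNG seed.
#' @param spec A [study_fixture_spec()].
#' @param dir Optional directory; when given, GENEPOP, STRUCTURE and CSV
#'   copies are written there.
#' @return A [genotype_dataset()] with 975 individuals, 11 populations, 17
#'   loci (alleles in bp).
#' @export
make_study_fixture <- function(seed = 1L, spec = study_fixture_spec(),
                               dir = NULL) {
  # three-phase split topology (generations before present)
  venetian <- split_node(700,
    split_node(350, leaf_pop("LAM"), leaf_pop("FOZ")),
    split_node(400, leaf_pop("ALP"), leaf_pop("BRO")))
  maghreb <- split_node(600,
    leaf_pop("NTH"),
    split_node(450, leaf_pop("SS"),
               split_node(250, leaf_pop("BAR"),
                          split_node(120, leaf_pop("QFO"), leaf_pop("CRO")))))
  tree <- split_node(2750,
    split_node(1500, leaf_pop("APP"), maghreb),
    split_node(2400, leaf_pop("DM"), venetian))

  loci <- spec$loci
  L <- nrow(loci)
  # allele-size walk in repeat units, reflected inside the published bp
  # windows; founder at the window midpoint
  lo <- ceiling(loci$size_min / loci$motif_length)
  hi <- floor(loci$size_max / loci$motif_length)
  founder <- as.integer(round((lo + hi) / 2))
  cfg <- sim_config(tree, N_e = spec$N_e, beta = spec$beta, L = L,
                    founder_allele = founder,
                    sample_sizes = spec$populations,
                    migration = spec$migration,
                    burnin = 2L * spec$N_e,
                    size_bounds = cbind(lo, hi),
                    motif_length = 2L, seed = seed)
  ds <- simulate_smm(cfg)
  # repeat counts -> bp, and attach the published locus metadata
  a1 <- sweep(ds$a1, 2, loci$motif_length, `*`)
  a2 <- sweep(ds$a2, 2, loci$motif_length, `*`)
  out <- genotype_dataset(a1, a2, pop = as.character(ds$pop),
                          individuals = ds$individuals, loci = loci)
  if (!is.null(dir)) {
    if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
    write_genotypes(out, file.path(dir, "study_fixture.gen"), "genepop")
    write_genotypes(out, file.path(dir, "study_fixture.str"), "structure")
    write_genotypes(out, file.path(dir, "study_fixture.csv"), "csv")
  }
  out
}
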