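# Genotype data model and readers/writers for the three de-facto dialects
# used in microsatellite studies: GENEPOP, STRUCTURE two-row, and long CSV.

#' Locus metadata table
#'
#' Builds the locus metadata table used to validate allele codes and to
#' convert fragment sizes (bp) to repeat units.
#'
#' @param name Character vector of locus names.
#' @param motif_length Integer repeat-motif length in bp (e.g. 2 for
#'   dinucleotide microsatellites). Recycled.
#' @param size_min,size_max Optional integer bounds (bp) of the allele size
#'   window per locus; `NA` disables range validation for that locus.
#' @param chromosome Optional chromosome identifier per locus.
#' @return A `data.frame` with one row per locus.
#' @export
locus_meta <- function(name, motif_length = 2L, size_min = NA_integer_,
                       size_max = NA_integer_, chromosome = NA_character_) {
  name <- as.character(name)
  n <- length(name)
  meta <- data.frame(
    name = name,
    motif_length = as.integer(rep_len(motif_length, n)),
    size_min = as.integer(rep_len(size_min, n)),
    size_max = as.integer(rep_len(size_max, n)),
    chromosome = as.character(rep_len(chromosome, n)),
    stringsAsFactors = FALSE
  )
  if (anyDuplicated(meta$name)) stop("duplicate locus names in metadata")
  if (any(meta$motif_length < 1L, na.rm = TRUE)) stop("motif_length must be >= 1")
  bad <- !is.na(meta$size_min) & !is.na(meta$size_max) & meta$size_min > meta$size_max
  if (any(bad)) stop("size_min > size_max for locus ", meta$name[which(bad)[1]])
  meta
}

#' Diploid multi-allelic genotype dataset
#'
#' The central container: an ordered set of diploid individuals with one
#' population label each, genotyped at a shared panel of co-dominant loci.
#' Alleles are integer codes (fragment sizes in bp, or repeat counts for
#' simulated data); a missing genotype is a pair of `NA`s. Half-missing
#' genotypes are rejected. Within each genotype the two alleles are stored
#' in non-decreasing order so that equal datasets compare identical.
#'
#' @param a1,a2 Integer matrices (individuals x loci) holding the two allele
#'   codes of each genotype; `NA` in both marks a missing genotype.
#' @param pop Population label per individual (character or factor);
#'   population order is first appearance.
#' @param individuals Individual identifiers (unique). Defaults to rownames
#'   of `a1` or `ind_1 ... ind_n`.
#' @param loci Locus metadata from [locus_meta()], or a character vector of
#'   names. Defaults to colnames of `a1`.
#' @return An object of class `genotype_dataset` with elements `a1`, `a2`
#'   (canonically ordered allele matrices), `pop` (factor), `individuals`,
#'   and `loci` (metadata data.frame).
#' @export
genotype_dataset <- function(a1, a2, pop, individuals = NULL, loci = NULL) {
  a1 <- as.matrix(a1); a2 <- as.matrix(a2)
  storage.mode(a1) <- "integer"; storage.mode(a2) <- "integer"
  if (!identical(dim(a1), dim(a2))) stop("a1 and a2 must have identical dimensions")
  n <- nrow(a1); L <- ncol(a1)
  if (is.null(individuals)) {
    individuals <- rownames(a1)
    if (is.null(individuals))
      individuals <- as.character(sprintf("ind_%d", seq_len(n)))
  }
  individuals <- as.character(individuals)
  if (length(individuals) != n) stop("individuals length does not match rows")
  if (anyDuplicated(individuals))
    stop("duplicate individual id: ", individuals[anyDuplicated(individuals)])
  if (length(pop) != n) stop("pop length does not match number of individuals")
  pop <- as.character(pop)
  pop <- factor(pop, levels = unique(pop))
  if (is.null(loci)) {
    loci <- colnames(a1)
    if (is.null(loci)) loci <- as.character(sprintf("locus_%d", seq_len(L)))
  }
  if (!is.data.frame(loci)) loci <- locus_meta(loci, motif_length = NA_integer_)
  if (nrow(loci) != L) stop("loci metadata does not match number of columns")

  half <- xor(is.na(a1), is.na(a2))
  if (any(half)) {
    idx <- which(half, arr.ind = TRUE)[1, ]
    stop("half-missing genotype for individual '", individuals[idx[1]],
         "' at locus '", loci$name[idx[2]], "'")
  }
  # canonical within-genotype order
  lo <- pmin(a1, a2); hi <- pmax(a1, a2)
  a1 <- lo; a2 <- hi
  dimnames(a1) <- dimnames(a2) <- list(individuals, loci$name)

  for (j in seq_len(L)) {
    mn <- loci$size_min[j]; mx <- loci$size_max[j]
    if (!is.na(mn) && any(a1[, j] < mn | a2[, j] > mx, na.rm = TRUE)) {
      bad <- which(a1[, j] < mn | a2[, j] > mx)[1]
      stop("allele outside declared size range [", mn, ", ", mx,
           "] at locus '", loci$name[j], "' (individual '",
           individuals[bad], "')")
    }
  }
  structure(list(a1 = a1, a2 = a2, pop = pop,
                 individuals = individuals, loci = loci),
            class = "genotype_dataset")
}

#' @export
print.genotype_dataset <- function(x, ...) {
  cat("genotype_dataset:", length(x$individuals), "individuals,",
      nlevels(x$pop), "populations,", nrow(x$loci), "loci\n")
  cat("populations:", paste(levels(x$pop), table(x$pop)[levels(x$pop)],
                            sep = ":", collapse = " "), "\n")
  invisible(x)
}

#' Number of individuals / loci / populations
#' @param ds A `genotype_dataset`.
#' @return Integer count.
#' @export
n_individuals <- function(ds) length(ds$individuals)

#' @rdname n_individuals
#' @export
n_loci <- function(ds) nrow(ds$loci)

#' @rdname n_individuals
#' @export
n_populations <- function(ds) nlevels(ds$pop)

#' Read a genotype file
#'
#' Parses GENEPOP, STRUCTURE two-row, or long-CSV genotype files into a
#' validated [genotype_dataset()]. Individuals keep file order; populations
#' keep first-appearance order. Missing-data codes are normalised (`0` /
#' `000` in GENEPOP, `-9` in STRUCTURE, empty cell in CSV).
#'
#' @param path Path to the genotype file.
#' @param format One of `"genepop"`, `"structure"`, `"csv"`.
#' @param locus_meta Optional [locus_meta()] table; when given, its names
#'   override file locus names positionally and allele codes are validated
#'   against the declared size windows.
#' @return A `genotype_dataset`.
#' @export
read_genotypes <- function(path, format = c("genepop", "structure", "csv"),
                           locus_meta = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  parsed <- switch(format,
    genepop = .read_genepop(path),
    structure = .read_structure(path),
    csv = .read_csv_long(path)
  )
  loci <- parsed$loci
  if (!is.null(locus_meta)) {
    if (nrow(locus_meta) != length(loci))
      stop("locus_meta has ", nrow(locus_meta), " rows but file has ",
           length(loci), " loci")
    meta <- locus_meta
  } else {
    meta <- NULL
  }
  genotype_dataset(parsed$a1, parsed$a2, pop = parsed$pop,
                   individuals = parsed$ind,
                   loci = if (is.null(meta)) loci else meta)
}

.read_genepop <- function(path) {
  lines <- readLines(path, warn = FALSE)
  if (length(lines) < 2) stop("GENEPOP parse error: file too short")
  lines <- lines[!grepl("^\\s*$", lines)]
  # locus names: one per line (or a single comma-separated line) until "Pop"
  pop_rx <- "^\\s*[Pp][Oo][Pp]\\s*$"
  first_pop <- grep(pop_rx, lines)[1]
  if (is.na(first_pop)) {
    # empty dataset: title + locus lines only
    locus_lines <- lines[-1]
    loci <- unlist(strsplit(paste(locus_lines, collapse = ","), "\\s*,\\s*"))
    loci <- trimws(loci[nzchar(trimws(loci))])
    L <- length(loci)
    return(list(a1 = matrix(NA_integer_, 0, L), a2 = matrix(NA_integer_, 0, L),
                pop = character(0), ind = character(0), loci = loci))
  }
  loci <- unlist(strsplit(paste(lines[2:(first_pop - 1)], collapse = ","),
                          "\\s*,\\s*"))
  loci <- trimws(loci[nzchar(trimws(loci))])
  L <- length(loci)
  ind <- character(0); pop <- character(0)
  a1 <- list(); a2 <- list()
  pop_i <- 0L
  for (k in seq(first_pop, length(lines))) {
    line <- lines[k]
    if (grepl(pop_rx, line)) { pop_i <- pop_i + 1L; next }
    if (!grepl(",", line, fixed = TRUE))
      stop("GENEPOP parse error at line ", k, ": missing ',' after individual id")
    parts <- strsplit(line, ",", fixed = TRUE)[[1]]
    id <- trimws(parts[1])
    toks <- strsplit(trimws(paste(parts[-1], collapse = " ")), "\\s+")[[1]]
    if (length(toks) != L)
      stop("GENEPOP parse error at line ", k, ": expected ", L,
           " genotypes, found ", length(toks))
    g <- .split_genepop_alleles(toks, k)
    ind <- c(ind, id)
    pop <- c(pop, paste0("pop_", pop_i))
    a1[[length(a1) + 1L]] <- g[1, ]
    a2[[length(a2) + 1L]] <- g[2, ]
  }
  list(a1 = do.call(rbind, a1), a2 = do.call(rbind, a2),
       pop = pop, ind = ind, loci = loci)
}

# split "090092" / "9092" style diploid tokens; "000"/"00" codes are missing
.split_genepop_alleles <- function(toks, lineno) {
  w <- nchar(toks)
  if (any(w %% 2L != 0L))
    stop("GENEPOP parse error at line ", lineno,
         ": genotype token of odd width '", toks[which(w %% 2L != 0L)[1]], "'")
  half <- w %/% 2L
  x1 <- suppressWarnings(as.integer(substr(toks, 1L, half)))
  x2 <- suppressWarnings(as.integer(substr(toks, half + 1L, w)))
  if (anyNA(x1) || anyNA(x2))
    stop("GENEPOP parse error at line ", lineno, ": non-numeric allele code")
  x1[x1 == 0L] <- NA_integer_
  x2[x2 == 0L] <- NA_integer_
  rbind(x1, x2)
}

.read_structure <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!grepl("^\\s*$", lines)]
  if (length(lines) < 1) stop("STRUCTURE parse error: empty file")
  loci <- strsplit(trimws(lines[1]), "\\s+")[[1]]
  L <- length(loci)
  body <- lines[-1]
  if (length(body) %% 2L != 0L)
    stop("STRUCTURE parse error: odd number of genotype rows")
  n <- length(body) %/% 2L
  a1 <- matrix(NA_integer_, n, L); a2 <- matrix(NA_integer_, n, L)
  ind <- character(n); pop <- character(n)
  for (i in seq_len(n)) {
    r1 <- strsplit(trimws(body[2 * i - 1]), "\\s+")[[1]]
    r2 <- strsplit(trimws(body[2 * i]), "\\s+")[[1]]
    if (length(r1) != L + 2L || length(r2) != L + 2L)
      stop("STRUCTURE parse error: row for individual ", i,
           " has wrong column count")
    if (r1[1] != r2[1])
      stop("STRUCTURE parse error: row pair ", i, " has mismatched ids ('",
           r1[1], "' vs '", r2[1], "')")
    ind[i] <- r1[1]; pop[i] <- r1[2]
    v1 <- suppressWarnings(as.integer(r1[-(1:2)]))
    v2 <- suppressWarnings(as.integer(r2[-(1:2)]))
    if (anyNA(v1) || anyNA(v2))
      stop("STRUCTURE parse error: non-numeric allele for individual '",
           ind[i], "'")
    v1[v1 == -9L] <- NA_integer_
    v2[v2 == -9L] <- NA_integer_
    a1[i, ] <- v1; a2[i, ] <- v2
  }
  list(a1 = a1, a2 = a2, pop = pop, ind = ind, loci = loci)
}

.read_csv_long <- function(path) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE,
                         colClasses = c("character", "character", "character",
                                        "integer", "integer"))
  need <- c("individual", "population", "locus", "allele1", "allele2")
  if (!all(need %in% names(tab)))
    stop("CSV parse error: header must contain ", paste(need, collapse = ", "))
  ind <- unique(tab$individual)
  loci <- unique(tab$locus)
  n <- length(ind); L <- length(loci)
  a1 <- matrix(NA_integer_, n, L); a2 <- matrix(NA_integer_, n, L)
  ri <- match(tab$individual, ind); ci <- match(tab$locus, loci)
  if (anyDuplicated(cbind(ri, ci)))
    stop("CSV parse error: duplicate (individual, locus) record")
  a1[cbind(ri, ci)] <- tab$allele1
  a2[cbind(ri, ci)] <- tab$allele2
  pop <- tab$population[match(ind, tab$individual)]
  list(a1 = a1, a2 = a2, pop = pop, ind = ind, loci = loci)
}

#' Write a genotype file
#'
#' Serialises a dataset to GENEPOP (3-digit allele coding, one `Pop` block
#' per population), STRUCTURE two-row, or long CSV. All writers are
#' deterministic, and `read_genotypes()` on the output returns an equal
#' dataset (locus metadata other than names is not stored in the files).
#'
#' @param ds A `genotype_dataset`.
#' @param path Output path.
#' @param format One of `"genepop"`, `"structure"`, `"csv"`.
#' @param title Title line for GENEPOP output.
#' @return `path`, invisibly.
#' @export
write_genotypes <- function(ds, path, format = c("genepop", "structure", "csv"),
                            title = "msatpop export") {
  format <- match.arg(format)
  switch(format,
    genepop = .write_genepop(ds, path, title),
    structure = .write_structure(ds, path),
    csv = .write_csv_long(ds, path)
  )
  invisible(path)
}

.write_genepop <- function(ds, path, title) {
  mx <- suppressWarnings(max(ds$a2, na.rm = TRUE))
  if (is.finite(mx) && mx > 999L)
    stop("GENEPOP 3-digit coding cannot hold allele code ", mx)
  fmt <- function(x) ifelse(is.na(x), "000", sprintf("%03d", x))
  con <- file(path, "w"); on.exit(close(con))
  writeLines(title, con)
  writeLines(ds$loci$name, con)
  for (p in levels(ds$pop)) {
    writeLines("Pop", con)
    for (i in which(ds$pop == p)) {
      geno <- paste0(fmt(ds$a1[i, ]), fmt(ds$a2[i, ]), collapse = " ")
      writeLines(paste0(ds$individuals[i], " , ", geno), con)
    }
  }
}

.write_structure <- function(ds, path) {
  fmt <- function(x) ifelse(is.na(x), "-9", as.character(x))
  con <- file(path, "w"); on.exit(close(con))
  writeLines(paste(ds$loci$name, collapse = "\t"), con)
  for (i in seq_along(ds$individuals)) {
    writeLines(paste(c(ds$individuals[i], as.character(ds$pop[i]),
                       fmt(ds$a1[i, ])), collapse = "\t"), con)
    writeLines(paste(c(ds$individuals[i], as.character(ds$pop[i]),
                       fmt(ds$a2[i, ])), collapse = "\t"), con)
  }
}

.write_csv_long <- function(ds, path) {
  n <- length(ds$individuals); L <- nrow(ds$loci)
  tab <- data.frame(
    individual = rep(ds$individuals, each = L),
    population = rep(as.character(ds$pop), each = L),
    locus = rep(ds$loci$name, times = n),
    allele1 = as.vector(t(ds$a1)),
    allele2 = as.vector(t(ds$a2)),
    stringsAsFactors = FALSE
  )
  utils::write.csv(tab, path, row.names = FALSE, quote = FALSE, na = "")
}

#' Missing-data QC report and filter
#'
#' Per-locus and per-individual missing-call rates, with optional removal of
#' loci/individuals whose rate exceeds a threshold. A light stand-in for
#' dedicated genotyping-error screens: it reports data completeness only.
#'
#' @param ds A `genotype_dataset`.
#' @param max_locus_missing,max_ind_missing Optional rates in `[0, 1]`;
#'   loci/individuals with a strictly greater missing rate are dropped.
#' @return A list with `locus_rates`, `individual_rates`, the (possibly
#'   filtered) `dataset`, and character vectors `dropped_loci`,
#'   `dropped_individuals`.
#' @export
qc_missingness <- function(ds, max_locus_missing = NULL, max_ind_missing = NULL) {
  miss <- is.na(ds$a1)
  locus_rates <- colMeans(miss)
  ind_rates <- rowMeans(miss)
  dropped_loci <- character(0); dropped_ind <- character(0)
  keep_l <- rep(TRUE, n_loci(ds)); keep_i <- rep(TRUE, n_individuals(ds))
  if (!is.null(max_locus_missing)) {
    keep_l <- locus_rates <= max_locus_missing
    dropped_loci <- ds$loci$name[!keep_l]
  }
  if (!is.null(max_ind_missing)) {
    keep_i <- ind_rates <= max_ind_missing
    dropped_ind <- ds$individuals[!keep_i]
  }
  out <- ds
  if (!all(keep_l) || !all(keep_i)) {
    out <- genotype_dataset(ds$a1[keep_i, keep_l, drop = FALSE],
                            ds$a2[keep_i, keep_l, drop = FALSE],
                            pop = as.character(ds$pop)[keep_i],
                            individuals = ds$individuals[keep_i],
                            loci = ds$loci[keep_l, , drop = FALSE])
  }
  list(locus_rates = locus_rates, individual_rates = ind_rates,
       dataset = out, dropped_loci = dropped_loci,
       dropped_individuals = dropped_ind)
}

#' Subset a genotype dataset by population
#'
#' @param ds A `genotype_dataset`.
#' @param pops Character vector of population labels to keep (order kept as
#'   given).
#' @return A `genotype_dataset` restricted to those populations.
#' @export
subset_populations <- function(ds, pops) {
  if (!all(pops %in% levels(ds$pop)))
    stop("unknown population(s): ",
         paste(setdiff(pops, levels(ds$pop)), collapse = ", "))
  keep <- ds$pop %in% pops
  genotype_dataset(ds$a1[keep, , drop = FALSE], ds$a2[keep, , drop = FALSE],
                   pop = as.character(ds$pop)[keep],
                   individuals = ds$individuals[keep], loci = ds$loci)
}
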