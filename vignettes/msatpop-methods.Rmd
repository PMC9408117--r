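---
title: "Methods and design notes for msatpop"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods and design notes for msatpop}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(msatpop)
```

`msatpop` implements a complete microsatellite population-genetics
workflow of the kind used in livestock phylogeography: from diploid
genotype tables to diversity summaries, differentiation and gene flow,
genetic distances, bootstrapped neighbor-joining trees, divergence dating,
Bayesian admixture clustering, and DAPC. This vignette records the models,
the parameter choices that matter, and the design decisions that were
genuinely open, so that results produced with the package can be audited.

## Data model and conventions

A `genotype_dataset` holds diploid, multi-allelic genotypes: integer
allele codes per (individual, locus), one population label per individual.
Allele codes are fragment sizes in bp for lab data, or repeat counts for
simulated data; the two are related per locus by
`repeat = (bp - offset) / motif_length` (an `allele_size_map`). Missing
data conventions follow the de-facto file dialects — `000` in GENEPOP,
`-9` in STRUCTURE two-row files, empty cells in CSV — and are normalised
to an `NA` pair; half-missing genotypes are rejected at validation rather
than silently repaired. Frequencies are always computed over non-missing
gene copies (`2 x` observed individuals); nothing is imputed. Populations
keep first-appearance order and alleles are sorted ascending, so every
matrix the package writes is reproducible byte-for-byte.

## Diversity summaries

Per locus, over the pooled sample: the total number of alleles (TNA),
rarefied allelic richness, Botstein's PIC, and observed/unbiased expected
heterozygosity. Allelic richness uses the hypergeometric rarefaction
expectation

$$AR(g) = \sum_a \left[ 1 - \binom{N - N_a}{g} \Big/ \binom{N}{g} \right],$$

the expected number of distinct alleles in a subsample of $g$ gene copies.
$AR(1) = 1$ and $AR(N) = TNA$ identically. The rarefaction size $g$ is a
mandatory, logged parameter: the `"auto"` rule uses the smallest
per-population gene-copy count at each locus, which is the largest $g$
that every sampled population could support on its own. Pooled-sample
statistics are the default because panel characteristics tables are
conventionally reported for the pooled sample; per-population variants
are available through `heterozygosities(..., per_population = TRUE)`.
Expected heterozygosity uses Nei's unbiased correction $n/(n-1)$ on gene
copies. Summary rows use the arithmetic mean and the sample SD
($n - 1$ denominator).

## Differentiation and gene flow

$F_{ST}$ is the Weir–Cockerham moment estimator: per (locus, allele)
variance components $a$ (among populations), $b$ (among individuals
within), $c$ (within individuals), combined as the ratio of sums
$\hat\theta = \sum a / \sum (a+b+c)$ over loci and alleles. Negative
pairwise estimates are reported as computed — truncation would bias
summaries — except in the island-model transform
$Nm = (1 - F_{ST})/(4 F_{ST})$, where non-positive inputs map to an
infinite-migration sentinel with a warning. The island-model conversion
is a strong idealisation (equal-sized demes, symmetric migration at
equilibrium); the package reports it because it is the field's standard
summary, not because the assumptions are credible for livestock breeds.
Significance of pairwise $F_{ST}$ uses permutation of individuals between
the two populations (seeded, 999 permutations by default). A
leave-group-out helper recomputes the global partition without a chosen
set of populations, the usual check of how much a single divergent group
drives the among-breed percentage.

## Genetic distances

Three frequency-level measures, all averaging over loci arithmetically:

* molecular coancestry $f_{ij} = \frac{1}{L}\sum_l \sum_a p_{l,i,a}\,p_{l,j,a}$,
  the identity-in-state probability of two random copies, one per
  population (diagonal: within-population expected homozygosity);
* Nei's standard distance $D_S = -\ln(J_{XY}/\sqrt{J_X J_Y})$ with gene
  identities averaged over loci before the logarithm (the 1972
  convention, not the mean of per-locus distances);
* Goldstein's $(\delta\mu)^2 = \frac{1}{L}\sum_l (\mu_{l,X}-\mu_{l,Y})^2$
  on mean allele sizes.

$(\delta\mu)^2$ sizes are expressed in repeat units; bp data are converted
through the per-locus offset and motif length. The unit choice rescales
distances by a constant and therefore cancels in any analysis calibrated
in the same unit (including the divergence dating below when the mutation
rate is per repeat step). Populations with completely disjoint allele
sets give $J_{XY} = 0$; the resulting infinite $D_S$ is propagated as a
large finite sentinel (`1e9`) with a warning, because downstream
neighbor-joining needs finite inputs. Locus bootstrap resamples loci with
replacement, deterministic under a seed.

## Neighbor-joining and supports

`neighbor_joining` is the Saitou–Nei agglomeration with the
Studier–Keppler criterion. Two numerical policies make it deterministic
and printable: ties in the criterion minimum are broken by the lowest
(row, column) pair in the current label order, and negative branch
lengths are clamped to zero with the deficit moved to the sister branch,
preserving leaf-to-leaf path lengths (raw lengths are kept in an
attribute). On additive matrices no clamping occurs and the input metric
is reproduced exactly; the test suite verifies topology recovery on 100
random additive matrices against trees generated with `ape`. Bootstrap
supports are the percentage of replicate trees containing each internal
edge's leaf bipartition; trees are `ape` `phylo` objects and serialise to
Newick with supports as internal node labels.

## Divergence dating

Under the single-step stepwise mutation model (SMM), the expected
$(\delta\mu)^2$ between two populations that split $\tau$ generations ago
is $2\beta\tau$, with $\beta$ the mutation rate per copy per generation.
The package inverts this linearly: $\hat\tau = D/(2\beta)$, years
$= \hat\tau \times G$.

Defaults: $\beta = 1.2\times10^{-3}$ (a dinucleotide rate appropriate for
highly polymorphic sheep panels) and $G = 4.0$ years. The 4-year default
deserves a note: the literature on Mediterranean sheep also uses 3.5
years per generation, and both values are exposed in `dating_config()`.
The packaged published divergence-time matrix that ships with this
package is numerically consistent, cell for cell (maximum deviation 0.8
years, attributable to the 3-decimal rounding of the distance matrix),
only with $G = 4.0$; with 3.5 the same cells are off by thousands of
years. `reproduce_printed_tables()` makes this check reproducible
offline, and the package default follows the value the tables actually
encode rather than the value the accompanying text states.

This calibration inherits the SMM's assumptions: strict single-step
mutation, no range constraints, rate homogeneity across loci, and no
post-split gene flow. Violations (notably migration and allele-size
bounds) compress distances and bias dates downward; the dates are
comparative statements, not radiocarbon.

## Admixture clustering

`admixture_gibbs` is a Gibbs sampler for the Pritchard admixture model:
latent cluster origins per allele copy, Dirichlet($\lambda$ + counts)
updates for cluster allele frequencies, Dirichlet($\alpha$ + copy counts)
updates for individual ancestry. Two deliberate simplifications relative
to the full STRUCTURE model: $\alpha$ is fixed (default 1.0) rather than
Metropolis-updated, and the allele-frequency prior is uncorrelated
($\lambda = 1$). Both are adequate for the well-separated synthetic
fixtures this package validates against; for weakly structured real data
an inferred $\alpha$ mixes better, which is a known limitation. The
evidence estimate is the usual
$\hat L = \mathrm{mean}(\ln L) - \mathrm{var}(\ln L)/2$ over the thinned
post-burn-in trace. Model selection uses Evanno's
$\Delta K = |L''(K)|/\mathrm{SD}(K)$ over replicate runs (at least 3 per
K; 5 by default). $\Delta K$ cannot evaluate the end points of the K
range and is undefined when replicate runs agree to machine precision —
both cases are reported as `NA` rather than guessed.

Label switching across runs is resolved by permuting cluster columns to
maximise ancestry agreement with a reference run; the optimum is found by
exhaustive enumeration for $K \le 8$ (at most 40,320 candidates, exact)
and greedily above.

Default chain settings (burn-in 2000, 10,000 sweeps, thinning 10) are
sized for the package's synthetic fixtures, which are far easier targets
than real weakly-admixed data; all settings are recorded in the pipeline
run log.

## DAPC

Individuals are coded as allele-dosage vectors (0/1/2 per allele column;
missing genotypes receive the column mean), centered, reduced by PCA, and
discriminant axes are fit on the retained scores with `MASS::lda`. The
`"auto"` rule keeps the smallest number of components explaining 90% of
the variance, capped at $n - g$; retaining full rank makes the procedure
equivalent to plain discriminant analysis. A permutation test on the
first discriminant coordinate (between-group variance fraction under
label shuffling) guards against the method's known ability to manufacture
apparent separation from noise when too many components are retained.

## The synthetic-data generator

`simulate_smm` is a forward-time Wright–Fisher simulator: discrete
non-overlapping generations, random union of gametes with selfing,
constant diploid size $N_e$ per branch, single-step SMM mutation at rate
$\beta$ per copy per generation, optional symmetric migration between
coexisting populations, and an arbitrary rooted split tree with times in
generations. Loci are unlinked: every locus resamples its parental copies
independently, as appropriate for panels whose markers sit on different
chromosomes. This matters beyond realism — with fully linked loci the
across-locus mean of $(\delta\mu)^2$ concentrates on a single genealogy
realisation, whose distribution is right-skewed, and replicate means sit
well below $2\beta\tau$.

The founder population starts monomorphic and runs a pre-split burn-in,
default $10 N_e$ generations. The within-population allele-size variance
relaxes to its drift–mutation equilibrium ($2 N_e \beta$) on a $2 N_e$
generation time scale, so the default is five time constants —
equilibration above 99% — which is what the $E[(\delta\mu)^2] = 2\beta\tau$
identity assumes at the split.

`simulate_admixture` generates genotypes directly at the frequency level
under the same admixture model the Gibbs sampler fits: cluster profiles
(`"random"` Dirichlet draws, `"disjoint"` private allele sets, or
user-supplied), individual ancestry from a symmetric Dirichlet
($\alpha = 0$ giving exactly pure individuals), and the true ancestry
matrix returned for recovery scoring.

`make_study_fixture` emulates the *shape* of the motivating 11-breed
Mediterranean sheep panel: 975 individuals in the published per-breed
sample sizes, 17 dinucleotide loci with the published fragment-size
windows, and a three-phase split topology (deep ~2750-generation splits
for the most divergent ancestries, an intermediate Maghrebian radiation,
recent Venetian breed splits) with mild migration. Scale parameters
($N_e = 300$, $\beta = 6\times10^{-3}$, migration $2\times10^{-3}$,
reflecting size bounds at the published windows) were chosen once so that
pooled per-locus allele counts land in the published 16–38 range for most
loci. It is a synthetic stand-in for raw genotypes that were never
deposited: it matches their dimensions and marker characteristics, not
their values, so passing the pipeline on it demonstrates mechanics and
determinism, not reproduction of the study's inferential results. What
the fixture does not emulate: genotyping error and null alleles,
inbreeding and non-random mating within breeds, bottlenecks, mutation
rate heterogeneity across loci, and the complex admixture history of
crossbred populations.

## Validation problem sizes

The shipped test suite validates: estimator arithmetic against
hand-computed oracles; NJ against 100 random additive trees (4–10
leaves); the dating identity on 20 replicate two-population simulations
at $N_e = 500$, $\tau = 500$, $\beta = 10^{-3}$, 50 loci (mean
$(\delta\mu)^2$ within 30% of $2\beta\tau$); clustering recovery on
disjoint-profile fixtures (two clusters, 10 loci, 50 individuals per
population; ancestry $\ge 0.95$ to the true cluster for every individual)
and Evanno selection of $K = 3$ over $K = 1..5$ with 5 runs each; and the
full pipeline, twice, on the 975-individual fixture with reduced chain
and bootstrap settings, asserting byte-identical artifacts. These sizes
are the package's chosen validation scale: large enough for the
stochastic identities to resolve, small enough to run routinely.

## Known limitations

* The Nm transform assumes the island model at equilibrium; printed
  migrant numbers from other software frequently differ because the
  $F_{ST}$ plugged in differs, not because the formula does.
* Dating is linear in a single rate; no mutation-model corrections or
  coalescent-based estimators are provided.
* The Gibbs sampler has no linkage model, no correlated-frequency prior,
  and no location priors; it is not a general STRUCTURE replacement for
  weak structure.
* No null-allele estimation, Hardy–Weinberg exact tests, or linkage
  disequilibrium screens: the QC stage reports missingness only.
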