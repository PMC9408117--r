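# msatpop

Microsatellite population genetics and phylogeography in R: a tested,
reusable implementation of the classic livestock-diversity workflow, for
researchers analysing diploid multi-allelic genotype panels (sheep, goat,
cattle breed surveys and similar).

Given a genotype table (GENEPOP, STRUCTURE two-row, or long CSV), the
package computes:

* **Marker diversity** — allele counts, rarefied allelic richness
  `AR(g) = Σ_a [1 − C(N−N_a, g)/C(N, g)]`, Botstein's PIC, observed and
  unbiased expected heterozygosity, with panel summary rows.
* **Differentiation** — Weir–Cockerham F_ST (global, pairwise,
  leave-group-out) from per-(locus, allele) variance components
  `θ = Σa / Σ(a+b+c)`, permutation significance, the among/within
  variance partition, and island-model gene flow `Nm = (1−F_ST)/(4F_ST)`.
* **Genetic distances** — between-population molecular coancestry
  `f_ij = (1/L) Σ_l Σ_a p_{l,i,a} p_{l,j,a}`, Nei's standard distance
  `D_S = −ln(J_XY/√(J_X J_Y))`, and Goldstein's
  `(δµ)² = (1/L) Σ_l (µ_{l,X} − µ_{l,Y})²` on mean allele sizes.
* **Trees** — neighbor-joining (Studier–Keppler criterion, deterministic
  tie-breaking) with locus-bootstrap bipartition supports, as `ape`
  `phylo` objects and Newick files.
* **Divergence dating** — the stepwise-mutation-model calibration
  `E[(δµ)²] = 2βτ`, inverted to generations and years.
* **Population structure** — a Gibbs sampler for the admixture model
  (Q ancestry proportions, P cluster frequencies, data log-probability),
  Evanno's ΔK model selection over replicate runs, label alignment
  across runs, and DAPC on allele dosages.
* **A forward-time Wright–Fisher simulator** of microsatellite genotypes
  under the stepwise mutation model on an arbitrary population-split
  tree with migration — so every inference stage is testable end to end
  without restricted data.

## Worked example

Simulate two populations that split 500 generations ago under the SMM,
then estimate their divergence time back from the data:

```r
library(msatpop)

tree <- split_node(500, leaf_pop("A"), leaf_pop("B"))
cfg  <- sim_config(tree, N_e = 500, beta = 1e-3, L = 50,
                   sample_sizes = 50, seed = 1)
ds   <- simulate_smm(cfg)
ds
#> genotype_dataset: 100 individuals, 2 populations, 50 loci
#> populations: A:50 B:50

freqs <- allele_frequencies(ds)
d <- delta_mu2(freqs)
d["A", "B"]
#> [1] 1.143104

divergence_generations(d["A", "B"], dating_config(beta = 1e-3))
#> [1] 571.552
```

The estimate (571.6 generations against a true 500) is one draw of a
noisy estimator; across 20 replicate seeds the mean `(δµ)²` lands within
a few percent of the expected `2βτ = 1.0` (the test suite checks this at
a 30% tolerance per run batch).

The full pipeline over a genotype file, from the shell:

```sh
exec/msatpop run-all --input herd.gen --format genepop \
    --out results_dir --bootstrap 1000 --k-min 2 --k-max 6 --seed 1
```

writes the diversity table, F_ST/Nm/f_ij/D_S/(δµ)²/years matrices,
bootstrapped Newick trees, Q-matrices with an Evanno table, DAPC
coordinates, and a run log recording every parameter and derived seed.

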