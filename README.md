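# planmosaic

Intraindividual clone-sequence diversity analysis and a forward-time
simulator of the **mosaic Meselson effect** in planarians.

## The problem

Fissiparous planarians reproduce by tearing themselves in two and
regenerating; every new body is rebuilt from the parent's stem cells
(neoblasts), the only dividing cell type. Because no zygotic bottleneck ever
intervenes, somatic mutations accumulate independently in different neoblast
lineages *and* in the homologous allele copies within each cell. The result
is a single "individual" that is genetically a mosaic, carrying highly
divergent homologous alleles spread across its cells — a somatic, mosaic
version of the Meselson effect known from anciently asexual lineages. Sexual
populations of the same species pass through a single-cell zygote each
generation and show none of this.

The standard way to observe the effect is PCR amplification of one nuclear
and one mitochondrial locus from a whole-animal lysate, cloning of the
products, and Sanger sequencing of ~15 clones per individual. That design
brings its own artifact: polymerase errors during the first PCR masquerade
as low-frequency somatic variants and must be modelled and corrected before
any diversity statistic is computed.

`planmosaic` implements the full analysis chain for such datasets, plus an
agent-based simulator that generates synthetic clone datasets with the same
statistical structure, so every estimator can be benchmarked against a known
truth.

## What is inside

* **PCR fidelity model** — expected polymerase errors per product,
  `lambda = rate x L x cycles` (e.g. `2.28e-5 x 948 x 35 = 0.7565`,
  i.e. "75.65%"), with the Poisson `P(>=1 error) = 1 - exp(-lambda)`
  reported alongside; `recode_singletons()` applies the standard correction
  that recodes singleton sequences one mutation away from a nonsingleton.
* **Haplotype handling** — exact-match collapsing into frequency-ordered
  haplotype tables; translation under NCBI codes 1 (standard) and 9
  (echinoderm/flatworm mitochondrial); reading-frame checks.
* **Diversity and selection** — Nei's unbiased haplotype diversity
  *H*<sub>D</sub> = *n*(1 − Σ*p*<sub>i</sub>²)/(*n* − 1), nucleotide
  diversity π (mean pairwise difference per gap-free site), and
  Nei–Gojobori *Ka*/*Ks* (Ω) with pathway averaging and Jukes–Cantor
  correction; between-strategy comparisons via ANOVA + Tukey, Welch +
  Games–Howell or Kruskal–Wallis + Dunn, chosen by the usual normality and
  homoscedasticity diagnostics.
* **Three-level AMOVA** — among populations / among individuals within
  populations / within individuals, from squared pairwise differences with
  unequal-size expected-mean-square coefficients, Φ-statistics and
  permutation *p*-values (separate permutation schemes per level).
* **Median-joining networks** (ε = 0) with inferred median vectors, plus a
  quantitative operationalization of the star-like vs divergent
  intraindividual pattern dichotomy.
* **Simulator** — neoblast pools carrying nuclear allele copies and
  mitochondria, evolving under homeostatic turnover, binary fission with
  regeneration, and facultative sexual crosses with single-allele sperm,
  two-allele oocytes and a mitochondrial bottleneck. Emits FASTA/TSV bundles
  with a stored per-clone truth table.

## Worked example

A small synthetic dataset (two populations, two individuals each, ten
clones per individual) ships with the package:

```r
library(planmosaic)

ex   <- system.file("extdata", "synthetic_example", package = "planmosaic")
seqs <- read_fasta(file.path(ex, "nuclear.fasta"))
meta <- read_specimen_meta(file.path(ex, "specimens.tsv"))
css  <- build_clone_sets(seqs, meta)
css  <- lapply(css, function(cs) recode_singletons(cs)$clone_set)

do.call(rbind, lapply(css, diversity_stats))[, c("individual", "population",
                                                 "n", "h", "Hd", "pi")]
#>  individual population  n h    Hd      pi
#>   pop1_ind1       pop1 10 2 0.467 0.00389
#>   pop1_ind2       pop1 10 3 0.511 0.01315
#>   pop2_ind1       pop2 10 4 0.800 0.04000
#>   pop2_ind2       pop2 10 3 0.689 0.02296
```

Each row is one individual: `n` clones collapsed into `h` distinct
haplotypes, with haplotype diversity `Hd` and per-site nucleotide diversity
`pi`. Collapse across individuals and build the median-joining network:

```r
ht <- collapse_haplotypes(css)
ht
#> <haplotype_table> TMED9: 12 haplotypes, 4 individuals, 40 clones
median_joining(ht)
#> <haplotype_network> 12 haplotypes + 2 median vectors, 13 links, cost 18
classify_pattern(ht$counts[, "pop1_ind1"], seqs = ht$seq)
#> [1] "star_like"
```

Partition the variation hierarchically:

```r
set.seed(1)
amova_permutation(pairwise_differences(css), n_perm = 999)
#> <amova_result>
#>               level df    SS   sigma2 percent     p
#>   among_populations  1  27.6  1.10500 15.3047 0.337
#>   among_individuals  2  11.0 -0.06833 -0.9464 0.398
#>  within_individuals 36 222.6  6.18333 85.6417 0.022
#> Phi_CT = 0.153  Phi_SC = -0.01117  Phi_ST = 0.1436
```

Here 86% of the molecular variance lies *within* individuals — the mosaic
signature (the small negative among-individual component is reported as-is,
as classical AMOVA does). Simulating cohorts from scratch:

```r
cfg  <- sim_config(sex_prob = 0, seed = 42)   # strictly fissiparous
scen <- run_scenario(cfg)
cs   <- sample_clone_dataset(scen$populations[[1]][[1]], cfg, n_clones = 15)
```

`run_simulate()`, `run_recode()` and `run_analyze()` wrap these stages into
config-driven (YAML or list) file-to-file pipelines.

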