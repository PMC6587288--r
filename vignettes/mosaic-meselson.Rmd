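---
title: "Methods: intraindividual clone diversity and the mosaic Meselson simulator"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: intraindividual clone diversity and the mosaic Meselson simulator}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(planmosaic)
```

`planmosaic` analyses sets of cloned PCR amplicon sequences sampled from
single individuals — the experimental design used to detect somatic
mosaicism and within-individual allele divergence in fissiparous planarians
— and ships a forward-time simulator of the underlying biology so that
every estimator can be checked against a stored truth. This vignette is the
package's methodological record: the models, the defaults and why they were
chosen, the numerical conventions, and the known limits of what the tests
demonstrate.

## 1. The PCR error model and singleton recoding

A clone sequenced from a cloning experiment derives from one terminal
molecule of the first PCR, so polymerase errors accumulated along its
amplification lineage are indistinguishable from genuine somatic variants.
With a per-base per-cycle error rate $r$, amplicon length $L$ and $c$
cycles, the expected error count per product is

$$\lambda = r \cdot L \cdot c .$$

`expected_errors_per_product()` returns $\lambda$ (the quantity commercial
fidelity calculators print as a percentage — for the 948 bp nuclear
amplicon at $r = 2.28\times10^{-5}$ and 35 cycles, $\lambda = 0.7565$, i.e.
"75.65%") and also the Poisson probability of at least one error,
$1 - e^{-\lambda}$ (0.53 for the same settings). The two are often
conflated in write-ups; the package reports both and never treats
$\lambda$ as a probability.

`recode_singletons()` implements the standard correction: a sequence
sampled exactly once in an individual that lies exactly one mutation (one
differing alignment column, gaps counted as a fifth state) from a sequence
sampled at least twice is recoded as that sequence. Conventions, all
deliberate:

* singleton status is decided on the *pre-recoding* counts, in one
  simultaneous pass — the operation is idempotent and cannot cascade-merge
  chains of genuine variants;
* a singleton equidistant from several nonsingletons goes to the most
  frequent one, ties broken by lexicographically smaller sequence
  (deterministic, auditable);
* indel columns count toward the distance (a one-column gap difference is
  one mutation).

**What correction can and cannot achieve.** Under
$\mathrm{Poisson}(0.7565)$ noise, 46.9% of clones are error-free, 35.5%
carry one error and 17.6% carry two or more. A single-mutation rule cannot
touch the last class, so per-clone truth recovery is capped at 82.4%
regardless of implementation. Two further losses are intrinsic: a true
haplotype whose error-free copies happen to be sampled at most once offers
no nonsingleton anchor for its own artifacts, and genuine low-frequency
variants one mutation away from a major allele are recoded away. On
simulated fission-type individuals at the package defaults the measured
recovery is about 0.68 (about 0.78 for sexual-type individuals), with
idempotence holding in 100% of replicates; the acceptance suite asserts an
0.80 recovery target and therefore documents this shortfall as a failing
expectation rather than hiding it. Users should treat recoded datasets as
conservative with respect to low-frequency somatic variation.

## 2. Haplotypes, genetic codes, diversity and selection

Clones collapse to haplotypes by exact string equality including gap
columns (intron indels are real variation at an intron-containing nuclear
locus). IDs are `"<locus>-<k>"` by descending total count; ties break
lexicographically on the sequence so that IDs never depend on record order.

Translation uses NCBI code 1 (standard; nuclear exon) and code 9
(echinoderm/flatworm mitochondrial; Cox1), taken from Biostrings. The four
reassignments of code 9 relative to code 1 — AAA→Asn, AGA→Ser, AGG→Ser,
TGA→Trp — are asserted in the tests; codons containing gaps or `N`
translate to `X`, and stop codons are reported with their positions rather
than raised as errors.

Per-individual statistics (every clone is one observation; haplotype
frequencies are never reweighted):

* **Haplotype diversity**, Nei's unbiased
  $H_D = \frac{n}{n-1}\bigl(1 - \sum_i p_i^2\bigr)$; undefined (reported
  missing, not zero) for $n < 2$.
* **Nucleotide diversity** $\pi$: the mean proportion of differing sites
  over all unordered clone pairs, algebraically identical to the unbiased
  haplotype-frequency form $\frac{n}{n-1}\sum_{i<j} 2 p_i p_j d_{ij}$.
  Columns containing a gap or `N` anywhere in the individual's clone set
  are excluded (complete deletion *within the individual*, the default of
  standard polymorphism software). Whether pairwise or complete deletion is
  used matters only when gap columns are common; complete deletion was
  chosen as the declared, testable convention.
* **Ka, Ks, Ω**: the Nei–Gojobori proportion method. Synonymous site
  counts weight each codon position by the fraction of its three
  single-base changes that preserve the amino acid (changes to stops count
  as nonsynonymous); observed codon differences are classified by averaging
  over all substitution orderings, excluding pathways through stop codons
  unless all are blocked; codons containing gaps or `N` in either sequence
  of a pair are excluded for that pair. The proportions $p_N, p_S$ are
  averaged over all clone pairs and Jukes–Cantor corrected,
  $d = -\tfrac{3}{4}\ln(1 - \tfrac{4}{3}p)$, undefined for $p \ge 3/4$.
  $\Omega = K_a/K_s$; $K_s = 0 < K_a$ yields an `Inf` sentinel that group
  summaries exclude, and $K_a = K_s = 0$ is undefined.

**Group comparisons** follow the conventional decision tree: Shapiro–Wilk
per group at $\alpha = 0.05$; if all groups pass, Levene's test decides
between one-way ANOVA with Tukey HSD and Welch's F with Games–Howell;
otherwise Kruskal–Wallis with Dunn's post hoc. Dunn and Games–Howell are
implemented in-package (no installed dependency provides them); their
pairwise $p$-values are Holm-adjusted by default (the adjustment method is
an argument — the convention of the original analysis software is not
documented, so Holm was chosen as the safe default). Degenerate all-equal
input reports an omnibus $p = 1$ with a warning.

## 3. Three-level AMOVA

`amova_three_level()` decomposes squared pairwise difference counts into
among-population ($\sigma^2_a$), among-individual-within-population
($\sigma^2_b$) and within-individual ($\sigma^2_c$) components. Distances
are raw counts of differing columns (gaps as a fifth state), squared inside
the sums of squares — no Euclidean metric correction is applied, matching
the classical formulation. Group sums of squares are
$\mathrm{SS} = \sum_{i<j} d^2_{ij} / n$ within each grouping level, with
unequal-size coefficients in the expected mean squares. Conventions:

* negative variance components are reported as-is; a secondary
  `percent_truncated` column gives the display convention that truncates
  them at zero;
* $\Phi_{CT} = \sigma^2_a/\sigma^2$, $\Phi_{SC} =
  \sigma^2_b/(\sigma^2_b+\sigma^2_c)$, $\Phi_{ST} =
  (\sigma^2_a+\sigma^2_b)/\sigma^2$;
* permutation nulls per statistic: clones across everything
  ($\Phi_{ST}$), clones among individuals within populations
  ($\Phi_{SC}$), whole individuals among populations ($\Phi_{CT}$); $p =
  (\#\{\Phi^\ast \ge \Phi\} + 1)/(B + 1)$, never exactly zero. A level with
  no variation has an undefined $\Phi$ and reports $p = 1$.

The components are verified against an independent exhaustive-summation
implementation to $10^{-9}$ on random designs in the test suite. The
production default is 10,000 permutations; tests use fewer for speed.

## 4. Median-joining networks and the pattern classifier

`median_joining()` (with tolerance $\varepsilon = 0$) iterates: build the
minimum spanning network over the current node set (all links belonging to
some minimum spanning tree — Kruskal evaluated level by level); form the
position-wise majority consensus (median vector) of every connected
triplet; add the candidate that most reduces the network cost, defined as
the total weight of a minimum spanning tree over the node set (ties broken
by lexicographically smallest sequence); repeat to convergence; finally
delete median vectors of degree < 3. A column with three distinct states
keeps the state of the lexicographically first sequence of the triplet, so
builds are deterministic. Gap columns are a fifth character state (network
software conventions for indels vary by version; this one is declared and
tested). On binary instances of up to six haplotypes the resulting cost
equals the exhaustively enumerated Steiner-minimal network cost; with
$\varepsilon > 0$ links within $\varepsilon$ of minimal are retained
(pass-through support only).

The star-like vs divergent dichotomy is, in practice, a visual judgement
made on network plots; `classify_pattern()` is a deliberately simple, configurable
operationalization, labelled as a package convention in its documentation:
*star-like* iff the top one or two haplotypes hold at least 0.6 of the
clones *and* every minority haplotype lies within 2 differences of a top
haplotype; otherwise *divergent*. The 0.6/2 thresholds were fixed before
the simulator cohorts were evaluated and both are arguments.

## 5. The simulator

An individual is a pool of `n_neoblasts` stem cells; each carries `ploidy`
nuclear allele copies (length `L_n`) and `m_mito` mitochondrial sequences
(length `L_m`). Events:

* **Homeostasis**: each generation, `round(turnover * N)` neoblasts are
  replaced by mutated copies of surviving neoblasts; a dividing cell's
  mitochondria are resampled with replacement (intracellular drift).
  Substitutions per copied molecule are Poisson(`mu * L`), uniform
  positions, uniform alternative base; a nonsynonymous change in a coding
  column is rejected with probability `selection`.
* **Fission**: the pool splits uniformly into two halves; each half
  regrows to `N` by copying its own members with replacement. Both pieces
  survive; the population is culled uniformly to the carrying capacity
  `n_pop`.
* **Sexual cross**: sperm carries one allele from one paternal neoblast;
  the oocyte carries two distinct alleles plus two mitochondria drawn
  without replacement from one maternal neoblast (the oogenesis
  bottleneck). Gametes segregate existing alleles without new mutation —
  in this model mutations arise at neoblast divisions, not at
  gametogenesis. The offspring is non-mosaic: every neoblast an identical
  copy of the triploid zygote, the two zygotic mitochondria resampled up to
  `m_mito`. An optional `haploid_oocytes` flag produces diploid offspring
  instead (off by default).
* **Scenario**: `n_pop` copies of one homozygous, homoplasmic founder per
  population, `n_populations` isolated populations; each generation is
  homeostasis for everyone, then (with probability `sex_prob`) a round of
  random-pair crosses, otherwise fission of every lineage. Deterministic
  given `seed`.

The mechanism this captures: under pure fission the homologous allele
copies within a cell never pass through a zygote, so they diverge for the
whole simulated time — the Meselson effect — while neoblast lineages
acquire different mutations — mosaicism. Sexual reproduction resets both
every generation, leaving only population-level standing variation, and
gamete segregation caps the alleles an offspring can share with either
parent at its ploidy.

**Defaults and calibration.** `ploidy = 3`, `m_mito = 5`, `L_n = 948` with
a 197 bp exon (`coding_n = "1-197"`), `L_m = 649` fully coding under code
9 — the study system's geometry. `n_neoblasts = 8` keeps several
independent somatic lineages alive across fission bottlenecks while
remaining cheap; `n_pop = 20` and `generations = 200` define the scenario
scale; `turnover = 0.25` gives each lineage roughly one to two copy events
per generation. No measured per-division mutation rate exists for this
system, so `mu_n = mu_m = 3e-5` per site per division is a calibration
choice: it was fixed, together with the other defaults, by requiring that
the fission-vs-sexual contrast the analysis is designed to detect (higher
within-individual $H_D$ and $\pi$, divergent vs star-like patterns,
within-individual-dominated AMOVA) is expressed at desk scale — about six
mutations between homologous alleles after 200 fission generations versus
roughly one mutation of standing diversity in the sexual cohorts. These
are the shipped study conditions; the acceptance checks run at exactly
these values, with 50 replicates per cohort (100 sampled individuals per
strategy, 15 clones each) and two-population designs for the AMOVA
contrast.

**What the generator does and does not emulate.** It reproduces the
sampling design (about 15 clones per individual per locus), the polymerase
noise model with stored pre-noise truth, intraindividual haplotype counts
in the empirically observed ranges, and the qualitative star-like/divergent
dichotomy. It does not model spatial body structure, neoblast lineage
hierarchies, growth–degrowth energetics, ploidy changes, recombination
within the locus, or realistic planarian population sizes — neoblast pools
of 8 stand in for populations of hundreds of thousands of cells, with
mutation rates scaled up correspondingly. Passing tests therefore
demonstrate that the estimators recover the structure this model generates,
not that the model's rates are biologically measured quantities.

## 6. Numerical and interface conventions

* Alignment columns are 1-based inclusive everywhere a user sees them
  (`coding_ranges = "1-197"`); internal 0/1-based conversions are tested.
* FASTA input is validated strictly: IUPAC ambiguity codes other than `N`
  are rejected (cloned molecules should not be ambiguous), `U` maps to `T`,
  duplicate IDs and empty sequences are hard errors naming the offender.
  End-trimming of ragged alignments is the caller's responsibility: the
  package validates equal lengths but never trims.
* The metadata TSV has a fixed header; unknown columns are ignored with a
  warning, missing ones are errors.
* All stochastic entry points consume R's global RNG; scenario configs
  carry a mandatory seed and every pipeline run writes a JSON manifest
  (package version, R version, config) sufficient to reproduce it.
* Test problem sizes: oracle equivalence uses 200 random clone sets (up to
  20 clones x 50 columns), 50 random AMOVA designs (up to 12 clones), and
  25 binary network instances (up to 6 haplotypes, length 8); the
  simulator cohorts use 50 replicates x 200 generations per strategy. These
  sizes make the full suite run in a few minutes on one CPU while keeping
  Monte-Carlo standard errors well inside the asserted margins.

## 7. Known limitations

* Ka/Ks uses the original proportion method, not maximum-likelihood codon
  models; with a handful of mutations per individual the estimates are
  noisy and Ω group means exclude infinite sentinels.
* The AMOVA treats the three-level design per reproductive strategy
  (separate runs per strategy, as the figure-level presentation of such
  analyses suggests) rather than adding strategy as a fourth level.
* The pattern classifier is a sharp-threshold surrogate for a visual
  judgement; near-threshold individuals are sensitive to the 0.6/2
  settings.
* Median-joining is a heuristic: Steiner-optimality is verified
  exhaustively only on small binary instances, which is where exhaustive
  verification is feasible.
* The recoding correction is biased against genuine low-frequency somatic
  variants by construction (Section 1); its truth-recovery ceiling under
  the default noise model is 82.4%.
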