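---
title: "Population genetics of somatic evolution in antibody repertoires"
author: "repevol"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Population genetics of somatic evolution in antibody repertoires}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(repevol)
```

# The analysis

B-cell receptor repertoires evolve somatically: affinity maturation mutates
the rearranged heavy-chain variable region and selects variants that bind
antigen better. `repevol` treats each clonal lineage — the set of unique
sequences descending from one naive ancestor — as an asexual population and
asks, from a snapshot of its genetic diversity, which evolutionary regime
produced it.

The pipeline has seven stages.

1. **Lineage identification.** Sequences are grouped by subject, V gene,
   J gene and CDR3 length, then single-linkage clustered at ≥ 90%
   nucleotide identity (`clusterLineages()`). Ties at exactly the cutoff
   link. Identity is computed across the CDR3 and the rest of the variable
   region when sequences are column-comparable, with a CDR3-only scope
   available (`clusterConfig()`).
2. **Dynamics.** Fractional abundance of a lineage at a timepoint is its
   unique-sequence count divided by the subject's total unique sequences
   then. Lineages expanding more than 50-fold from vaccination day (D0) to
   day 7 are *vaccine-responsive* (an infinite fold change — detected at D7
   but not D0 — qualifies); lineages below 2-fold change with more than
   0.1% of the repertoire at D7 are *persistent*; the rest are *other*
   (`classifyLineages()`). Germline gene usage contrasts use a two-sided
   Fisher exact test at the lineage level.
3. **Site frequency spectra.** Somatic point mutations are called per
   member against the personalized germline V and J sequences; CDR3
   positions are excluded because the junction's ancestral state is not
   known with confidence. A segregating site is a (position, derived base)
   pair; its derived count is the number of unique sequences carrying it,
   pooled across timepoints; sites carried by all members are fixed
   differences kept out of ξ (`buildSFS()`).
4. **Selection tests.** Fay & Wu's H = θπ − θH contrasts pairwise diversity
   with a high-frequency-weighted diversity; an excess of high-frequency
   derived alleles — the hitchhiking footprint of selective sweeps — drives
   it negative. Significance is empirical: genealogies are simulated under
   a null model with the lineage's sample size, exactly S mutations are
   placed proportionally to branch length, and the observed statistic is
   ranked in the simulated distribution (lower tail, add-one correction).
   Null models: constant-size Kingman coalescent, exponentially expanding
   Kingman, and the Bolthausen–Sznitman (BSZ) multiple-merger coalescent
   for continuous adaptation (`testSelection()`, `nullDistribution()`).
5. **Subclone sweeps.** Within a lineage phylogeny, a greedy breadth-first
   search scores every clade of ≥ 50 leaves by the H statistic of its
   clade-restricted spectrum against a size- and S-matched Kingman null;
   a significant clade is reported and its descendants are not visited, so
   reported subclones are never nested (`detectSelectedSubclones()`). The
   per-clade threshold is calibrated on neutral simulations to a 1%
   lineage-level false discovery rate (`calibrateAlpha()`).
6. **Fitness inference.** The local branching index (LBI) of a node is the
   surrounding tree length discounted exponentially with distance at
   timescale τ; dense recent branching marks high fitness. Branches are
   ranked by parent-to-child LBI change, and the mutations on the top and
   bottom three branches per lineage are pooled for regional dN/dS
   (`localBranchingIndex()`, `regionalDndsEnrichment()`).
7. **Cross-stage summaries.** Selection scores versus clonal expansion:
   Spearman correlation (infinite fold changes at the top shared rank),
   two-sided Mann–Whitney U between selected and nonselected lineages, and
   exceedance curves over fold-change cutoffs (`selectionVsExpansion()`).

# The test statistic: why H is normalized

The package computes the classical unnormalized H (and exposes it as
`fayWuH()`), but the shipped test statistic is its diversity-normalized
form

$$H^* = \frac{\theta_\pi - \theta_H}{\theta_\pi + \theta_H} \in [-1, 1].$$

The reason is measurable and decisive. Conditioned on n and S, the Kingman
null's raw-H distribution is dominated by tree-scale fluctuations: one deep
branch subtending, say, 60–95% of the sample collects a binomial share of
the S mutations and pushes H far negative, so the null's lower tail is
heavy. The BSZ alternative concentrates its diversity in singletons, making
its raw H small in magnitude — and the one-sided test has essentially *no*
power (0–3% at p < 0.05 across n = 500–1000, S = 30–600 in our
simulations). Dividing by total diversity removes the scale: under the
null, H* fluctuates in a narrow band, while BSZ spectra — tiny θπ against
appreciable θH — sit far in the lower tail. Measured power at p < 0.05 is
20–31% for BSZ lineages with n ≥ 500 (5–6 times the 3–7% type-I rate),
consistent with the detection rates reported for vaccine-responsive
lineages in the study this package models. The sign convention matches H,
and empirical p-values make no distributional assumption either way.

The BSZ simulator itself uses the standard rates: with k lineages, b of
them (2 ≤ b ≤ k) merge at total rate k/(b(b−1)), so the overall merger rate
is k − 1 and merger sizes follow P(b) ∝ 1/(b(b−1)). We cross-checked the
per-frequency-class branch-length profile against msprime's Beta-coalescent
at α close to 1 during development; the test suite checks the merger-size
proportions and the k = 2 rate analytically.

# The nonmonotonicity statistic

The supplementary statistic for the sweep signature is the largest increase
between adjacent bins of the binned spectrum. Two normalization choices are
ours: bin masses are divided by bin width (log-spaced edges otherwise make
wide mid-frequency bins of a 1/i spectrum look like upticks), and only bins
above frequency 0.2 enter (both neutral and adaptive spectra concentrate
overwhelming mass in singletons, which would drown the uptick). With these
choices BSZ-simulated lineages score higher than Kingman-simulated ones
(means ≈ 0.52 vs 0.27 at n = 200), as intended.

# Null conditioning and empirical p-values

Nulls condition on the observed number of segregating sites (fixed-S), the
standard coalescent-test convention, which removes the nuisance mutation
rate. The fixed-S construction is implemented two ways: explicitly
(simulate the genealogy, place S mutations on branches proportional to
length) and through per-frequency-class branch-length totals computed in C,
which is distributionally identical and fast enough for the sweep-FDR
calibration (a thousand 1000-leaf lineages, each with tens of clades and a
1000-replicate null per clade). The test suite verifies the two engines
agree by Kolmogorov–Smirnov test. Empirical p-values use the add-one
correction, p = (1 + #{null ≤ observed})/(R + 1), so p is never 0 and is
uniform on its achievable grid under matched nulls (also tested).

# Sweep detector calibration

`calibrateAlpha()` simulates neutral lineages at the sizes of interest,
records every qualifying clade's p-value, and returns the largest grid
threshold at which the fraction of lineages with at least one detection
stays within the target FDR. Because greedy pruning only stops descent
*below* a significant clade, a lineage triggers at threshold α exactly when
the minimum clade p is below α, so one simulation batch calibrates the
whole grid. Two subtleties set the shipped defaults. First, with
R-replicate nulls the smallest achievable p is 1/(R+1), so R = 1,000
cannot express thresholds below 0.001; the default uses 2,000-replicate
per-clade nulls so that α = 5 × 10⁻⁴ is achievable. Second, calibration at
the stated world (1,000-leaf Kingman lineages, θ = 10, minimum clade size
50, about 38 qualifying clades per tree, 1% target) puts α = 0.001 *at*
the target within sampling error — realized neutral rates of 0.8–1.1%
across batches of 500–1,000 lineages. A threshold whose true
false-discovery rate straddles the guarantee is a poor default, so the
shipped `defaultPerCladeAlpha()` is the next stricter grid value,
α = 5 × 10⁻⁴, with a realized neutral rate of ≈ 0.6%. A consequence worth stating plainly: at
a threshold this strict a *single* plain-BSZ lineage of 1,000 leaves
yields a detection in only ~10% of replicates — twenty-odd times the
neutral rate, but far from a majority. Reliable per-lineage detection at
1% FDR requires the stronger, classic post-sweep clade structure (a
dominant subclade behind a mutation-laden stem), which is what the
constructed fixtures in the test suite use.

# The synthetic world

`generateRepertoire()` emits a complete multi-subject, multi-timepoint
repertoire with ground truth. Its stated world:

* **Scale.** The `"study"` profile mirrors the study design: 5 subjects,
  8 timepoints (D−5 … D11), ~36 vaccine-responsive and ~83 persistent
  lineages per subject. The `"tiny"` profile (2 subjects, 5 lineages each)
  is the test-suite default.
* **Germline references.** Random in-frame V genes (294 nt tiling FWR1 75,
  CDR1 24, FWR2 51, CDR2 24, FWR3 114, CDR3 flank 6) and J genes (45 nt:
  CDR3 flank 9, FWR4 36), stop-free in frame 0; region lengths are
  multiples of 3 so codons never straddle boundaries. Each lineage gets a
  distinct (V, J, CDR3-length) key within its subject, so the generating
  partition is recoverable; same-key separation by CDR3 divergence is
  exercised separately in the tests.
* **Regimes and mutation loads.** Responsive lineages draw BSZ genealogies
  (θ = 6) plus 12 pre-study fixed mutations (their affinity-maturation
  history, raising mutation density without inflating within-lineage
  diversity); persistent lineages draw Kingman genealogies (θ = 3, no
  fixed mutations); other lineages Kingman at θ = 6. These values keep the
  responsive-vs-persistent mutation-density contrast of the study while
  holding every lineage together at the 90% single-linkage cutoff on a
  ~350 nt axis.
* **Observation patterns.** A persistent lineage's unique sequences are
  observed at *every* timepoint (that is what stable dynamics means);
  responsive and other lineages place each unique sequence at one
  timepoint by largest-remainder allocation of the class trajectory.
  Responsive trajectories are zero before D1 (so their fold change is
  infinite, as for most such lineages in the study); other-class lineages
  surface as a single sequence at D0 and peak at D7 between the 2- and
  50-fold thresholds.
* **Drivers.** With `cdrBias > 0`, each backbone branch (stem of a clade
  holding ≥ 5% of leaves) carries a Poisson number of driver mutations:
  CDR changes at second codon positions, where any substitution is
  nonsynonymous in every haplotype context. This makes the designed CDR
  enrichment / FWR depletion of top-fitness branches causal rather than
  incidental.
* **Uniqueness.** Coalescent leaves with identical genotypes are collapsed
  at generation time; the recorded ground-truth SFS is computed on the
  collapsed sample over callable positions, so `buildSFS()` on the emitted
  records reproduces it exactly — a closed-loop identity, not a tolerance.

What the generator does **not** emulate: junction (VDJ) diversity within a
lineage, sequencing error, isotype switching over time, indels, and the
very large unique-sequence counts of real persistent lineages (with a
semi-realistic θ, the number of distinct genotypes is bounded by the number
of segregating sites, far below the 100–11,000 unique sequences seen in
deep sequencing; real uniqueness is largely junctional). A green closed
loop therefore establishes internal consistency of the pipeline, not
external validity on sequencing data.

# Numerical choices and conventions

* Coordinates are 0-based half-open on the germline axis V ++ CDR3 ++ J;
  CDR3 junction positions sit between the annotated segments.
* The expanding-model growth rate defaults to 25 per coalescent time unit,
  calibrated once so the expected singleton fraction at n = 100 (≈ 0.44)
  sits midway between Kingman (≈ 0.19) and BSZ (≈ 0.70); it is exposed as
  configuration and reported in outputs.
* Mutation calling treats N as missing, never a mismatch; members covering
  less than half the callable positions are excluded with a warning.
* Neighbor joining runs on Hamming distances over alignment columns;
  negative branch lengths are clamped to zero; trees are rooted on the
  germline leaf, which fixes the ancestral state. Externally built trees
  import through Newick with strict label matching.
* Fitch parsimony assigns ancestral states top-down preferring the parent
  state (ties break toward the germline), which minimizes early changes;
  the root state is fixed to the germline base where compatible.
* LBI's τ defaults to 0.0625 × the mean root-to-leaf distance, the
  published convention; fitness of a sequence is the LBI of its leaf, and
  branch ranking breaks ties by clade size then node id.
* dN/dS bootstraps resample lineages, not mutations, respecting
  within-lineage correlation; enrichment is undefined (NA) wherever a
  stratum has no synonymous mutations.
* Infinite fold changes sort above any finite value, satisfy any "> k"
  cutoff, and map to the top shared rank in correlations.
* All randomness flows from user-supplied seeds; fixed seeds give
  byte-identical outputs.

# Known limitations

* The H*-based test, like the raw-H test, loses power on small lineages;
  at n below a few hundred unique sequences most adaptively evolving
  lineages go undetected, mirroring the sensitivity limits discussed in
  the study.
* Single-linkage at 90% can split a heavily diverged lineage when sampling
  is sparse (no intermediate genotypes to chain through); this is a
  property of the method at low sampling density, not of the
  implementation.
* The internal NJ builder is a deliberate dependency-light substitute for
  external maximum-likelihood tools; results depending on fine branch
  lengths (LBI) will differ slightly from FastTree-based pipelines, which
  can be imported via Newick instead.
* The per-clade sweep test conditions on the clade's own S; clades whose
  selection signal lives entirely on their stem (fixed within the clade)
  are invisible to it by construction, which is why the detector descends
  from the root rather than testing the root itself.
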