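---
title: "Copy-number lineage analysis: models, parameters and design choices"
author: "gclineage"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Copy-number lineage analysis: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gclineage)
```

## The problem and the model

Gland-forming gastric neoplasms confined to the mucosa vary widely in
outcome, and morphology alone predicts progression poorly. The premise of
this analysis is that a tumour's genome-wide copy-number alteration (CNA)
profile is a lineage marker: alterations accumulate along a tumour's
history, profiles of related samples stay similar, and tumours fall into a
small number of lineages of different genomic instability. Clustering
samples by profile similarity therefore yields groups — *stable*,
*intermediate*, *unstable* — that stratify progression risk, with invasive
disease concentrating in the unstable lineage.

The measurement is two-colour array CGH on FFPE material: per probe, the
base-2 log of the tumour/reference intensity ratio, `log2(T/R)`, is 0 for a
diploid locus, `log2(3/2) ≈ +0.585` for a one-copy gain and
`log2(1/2) = −1` for a one-copy loss. FFPE plus whole-genome amplification
makes single probes noisy and introduces a locus-dependent amplification
bias; two properties of the design mitigate this, and both are modelled
here. First, the bias is reproducible across samples and affects both
channels, so it cancels in the T/R ratio (as do germline copy-number
variants). Second, averaging the probes within a gene shrinks independent
probe noise by `1/sqrt(n_probes)`, which is why the clustering prefers
genes with many probes.

## Pipeline stages and their parameters

**Gene averaging.** A probe belongs to a gene iff its midpoint lies inside
the gene interval; all coordinates are 0-based, half-open (BED convention).
The source analyses do not state an assignment rule for edge-straddling
probes; midpoint containment was chosen because it is unambiguous and
assignment-stable under small interval changes (a stricter full-overlap
assignment is available via `assignment = "full_overlap"`). Missing probe ratios are
excluded from the mean (never imputed); a gene's value is missing only when
all its probes are missing. Genes that acquire no probes are dropped —
"gene regions" downstream always means the post-assignment gene set.

**CNA calling.** Gain iff `log2(T/R) > 0.3219`, loss iff `< −0.3219`,
i.e. a 1.25-fold change; comparisons are strict because the definition is
stated with strict inequalities. An inclusive mode exists
(`cna_call_params(strict = FALSE)`). Per-sample burden is reported both as
a count and as the fraction of non-missing genes, because the count depends
on the size of the gene set while the fraction is comparable across gene
filters.

**Arm penetrance.** There is no single convention for chromosome-level
CNA calling from gene-level states; this package uses an explicit rule — a sample
carries an arm gain (loss) iff ≥ `arm_fraction_threshold` (default 0.5) of
the arm's called genes share that state — and reports the percentage of
samples per group. The threshold is exposed because it is an artifact
decision, not an estimated quantity.

**Distance and linkage.** The uncentred correlation distance
`d = 1 − Σxy/(‖x‖‖y‖)` is Pearson's formula without mean-centring (range
[0, 2]): profiles are compared against the fixed diploid baseline at 0, so
two flat profiles are similar regardless of their means. Missing values are
handled pairwise-complete inside the distance (at least two complete pairs
required); an all-zero vector has no defined direction and is an error
rather than a silent 0/0. Agglomeration is complete linkage (inter-cluster
distance = maximum pairwise member distance), implemented in the package
with an explicit deterministic tie-break — among equally distant pairs, the
pair whose clusters contain the smallest original item indices merges first
— so results are invariant to input order. The implementation is verified
in the tests against both a naive O(n³) re-agglomeration oracle and
`stats::hclust`.

**Model selection (gene-size sweep).** Clustering is repeated at minimum
probe counts 10, 6, 4, 3, 2 (largest genes first). Two standards score each
threshold: samples of the same tumour should sit at neighbouring positions
in the dendrogram, and the k = 3 partition should stop changing as the gene
set grows. "Neighbouring positions" is implemented as the *sibling*
relation (the two leaves merge with each other before anything else)
because displayed leaf adjacency is ambiguous under the arbitrary
left/right flips of a drawn dendrogram (`adjacency = "leaf_order"`
reproduces the looser criterion on the package's drawn ordering). The selected threshold is the
largest one whose partition equals the next smaller threshold's partition
and whose same-tumour adjacency is maximal — "largest" is read as the
largest minimum-probe threshold, consistent with selecting a gene-size
condition rather than a per-gene criterion. The sweep runs on the combined
mucosal + deep sample set (that is where same-tumour pairs exist), while
the final lineage call is made on the mucosal samples, where progression
risk is the question of interest.

**Lineage labels.** At k = 3, the cluster with the lowest mean CNA burden
is *stable*; of the remaining two, the larger is *unstable* and the other
*intermediate*. The size rule (rather than a second burden comparison)
matches the observed structure — the unstable lineage dominates invasive
disease and is the larger of the two high-burden clusters — and exact ties
abort with a request for a manual cluster→label map rather than guessing.

**Differential screen.** Per contrast, a Welch (unequal-variance) t-test
per gene on the averaged log2 ratios, `p` adjusted by Bonferroni with
m = the number of genes actually tested in that contrast. Genes failing the
preconditions (a group with < 2 values, or zero variance in both groups)
are recorded as untestable, never dropped silently. Five contrasts are
screened; the combination into one gene set is a design choice here: the
*union* rule (significant in ≥ 1 contrast) is the default and the
per-contrast sets and their intersection are also returned. Contrast
multiplicity is reported, not corrected: m counts genes within a contrast,
not 5× genes, matching per-comparison presentation. `alpha` defaults to
0.05 on the adjusted p.

**Phenotype statistics.** Marker scores use the bands −: [0, 5),
+: [5, 30), ++: [30, 60), +++: [60, 100]; positivity for classification is
score ≥ "+", the only threshold the scoring system supplies. Gastric
positivity is MUC5AC and/or MUC6, intestinal MUC2 and/or CD10; G/GI/I/N is
the four-way combination and is total over all 4⁴ score patterns (tested
exhaustively). The Cochran–Armitage trend statistic uses scores 1..k and a
two-sided asymptotic normal p; the default outcome dichotomy is "expresses
gastric markers (G or GI) vs not", which is the comparison the grouped
results report — the full phenotype ordering is a config option flagged as
an interpretation. Fisher's exact test is two-sided by probability
ordering.

## The synthetic cohort generator

The generator defines the conditions under which the pipeline is tested.
It emulates:

* a miniature genome — 8 chromosomes named after human chromosomes
  relevant to gastric cancer CNA biology (including 5, 8, 20, 21), ~100
  genes per chromosome in 10 kb slots, centromere at 40% of the length,
  2–12 probes per gene so the ≥2…≥10 sweep is exercisable, and a few
  intergenic probes that must be dropped by gene assignment;
* three lineage archetypes with recurrent signatures. Because the
  uncentred correlation is scale-invariant, what makes a lineage
  clusterable is *recurrence* of alterations across its members, not raw
  burden; each archetype therefore owns core arm events with probability 1
  (stable: 5q loss — arm losses at 5q concentrate in non-invasive tumours;
  intermediate: 8q gain with sub-clonal 17p/18q losses; unstable: 8q and
  20q gains with sub-clonal 21q/3p losses and a 1q gain) plus private
  focal events at rates 0.02 / 0.08 / 0.15 (ordered stable < intermediate
  ≤ unstable). Gains are copy 3, losses copy 1, diploid reference 2;
* paired structure: two parts of one tumour share a profile re-drawn
  per gene with probability `part_divergence = 0.005`; two concurrent
  lesions of one patient derive from a patient-level base profile with
  per-lesion divergence `concurrent_divergence = 0.05`. These defaults are
  calibration choices, not estimates — they qualitatively reproduce the
  observed "nearly all same-tumour pairs adjacent, some concurrent pairs
  adjacent" pattern and were not fitted;
* measurement: emitted ratio = difference of log2 channel intensities,
  with a per-gene N(0, 0.5²) amplification bias added to *both* channels
  (cancelling exactly, by construction) and independent N(0, probe_sd²)
  probe noise added to the ratio. `probe_sd` defaults to 0.3 — no
  quantitative noise level is published for FFPE + WGA aCGH, so this is a
  calibration choice giving gene-level standard errors of 0.09–0.21 after
  averaging 2–12 probes, comfortably below the loss amplitude (1.0) and of
  the same order as the gain amplitude (0.585) for few-probe genes; and an
  optional tumour-purity multiplier (default 1.0, as dissected samples
  were ~90% neoplastic).

Random streams are split per lesion and per sample from one cohort seed, so
enlarging a cohort never perturbs the samples already generated. The
default cohort is study-shaped: 11 stable + 4 intermediate + 28 unstable
mucosal lesions, 16 two-part tumours, 5 concurrent pairs.

What the generator does *not* model — dye effects, spatial artefacts,
segment-level (CBS/HMM) structure within arms, subclonal mixtures beyond
the divergence events, and waviness/GC noise correlated along the genome —
bounds what the passing tests show: they demonstrate that the pipeline's
inference is correct under the stated data model, not that real FFPE
arrays meet that model.

## Numerical and degenerate-input choices

* Ties in agglomeration break on the smallest original-index pair; ties in
  auto lineage labelling abort (manual map required).
* `welch_t` errors when both groups have zero variance or either has < 2
  values; the genome-wide screen records such genes as untestable.
* Zero-margin contingency tables are errors for both the trend and exact
  tests.
* Probe tables with wrong field counts abort with line numbers; non-numeric
  ratios become missing with a warning, never silently dropped.
* Written floating point uses 10 significant digits; write→read round
  trips are identity at that precision, and merge scores in `.gtr/.atr`
  files are similarities (1 − distance), the Cluster 3.0 convention.
* Full Agilent Feature Extraction output is not parsed; real series enter
  through `import_geo_series()` (per-probe log2 ratios + a platform
  position table). If a series supplies only raw two-channel intensities,
  they must be reduced to per-probe log2 T/R first; both paths are noted in
  the function documentation.

## Problem sizes used in tests and the acceptance script

The test suite and `scripts/acceptance.R` run on cohorts of 12–59 samples
over 120–800 genes (the default miniature genome), 20 replicate cohorts
for recovery rates, 200 simulated families for the screen's family-wise
error, 10⁵ permutations for the trend-test null, and every 2×2 table with
N ≤ 30 for the exact test — sizes chosen so the whole suite completes in
about a minute while keeping Monte-Carlo error well below the margins
being asserted.

## Known limitations

* The clustering's separability on real data depends on lineages having
  recurrent signatures; cohorts whose "stable" tumours share no
  alterations would cluster diffusely under any correlation distance.
* Bonferroni within contrast is conservative for correlated genes (arms
  move together); the screen's calibration property is an upper bound on
  the family-wise error, not an exact level.
* The arm-penetrance rule (≥50% of arm genes) is a reasonable but
  unvalidated stand-in for the unstated chromosome-level calling of the
  original figures.
* `run_pipeline()` labels lineages automatically only when burden and size
  break ties; balanced synthetic designs can require `labelling: manual`.
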