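---
title: "Cross-modality genotype concordance: models, parameters and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Cross-modality genotype concordance: models, parameters and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(omicmatch)
```

# The problem

Multi-omics studies collect several datasets per donor — WGS, WGBS,
RNA-seq, methylation arrays — through independent lab workflows, each an
opportunity for a labelling mistake. Per-assay QC cannot catch a swap
because a mislabelled dataset is perfectly healthy; only the donor's
genetic signature can. `omicmatch` infers genotypes independently from
each modality at a fixed locus panel and compares every sample against
every other. Two datasets from the same donor agree at essentially every
locus; two unrelated donors agree at the Hardy–Weinberg chance rate
(for genotype frequencies $f_0,f_1,f_2$ the chance of agreement is
$\sum_g f_g^2$, which is $0.375$ at minor-allele frequency $0.5$ —
maximally informative, which is why array SNP control probes target
common variants). The gap between ~100% and ~40% is the decision
surface.

# Genotypes from array SNP control probes

The 450k array carries 65 probes aimed at common SNPs for exactly this
tracking purpose. Their β-values (signal ratios in $[0,1]$) are
tri-modal: near 0.5 at heterozygous probes and near the bounds at
homozygous ones. `classify_beta()` uses fixed cuts:

* below `low_cut` (default 0.25) → `LOW`,
* above `high_cut` (default 0.75) → `HIGH`,
* otherwise (cuts included) → `MID`; missing → `NO_CALL`.

Fixed cuts rather than a fitted mixture are a deliberate design choice:
the probes are selected to be maximally variable, so the three peaks are
separated by several standard deviations and an estimation step would add
failure modes without discrimination benefit. The cuts are arguments for
unusual datasets.

A class is only zygosity; to obtain an alt-allele *dosage* the manifest
must record which allele drives β towards 1 (`high_beta_allele`). With
that orientation `array_genotypes()` emits dosages, which are strictly
more discriminative than zygosity (homozygous-ref vs homozygous-alt
mismatches are visible). When orientation is unavailable or suspect,
every matching function accepts `mode = "zygosity"`, which collapses
dosage to HOM/HET on both sides. The QC filter (detection p ≥ 0.01 or
bead count < 3 → no-call) is off by default — at these deliberately
robust probes it rarely changes a call — and available via `qc_filter`.

`cross_tissue_check()` compares each donor's blood and saliva arrays at
the class level: germline genotypes are tissue-independent, so anything
below 100% agreement flags a handling problem before any sequencing
comparison is attempted.

# Forced calls from allele counts

Sequencing modalities are reduced to strand-resolved allele counts at the
panel loci (the package deliberately consumes count tables, not BAMs:
read extraction is standard tooling, the calling contract is the
interesting part). `genotype_likelihoods()` implements a transparent
binomial model: with per-read error $\varepsilon$, a read reports the alt
allele with probability

$$p_d = \tfrac{d}{2}(1-\varepsilon) + \left(1-\tfrac{d}{2}\right)\varepsilon, \qquad d \in \{0,1,2\},$$

and $\log L(d) = n_\text{alt}\log p_d + n_\text{ref}\log(1-p_d)$. The
call is the maximum-likelihood dosage under a flat prior. Numerical
choices:

* **Ties** (within $10^{-12}$ of the maximum) break towards the
  heterozygote — conservative for concordance, since a HET mismatch is
  symmetric between the two comparison directions.
* **Depth gate**: no call below `min_depth` (default 4) total reads;
  reads supporting neither allele count towards the gate but not the
  likelihood (they carry no information about which allele, only that
  the site was covered).
* **$\varepsilon$** defaults to 0.01 and must lie strictly inside
  $(0, 0.5)$ — the likelihood is undefined at 0 and the model loses
  identifiability at 0.5.

This is a deliberately minimal stand-in for a full variant caller: at a
few hundred fixed, biallelic, well-behaved sites, realignment, base
quality recalibration and priors change essentially nothing, while a
closed-form model can be verified exhaustively (the test suite compares
the argmax against an independent binomial-density evaluation for every
count pair up to depth 50).

## The bisulfite confound

WGBS converts unmethylated cytosine to uracil (read as T) on the read's
template strand. At a genomic C/T SNP, a converted C on the original-top
(OT) strand is indistinguishable from the T allele; at a G/A SNP the
original-bottom (OB) strand is confounded the same way (bottom-strand C,
the complement of G, reads as A in top coordinates). A naive caller
therefore systematically miscalls homozygous-C sites as heterozygous.
`bisulfite_effective_counts()` drops exactly the manufacturable
observations: T-allele counts on OT for C/T sites, A-allele counts on OB
for G/A sites. The retained OT C observations are safe — only a genuine,
methylated C produces them — so a C/T site is effectively called from
~50% of its reads (all OB, plus methylated-C OT reads), biased in count
but not in sign. A/T and C/G sites pass through untouched. The test
suite runs the conversion-aware and naive callers on the same simulated
draws; at 15X the aware caller stays above 95% accuracy at C/T loci
while the naive one loses roughly ten points.

# Panels and locus selection

DNA-level comparisons (450k vs WGS, WGBS vs WGS) use the 65-probe array
panel. RNA-seq only covers expressed exons, so `select_rnaseq_loci()`
builds a dedicated panel by intersecting two independent filters: a
cohort-presence gate (non-reference genotype called in at least
`min_samples = 4` WGS samples; "merely covered" is available as
`presence_mode = "covered"`) and an expression gate (the locus lies in a
gene ranked in the top `top_k = 100` by mean expression, ties broken by
gene id). Loci mapping to no gene are excluded; a locus inside
overlapping genes is assigned to the first containing interval in sorted
order. Because the filters are independent they commute — a property the
tests check against a brute-force re-implementation.

# Matching and reporting

`pair_concordance()` defines the core statistic: over loci *called in
both* samples, the fraction with equal dosage (or zygosity). No shared
calls yields an undefined percentage, never 0%. `verify_identity()`
confirms a sample when its expected partner's cell is the strict row
maximum *and* clears a threshold; defaults of 90% (DNA) and 60%
(RNA-seq) sit midway between the same-donor and unrelated-donor regimes,
with margin on both sides. Argmax ties are always flagged, never
silently confirmed.

`summarize_matching()` reports both the **macro** mean (average of
per-sample percentages) and the **micro** mean (pooled matches over
pooled loci), because "mean agreement" in cohort reports is ambiguous
between them; they differ whenever shared-locus counts differ across
samples. The pooled value is additionally reported floored at two
decimals (`micro_pct_floor`) alongside the rounded value, since printed
tables in the field use either convention — e.g. a pooled 548/551 =
99.4556% prints as 99.46 rounded and 99.45 truncated.

# The synthetic cohort generator

`simulate_cohort()` generates ground truth plus per-modality
observations; all defaults are the study conditions the package is built
around, and parameter choices not fixed by those conditions are stated
here once:

* **Cohort**: 10 donors. Genotypes are Hardy–Weinberg draws,
  $d \sim \mathrm{Binomial}(2, q)$, with $q = 0.5$ at the 65 array loci
  (control probes target maximally informative SNPs) and
  $q \sim U(0.05, 0.5)$ at 300 exonic candidate loci spread over 500
  genes.
* **Arrays**: β drawn around class centres $(0.05, 0.50, 0.95)$ with
  Gaussian noise (sd 0.04), censored to $[0,1]$ and rounded to 6
  decimals. The centres sit inside the unit interval because real
  β-values never reach the bounds; censoring (rather than rejection
  sampling) keeps the RNG consumption count fixed, which the
  determinism contract relies on. Detection p-values fail (p ≥ 0.01) at
  rate $5\times10^{-4}$; bead counts are Poisson with mean 14. Both
  tissues share the donor's genotype; noise is independent per tissue.
* **Sequencing depth**: Poisson per (sample, locus) with mean 30 (WGS)
  and 15 (WGBS). RNA-seq uses a base mean of 30 scaled by the locus's
  gene expression (log-normal, sdlog 1.5) normalised so the panel mean
  equals the base — dropout at weakly expressed loci then *emerges* from
  the depth model rather than being a separate parameter, mirroring why
  real RNA-seq covers only part of an exonic panel.
* **Reads**: true allele with probability $1-\varepsilon$
  ($\varepsilon = 0.01$), otherwise a uniformly chosen other base.
  Heterozygous RNA-seq loci receive a per-(sample, locus) allelic
  imbalance: the alt fraction is the logistic of a $N(0, 0.5)$ draw.
  WGBS reads get a fair-coin template strand, per-read methylation
  (rate 0.75) and conversion (rate 0.995) exactly as the confound
  section describes.
* **Seeding**: one master seed; each stage (truth, array, each count
  protocol) derives its own substream by hashing the stage name, so
  adding a stage never perturbs earlier draws, and derived seeds stay
  below $2^{31}$.

`inject_swap()` relabels observation data under a permutation while the
truth keeps its labels, providing the ground truth for swap-detection
tests.

## What the simulation does and does not show

The generator reproduces the statistical structure the matching decision
relies on: HWE genotype sharing between unrelated donors, tri-modal β,
depth-limited calling, bisulfite confounding, expression-driven dropout.
It deliberately omits GC bias, duplicate reads, mapping error,
contamination, relatedness between donors and population structure.
Passing tests therefore demonstrate that the *decision logic* is correct
under its stated model — not that the thresholds are optimal for cohorts
with related individuals (siblings share far more than 37.5%) or
contaminated libraries, where the margin between regimes narrows.

# Problem sizes and verification

The shipped tests and the acceptance script run the generator at its
default sizes (10 donors, 365 loci, 500 genes), which keeps a full
multi-modality round trip under ten seconds while leaving thousands of
genotype cells per run; recovery and swap-detection properties are
checked across multiple fixed seeds (10 for WGS accuracy and
cross-tissue agreement, 3 × 10 transpositions for swap detection). The
Hardy–Weinberg recovery test uses 10,000 donors at a single locus, and
the likelihood argmax is verified exhaustively to depth 50.

# Known limitations

* Only biallelic SNPs; indels and multiallelic sites are out of scope.
* The caller has no base-quality model; counts are taken at face value.
* Zygosity-mode matching cannot distinguish the two homozygous classes,
  halving the information per homozygous locus.
* The cross-tissue check requires both tissue columns; donors missing
  one are reported unevaluable rather than imputed.
* Thresholds (90/60) are calibrated for unrelated donors; cohorts with
  close relatives should raise them and inspect the full concordance
  matrix.
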