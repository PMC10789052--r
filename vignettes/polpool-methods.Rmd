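---
title: "Methods and design of polpool"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods and design of polpool}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(polpool)
```

polpool analyzes the genomic consequences of an enlarged RNA polymerase II
(Pol II) pool — the situation that arises when the ubiquitin-ligase-mediated
degradation of Pol II subunits is lost — together with the downstream
phenotype and human-genetics questions that accompany such a study: does
Pol II accumulate on genes, does transcription change, do rare coding
variants in the responsible ligase subunit associate with neural tube
defects (NTDs), and how much embryonic lethality hides behind a distorted
Mendelian ratio at weaning. This vignette explains the models, the
parameters that matter, the numerical choices, and what the synthetic data
can and cannot establish.

## Genomic region scheme

All occupancy quantities are computed on strand-aware windows around the
transcription start site (TSS) and transcription end site (TES), applied in
transcript orientation and mapped back to genome coordinates:

| region | window | length |
|---|---|---|
| promoter | TSS−400 .. TSS+100 | always 500 bp |
| gene body | TSS+100 .. TES−100 | gene length − 200 |
| TES region | TES−100 .. TES+2000 | always 2,100 bp |
| enhancer | TSS−5000 .. TSS−400 | 4,600 bp |
| upstream / downstream | ±10 kb of TSS | 10 kb |
| PI gene body | TSS+100 .. TES+2000 | gene length + 1,900 |

Coordinates are 0-based half-open (the BED convention) throughout, which
makes the nominal 500-bp promoter length exact on both strands. A gene of
200 bp or less yields an empty (flagged, not error) gene body.

Peak-to-feature annotation assigns each peak midpoint one category with the
fixed priority promoter > 5′UTR > 3′UTR > exon > intron > TES/downstream >
enhancer > intergenic; overlapping-gene ties go to the nearest TSS. No
single standard resolves multi-feature overlaps, so the priority order is
this package's design choice: proximal regulatory assignments
are preferred over structural ones because they are the categories the
occupancy analysis interprets.

## Occupancy quantification and the pausing index

Fragments are assigned to a region iff their midpoint falls inside it; one
fragment may count toward several region types of the same gene because
region types are analyzed independently. Region signal is expressed as
FPKM = count × 10⁹ / (length × library).

The pausing index is implemented in its standard reported form,

$$\mathrm{PI} = \frac{\mathrm{promoter\ FPKM}/L_1}{\mathrm{gene\ body\ FPKM}/L_2},
\qquad L_1 = 500\ \mathrm{bp},$$

with $L_2$ the variable PI-gene-body length. Because FPKM is already
per-kilobase, this double length normalization makes equal signal densities
give PI = $L_2/L_1$ rather than 1. Because that convention is debatable, `pausing_index()` also
offers
`mode = "density"`, the plain density ratio (equal densities give 1). Both
modes are invariant under global count scaling, and PI is undefined
(flagged `NA`, not propagated) exactly when the gene-body FPKM is zero.
Group comparison of PI uses a per-gene paired two-sided t test across
replicate pairs with Benjamini–Hochberg correction, plus the per-sample
empirical PI distribution curves.

Metagene profiles use 20 fixed 100-bp bins per 2-kb flank and 60
length-scaled gene-body bins (100 bins total), as FPKM-like bin densities
averaged across genes with standard errors. The TSS-centred peak profile
uses 51 bins of 400 bp; since 51 × 400 bp exceeds a ±10 kb span, the centre
bin is anchored on the TSS (bin 26 spans TSS±200) and the profile covers
±10.2 kb — the bin-edge convention is a package decision and is flagged as
such. Browser tracks are scaled to read
count per bp per 10 million mapped reads.

## Differential Pol II occupancy

For a chosen region type, genes with a zero count in any KO replicate are
filtered out (the knockout accumulates Pol II, so a gene with no KO signal
is taken to have no signal at all), counts are TMM-normalized against total
mapped fragments (edgeR), transformed to log2 CPM with `limma::voom`, and
tested with the moderated t statistic of a paired design (`~ pair +
group`), followed by Benjamini–Hochberg control at FDR < 0.1.

The choice of the moderated paired test is deliberate. The upstream
normalization (TMM, then voom) implies the limma pipeline, and with three
replicate pairs a plain per-gene paired t statistic has two residual
degrees of freedom: its variance estimate is so unstable that a genuine
2-fold occupancy change in a gene with several hundred fragments per window
is recovered less than half the time at FDR < 0.1. Variance moderation
borrows strength across genes and restores the power the design intends; a
design-time power calculation, not a posthoc fit, drove this choice. The PI
comparison, by contrast, keeps the plain paired t, which is what that
analysis states.

## Anchored differential expression

Transcript counts are filtered at a mean CPM ≥ 1 across all samples (the
filter scope — per-sample vs aggregate — is an open choice; the mean keeps
one transcript set for both groups). Normalization does not use
TMM: because an enlarged Pol II pool could skew all Pol II transcripts
coherently, counts are anchored to a Pol III-transcribed gene (*Rn7sk*),
whose abundance is independent of the Pol II pool. The per-sample factor is
a ratio of log2 CPMs,

$$f_s = \frac{\log_2 \mathrm{CPM}_s(\mathrm{anchor})}
{\overline{\log_2 \mathrm{CPM}(\mathrm{anchor})}},$$

applied as an effective library size (library × $f_s$). This is a ratio of
logs, not a log-ratio; it is implemented exactly in this form, with an
error when any anchor log2 CPM is ≤ 0 (anchor CPM ≤ 1), where the
expression loses meaning. At realistic anchor abundances (thousands of
CPM) a log-ratio variant would differ only in scale sensitivity.

Testing is the edgeR negative-binomial likelihood-ratio test
(`Var = μ + φμ²`, `estimateDisp`/`glmFit`/`glmLRT`) with the anchor factors
in the normalization-factor slot, FDR < 0.05, and gene-level summarization
into unique up/down/both sets with direction percentages. Under the
generator's null this pipeline holds a raw type-I error of ~0.05 and
recovers a planted log2 fold change of 2 with bias well under 0.3 (both are
asserted in the test suite at 2,000 transcripts, 3 vs 3, ten seeds).

## Rare-variant prioritization

The cascade applies the exome-sequencing filters exactly as defined: a site is kept
iff VQSR = PASS **and** (MQ > 20 **or** inbreeding coefficient < −0.3) —
the disjunction is deliberate (a conjunction would be the stricter
alternative); a genotype call is kept iff DP > 10, GQ > 20 and,
for alternate-allele carriers, AD_alt/DP > 0.25 (all strict). The
alternate-depth clause exempts hom-ref calls — otherwise no reference
genotype could pass and allele numbers could never be recalculated. AC, AN
and AF are then recalculated per population from passing calls only.

Variants absent from the matched control population (control AF = 0) are
*novel* when the control locus is covered at ≥ 30X and discarded otherwise;
observed variants are *rare* below control AF 0.01 and *common* at or above
it. Deleteriousness uses the CADD Phred convention: C-score =
−10·log10(percentile rank), so 13.01 marks the top 5% and 20 the top 1%;
selection is strictly greater-than.

Association offers both the allele-count 2×2 (`[AC, AN−AC]` case vs
control) and a carrier construction, one- or two-sided Fisher exact. Cohort
p-values quoted from summary tables are frequently not reproducible from
the summary allele counts under either construction, so neither is
privileged: both are implemented, the carrier mode is the default, and the raw
cross-product OR is reported with an explicit infinity flag when a control
cell is zero, alongside a Haldane (+0.5) corrected OR. Raw p values are
reported by default — the cohort's variants sit in one locus in strong
linkage disequilibrium, where a multiple-testing penalty would be
inappropriate — with `bh_fdr()` available as a switch.

## Lethality and incidence accounting

From a heterozygote intercross the knockout expectation is 25%. The
headline lethality figure is the shortfall `(expected − observed)/expected`
(25% expected, 10% observed ⇒ 60%). That arithmetic ignores that removing
dead homozygotes renormalizes the surviving genotype fractions: with true
lethality ℓ the weaning fraction is `f = e(1−ℓ)/(1−eℓ)` (11.76%, not 10%,
at ℓ = 0.6). The package therefore ships both: `lethality()` computes the headline
quantity, and `estimate_lethality()` inverts the renormalization,
which is the estimator that recovers a planted lethality from simulated
litters. Combined incidence converts the survivor phenotype rate to the
all-conceived scale (`survivor_rate × (1 − lethality)`), adds the prenatal
rate, and rounds components to one decimal and the total to a whole percent
(0.277 × 0.4 = 11.1%; 14.6% + 11.1% = 25.7 → 26%) — the rounding convention
matches how such figures are conventionally quoted and is configurable.
Incidence comparisons use Pearson's χ² without continuity correction;
Yates is a flag.

## AP-MS interactor scoring

Spectral-count zeros are imputed from a normal distribution matched to the
mean and SD of the lowest 20% of observed non-zero counts, truncated at
zero (counts cannot be negative — the truncation is this package's
addition), seeded and deterministic. Counts are then normalized by the
bait's spectral count per run. Empty-vector control runs contain no bait;
`bait_normalize(bait_cols = …)` scales them by the mean bait count of the
bait runs, placing all runs on one per-unit-bait scale, and
`rescale = "mean_bait"` keeps values in spectral-count units so that
count-scale constants stay meaningful. Preys quantified in ≥ 3 of 4 runs of
either condition are kept; high-confidence interactors need p < 0.05
(two-tailed t) *and* a ratio over control > 1.5. Differential interaction
between bait variants uses a stabilized t statistic with an additive
denominator constant `s0 = 0.1` — such zero-correction stabilizers have no
single canonical form, so the constant and its placement are explicit
arguments — with BH control, calling significance at
FDR < 0.05 and mean fold change beyond ±2.

## The synthetic-data generators

Every pipeline input can be generated from a single `sim_config()` whose
seed makes outputs bit-identical; each generator derives its own stream, so
adding one never perturbs another. Defaults are the scaled-down study
conditions used by the tests: 2,000 genes, 3 replicate pairs, 10⁶ fragments
or reads per sample, a 2-fold knockout occupancy effect on 5% of genes, 5%
differentially expressed transcripts at |log2 FC| = 2, NB dispersion 0.05,
an abundant anchor transcript (mean 50,000 counts, identical in both
groups), 60% homozygous lethality, 27.7% penetrance among surviving
homozygotes against a 3.7% background rate, and a cohort with planted
case-only alleles at AF 0.02 over ≥30X-covered control loci. Problem sizes
in the test suite (hundreds to 2,000 genes, libraries of 10⁵–10⁶) were
chosen as the smallest at which the estimators' sampling error is clearly
separated from the tolerances being asserted.

ChIP fragments have a fixed 200-bp length (real sonication spans 100–800
bp; a single length makes midpoint assignment deterministic) and are drawn
per gene from a two-component mixture: a promoter window component whose
density is `(1 + pausing_level)` times the body density — so
`pausing_level = 0` means no pausing and a density-mode PI of 1 — and a
uniform component over TSS+100..TES+2000, i.e. the transcribed region plus
termination read-through, matching the PI gene-body window. Intergenic
background is uniform. Fragment counts per sample sum exactly to the
library size (multinomial allocation), which also means a planted 2-fold
gene realizes slightly less than 2× the WT count (2/1.05 at 5% affected
genes) — the truth tables carry the exact expectations.

What the generators do **not** emulate: mappability and GC bias,
read-level sequences, overdispersed biological replicate effects beyond the
NB dispersion, linkage between variant sites, litter random effects, or
correlated prey contamination structure in AP-MS. Passing recovery tests on
this synthetic data therefore demonstrates the estimators' correctness and
calibration under the stated model, not robustness to artefacts real data
may carry.

## Numerical and degenerate-input conventions

Strict inequalities are used throughout (DP > 10,
C-score > 13.01, ratio > 1.5, CPM "less than one" removed). Degenerate
inputs prefer flags over exceptions when a value is meaningfully undefined
(PI with zero body signal, allele stats with all calls filtered) and
errors when computation cannot proceed (zero-length region in FPKM, anchor
failing its filter, all genes filtered). Identical-input comparisons
short-circuit to p = 1 rather than relying on 0/0 arithmetic. The voom
pipeline guards the fully degenerate identical-matrix case (all residual
variances zero) by reporting p = 1 everywhere instead of failing inside
the empirical-Bayes step.
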