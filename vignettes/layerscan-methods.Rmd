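---
title: "Methods: scanning layer-chicken genomes for recessive lethals and deleterious variation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: scanning layer-chicken genomes for recessive lethals and deleterious variation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`layerscan` implements two complementary routes to deleterious variation in
closed, intensively selected poultry populations: a pedigree-aware scan for
*missing homozygosity* in chip genotypes, and sequence-level surveys of a
functionally annotated variant catalogue. This vignette documents the
models, the tunable parameters and their defaults, the numerical choices,
and what the synthetic-data generator does and does not emulate.

## 1. The missing-homozygosity model

A recessive lethal allele kills homozygous embryos before genotyping. In a
large pedigreed population the haplotype carrying it therefore appears in
heterozygotes at normal frequency but never (or rarely, under incomplete
penetrance) in homozygotes. The scan:

1. QC-filters the SNP panel (`qc_filter_panel`): unmapped and
   sex-chromosome SNPs are dropped first, then animals with call rate
   below 0.7, then SNPs with minor allele frequency not above 0.01 or call
   rate not above 0.85. Both SNP rules are strict inequalities. No
   Hardy–Weinberg filter is applied — the deficit signal *is* an HWE
   deviation and would be destroyed by one.
2. Enumerates sliding windows (`enumerate_windows`) of 250 kb, 500 kb and
   1 Mb, stepping by half the window size, with a final window anchored at
   the chromosome end so the tail is covered; windows holding fewer than
   two SNPs are dropped. Coordinates are 0-based half-open internally and
   reported 1-based inclusive.
3. Extracts haplotype alleles per window (`extract_haplotypes`) by exact
   allele-string identity. Individuals with any missing allele in a window
   are excluded from that window only. Haplotypes at frequency strictly
   above 0.5% are retained.
4. Computes the expected homozygote count (`expected_homozygotes`). For a
   mating with `h_s` and `h_d` parental copies, each genotyped offspring is
   homozygous with probability `(h_s/2)(h_d/2)`; the expectation sums
   `n_offspring × p` over matings with `p > 0`. Matings whose parents are
   not both genotyped and phased are excluded rather than imputed: with
   medium-density chips and routine genotyping, the at-risk-mating
   expectation is identifiable without transmission-probability
   refinements, and exclusion cannot bias the test toward significance.
5. Tests the deficit (`binomial_deficit_test`) with the one-sided exact
   binomial lower tail `P(X ≤ O)`, `X ~ Binomial(n_at_risk, E/n_at_risk)`,
   flagged at `p < 0.005` with no multiple-testing correction (the
   threshold is the analysis's published operating point; the null
   calibration below shows the discrete test is conservative at it).

**Aggregation choice.** Mixed carrier matings (`h = 1` and `h = 2`
parents) give heterogeneous per-offspring probabilities; the exact law of
the homozygote count is Poisson-binomial. The scan aggregates to a single
`Binomial(n, E/n)` — one observed-vs-expected comparison per haplotype. By
the AM–GM inequality the single binomial has the *larger* lower tail at
`O = 0`, so the aggregation is conservative for the deficit hypothesis; the
exact Poisson-binomial is implemented as a test oracle
(`layerscan:::poisson_binomial_cdf`) and the test suite verifies both the
equality in the homogeneous case and the conservative direction in the
mixed case. In practice `h = 2` parents of a lethal haplotype do not exist,
so the homogeneous case dominates.

**One-sided, lower tail.** The alternative is a *deficit* of homozygotes;
a two-sided test would halve power against that alternative and answer a
different question.

**Carrier-mating diagnostics.** For each haplotype the scan also reports
the percentage of heterozygous progeny from carrier × carrier matings.
Under Mendelian segregation it is ~50%; when homozygotes die before
genotyping, survivors are 2:1 heterozygote : non-carrier (~66.7%), a
second, threshold-free signature of lethality. Overlapping significant
windows on a chromosome are merged into unique loci
(`merge_significant_loci`), so a lethal spanned by several window sizes
counts once.

## 2. The variant catalogue

`filter_sites` removes SNVs within 3 bp of an indel — implemented as
distance ≤ 3 bp, the conservative (inclusive) reading, fixed by tests —
and sites with phred quality below 20 or call rate below 0.7.
`filter_genotypes` masks genotype calls with depth outside
`[4, 2.5 × sample mean depth]`, bounds inclusive (a call at exactly depth
4 is kept), then recomputes site call rates and per-line allele counts.
The order — site filters, then depth masking, then call-rate recomputation
for reporting — is a documented choice; the alternative (recomputing call
rate before the 0.7 site cut) would couple the two filters.

`classify_variants` assigns: `lof` for splice acceptor/donor, inframe
insertion/deletion, frameshift, stop gain/loss and start loss; missense
split at SIFT ≤ 0.05 into deleterious vs tolerated (missense without a
SIFT score is labelled `missense_unscored` and excluded from class
comparisons); `synonymous`; `other`. Membership in the *final deleterious
set* additionally requires a 1:1-ortholog gene and combined RNA-seq
expression coverage ≥ 200 — gene-level guards against paralog-driven
mapping artefacts and broken gene models. Two SIFT thresholds coexist
deliberately: ≤ 0.05 defines the deleterious *class* for spectra and
ratios, while the per-individual mutation load counts variants at
SIFT < 0.01; both are exposed as parameters. PROVEAN is used only where
missense SIFT does not apply: inframe indels must be PROVEAN-deleterious
(≤ −2.5, the tool's canonical cutoff) to qualify as embryonic-lethal
candidates, and ≤ −5 is reported as "highly deleterious".

## 3. Selection signatures

The allele-frequency spectrum uses 20 bins of width 0.05; interior edges
are half-open upward and AF = 1.0 goes to the top bin so the partition is
total. Pooled heterozygosity per 20-kb window is
`Hp = 2 ΣnMAJ ΣnMIN / (ΣnMAJ + ΣnMIN)²` with major/minor assigned per SNP
from within-line counts, making `Hp` invariant to reference-allele
labelling and bounded by 0.5. Windows are a non-overlapping tiling anchored
at position 0 — the minimal reading absent a stated step — scored only with
≥ 20 variants, and standardized per line to
`zHp = (Hp − mean)/sd`; windows at `zHp ≤ −2.7` (the extreme lower tail)
are sweep candidates. A pooled mode exists behind `line = NULL`.
Fixed/nearly fixed intolerant variants are final-set deleterious variants
with within-line AF > 0.9; line-specific sets require AF > 0.7 in exactly
one line and a zero alternate count in all others, which makes them
pairwise disjoint by construction.

## 4. Purging and positional signatures

Recombination rate is genetic length (cM) over physical length (Mb) in
750-kb bins on macrochromosomes 1–5, with bin-edge cM obtained by linear
interpolation of the map; beyond the terminal markers cM is held constant
(rate 0, flagged `extrapolated`), and terminal bins shorter than half the
bin size are dropped. Per-bin genetic lengths telescope, so they conserve
each chromosome's total mapped cM exactly. The deleterious/tolerated ratio
is deleterious missense over synonymous + tolerated missense; Pearson
correlation against the bin rate is reported with both the t-transform
p-value and a permutation p-value, because bins are spatially
autocorrelated and the t reference can be optimistic. A two-class summary
contrasts bins at ≤ 2 cM/Mb with the rest.

Protein positions map to deciles by `ceiling(10 × aa_pos/aa_len)` with
`relpos ∈ (0, 1]`: bin 10 closes at the C terminus, bin 1 is reachable
only within the N-terminal 10%, and the map is scale-invariant. Terminal
enrichment of a class is its bin-1+bin-10 proportion over the synonymous
baseline, with a one-sided label-permutation p-value. Indel lengths are
profiled at 1–15 bp; the in-frame fraction (length divisible by 3) is
compared between coding and non-coding indels with a two-proportion test.

## 5. Embryonic-lethal candidates

`el_filter` keeps LoF and deleterious-missense variants (inframe indels
additionally PROVEAN-deleterious) with zero homozygous-alternate genotypes
— evaluated on post-QC genotypes, since a spurious homozygote at depth 2
should not disqualify a candidate — in genes flagged lethal in null-mutant
mice. The gene list is a plain input table, and a machine-readable
exclusion list replaces manual browser curation of alignment artefacts.
Each candidate carries a reason trail and a line-specificity annotation;
the filter is monotone in the gene set. `haplotype_concordance` matches
deficit haplotypes to candidate causal variants: protein-altering variants
in the window whose sequenced alternate-allele carriers coincide with the
sequenced haplotype carriers — strict set equality by default, with a
relaxed Jaccard-fraction mode because genotyping error tolerance is
otherwise unspecified. Hatchability of carrier × carrier vs carrier ×
non-carrier matings is compared with a pooled-variance two-sample t-test,
reported two-sided (the more conservative choice where sidedness is not
stated).

## 6. What the simulator emulates

`simulate_population` gene-drops founder haplotypes through discrete
generations: founder alleles are drawn per SNP from chip-like frequencies
(uniform 0.05–0.95); meioses follow the Haldane model (Poisson crossovers
with mean equal to the chromosome's Morgan length, positions uniform, no
interference) — the simplest model consistent with using a cM map. The
mating scheme is random within line with a configurable sire fraction
(default 25%) and discrete generations; real breeding programs are
proprietary, so this is a stand-in, not a reconstruction. One shared
haplotype across the lethal window is planted on a configured fraction of
founder chromosomes (one chromosome per carrier founder, so no founder is
born homozygous), and a hidden tag marker at the window midpoint is
transmitted through the same meioses; conceptuses homozygous for the tag
are removed *before* genotyping with probability `penetrance` — mirroring
missing homozygosity at the chip stage, and leaving surviving carrier ×
carrier progeny 2:1 het : non-carrier. Phase is emitted as truth (phasing
is upstream of this package's scope); a switch-error injection hook exists
and is off by default.

`simulate_variant_catalog` draws allele frequencies per functional class —
`Beta(0.8, 0.8)` for neutral classes vs `Beta(0.2, 2.0)` for deleterious
ones (means 0.5 vs 0.091), the skew the AFS analyses assume — and genotypes
under Hardy–Weinberg within line. Variants flagged as embryonic-lethal
truth have homozygous-alternate draws rejected and resampled from the
conditional heterozygote/reference distribution, which guarantees the
no-homozygote criterion while approximately preserving the marginal
frequency (a frequency adjustment would not guarantee it). SIFT/PROVEAN
scores are drawn consistently with class; coding indels are in-frame with
probability 0.6 against 1/3 for non-coding (uniform 1–15 bp); frameshift
and stop-gained protein positions are terminal-inflated with weight 0.4.
The recombination landscape is piecewise-constant on a 500-kb grid,
Gamma-distributed around the 3 cM/Mb baseline and clamped to
[0.5, 2 × baseline] — macrochromosome-like — and the deleterious/tolerated
ratio varies linearly with the local rate at `purging_gradient_slope`
(default −0.04 per cM/Mb from a base ratio of 0.2); a slope that would
drive the ratio non-positive anywhere in the landscape is rejected.

**What it does not emulate:** coalescent ancestry and realistic linkage
disequilibrium decay, sequencing reads and their error modes, phasing and
imputation error (beyond the off-by-default switch hook), overlapping
generations and non-random mate allocation, selection on polygenic
background. Passing tests therefore demonstrate the *statistical
machinery* — power, calibration, invariants — under the stated generative
model, not performance on any particular real dataset.

## 7. Default parameters

| Parameter | Default | Where |
|---|---|---|
| Panel MAF / SNP CR / animal CR | > 0.01 / > 0.85 / ≥ 0.7 | `qc_filter_panel` |
| Window sizes, step | 250 kb–1 Mb, 0.5 × size | `enumerate_windows` |
| Haplotype frequency retention | > 0.005 | `extract_haplotypes` |
| Deficit significance | p < 0.005 | `scan_deficit` |
| Site quality / call rate / indel distance | ≥ 20 / ≥ 0.7 / ≤ 3 bp removed | `filter_sites` |
| Genotype depth | 4 ≤ d ≤ 2.5 × mean | `filter_genotypes` |
| SIFT class / load thresholds | ≤ 0.05 / < 0.01 | `classify_variants`, `mutation_load` |
| RNA-seq coverage (gene filter) | ≥ 200 | `classify_variants` |
| Fixed / line-specific AF | > 0.9 / > 0.7 | `fixed_intolerant`, `line_specific_high_freq` |
| Sweep window / min variants / zHp | 20 kb / 20 / ≤ −2.7 | `zhp_scan` |
| Recombination bins / chromosomes | 750 kb / 1–5 | `recombination_bins` |
| PROVEAN deleterious / severe | ≤ −2.5 / ≤ −5 | `el_filter` |

## 8. Problem sizes used in the test suite

The suite exercises detection power on single-line populations of 4,000
founders producing 3,000 genotyped trios from single-offspring matings,
with the lethal haplotype at 5% founder frequency (20 replicates), plus
null calibration on the same design without a lethal. The mating design
matters: at the `p < 0.005` threshold a zero-homozygote haplotype needs at
least 19 at-risk progeny (`0.75^19 ≈ 0.0042`), and under random mating the
expected at-risk count is pinned by the conditions themselves — 3,000
trios × (10% carrier fraction)² × 3/4 surviving ≈ 22.5, the last factor
because a quarter of carrier-mating conceptuses die before genotyping and
so never enter the at-risk denominator. Many single-offspring matings
minimize the variance around that mean (≈ Poisson), giving per-replicate
power ≈ 0.79; this is a ceiling of the design conditions, not of the
implementation, and the power test documents it: a 5% lethal haplotype at
3,000 trios sits near the detection boundary of the missing-homozygosity
method at `p < 0.005`, which is consistent with the method being quoted as
reliable only from several thousand genotyped animals upward for rare
haplotypes. Further checks:
Monte-Carlo equivalence of the expectation at 100,000 gene droppings
across 20 random mating designs, and 100-replicate recovery runs for the
AFS contrast (2,000-variant catalogues) and the purging gradient
(15,000 variants across three 10-Mb chromosomes, i.e. 39 recombination
bins — the resolution `p < 0.01` requires), with 30 sequenced samples per
line. These sizes give the Monte-Carlo assertions comfortable
3-standard-error margins while keeping each check's cost proportionate to
what it demonstrates.

## 9. Known limitations

- Haplotype identity is exact string match; genotyping error in a window
  fragments a haplotype class rather than fuzzily matching it.
- The binomial aggregation of heterogeneous matings is conservative, not
  exact (the exact Poisson-binomial is available as an oracle).
- `expected_homozygotes` excludes matings with ungenotyped or unphased
  parents instead of imputing transmission probabilities.
- The AFS can be computed pooled or within line; the pooled default is a
  convention, and class comparisons should hold the mode fixed.
- Recombination-bin counts treat variant positions as exact; variants on
  bin boundaries belong to the upper bin (half-open convention).
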