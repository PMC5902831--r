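# layerscan

Detection of recessive lethal haplotypes and surveys of deleterious coding
variation in commercial layer-chicken breeding lines.

Purebred layer lines are routinely genotyped on medium-density SNP chips as
part of genomic selection. A recessive embryonic lethal never appears in
homozygous state among genotyped animals, so it leaves a statistical
footprint: a *deficit of homozygotes* for the SNP haplotype it rides on.
`layerscan` implements that scan, plus the sequence-level analyses used to
characterise deleterious variation in whole-genome-sequenced animals from
the same lines, and a pedigree gene-dropping simulator so the whole pipeline
is testable without proprietary data.

## The core statistic

For each haplotype `h` in a sliding window, matings are collected where the
sire carries `h_s` and the dam `h_d` copies (0, 1, 2) of `h`. Each genotyped
offspring of such a mating is homozygous for `h` with probability

    p = (h_s / 2) * (h_d / 2)

so the expected homozygote count is `E = Σ n_offspring × p` over matings
with `p > 0` — under a single heterozygote × heterozygote (carrier ×
carrier) mating, 25% of offspring. With `O` observed homozygotes among the
`n` at-risk progeny, the one-sided exact binomial lower tail

    P(X ≤ O),  X ~ Binomial(n, E / n)

flags a deficit at `p < 0.005`. At `O = 0` this is `(1 − E/n)^n`, i.e.
`0.75^n` for pure carrier × carrier matings. Haplotypes below 0.5%
frequency are not tested, and the surviving carrier-mating progeny of a
fully penetrant lethal are 2:1 heterozygote : non-carrier (≈ 66.7%
heterozygous, against 50% under Mendelian expectation).

Around the scan, the package provides:

- **Panel QC** (`qc_filter_panel`): MAF > 0.01, SNP call rate > 0.85,
  animal call rate ≥ 0.7, sex/unmapped SNPs dropped, no HWE filter.
- **Variant catalogue** (`filter_sites`, `filter_genotypes`,
  `classify_variants`, `per_line_af`, `ts_tv`, `mutation_load`): site
  filters (quality ≥ 20, call rate ≥ 0.7, SNVs within 3 bp of an indel
  removed), depth-based genotype masking (4 ≤ depth ≤ 2.5 × sample mean),
  SIFT/LoF classification and per-line allele frequencies.
- **Selection signatures** (`afs_histogram`, `zhp_scan`,
  `fixed_intolerant`, `line_specific_high_freq`, `sweep_overlap`):
  20-bin allele-frequency spectra per functional class, pooled
  heterozygosity `Hp = 2ΣnMAJ ΣnMIN / (ΣnMAJ + ΣnMIN)²` in 20-kb windows
  standardized to zHp (sweeps at zHp ≤ −2.7), fixed (AF > 0.9) and
  line-specific (AF > 0.7, absent elsewhere) intolerant variant sets.
- **Purging vs recombination** (`recombination_bins`,
  `purging_correlation`, `position_profiles`, `indel_length_spectrum`):
  cM/Mb in ~750-kb bins against the deleterious/tolerated ratio (Pearson),
  protein-decile position profiles with terminal-enrichment statistics, and
  coding vs non-coding indel-length spectra.
- **Embryonic-lethal candidates** (`el_filter`, `haplotype_concordance`,
  `hatchability_test`): LoF/deleterious-missense variants with zero
  homozygotes in genes lethal in null-mutant mice; carrier-concordance
  matching of candidate causal variants; equal-variance t-test of
  hatchability in carrier × carrier vs carrier × non-carrier matings.
- **Simulator** (`sim_config`, `simulate_population`,
  `simulate_variant_catalog`, `simulate_hatchability`): gene dropping with
  Haldane recombination, an embedded lethal haplotype removed before
  genotyping, class-dependent allele-frequency distributions, and a
  configurable purging gradient.

## Worked example

```r
library(layerscan)

cfg <- sim_config(seed = 1, lines = "WA", n_founders_per_line = 800,
                  n_generations = 2, offspring_per_mating = 5)
pop  <- simulate_population(cfg)   # lethal haplotype at 5% on 1:4.75-5.0 Mb
scan <- scan_deficit(pop)
scan
#> <dh_scan> 1491 haplotype tests, 1 significant at p < 0.005

dplyr::select(tidy(scan)[tidy(scan)$significant, ],
              chrom, start, end, frequency, expected_hom, observed_hom,
              n_at_risk, p_value, pct_het_carrier_progeny)
#> # A tibble: 1 × 9
#>   chrom   start     end frequency expected_hom observed_hom n_at_risk p_value pct_het_carrier_progeny
#>   <chr>   <dbl>   <dbl>     <dbl>        <dbl>        <int>     <int>   <dbl>                   <dbl>
#> 1 1     4750001 5000000    0.0534            6            0        24 0.00100                    66.7
```

The one significant window is exactly the simulated lethal region: 6
homozygotes expected among 24 at-risk progeny, none observed
(`p = (3/4)^24 ≈ 0.001`), and 66.7% of surviving carrier-mating progeny
heterozygous — the survivor signature of a fully penetrant recessive
lethal. `glance(scan)`
gives the per-scan summary (haplotypes per window, carrier matings, merged
locus count); `autoplot(scan)` draws the genome-wide scan.

The full pipeline (simulate → scan → catalogue → AFS → sweeps →
recombination → EL candidates) runs from one configuration:

```r
run_pipeline(pipeline_config(out_dir = "run1", seed = 1))
```

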