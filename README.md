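# rareburden

Rank-based analysis of the burden of rare genetic variants on gene
expression in a population panel.

## The problem

Under stabilizing selection, gene expression evolves toward an
intermediate optimum, and the mildly deleterious regulatory variants that
purifying selection keeps rare (minor allele frequency < 5%) are expected
to push their carriers toward the *extremes* of the population's
expression distribution — in either direction. In a panel of genotyped
individuals with per-gene expression, this predicts a U-shape: rank the
samples by each gene's expression, count each sample's rare variants in
the gene's cis region, and the mean count per rank is elevated at both
ends. The strength of this "rare variant effect" is informative about
selection: it should weaken with distance from the TSS, in
high-recombination regions (Hill–Robertson), in highly expressed and
highly network-connected genes, and strengthen for variants with high
fitness-consequence (fitCons ρ) scores and under environmental stress.

`rareburden` implements the full analysis for diploid, largely selfing
populations (e.g. rice landraces): population variant QC (GATK-style hard
filters, duphold depth rules for SVs, cross-sample SV merging at 50%
reciprocal overlap), rarity selection with class-specific evidence rules,
robust-expression gene filtering and per-gene ranking, variant assignment
to genic and strand-aware upstream windows, and the statistics:

* per-rank burden profiles with OLS quadratic fits
  (*m(x) = a + bx + cx²*; convexity *c* > 0 and *r²* quantify the
  U-shape),
* Mann–Whitney comparisons of the top/bottom 20% of ranks against the
  40–60% block,
* the extreme-to-middle ratio **φ = E_r / M_r**, where *E_r* counts rare
  variant carrier events in the top and bottom 10% of expression ranks
  and *M_r* in the 40–60% ranks (φ ≈ 1 under no association),
* Fisher's exact contingency comparisons between strata, whose sample
  odds ratio is exactly φ_A/φ_B, and a within-gene permutation test for
  condition differences,
* stratified analyses by variant class, linkage window, recombination
  rate, fitCons score, expression level and network connectivity.

A synthetic-population generator (`simulate_population()`) writes
VCF/GFF3/TSV datasets with planted cis-regulatory effects and full ground
truth, so every stage is testable end to end without external data.

## Worked example

The numbered scripts under `analysis/` run the study sequence on one
simulated population (129 samples, 2,000 genes, ~25,000 rare variants
with planted effects). From the repository root:

```sh
Rscript analysis/01_simulate.R
Rscript analysis/02_prepare_variants.R
Rscript analysis/04_burden_profiles.R
Rscript analysis/05_phi_conditions.R
Rscript analysis/06_strata.R
```

prints, among other things:

```
26510/26590 variants remain after QC; 25300 rare variants selected
wet: convex quadratic c = 0.188 (r2 = 0.565); high-vs-mid p = 1.6e-05, low-vs-mid p = 7e-08
phi_wet = 1.347, phi_dry = 1.578 (+17.1% under stress)
Fisher OR = 1.171 (p = 1.3e-10); permutation p = 0.001
  recombination low vs high: phi 1.571 vs 1.152 (OR 1.364, p 8.8e-19)
  fitcons_rho low vs high: phi 1.175 vs 1.494 (OR 0.786, p 6.6e-08)
```

Read: the QC filters removed the planted low-quality records; the
per-rank profile is convex (U-shaped) with both expression extremes
carrying significantly more rare variants than the middle ranks; φ > 1 in
both conditions and higher under drought stress (the generator amplifies
causal effects under stress); and the stratified contrasts recover the
planted couplings — a stronger rare-variant effect in low-recombination
genes and for high-ρ SNPs. Each script writes its tables under
`results/`.

The same machinery works on real data: point `read_vcf()`,
`read_gene_models()`, `read_expression()`, `read_site_scores()` and
`attach_gene_metadata()` at your files and follow the same sequence (see
`run_pipeline()` for the orchestration and
`inst/extdata/default_config.yaml` for every tunable threshold).

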