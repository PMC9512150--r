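---
title: "The rare-allele burden on gene expression: models, statistics and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The rare-allele burden on gene expression}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rareburden)
```

## The scientific question

Under stabilizing selection, gene expression is selected toward an
intermediate optimum. Deleterious regulatory variants — which purifying
selection keeps rare — are then expected to push their carriers toward the
*extremes* of the population's expression distribution, in either
direction. In a population panel with per-gene expression measurements,
this predicts a U-shaped relationship: when samples are ranked by a gene's
expression, carriers of rare cis variants should be over-represented at
both the lowest and the highest ranks relative to the middle. The effect
is expected to be modulated by linkage (distance to the TSS),
recombination rate (Hill–Robertson interference weakens selection in
low-recombination regions), expression level, per-site fitness-consequence
scores, network connectivity, and environmental stress (de-canalization of
buffered cryptic variation). This package implements that analysis for a
diploid, largely selfing population genotyped for SNPs, small indels and
structural variants (SVs), with replicated expression in two conditions.

## The procedure

1. **Variant preparation.** Population variant calls are hard-filtered
   with the standard GATK site-annotation thresholds (SNPs:
   QD > 2, FS < 60, MQ > 40, SOR < 4, MQRankSum > −12.5,
   ReadPosRankSum > −8; indels: QD > 2, FS < 200, SOR < 10, length ≤ 20
   bp). SV records keep deletions with duphold depth fold-change < 0.70
   and duplications with fold-change > 1.30, discard non-breakend SVs
   of ≤ 20 bp or > 200 kb, and per-sample calls are merged across samples
   at 50% reciprocal overlap with breakends within 1 kb (breakend records
   merge only at identical positions; same-sample overlapping calls are
   excluded before merging as likely complex rearrangements).
2. **Rarity.** The minor allele is frequency-defined
   (`maf = min(f, 1−f)`); a variant is rare when MAF < 5%, computed over
   non-missing genotypes. SNPs and indels additionally need ≥ 1 minor-allele
   homozygote or ≥ 3 heterozygotes — a guard against singleton
   heterozygote call errors — while SV singletons are accepted because SV
   calls rest on multiple independent read signals.
3. **Expression preparation.** Genes are analysed when non-zero in ≥ 2 of
   3 replicates for at least `floor(0.85 × N)` samples (109 of 129), genes
   with > 50% reciprocal TE overlap are removed, replicates are averaged,
   and samples are ranked per gene (ascending; ties broken by panel
   order). Percentile is `(rank − 0.5)/n`.
4. **Burden.** Rare variants are assigned to the gene body (`GENIC`) and
   strand-aware upstream windows (0–2, 2–4, …, 18–20, > 20 kb from the
   TSS, the distal window capped at 100 kb). Carriers contribute one count
   per variant (allele-dosage weighting is available but off by default —
   in a selfing population nearly all carriers are homozygous, so the
   distinction is minor). SVs count in every bin their span overlaps,
   since a multi-kb deletion genuinely touches several windows; a
   start-position mode is available for sensitivity analysis.
5. **Statistics.** The per-rank profile is the mean count over genes of
   the sample at each rank. It is summarised three ways: an OLS quadratic
   fit on percentile (convexity `c > 0` plus `r²` quantify the U-shape), a
   two-sided Mann–Whitney comparison of the top/bottom 20% of ranks
   against the 40–60% block, and the extreme-to-middle ratio
   `phi = E_r/M_r`, where `E_r` counts carrier events in the top and
   bottom 10% of ranks and `M_r` in the middle 20%. Strata are compared on
   the 2×2 table `[[E_A, M_A], [E_B, M_B]]` with Fisher's exact test; the
   sample odds ratio of that table is algebraically `phi_A/phi_B`.
   Conditions are additionally compared with a permutation test.

## Numerical and design choices

**Rank bins for phi.** With the percentile convention
`(rank − 0.5)/n`, literal half-open percentile intervals
(`p < 0.10 | p ≥ 0.90` vs `0.40 ≤ p < 0.60`) do not contain the same
number of ranks for every panel size; at `n = 129` they give 26 extreme
and 25 middle ranks, which biases the null expectation of `phi` upward by
about 4%. Since phi's entire interpretation rests on `phi ≈ 1` under no
association, bin membership is computed on rank counts instead:
`k = round(0.1 n)` ranks at each extreme and a middle block of exactly
`2k` ranks centred on the median rank (`phi_rank_bins()`). For panel
sizes where the percentile intervals are already balanced (e.g. `n = 10`
or `n = 130`) both rules coincide. Genes ranked in fewer than `n` samples
use their own rank-bin partition.

**Mann–Whitney.** For group sizes ≤ 8 the null is enumerated exactly over
all assignments of the pooled values (valid under ties); larger groups use
the tie-corrected normal approximation with continuity correction,
matching `stats::wilcox.test`. Two-sided p-values are
`min(1, 2·min(P(U ≤ u), P(U ≥ u)))`.

**Fisher comparisons.** The p-value comes from `stats::fisher.test`; the
reported odds ratio is the *sample* OR `(E_A·M_B)/(M_A·E_B)` — not the
conditional MLE — so the identity `OR = phi_A/phi_B` holds exactly.

**Permutation null.** The permuted quantity is the within-gene assignment
of samples to ranks, independently in both datasets: this breaks any
genotype–expression link while preserving each dataset's count totals and
rank structure. The p-value uses the add-one correction
`(1 + #{|Δ*| ≥ |Δ|})/(B + 1)`, so it is never exactly zero. Permuting
condition labels instead is a coarser null and is not the default.

**Degenerate inputs.** `phi` is flagged undefined when `M_r = 0`;
quadratic fits refuse fewer than 4 points or a singular design; genes
ranked in < 10 samples are excluded from rank analyses; median-split ties
go to the `low` stratum; connectivity values outside the stated class
ranges (0.16–0.77, 0.80–0.99) are excluded rather than clamped; absent
hard-filter annotations pass their criterion (GATK emits the RankSum
annotations only at heterozygous sites, and dropping hom-only sites
silently would be wrong).

## What the synthetic generator emulates

`simulate_population()` draws a population of 129 diploid, 95%-homozygous
(selfing) samples and 2,000 genes placed far apart on one chromosome so
that 100-kb upstream windows never overlap a neighbouring gene. Rare
variants of the three classes are placed in genic and upstream bins with a
proximal-heavy mixture; their carrier counts (1–12 minor alleles, weighted
toward singletons) keep MAF < 5% by construction, and the SNP/indel
evidence rule is satisfied by construction while dedicated low-evidence
and QC-failing records are planted to exercise the filters. A fraction π
of rare variants is causal: each carrier's expected log2(TPM+1) value
shifts by `±δ·σ_b·exp(−d/λ)`, where `d` is the distance to the TSS
(weight 1 inside the gene), and dry-condition effects are multiplied by
`κ_dry`. Causal probability is coupled (multiplicatively, ±50% by
default) to low recombination, low expression and high fitCons ρ,
emulating the stratified contrasts the analysis is meant to detect.
Replicates add independent technical noise and a small dropout fraction
zeroes whole (gene, sample) cells.

Default parameters, chosen once as the study conditions: variant counts
20,000 SNP / 3,800 indel / 1,500 SV rare variants (a deliberately
scaled-down population — roughly a third of the per-gene cis density of a
real rice panel — keeping simulations affordable while leaving counting
noise in `phi` near ±0.02); π = 0.15 for SNPs/indels and 0.30 for SVs
(SVs have larger regulatory effects); δ = 1.5 biological SDs; λ = 2 kb;
κ_dry = 1.5; biological SD 0.7 and replicate SD 0.25 on the log2 scale;
dropout 2%. Effects are symmetric in sign by default; `sv_sign_bias`
skews indel/SV effects toward decreased expression for sensitivity
analyses.

What the generator does **not** emulate: linkage disequilibrium between
variants, coalescent haplotype structure, population stratification,
shared-environment batch effects, and mapping biases of 3′ tag
sequencing. Passing the calibration and recovery checks therefore shows
the *statistics* behave correctly on data satisfying the model's
assumptions, not that real data meet those assumptions.

## Calibration and recovery experiments

The test suite re-derives every documented example exactly (hand-counted
fixtures for the per-rank profile, `phi = 2.5` on the 10-rank example,
the SV merge boundary cases) and runs two simulation experiments:

* **Null calibration** — 100 seeds at study scale (129 samples, 2,000
  genes, π = 0): `phi` must fall in [0.95, 1.05] in ≥ 95% of seeds; and
  200 null wet/dry pairs (smaller populations: 40 samples, 80 genes) must
  give uniform permutation p-values (Kolmogorov–Smirnov p > 0.01).
* **Signal recovery** — at the default planted effects, `phi > 1`, the
  profile is convex with `r² > 0.1`, `phi` responds monotonically to π, δ
  and κ_dry (400-gene populations across the grids), and the stratified
  contrasts recover the planted couplings (low recombination, high ρ, low
  expression, proximal windows).

The analysis scripts under `analysis/` run the same sequence on one
simulated population and write their tables under `results/`;
`scripts/acceptance.R` recomputes the headline quantities from scratch
under a caller-supplied seed.

## Known limitations

Upstream windows are not truncated at neighbouring genes, which is
harmless for the widely spaced synthetic genes but double-counts shared
upstream sequence in dense real genomes. Breakend records are counted as
single variants at their position; partner breakends are not paired. The
permutation and contingency comparisons treat carrier events as
exchangeable units and ignore LD between nearby rare variants, so their
p-values are anti-conservative where rare haplotypes carry many variants.
Cross-stratum comparisons are reported without multiple-testing
correction, matching standard practice for this analysis.
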