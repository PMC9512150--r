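# Default analysis thresholds for the rare-allele burden pipeline.
# Values here mirror the package defaults; override any subset and load
# with rareburden::load_config("my_config.yaml").
maf_threshold: 0.05        # rarity cutoff on folded minor-allele frequency
min_hom: 1                 # SNP/indel evidence: minor-allele homozygotes ...
min_het: 3                 # ... or heterozygous carriers
sv:
  dhffc_max: 0.70          # deletions: depth fold-change vs flanks
  dhbfc_min: 1.30          # duplications: fold-change vs similar-GC bins
  min_length: 20           # bp, exclusive
  max_length: 200000       # bp, inclusive
  reciprocal: 0.50         # cross-sample merge: reciprocal overlap
  bnd_window: 1000         # bp, breakend distance for merging
expression:
  min_fraction: 0.85       # robust genes: fraction of samples expressed
  min_replicates: 2
  te_reciprocal: 0.50      # TE-gene removal threshold (strict >)
  min_ranked_samples: 10
phi:
  extreme: [0.10, 0.90]    # extreme rank mass: below/at-or-above
  middle: [0.40, 0.60]
rank_groups:
  low: [0.0, 0.20]
  mid: [0.40, 0.60]
  high: [0.80, 1.0]
fitcons:
  high_min: 0.2            # rho > 0.2 -> high class
  low_max: 0.1             # rho < 0.1 -> low class
connectivity:
  high_range: [0.80, 0.99]
  low_range: [0.16, 0.77]
conditions: [wet, dry]
n_perm: 1000
seed: 1
simulation: {}             # overrides for sim_config()
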