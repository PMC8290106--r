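# profhom

Profile-based detection and classification of remote homology among
deeply divergent paralogous protein families.

## The problem

The CATCHR-class multisubunit tethering complexes of the eukaryotic
endomembrane system — exocyst, COG, GARP and DSL1 — are built from
subunits that fall into four homology classes (g51, g52, g53, g54,
named after the GARP subunit each contains) and appear to descend from
one ancestral tetramer, itself derived from an ancestral dimer.
Establishing this is hard because the orthologs sit in the *twilight
zone*: pairwise identity below ~20%, where single-sequence searches
fail, paralogs confound reciprocal hits, and a shared N-terminal coiled
coil (CC) injects spurious similarity between otherwise unrelated
families.

profhom implements the full analysis pattern for this regime:

- **reciprocal profile orthology** — jackhmmer-style iterative profile
  enrichment from each seed protein, forward best-hit search
  (e ≤ 1e-3), and a reciprocal check in which the hit is itself
  enriched into a profile and searched back (rank-1 must be the seed);
  in parallel, a phmmer-style single-sequence route (1e-2 / 1e-3,
  coverage > 40%); results from three seed taxa combined by best
  e-value with conflicts flagged;
- **coiled-coil masking** — a COILS-style sliding-window heptad
  predictor; masked residues are excluded from profile columns;
- **profile–profile comparison** — Smith–Waterman over the half-bit
  co-emission score `2·log2(Σ_a f1_a f2_a / b_a)` with gap costs scaled
  by column gap fractions, and shuffle-null significance (rank-based
  p-values plus Gumbel-calibrated tails);
- **classification** — three-seed UPGMA cladograms with a majority-rule
  (≥ 2/3) consensus and replicated-cluster extraction; thresholded
  (P < 1e-2) similarity networks weighted by `min(−log10 P, 20)`,
  partitioned by greedy modularity maximisation, with sub-network
  re-clustering of merged classes;
- **a synthetic-family simulator** — duplication–neofunctionalization
  of an ancestral dimer → tetramer → five complexes plus one
  half-complex (22 families), evolved along a two-clade species tree to
  twilight-zone divergence, with a shared slow-evolving N-terminal CC
  as a planted confounder and full ground truth (losses, lineage
  duplications, site genealogy), so every stage is testable without
  external databases.

## Worked example

```r
library(profhom)

cfg <- pipeline_config(seed = 1)      # defaults = the study conditions
res <- run_pipeline(cfg, "run1")      # writes all artifacts to run1/

# twilight-zone calibration of the simulated orthologs
st <- ortholog_identity_stats(res$dataset)
median(st$identity)                   # 17.85  (percent identity)
median(st$similarity)                 # 37.59  (percent similar pairs)

# classification outputs, exactly as computed
res$orthology$combined                # validated assignments + conflicts
res$cluster_consensus$k               # replicated cladogram clusters
res$partition_masked$n_clusters       # masked P<1e-2 network clusters
res$subpartition$n_clusters           # re-clustering the largest cluster
```

On the default run the median ortholog identity sits below 20% (the
published characterisation of these orthologs) and combined reciprocal
orthology recovers over 90% of the planted orthologs, with
disagreements flagged as conflicts rather than silently resolved (both
properties are asserted by the acceptance tests). The classification
stages are computed and reported exactly as the procedures define them;
with the in-house alignment engine and this desk-scale dataset the
shuffle-null network is stricter than database-calibrated profile-HMM
significance, and the class-level cluster structure it reports differs
from the published four-cluster / three-cluster picture — the methods
vignette analyses why in detail. `run1/` contains the ortholog count
matrix (`ortholog_matrix.tsv`), per-protein coiled-coil annotations
(`cc.tsv`), orthogroup MSAs and profiles, cladograms and consensus
(`*.nwk`), network edge lists and cluster memberships (`clusters.tsv`,
`subclusters.tsv`), the asymmetric alignment-length / log10-P heatmap
matrices, and a manifest; identical configuration and seed reproduce
every file byte for byte.

A thin command-line wrapper is installed with the package
(`exec/profhom`): `profhom simulate|run|report --config cfg.yaml
--seed 1 --out dir`.

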