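---
title: "Methods: simulation, search and clustering in profhom"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: simulation, search and clustering in profhom}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

profhom detects and classifies remote homology among deeply divergent
paralogous protein families. Its motivating system is the CATCHR class
of multisubunit tethering complexes (exocyst, COG, GARP, DSL1), whose
subunits fall into four homology classes (g51, g52, g53, g54) thought to
descend from one ancestral tetramer, itself derived from an ancestral
dimer. Their orthologs sit in the twilight zone of sequence similarity
(roughly below 20-25% pairwise identity), where single-sequence methods
fail and where an N-terminal coiled coil injects spurious similarity
across otherwise unrelated families. This vignette documents the models,
parameters and numerical choices; the README shows a worked example.

## The synthetic-family generator

Because the real analysis depends on database-scale searches that cannot
be reproduced at desk scale, the package ships a generator that emulates
the study conditions and provides ground truth for every downstream
stage.

**Duplication history.** One ancestral protein gives rise, pre-LECA, to
an ancestral dimer (body + arm), the dimer duplicates into a tetramer of
four classes, and tetramer duplications radiate five full complexes plus
one half-complex retaining only its g53/g54 subunits (the DSL1
analogue) - 22 families in total. The true class topology is
((g51, g52), (g53, g54)); the observed similarity ordering (g53-g54
closest, g52 most remote) is produced by branch lengths, not topology:
the g53/g54 split is the shallowest (default 1.5 substitutions/site
above the LECA analogue, versus 2.3 for g51/g52 and 2.8 for the dimer
origin), the g51 and g52 stems carry extra length (0.4 and 1.0)
modelling their faster divergence, and the complex radiation spans
1.1 to 0.45. No quantitative schedule exists for these splits in the
literature; the defaults were chosen once to reproduce the qualitative
ordering and are configuration-exposed.

**Species tree.** Six taxa in two clades of three, with within-clade
splits at 0.35 and 1.3 and a species root at 3.6. The ladder of
progressively more divergent relatives inside each clade plays the role
a deep sequence database (UniRef90) plays for iterative profile
enrichment: a seed can walk outward stone by stone. Cross-clade
ortholog pairs are twilight-zone remote; within-clade pairs remain
alignable. The three seed taxa are tax1, tax2 (same clade - mirroring
the fact that two of the published seed organisms, human and yeast, are
both opisthokonts) and tax4.

**Substitution process.** Per site, a replacement event occurs on a
branch of length `t` with probability `1 - exp(-r t)`; the replacement
is drawn from the off-diagonal BLOSUM62-conditional distribution
(reconstructed from the log-odds matrix shipped with Biostrings), so
events always change the residue and branch lengths read as expected
substitutions per site. Site rates mix a small conserved structural
core (fraction 0.08 at relative rate 0.2, drawn once at the ultimate
root and inherited by every family - helical-bundle packing positions)
with gamma-distributed rates (shape 2) elsewhere, rescaled to overall
mean 1.

**Neofunctionalization as changed constraint.** The class signal that
profile comparison detects is modelled as site-specific residue pools:
45% of ancestral body sites carry a pool of six residues to which
substitutions are confined, and on each child branch of a duplication a
further fraction of sites (0.35 at dimer/class duplications, 0.05 at
complex duplications) acquires a fresh pool - the changed functional
constraint of the duplicate. Pools also turn over slowly along branches
(rate 0.08/unit), so pool sharing between two lineages decays with
divergence. Descendants of a duplication therefore share site-specific
amino-acid preferences that other lineages do not: profiles diagnose
the groups through shared column distributions, while pairwise identity
barely moves (within a 6-residue pool two orthologs coincide only
slightly more often than at random). This is the standard picture of
duplication followed by neofunctionalization expressed at the level of
site constraint.

**Coiled-coil confounder.** All families inherit one N-terminal
56-residue heptad segment from the ultimate root. It evolves at 1/4 of
the body rate and its replacements are drawn from heptad-position-
specific propensity distributions, so the segment keeps its coiled-coil
character indefinitely: every family, however remote, shares a
recognisable N-terminal block. Indels never touch it.

**Indels and gene content.** Indels are Poisson (0.015 events/site per
unit branch length) with geometric lengths (mean 3). Per taxon and
family, losses occur with probability 0.14 under a zero-truncated model
(every taxon loses at least one family - the irregular distribution
every real lineage in this regime shows); lineage-specific duplications
occur with probability 0.05 (the extra copy diverges by a further 0.3).
Site identity is tracked through all indels, so the true alignment of
any family is recoverable (`truth_msa()`), and a single integer seed
governs everything.

**Calibration.** With these defaults the median percent identity of
orthologs against their seed-taxon representative is 17-19%, matching
the published characterisation of such orthologs ("lower than ~20%").
The identity statistic itself uses stiffer gap penalties (open 14,
extend 4) than the search alignments: with cheap gap extension an
aligner pairs only matching stretches and the gapless-pair identity of
even unrelated sequences floors near 22%, which would make the
twilight-zone calibration meaningless; at (14, 4) unrelated pairs sit
near 13%.

**What the generator does not emulate.** Real domain gains/losses,
length heterogeneity between families, compositional biases beyond
BLOSUM62, heterotachy beyond the pool shifts, and alignment-level
annotation noise. Passing tests demonstrate that the pipeline's logic
recovers planted structure under this model, not that it would resolve
any particular real family.

## Alignment engine and significance

Profiles are per-column pseudocounted frequency models
(`(counts + 0.1 b) / (n + 0.1)`) with per-column gap fractions - a
deliberate simplification of profile HMMs; the comparison logic, not
the search engine, is the subject here, and the engine sits behind a
narrow interface. Profile-profile comparison is Smith-Waterman over the
half-bit co-emission score `2 log2(sum_a f1_a f2_a / b_a)` with affine
gaps (open 10, extend 1) scaled by `1 -` the skipped column's gap
fraction. Tracebacks use a fixed tie-break (diagonal > up > left), so
everything is deterministic. Scoring a profile against a single
sequence collapses to a PSSM lookup, which is how database scans are
executed. Score-only paths run in single precision inside a diagonal
band (half-width 64; cumulative indel displacement has standard
deviation ~25 residues at full depth, so the band is generous);
observed and null scores use the same banded statistic, keeping
significance internally consistent. Exact double-precision kernels back
all tracebacks and are verified against brute-force path enumeration in
the tests.

Significance is empirical: column-order shuffles of the target profile
give a null, and `p = (1 + #{null >= obs}) / (n_shuffles + 1)`. For
network construction the shuffling stops early (sequential estimate
`h/T` after five exceedances), which prices hopeless pairs cheaply
and leaves significant pairs exact. For database searches, where
thresholds like 1e-5 lie far below the resolution any affordable
shuffle count can reach, e-values come instead from a Gumbel
(extreme-value) tail fitted by the method of moments to shuffled-query
scores against a database subsample - the same family of calibration
HMMER uses. Both quantities appear on hits: the rank-based p-value
where it is resolvable, the fitted e-value where extrapolation is
required.

## Orthology workflow

From each seed protein of each seed taxon: (1) iterative profile
enrichment against the pooled proteomes (3 rounds, inclusion e <= 1e-5;
rounds after the member set stabilises are provably no-ops and are
skipped); (2) forward best-hit search into every target proteome
(e <= 1e-3, ties by alignment length then id); (3) reciprocal check -
the hit is enriched into its own profile (4 rounds at 1e-2) and
searched back against the seed proteome with no threshold; the rank-1
hit must be the seed (rank-1 by score equals rank-1 by e-value, so the
back search needs no null calibration). In parallel, a single-sequence
route takes reciprocal best hits from global-alignment scores (forward
1e-2, reciprocal 1e-3, query coverage strictly above 40%). One pooled
all-vs-all sequence scan provides every forward and reciprocal slice
of that route. The three seed analyses and both routes are combined per
(family, target taxon) by best e-value; disagreements between validated
assignments are flagged `conflict` rather than manually curated, and an
optional curation overlay can be applied downstream. Forward hits
beyond the best (scan depth 3) feed the lineage-duplication scan behind
the co-ortholog counts.

## Clustering stages

**Three-seed cladograms.** Each seed taxon's enrichment profiles are
compared all-vs-all; scores are symmetrised (`S = (S + S') / 2`) and
turned into distances by `max(S) - S` (rank-preserving; `1/(1+S)` is
available), then clustered by average linkage (UPGMA). The consensus
over the three cladograms is majority-rule (clades in >= 2/3 of trees,
annotated with support). "Clusters replicated in at least two of three
analyses" is operationalised as the largest k for which every group of
the k-cuts is replicated in >= 2/3 of the trees and the replicated
groups cover all leaves; replicated groups are automatically disjoint
once the threshold exceeds one half.

**Similarity networks.** Orthogroup MSAs (progressive alignment with a
UPGMA guide tree on 1 - identity, trimmed of columns with more than 80%
gaps) yield one profile per family, built with and without coiled-coil
masking (masked residues are excluded like `X`, preserving
coordinates; a fully masked column carries background frequencies).
All-vs-all hits below p < 1e-2 define an undirected graph (an edge when
either direction passes; weight `min(-log10 p, 20)`). Greedy modularity
maximisation (Clauset-Newman-Moore agglomeration via igraph;
deterministic) partitions the graph, with Q recomputed independently
from the standard weighted formula. The largest cluster - in the
default model the merged g53/g54 twin classes - is re-clustered on its
induced subgraph. A second network variant keeps only each query's four
best hits with p < 1e-2 and alignment length > 300 positions, probing
complex-level rather than class-level relationships.

## Numerical and design choices worth knowing

- Reciprocal-profile enrichments and pooled sequence scans are memoised
  per protein within a run; results are identical to recomputation.
- Degenerate inputs: empty optimal local alignments return score 0 with
  empty spans; all-gap columns carry background frequencies with a
  warning; an edgeless graph partitions into singletons with Q = 0.
- The coiled-coil predictor uses the package's curated heptad propensity
  table (COILS-style: aliphatics at a/d, charged residues at e/g,
  helix breakers penalised) and a two-Gaussian posterior whose
  parameters were calibrated on random background sequences (globular
  component) and on simulator-evolved heptad segments (coiled-coil
  component); with the default 0.5 cutoff the mask recovers ~98% of
  true coiled-coil residues at ~1% false positives.
- Problem sizes used throughout the tests (22 families, 6 taxa,
  700-residue proteins, 120 shuffles for network significance) are the
  package's default study conditions; unit tests use smaller
  configurations of the same generator.
- Thread count never affects results; all reductions are order-fixed.

## Known limitations

Profiles carry no insert/delete states, so position-specific gap
structure is only approximated by gap-fraction scaling. Gumbel
calibration from small null samples carries order-of-magnitude jitter
in deep tails; thresholds inherited from the published workflow are
interpreted against that calibration. Enrichment can absorb paralogs
when classes are close (the "mix of orthologs" problem the original
workflow also faced); the reciprocal check and the three-seed
combination are the designed mitigations, and conflicts are surfaced as
data rather than resolved silently.

Two consequences of desk scale deserve emphasis, because they determine
which published observations this package reproduces and which it does
not.

First, the column-shuffle null: a shuffled profile retains its column
content, so any similarity that is compositional - the shared coiled
coil, the superfamily-wide conserved core, chance pool overlaps - is
largely credited to the null rather than to the hit, and only the
*colinear excess* of an alignment counts as significant. This makes the
network stage strict: in the default simulation the masked P < 1e-2
network is sparse, resolves classes into separate (sometimes
fragmented) clusters, and the g53/g54 twin classes do not merge the way
they do under database-calibrated profile-HMM significance, where
shared composition between genuinely related families contributes to
the score.

Second, profile depth: each orthogroup here holds 4-6 sequences, where
the published automated HMMs were database-enriched with hundreds. At
twilight-zone divergence the in-house progressive aligner recovers only
about half of the true homologous column pairs (measured against the
simulator's site genealogy), and that alignment noise varies between
the three seed analyses, so their cladograms rarely replicate the
class-level partition even though profiles built on the *true*
alignments recover all four classes cleanly (this is verified
directly against the generator's ground truth during development). The
consensus machinery therefore reports many small replicated groups or
a single trivial one rather than the published four. Both cluster
outcomes are computed and reported exactly as the procedures define
them; the orthology, calibration and masking results do reproduce the
published characterisations.
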