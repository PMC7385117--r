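---
title: "Models and methods behind syngloss"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind syngloss}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`syngloss` bundles three comparative-genomics analyses — macrosynteny
detection, Dollo gain/loss mapping, and habitat-paired convergent-loss
testing — together with the simulator used to validate them. This
vignette explains the models, the parameters that matter, the numerical
choices, and what the validation does and does not establish.

## Data model and coordinate conventions

Genomes enter as ordered gene lists: each gene has a scaffold and a
0-based ordinal `rank` along it, assigned by ascending start coordinate
with ties broken by (end, gene id) so rank assignment is deterministic.
BED input is treated as 0-based half-open; GFF3 (1-based inclusive,
`gene` features, `ID` attribute) is converted to the same internal
convention on read. Gene identity across files is exact string match —
no prefix stripping — because silent identifier munging is a classic
source of phantom synteny. `validate_taxa()` reports name disagreements
between the orthogroup matrix, tree and habitat panel before any
analysis runs.

## Orthology

`reciprocal_best_hits()` collapses multiple HSP rows per (query,
subject) to the best-scoring one, ranks each query's subjects by
bitscore, then e-value, then lexicographically smallest subject id, and
keeps mutual best pairs. Whether bitscore or e-value leads the ranking
is configurable (`rank_by`) since similarity pipelines differ; bitscore
is the default. Two tie policies are exposed: resolve score ties
lexicographically (default, fully deterministic) or exclude genes whose
top two subjects tie on both score keys (`ambiguous = "exclude"`), for
users who prefer dropping genuinely ambiguous genes to guessing. Output
is one-to-one by construction and invariant to input row order.

Within-genome families for tandem/segmental duplication analysis come
from single-linkage components over self hits at
`min_bitscore >= 50` (a conventional screen-level cutoff; no published
value exists for this step, so it is explicit configuration).

## Macrosynteny

The counting universe of the Oxford grid is **ortholog pairs**, not
genes: every dot on the grid is one pair, margins are pair counts per
scaffold, and `n_total` is the number of pairs with both genes
annotated. Cell enrichment is the hypergeometric upper tail
`P[X >= n_shared]` with BH correction across the non-empty cells of one
species pair — the scale at which a grid is read. The test is an
operationalization: reports of scaffold-level macrosynteny in the
literature typically name matched scaffolds without stating a
significance procedure, so the procedure here is this package's own,
recorded in every run report.

Co-linearity is summarized two ways. Spearman's rho is familiar but
punishes a single large inversion severely; `lis_fraction` — the longer
of the longest strictly increasing and strictly decreasing subsequences
of one side's ranks taken in the other side's order, divided by the
number of pairs — scores any single monotone rearrangement as 1 and
decays toward `2/sqrt(n)` (the Ulam limit for random permutations) as
within-chromosome shuffling accumulates. Classification uses
`lis_fraction` alone; rho is descriptive and reported as `NA` below 3
pairs, in which case it plays no role.

Defaults `q_max = 0.05`, `min_pairs = 5`, `colinear_min = 0.8` are
package choices (no published thresholds exist for this pipeline): 5
pairs is the smallest cell where "order" is meaningful, and 0.8 keeps a
cell with one secondary rearrangement on the co-linear side while
sending genuinely shuffled cells (which sit near `2/sqrt(n)`, about 0.14
at n = 200) to the shuffled class. All three are configurable and echoed
in the run report.

Tandem arrays are maximal same-family runs along a scaffold with at most
`max_gap` intervening genes (default 1, tolerating single insertions
inside an array). The self-similarity dotplot projects within-species
hits onto one scaffold's rank coordinates with forward/reverse
orientation from strand agreement and mirrored points, the conventional
rendering for segmental duplications.

## Dollo gain/loss

Presence/absence of each orthogroup is mapped onto the rooted species
tree under Dollo parsimony: a single origin at the MRCA of the carrying
taxa, and losses exactly on edges from a live parent to a dead child
within the origin's subtree. This is the unique minimal single-gain
explanation; the implementation is vectorized over orthogroups (one
indicator-matrix product per matrix) and verified against an exhaustive
minimal-assignment oracle on every rooted binary shape with up to six
tips and every presence pattern. Dollo (rather than a birth–death rate
model) is fixed as the criterion because presence/absence of gene
families is the regime where re-gain is negligible; the choice is
recorded in the output metadata. Polytomies are allowed, with losses
attributed per child edge.

Because the origin is inferred from surviving carriers, events are only
identifiable up to the *observable projection* of the truth: if losses
eliminate every carrier on one side of the true gain node, the inferred
origin contracts to the MRCA of the survivors, and two sibling losses
covering a clade are inferred as one loss into their parent. Recovery
tests therefore assert exact equality between inference and the
independently computed projection of the simulated event log, plus the
bound that inference never claims more loss events than were simulated
for surviving orthogroups. Summed over orthogroups, origins always equal
the number of orthogroups present in at least one taxon — checked on
every run.

Per-tip "gene gain" is reported under two definitions, because published
headline gain counts are gene-level while their recipes are typically
unstated: (i) orthogroups originating on the terminal edge, and (ii) the
member genes of those orthogroups plus the copy-number excess
(count − 1) in older orthogroups. `topology_contrast()` reruns the
reconstruction under two root hypotheses over the same tips and aligns
clades by tip content, exposing how loss counts shift with the root —
the sponges-sister versus ctenophores-sister question.

## Convergent loss

A habitat panel pairs one marine and one freshwater taxon per phylum.
The freshwater loss set of a pair is the orthogroups present in the
marine taxon and absent in the freshwater one; requiring additional
presence outside the pair (`require_outside_presence`) is off by
default, matching the plain reading of "losses specific to freshwater
species", but exposed because the stricter rule is equally defensible.
The analysis reports all-`n` and leave-one-out intersections in both
directions, the background mean shared absence over random taxon subsets
of the panel size (exact enumeration when `choose(T, n) <= 10000`, else
seeded Monte Carlo), all four t-test variants on the leave-one-out
counts — pooled/Welch × one/two-sided, with `glance()` flagging which
variant lands nearest a user-supplied reference p, rather than silently
choosing one — and an exact permutation test.

The permutation test swaps marine/freshwater labels within pairs over
all `2^n` assignments (identity included, so p ≥ 1/2^n) and uses the
difference in mean leave-one-out counts as the default statistic; the
all-`n` difference is an option. With the classic four-pair design the
attainable floor is 1/16 = 0.0625, so the test can never reject at 5% —
a design constraint, not a bug — and calibration is therefore
demonstrated on six-pair panels, where the rejection rate at the 5%
level over 1000 null panels falls at the near-nominal value dictated by
the discrete support (3/64 ≈ 0.047 minus tie effects).

## The simulator

`simulate_dataset()` generates, from one seed: orthogroup content
evolving by Poisson gains (rate γ per unit branch length), strict Dollo
losses (probability `1 − exp(−λ·len)` per branch, re-gain disallowed so
recovery can be asserted exactly), and Poisson duplications (δ per
retained orthogroup); gene order evolving by uniform-interval inversions
(which flip strands, so dotplot orientation is testable) and
between-chromosome translocations (start uniform, length 1 + Poisson(4)
capped at the chromosome end); duplicates inserting adjacent to their
parent with probability `p_tandem`, creating tandem arrays; and
similarity tables with one mutual hit per within-orthogroup gene pair
(same-lineage pairs scored higher than paralogs), degraded by per-row
dropout and contaminated with low-score spurious hits. Branch lengths
come from the Newick; unit lengths are substituted with a warning.

Defaults — 200 root orthogroups, γ = 5, λ = 0.3, δ = 0.2, 3
chromosomes, inversion rate 5, translocation rate 0.2, p_tandem 0.6,
dropout 0.05, spurious 0.02 — are fixed once as a plausible
metazoan-scale regime scaled to desk size: loss probability ≈ 26% per
unit branch, a few inversions per branch so order decays visibly within
a few branches, translocations an order of magnitude rarer than
inversions (the DCJ-DS premise), and noise levels at which RBH remains
mostly but not perfectly recoverable. Validation suites override only
the parameters a given check is about (e.g. inversions-only sweeps with
translocation rate 0).

Every event is logged with concrete coordinates; `replay_gene_order()`
re-applies the log from the root and asserts byte-level equality with
the stored tip genomes. All randomness flows through fixed per-stage
substreams of the config seed, so identical configs emit byte-identical
files — the basis of the pipeline determinism checks.

**What the simulator does not emulate**: sequence evolution (bitscores
are stylized, not alignment-derived), gene conversion, many-to-many
orthology noise from real clustering, assembly fragmentation,
annotation error, and rate heterogeneity across lineages. Passing
recovery tests therefore shows the algorithms are correct under their
generative assumptions, not that real-data inputs satisfy those
assumptions; on real data, orthogroup quality and annotation
completeness dominate the error budget.

## Problem sizes and degenerate inputs

The shipped validation runs at desk scale, chosen as the package's own
test conditions: synteny sweeps use 2 genomes × 3 chromosomes × 200
genes over 20 seeds and inversion loads {0, 5, 20, 100}; Dollo recovery
uses an 8-tip tree over 10 seeds; enrichment is checked against
exhaustive enumeration for every margin combination with `n_total <= 20`
(agreement to 1e-12); permutation calibration uses 1000 six-pair null
panels of 12,000 orthogroups.

Degenerate inputs are contracts, not crashes: empty annotation files
parse to empty tables; cells with fewer than 2 pairs get `NA`
co-linearity (flagged, not an error); orthogroups absent from every
analysis taxon are dropped with a counted warning; both-groups-constant
t-tests return t = 0, p = 1 when means agree; a gene id appearing in
both species' namespaces, duplicated gene or orthogroup ids,
inconsistent Oxford-grid margins, unknown taxa and unreadable trees are
hard errors naming the offender.

## Known limitations

- Macrosynteny classification is per-cell; no microsynteny block
  chaining or ancestral karyotype reconstruction is attempted.
- Dollo parsimony understates loss when re-gain (e.g. horizontal
  transfer) occurs, and the origin of an orthogroup surviving in a
  single clade is indistinguishable from a later gain.
- The hypergeometric test assumes pairs fall on scaffolds independently
  under the null; strong scaffold-size heterogeneity makes it
  conservative for small scaffolds rather than anti-conservative.
- The convergence t-test inherits the small-n fragility of its inputs;
  that is why all four variants and the exact permutation test are
  always reported side by side.
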