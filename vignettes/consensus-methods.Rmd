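---
title: "Consensus analysis of multi-study transcription-factor targets: models and choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Consensus analysis of multi-study transcription-factor targets: models and choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fkhconsensus)
```

## The problem

Genome-wide binding assays — ChIP-chip on microarrays, ChIP-exo/seq,
ChEC — for the same transcription factor disagree substantially in the
target genes they report, for reasons ranging from platform resolution
to peak-calling stringency to growth conditions. For the budding yeast
Forkhead factors Fkh1 and Fkh2, six published studies yield target
lists whose pairwise overlaps are small relative to their sizes. It is
unrealistic to demand that a functional target appear in every study;
it is equally unsafe to accept any single study's list. This package
implements the middle road: treat each study as a Boolean vote over a
common gene universe, require a target to recur in at least *k* of *n*
studies, and then demand independent functional evidence — a
transcriptional response to deleting or overexpressing the factor —
before calling a consensus target validated.

## Model and assumptions

**Boolean summarization.** A study contributes only a target set; score
magnitudes are consumed once, at load time, by a per-study threshold
rule, and never weighted afterwards. This is deliberate: the six
studies' scores live on incommensurable scales, and the analysis's unit
of evidence is a (study, gene) call, not a score. No probabilistic
reliability model is fitted — the consensus rule is a plain count, so
every downstream number can be re-derived by hand from the target
matrix.

**Gene identity.** Systematic names (e.g. `YPR119W`) are canonical;
standard names map through an alias table, case-insensitively. Names
that map nowhere are kept verbatim (uppercased) and logged rather than
dropped: silently losing a gene because a study used an unusual label
would bias every count downstream. Duplicate rows for a gene collapse
by OR — multiple peaks in one promoter are one membership.

**Hamming similarity.** Agreement between two studies counts both
both-target and both-non-target genes, divided by the number of rows in
the matrix. The denominator is therefore a modelling choice. The
default is the full declared genome (`universe_mode: genome`): two
small, clean studies then score as highly similar because they agree on
the vast non-target majority. The alternative union mode restricts
rows to genes targeted by at least one study and is more sensitive to
target-set disagreement. Because the numbers change with the choice,
the mode is carried on every similarity object and echoed in the run
metadata; padding the universe with never-targeted genes provably moves
all similarities monotonically toward 1 while leaving intersections and
consensus sets untouched (this invariant is under test).

**Validation.** Deletion response is a single signed score per gene;
overexpression is an ordered time course. A gene responds on an axis
when its score reaches a configurable cutoff in magnitude; genes absent
from a table carry *no evidence*, which is not the same as a zero
response — they can still be validated on the other axis.
Overexpression responsiveness is judged at the final time point by
default (`oe_rule: final`): the stable end-state is the biologically
interpretable readout, and several genuine targets overshoot early
before settling. An any-time-point rule is available behind
`oe_rule: any` for sensitivity analyses. Non-monotone trajectories
(up-then-down and the mirror) are flagged only when the course crosses
*both* the positive and negative cutoffs — a sign change inside the
noise band is not a reversal.

**Phase enrichment.** Validated targets are binned by phase of peak
expression. Genes without a phase (`NO_DATA`) stay in the set — they
appear in the CCR-fraction denominator and as an explicit display
category — but are excluded from phase-fraction denominators, so phase
fractions are proportions of the cell cycle-regulated genes in the set.
The enrichment baseline is the genome-wide distribution over all CCR
genes (not all genes), matching the question "among cycling genes,
where do this factor's targets peak?"; the baseline set is configurable.
Enrichment is reported as a difference and a ratio of proportions with
no attached hypothesis test: the input target lists are themselves the
product of thresholding decisions, and a p-value computed downstream of
those would suggest a precision the design does not have. Differences
across phases sum to zero by construction, which is asserted in tests.

## Tunable parameters

| Parameter | Default | Units / range | Why |
|---|---|---|---|
| `k` | 4 | studies | consensus vote threshold; 4 of 6 balances the studies' high variability against false accumulation of popular false positives |
| `universe_mode` | `genome` | — | Hamming denominator (see above) |
| threshold rule | per study | score units | each study's score column, direction (≥ / ≤) and cutoff are explicit config — published scales differ in sign and meaning, so nothing is hard-coded |
| `cutoffs` | 1, 1 | score units (e.g. log2 fold change) | deletion / overexpression response thresholds; must be ≥ 0 |
| `oe_rule` | `final` | — | where overexpression responsiveness is judged |
| phase grouping | Early = G1(P), G1, G1/S; Mid = S; Late = G2, G2/M, M, M/G1 | — | growth / genome-duplication / division stages; any grouping covering the 8 phases once is accepted |

A study whose published list merges several sub-experiments (for
example a study reporting both a standard and an extended probe-level
experiment) is handled upstream of the matrix: supply the merged list
as one pre-called table (the default posture), or supply the
sub-experiments as separate studies if their disagreement is itself of
interest. The package takes no position beyond what the config states.

## The synthetic-data generator

`generator_config()` defines a two-factor benchmark whose defaults are
the package's standing study conditions:

* 6000 genes; true regulons of 350 and 90 genes, the smaller sharing
  55% of its genes with the larger — mirroring a pair of paralogous
  factors with a large-regulon / small-regulon asymmetry and
  substantial overlap;
* six studies per factor at sensitivity 0.8 and false-positive rate
  0.02, independent across genes and studies;
* true targets respond to deletion and to overexpression with
  probability 0.35 each (independently — so ~12% respond to both and
  ~58% to at least one); responding deletion scores are positive with
  probability 0.8 and responding overexpression courses end below
  threshold with probability 0.9, reproducing the asymmetry expected
  for targets under active regulation; background response rates 0.02;
* responder score magnitudes are `cutoff + |N(1, 0.5²)|` and
  non-responders (and all earlier time-course points) draw
  `N(0, (cutoff/4)²)` — recorded in the bundle manifest; analyses and
  tests depend only on threshold crossings, never on these shapes;
* phases: true targets are CCR with probability 0.55, concentrated in
  S/G2/M phases; background genes are CCR with probability 0.11, so the
  genome-wide CCR fraction lands near 14%, under the sub-15% regime
  typical of yeast.

All draws flow from one seed in a fixed order (truth, studies in
factor-major order, validation per factor, phases, annotation), so a
bundle regenerates byte-identically. What the generator does **not**
emulate: correlated errors between studies (shared platform biases,
shared growth conditions), promoter-level signal, score distributions
with realistic tails, or regulatory structure beyond factor→target
edges. A pipeline that passes on this generator is therefore shown to
be *correct under independence*, not robust to correlated artefacts —
on real data, correlated false positives will inflate k-of-n consensus
sets in a way these tests cannot detect.

## Numerical and degenerate-input choices

* Phase- and group-fraction sums are asserted to 1 within 1e-12; an
  all-`NO_DATA` gene set has undefined (NA) phase fractions rather
  than zeros.
* A ratio against a zero baseline fraction is NA, with the difference
  still reported.
* Intersection tables sort by count descending, then subset size, then
  label; consensus sets and shared-target lists sort lexicographically —
  all output files are byte-stable across reruns, which is under test.
* Empty target sets, empty validation tables, and genes absent from
  every table are all legal inputs that flow through with warnings, not
  errors; ragged overexpression tables and unknown phase labels are
  format errors that abort.
* `k` outside 1..n, unknown config keys, duplicate study ids, and
  negative cutoffs abort before any file is read; a failed pipeline
  stage leaves no partial output directory (writes are staged).

## Problem sizes

The test suite and the acceptance script run entirely on generated
data: oracle comparisons enumerate up to 4 studies × 10 genes
exhaustively; property loops use universes of 500–6000 genes; the
consensus-recovery study uses 20 replicates of 6 studies over 1000
genes (true regulon 100, sensitivity 0.9, false-positive rate 0.01),
where the 4-of-6 consensus recovers the truth at a mean Jaccard above
0.9; the law-of-large-numbers check on validation categories uses a
regulon of 10⁴. The full suite completes in well under a minute on one
CPU.

## Known limitations

* The consensus rule weighs all studies equally; a study known to be
  noisy dilutes the vote, and the only defence is its load-time
  threshold.
* Hamming similarity in genome mode saturates near 1 for sparse target
  sets; compare studies in union mode as well before reading similarity
  rankings.
* Validation classifies evidence, not causation: an upregulated gene
  after deletion may respond through an intermediate regulator.
* The network export restricts edges to supplied annotation tables; it
  performs no inference and renders no figure — the node/edge TSVs are
  meant for downstream graph tools.
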