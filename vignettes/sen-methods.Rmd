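---
title: "Structural ensemble neutrality: model, design choices and validation"
author: "senRNA"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Structural ensemble neutrality: model, design choices and validation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(senRNA)
```

## The problem and the statistic

Structured RNAs — riboswitches, ribozymes, regulatory elements — are
conserved at the level of secondary structure more than sequence, and
evolved structures tend to be *mutationally robust*: most single point
mutations leave the functional fold intact.  senRNA quantifies this
through **neutrality**: the mean structural similarity between a
sequence's reference structure and the structures adopted by its
1-mutant neighbours.  A sequence of length $L$ over $\{A,C,G,U\}$ has
exactly $3L$ such neighbours.

Three metrics are implemented, differing in how a mutant's structure is
summarised and compared with the reference $T$:

* **SEN** (structural ensemble neutrality) samples $N$ structures from
  each mutant's Boltzmann ensemble and averages the fraction of
  reference pairs retained, $|T \cap T'|/|T|$.  Pairs *gained* by the
  mutant are not penalised — the statistic asks only whether the core
  structure survives.
* **bp-distance neutrality** compares $T$ with each mutant's single MFE
  structure through the symmetric-difference base-pair distance,
  normalised by $L$: the per-mutant term is $1 - d(T, \mathrm{MFE})/L$.
  The normalisation by $L$ (rather than the maximal pair count $L/2$)
  is kept as conventionally defined, although it compresses the usable
  range into $[1/2, 1]$ for structures; the metric is used comparatively,
  so the compression is harmless.
* **PCC neutrality** reduces the centroid of each mutant's sampled
  ensemble (pairs present in strictly more than half of the draws) and
  the reference to 0/1 paired-position vectors and correlates them.
  The per-mutant term maps the correlation $r$ into $[0,1]$ as
  $(1+r)/2$, so an identical centroid scores 1.  The alternative
  orientation $(1-r)/2$, which scores identity as 0, is inconsistent
  with the requirement that structured sequences sit high on the scale
  (and with how every other metric here is oriented); it remains
  available through `form = "printed"` for comparison.  When either
  vector is constant, $r$ is undefined; the term is then 1 for equal
  vectors and 0.5 — the no-information midpoint — otherwise.

Crucially, the reference structure $T$ is **not** the sequence's own
MFE structure but the consensus of a homologous alignment (given
annotation, or predicted by consensus folding).  The per-sequence
workflow is: degap sequence and consensus simultaneously (a pair losing
its partner column becomes unpaired; a pair squeezed below the minimal
hairpin loop of 3 enclosed bases is dissolved, because it is physically
impossible in the gap-free sequence); drop non-canonical pairs
(everything but Watson–Crick and G–U wobble); then evaluate the metric
over all $3L$ mutants.  Sequences with ambiguity codes, or whose
filtered reference retains no pairs, are skipped with a recorded
reason — neutrality over the $3L$ defined mutants is ill-posed for
them, and an empty reference makes the SEN ratio undefined.

## Folding engines

All metrics are engine-agnostic.  Two backends are provided:

* `viennaEngine()` drives the ViennaRNA suite (RNAfold, RNAsubopt with
  `--random-seed`, RNAalifold, RNAeval) at 37 °C with suite defaults.
  Engine name and version are written into every provenance sidecar,
  since absolute neutrality values are engine- and version-dependent.
* `toyEngine()` is a self-contained model with additive per-pair
  energies (GC/CG $-3$, AU/UA $-2$, GU/UG $-1$ in arbitrary units), a
  minimum hairpin loop of 3 unpaired bases, no stacking or loop terms,
  and Boltzmann weights $e^{-E}$ ($kT = 1$).  The model is small enough
  that MFE, exact pair probabilities and ensemble frequencies can be
  verified against full enumeration — the test suite does exactly that
  with an enumeration oracle written independently of the engine —
  while still producing the qualitative behaviour the metrics rely on:
  designed stems dominate their ensembles, shuffled sequences fold
  diffusely.

Numerical choices in the toy engine: the partition function is
unscaled, which bounds usable lengths at ~300 nt (far above every use
here); MFE traceback resolves co-optimal structures deterministically
by preferring a paired leftmost position and then the smallest partner
index — any fixed rule serves, since the accompanying tests check
optimality (energy equal to the enumerated minimum, structure contained
in the enumerated optimal set) rather than a particular tie
representative.  Boltzmann sampling uses per-interval cumulative weight
tables and one RNG draw per backtracking decision; every 1-mutant
neighbour samples from its own substream indexed by mutant rank, so
results are reproducible and independent of evaluation order.
Coordinates are 1-based throughout, matching both R idiom and
reporting convention.

## Tunable parameters

| parameter | default | rationale |
|---|---|---|
| `n` (ensemble sample size) | 1000 | 100 gives unstable values; 10000 does not measurably improve them |
| centroid threshold | > 0.5 strictly | majority pairs cannot conflict, so the centroid is always a valid structure |
| JSD composition threshold | 0.01 bits | tight composition matching of background sequences |
| background design | 10 inverse folds × 10 walks | 100 members per tested sequence |
| neutral walk length | exactly 4L attempted proposals | long enough to decorrelate from the inverse-fold seed |
| inverse-fold budget | 50 restarts × 10L steps | guarantees termination; the best (possibly inexact) match is returned |
| fixture substitution rate | 0.15 per unit | typical seed-alignment divergence |
| fixture pair-type weights | GC/CG 0.3 each, AU/UA 0.15, GU/UG 0.05 | GC-biased stems, as in structured RNAs |

## Mutational robustness

A sequence is robust when its neutrality strictly exceeds the mean
neutrality of a background of composition-matched sequences folding
into the same structure.  Backgrounds are built by inverse folding
(restarts of an adaptive walk minimising base-pair distance to the
target, with proposals preferentially aimed at currently mispaired
positions, as inverse folders conventionally do; the match is not
forced to be exact), filtered by Jensen–Shannon divergence of
mononucleotide composition < 0.01 bits, and each seed is refined by
10 neutral random walks.  Because an unconstrained structure search
rarely lands inside so tight a composition band, each inverse-folded
candidate passes through a structure-preserving *composition repair*
walk first: single mutations (compensatory at paired sites) that
never worsen the achieved base-pair distance and strictly reduce the
divergence, until the band is reached or a 10L move budget is spent.  A walk attempts exactly $4L$
proposals; a proposal mutates one random position (with a compensatory
mutation restoring a canonical pair when the position is paired in the
reference: a new G draws its partner uniformly from {C, U}, and by the
minimal symmetric completion A→U, C→G, U→{A, G}) and is accepted only
if the MFE structure is unchanged.  Two interpretations of "the
structure does not change" are possible — against the walking
sequence's own MFE structure or against the target; the default is the
own-MFE reading (the walk's natural invariant, since inverse-folded
seeds need not reach the target exactly), with `reference = "target"`
exposed as an option.

Because walks mutate composition, the JSD constraint is enforced both
on the inverse-fold seeds and as a guard inside walk acceptance, so
every final background member satisfies it by construction and
generation always terminates.  Inverse-fold start sequences draw their
stems from composition-weighted pair types and their loops from the
residual composition (target counts minus what the stems consumed);
without this, backgrounds for skewed compositions would almost never
pass the filter.  If no valid seed is found within the attempt budget
the sequence is omitted, and omitted sequences are excluded from the
robust-fraction denominator.

The designed high-neutrality control `plateauSequence()` alternates
G–C pair orientation along each stem.  This is deliberate: a
homopolymeric G…G/C…C helix admits equally stable register-shifted
foldings, diluting the ensemble and *lowering* neutrality, whereas the
alternating arrangement locks the register.  Loops are filled with A,
which cannot pair in the absence of U.

## Synthetic data: what it does and does not emulate

`syntheticStructuredAlignment()` emulates the statistical structure
the method assumes of a curated seed alignment: a shared consensus
structure, canonical (and with `covariation = TRUE`, compensatorily
covarying) paired columns, and controlled divergence from a common
ancestor at substitution rate 0.15.  The benchmark conditions are 30
such alignments on a 60-nt two-hairpin consensus (two 9-bp stems) with
5 rows each, against their exact dinucleotide-preserving shuffles
(Euler-path construction, per-row, gap columns held in place), whose
consensus is re-predicted by consensus folding — decoys never inherit
the positive structure.  The generator does **not** emulate: alignment
gaps along a phylogeny (rows are gap-free; the degapping machinery is
exercised by dedicated fixtures instead), non-independent rows related
by a tree, flanking genomic context, pseudoknots, or the
nearest-neighbour thermodynamics of real RNA.  Passing the synthetic
benchmark therefore demonstrates that the statistics and machinery
behave as designed under the model's assumptions — not that the
specific AUC or robust-fraction values transfer to curated seed
alignments with a physical engine, for which
`reproduceRfamStudy()` documents the full-scale path (local directory
of Stockholm seed alignments, Vienna engine; hours of compute).

The toy consensus folder is an alifold-style dynamic program on
alignment columns: a column pair is admissible when at least half the
rows could form a canonical pair there, weighted by the mean pair
energy over rows.  A pure majority-rule vote over independently folded
rows (kept in the test suite as an oracle) returns an empty consensus
for almost every shuffled alignment, which would leave decoys without
a reference structure; the column DP always yields the structure a
consensus folder would report, including for decoys.

## Classification and disruption analysis

The six standard alignment features (mean MFE Z-score against 100
per-row dinucleotide shuffles, structure conservation index, mean stem
entropy, mean stem mutual information, mean pairwise identity, number
of sequences) are assembled per alignment, optionally with mean
alignment neutrality as a seventh.  Gap handling: entropy and MI
exclude rows gapped at the relevant columns; identity excludes columns
gapped in both rows and counts gap-versus-base as mismatch.  The SVM
is radial-basis with default hyperparameters under stratified 10-fold
cross-validation; features are standardised on the training folds only
and decision values are pooled for a single ROC/AUC.  Because the sign
of SVM decision values depends on training-data class order, each fold
is oriented on its training data before pooling.

For disruption analysis, per-mutation structure-correlation values are
converted to the expected structure disruption coefficient
$\mathrm{eSDC} = (1 - \mathrm{PCC})\sqrt{L}$, the top half (strict,
stable ties) labelled disrupting, and a single-predictor logistic
regression of the label on neutrality is evaluated by ROC/AUC.

## Validation strategy and statistical conventions

The test suite validates the engine against exhaustive enumeration for
lengths up to 12 (MFE optimality, exact pair probabilities to 1e-9,
and sampled pair frequencies against exact Boltzmann probabilities).
One convention deserves a note: a per-entry $3\sigma$ binomial band
applied across the thousands of matrix entries the suite accumulates
would be violated by *correct* sampling roughly 0.3% of the time, so
the band is checked jointly — at least 98% of entries within
$3\sigma$ and every entry within $5\sigma$ — which is the
multiplicity-aware reading of the same bound.  Metric semantics are
checked metamorphically: augmenting every sampled mutant structure
with a non-conflicting extra pair must leave SEN unchanged and must
strictly lower bp-distance neutrality, the one behavioural difference
that separates the two definitions.

Problem sizes were chosen once as the package's study conditions: the
separation benchmark runs 30 structured/decoy pairs at $L = 60$, 5
rows, $N = 1000$; the robustness experiments run on a 20-nt stem-loop
with $N = 200$ and 20 replicates for the plateau-versus-random
comparison.  `scripts/acceptance.R` recomputes the headline quantities
from scratch at exactly these conditions.

## Known limitations

* The toy model has no stacking, dangles or loop penalties; absolute
  neutrality values are not comparable between engines.
* Pseudoknots are out of scope everywhere: WUSS pseudoknot letters are
  read as unpaired, and all metrics are defined on nested structures.
* A reference with very few pairs inflates SEN (few pairs can be
  broken); such sequences are better treated via the skip rule or
  interpreted with the pair count in hand (`n_pairs` is reported).
* RNAinverse (exposed as `rnaInverse()`) has no seed and is therefore
  not reproducible; the default inverse folder is the package's own
  seedable adaptive walk for both engines.
* Predicting *which* positions disrupt structure remains hard
  (positional profiles separate stems from loops clearly, but
  correlation with experimental disruption data is known to be weak);
  the machinery is provided for analysis, not as a validated
  predictor.
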