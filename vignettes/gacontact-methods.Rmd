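---
title: "Methods: genetic-algorithm classifier ensembles for long-range contact prediction"
author: "gacontact developers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: genetic-algorithm classifier ensembles for long-range contact prediction}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Residue pairs that are far apart in a protein's sequence but close in
space — long-range contacts — pin down the global fold. `gacontact`
predicts them from sequence information alone: per-residue sequence
profiles (20 numbers per residue summarizing a multiple sequence
alignment). A pair $(i, j)$ is a **long-range contact** when the
sequence separation satisfies $j - i \ge 24$ and the C$\alpha$–C$\alpha$
distance is at most 8 Å. Pairs at that separation whose distance exceeds
8 Å are long-range non-contacts; together the two classes form a
severely imbalanced binary classification problem (in typical chains
only a few percent of long-range pairs are contacts).

## The model

### Pair encoding

Each candidate pair $(i, j)$ is encoded from three profile windows: a
9-residue window centered at $i$, a 5-residue window centered at the
midpoint $\lfloor (i+j)/2 \rfloor$, and a 9-residue window centered at
$j$. The mid-window captures the chain segment that must bend to bring
$i$ and $j$ together. With 20 profile columns per residue this gives
$20 \times (9 + 5 + 9) = 460$ features. Window rows that fall outside
$1..L$ are zero vectors: zero-padding keeps the dimension fixed and
implicitly encodes proximity to the termini. The concatenated vector is
L1-normalized, because profiles are compositional and only relative
column weights carry information.

### Sequence profile centers

The **sequence profile center** (SPC) of a class within one chain is
the mean of that chain's encoded vectors of the class. At test time the
chain's structure is unknown, so pooled test SPCs are formed as the mean
of the training chains' per-chain centers; every test chain uses the
same pooled centers. Chains with zero contacts have no class-1 center
and are excluded from the pooled average (an error is raised if a
per-chain center is requested for an empty class).

### Chromosome grammar and feature transformation

A classifier's feature transformation is described by a string over
$\{a, b, c\}$ of length 460:

* `a` removes the feature at that position;
* a maximal run of identical `b`s or `c`s merges (sums) the features of
  the run into one output feature.

Runs are read on the *original* string: an `a` or a change of character
breaks a run, so `cbbabcca` on 8 inputs removes positions $\{4, 8\}$ and
emits four features $[1], [2{+}3], [5], [6{+}7]$. Two deliberate
readings are baked in: runs longer than two merge into a single group
(pairwise-only merging cannot produce large dimension reductions), and
merged values are **summed** before the output is re-L1-normalized, so
merging is mass-preserving. The package reports a transformation's
discard ratio as (removed + merged-away) / 460.

### Fitness and the evolutionary loop

A chromosome is scored on a labeled training set by compiling it,
transforming all vectors, forming the two class centroids *from the same
set*, and counting the samples whose nearest centroid (Euclidean
distance in the transformed space) matches their true label. The
maximum, positives plus negatives, is reached exactly when the imposed
class structure coincides with the true one. Ties in the distance
comparison go to class 0 (conservative for a precision-oriented task),
and the all-`a` chromosome scores 0 by convention.

The GA itself uses a population of 150 random chromosomes, copies the
top 5% unchanged (elitism — the best fitness is therefore
non-decreasing), fills the rest by roulette-wheel-selected parents
undergoing single-point crossover with probability 0.95 and per-position
mutation with probability 0.01, and stops when the best fitness has not
changed for 120 generations. A hard cap (`max_generations`, default
2000) guarantees termination; it triggers essentially never at the
default stall window. All of these are `ga_config()` parameters.

Two implementation notes. Distances are compared via the expanded form
$2\,x^\top(c_1 - c_0) > \lVert c_1\rVert^2 - \lVert c_0\rVert^2$, and
group sums are taken from a per-run precomputed row-cumulative-sum
matrix, so evaluating a chromosome is two column-gathers rather than a
matrix product — this is what makes the suite's GA runs affordable.
Both shortcuts are checked against naive interpreters in the tests.

### Undersampling ensemble

Negatives are partitioned into `n_gacs` (default 20) pairwise-disjoint
random subsets of positive-set size (capped at
$\lfloor |negatives| / n\_gacs \rfloor$ when negatives run short —
subsets never overlap). Each GaC trains on (all positives, one subset)
and holds two GA-evolved sub-classifiers, one targeting each class, with
independently derived seeds. How the two sub-classifiers combine into
one decision is a genuinely open design point: the default uses the
class-1 sub-classifier's nearest-centroid assignment, with an
"agreement" alternative (positive only if both assign class 1)
available.

The ensemble label is an OR rule — positive if *any* GaC votes positive
— which maximizes coverage under extreme imbalance; a stricter
`majority` rule is provided, and OR-positives are always a superset of
majority-positives. For ranking, each GaC emits the dimensionless ratio
$d_1 / (d_1 + d_0)$ of distances to its transformed contact and
non-contact centroids ($0.5$ if both vanish); the ensemble score is the
mean over GaCs. The ratio, rather than the raw distance, is used because
different chromosomes produce transformed spaces of different dimension
whose raw distances are not comparable. Lower score = more
contact-like.

### Evaluation

Per chain, all long-range pairs are ranked by ascending score and the
top $K = \max(1, \lfloor L \cdot f\rfloor)$ are kept at each level
$f \in \{2, 1, 1/2, 1/5, 1/10, 1/20\}$; accuracy at a level is the
fraction of selected pairs that are true contacts (for $L = 142$ the
$L/5$ level selects exactly 28 pairs). Accuracy and coverage over
labeled predictions are $TP/(TP+FP)$ and $TP/(TP+FN)$; $0/0$ is
reported as undefined (`NA`), never as 0, and group means skip and count
undefined entries rather than silently deflating. Ties in the ranking
are broken by $(i, j)$ lexicographic order so selection is a pure
function of the scores.

## Tunable parameters

| parameter | default | units | why |
|---|---|---|---|
| `cutoff` | 8 | Å | conventional C$\alpha$ contact threshold |
| `min_sep` | 24 | residues | long-range definition; $j - i \ge 24$ |
| `w_flank`, `w_mid` | 9, 5 | residues | 460-feature encoding above |
| `population_size` | 150 | chromosomes | GA protocol above |
| `elite_fraction` | 0.05 | — | top 5% copied unchanged |
| `crossover_prob` | 0.95 | — | single-point recombination rate |
| `mutation_prob` | 0.01 | per position | exploration rate |
| `stall_generations` | 120 | generations | convergence criterion |
| `n_gacs` | 20 | classifiers | one per disjoint negative subset |

The sequence-separation rule is $j - i \ge 24$ (inclusive); the
exclusive reading was rejected because "separated at least 24" naturally
includes equality. Profile tables may be frequencies or percentages —
encoding normalizes every vector, so only relative values matter.

## The synthetic generator

`generate_chain()` builds a compact self-avoiding random walk: 3.8 Å
C$\alpha$ steps, a 4 Å excluded-volume distance, confined to a sphere
whose radius scales as $L^{1/3}$ with a calibrated log-linear length
correction. Confinement density controls how many geometry-derived
contacts appear; the calibration makes the expected long-range contact
count approximately `slope` $\times\,L$ (default 1.2 contacts per
residue), recoverable by `fit_length_contact_line()` to within 25% over
a couple hundred chains, while positives stay below 10% of long-range
pairs. Residues participating in contacts draw their letters with
hydrophobics C/V/I/L enriched by $2^{\delta}$ and charged E/D/K depleted
by $2^{-\delta}$ (default $\delta = 0.8$), so measured log2 contact
propensities are positive for the hydrophobics; $\delta = 0$ is an exact
null. Profile rows are Dirichlet draws (concentration $\kappa = 40$)
centered on a 50/50 blend of the residue's smoothed one-hot identity and
its contact-status composition.

What a green test on this generator establishes: the geometric
bookkeeping (contact maps, labeling, conservation), the learnability of
a class-conditional profile signal, and end-to-end determinism. What it
does not establish: performance on real proteins. Real chains have
secondary-structure topology, correlated profile columns from true
alignments, and contact geometry far from a biased random walk; absolute
accuracies on synthetic data say nothing about accuracies on PDB chains.

`planted_separation_dataset()` is the GA test harness: class means
differ by `separation` (default 1, against a base level of 1) on the
informative dimensions only — class 1 elevated on the odd-indexed ones,
class 0 on the even-indexed ones, a *shape* difference that L1
normalization cannot erase (a pure scale difference would vanish).
Noise dimensions are i.i.d. unit-mean exponentials identical across
classes. At the default separation a transformation that drops the
noise dimensions classifies the training set perfectly while a typical
random chromosome does not, so the GA is genuinely rewarded for pruning
noise; at large separations almost any chromosome is perfect and no
pruning pressure exists, which is why the default is deliberately
moderate.

## Numerical choices

* All-zero vectors stay all-zero under L1 normalization (no 0/0).
* Nearest-centroid ties go to class 0; top-K ties go to $(i,j)$ order.
* $K$ uses `floor`, minimum 1.
* Every entry point takes a seed; child seeds are derived by a fixed
  integer recurrence, so whole pipelines are reproducible from one
  master seed without touching the caller's RNG state (`.Random.seed`
  is saved and restored).
* Model files are JSON with doubles printed via `%.17g`, which
  round-trips every finite double exactly; predictions before and after
  save/load are bit-identical.
* PDB coordinates are written at the format's column precision
  (0.001 Å), the only lossy step in the file pipeline, and the tests
  bound it.

## Known limitations

* Only C$\alpha$ geometry is supported — no C$\beta$ or heavy-atom
  contact definitions, and no inter-chain contacts.
* Profile input is a simple 20-column table; alignment-database dialects
  must be converted upstream.
* The GA is stochastic: two seeds can yield transformations of different
  dimension with similar fitness. Determinism holds per seed, not across
  BLAS implementations at the last ulp.
* The discard-ratio report counts removed plus merged-away positions;
  other conventions (removed only) give smaller numbers for the same
  transformation.
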