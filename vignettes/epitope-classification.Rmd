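---
title: "Classifying linear B-cell epitopes with GA-selected k-mer features and an instance-based ensemble"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Classifying linear B-cell epitopes with GA-selected k-mer features and an instance-based ensemble}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(epitopeGA)
```

## The problem

Linear B-cell epitopes (LBCE) are contiguous stretches of amino acids on an
antigen that antibodies recognize; finding them in protein sequences is a
routine step in vaccine design and peptide screening. `epitopeGA` treats LBCE
detection as binary sequence classification: each peptide, a string over the
20-letter alphabet `ACDEFGHIKLMNPQRSTVWY`, carries a label (1 = epitope
present, 0 = absent), and the task is to predict the label of new peptides
from composition alone.

The method has three stages: k-mer featurization, a two-part genetic search
(over train/test partitions, then over sequence truncation lengths), and an
instance-based four-classifier ensemble with correlation routing.

## k-mer composition features

Each sequence $S$ of length $N$ is encoded by sliding-window counts:

* $F_{uni,i}$ — occurrences of amino acid $AA_i$ (20 values),
* $F_{bi,i,j}$ — occurrences of the ordered pair $(AA_i, AA_j)$ at adjacent
  positions (400 values),
* $F_{tri,i,j,k}$ — occurrences of the ordered triple (8000 values),

concatenated into an 8420-dimensional count vector; with the class label a
row carries 8421 values. For a fully standard sequence the counts conserve
length: $\sum F_{uni} = N$, $\sum F_{bi} = N-1$, $\sum F_{tri} = N-2$
(empty sums for sequences shorter than the window, so 1- and 2-residue
peptides are legal inputs).

Column order is a package convention, since flattening order is otherwise
underdetermined: alphabetical, row-major, first residue slowest
(`kmer_names()` emits the full mapping, and the CSV writer uses it as a
header, so every column is identifiable downstream).

Nonstandard symbols (X, B, Z, U, O, J, `*`) occur in real data but are
outside the model. The default policy (`skip`) excludes any window touching
one and warns — this keeps the conservation laws valid on the windows
actually scanned; `error` and `drop-sequence` are available when stricter
hygiene is wanted.

## Stage one: partition search by inter-class variance

A useful train/test split should expose the class contrast. The fitness of a
candidate training subset is built from a directed variance statistic: for
classes $a$ (size $m$) and $b$ (size $n$), per feature dimension,

$$V(a,b) = \sqrt{\frac{\sum_{i=1}^{m}\left(x_i - \overline{sd_b}\right)^2}{m-1}},$$

where $\overline{sd_b}$ is the mean over class $a$'s samples of class $b$'s
sample standard deviation — a constant per dimension, so the inner term *is*
$sd_b$. The statistic is printed for scalars; features are 8420-vectors, so
the package applies it independently per dimension and averages — this keeps
the printed formula intact while making the fitness well defined (a scalar
transliteration is the test oracle). The fitness of a split is the mean of
the directed values over the classes.

The search itself is a mark/regenerate genetic loop: `Ns` candidate
stratified splits (equal per-class training counts — the "ratio 1/k" rule —
with total size set by the train ratio `Tr`); a freshly drawn candidate is
accepted when it beats the running best (`CVV`); at the end of each of `Ni`
iterations, candidates above the survival threshold
$M_{threshold} = \overline{f} \cdot Mu$ are frozen, the rest are redrawn.
Two numerical choices matter:

* **Acceptance direction.** The procedure as published compares new
  candidates *below* `CVV` with `CVV` initialized at 0 — which would reject
  every candidate of a non-negative fitness and contradicts the final
  "select the maximum-fitness solution" step. The package accepts when the
  fitness *exceeds* `CVV` and maximizes throughout; this is the only
  internally consistent reading.
* **Regeneration budget.** "Discard and regenerate" can loop forever once
  `CVV` is high; regeneration is capped (50 attempts per slot per iteration,
  `regen_attempts`), after which the best rejected candidate fills the slot.

Because the threshold is at most the mean (for $Mu \le 1$), the best
candidate always survives, so the best-fitness trace is monotone — an
elitism property the tests assert on ten seeds.

One caveat worth knowing: since $V$ measures spread around the *other
class's standard deviation* rather than its mean,
$V \approx \sqrt{\mathrm{var}_a + (\mu_a - sd_b)^2}$, and for symmetric
location-shifted classes the mixture-variance inflation under label
shuffling almost exactly cancels the separation term — the statistic is then
nearly shuffle-invariant. For skewed count data (a near-zero background rate
versus an enriched class), the expected gap is real and the package's
separation-sensitivity test uses exactly that geometry. On k-mer counts this
is the relevant regime.

`selection_rate` and `crossover_rate` appear in the published parameter
table but the written procedure has no pairwise selection or crossover; they
are carried in `ga_config()` for compatibility and documented as unused —
fidelity to the described algorithm was preferred over the parameter table.

## Stage two: truncation-length search

The second search selects a sequence length $SL_{sel}$ between the shortest
and longest sequence in the stage-one partition. "Selecting features" here
means *prefix truncation*: all sequences are cut to their first $SL_{sel}$
residues (shorter ones pass through whole), features are re-extracted, and
the candidate is scored by the test accuracy of a linear-kernel support
vector classifier (cost 1, unscaled counts — the method names no settings,
so defaults are minimal and echoed in the run report). The loop mirrors
stage one with the running best accuracy `CA` and threshold
$f_{th} = \overline{A} \cdot Mu$. Candidate scores are memoized within a run
(a length's score is deterministic), which bounds the number of classifier
fits by the number of distinct lengths.

Prefixes — not suffixes or sliding windows — are this package's reading of
"extract $SL_{sel}$-length sequences"; it is the simplest interpretation
consistent with re-extraction, and truncation is idempotent.

Scoring candidates on the stage-one *test* partition follows the procedure
(the length bounds are explicitly initialized "from both training and
testing sets"), but it means the selected length has seen the test set —
an optimism the package documents rather than hides. `ga_config(inner_split
= f)` switches the fitness to an inner validation fraction carved from the
training set for honest selection; the default reproduces the procedure.

## The instance-based ensemble

Four classifiers with fixed hyperparameters are fitted on the truncated
training table:

| member | implementation | settings |
|---|---|---|
| `knn` | 1-nearest neighbour (exact, cross-product distances) | k = 1 |
| `rf` | random forest (`ranger`) | 100 trees, seeded |
| `lr` | ridge logistic regression, L-BFGS (`stats::optim`) | C = 1 |
| `svm` | support vector machine (`e1071`/libsvm, RBF) | tolerance 1e-4 |

Each member's *correct set* is the indices of test instances it classifies
correctly; the deduplicated union $C_{final}$ defines the **union accuracy**
$|C_{final}|/n_{test}$. This is an oracle-style number — it assumes the right
member is known per instance — and is reported as such, never as the honest
end-to-end accuracy. It dominates every individual accuracy by
construction (tested exhaustively over correctness patterns).

For a new sequence, routing compares its feature vector against the stored
correct instances of each member; $Corr_j$ is the *maximum* pairwise
correlation over member $j$'s store (the nearest-match reading of the
procedure's aggregation, which is otherwise unspecified), and the
highest-$Corr_j$ member (ties broken knn > rf > lr > svm; empty stores get
$-\infty$) makes the prediction. The **routed accuracy** — calibration
correct-sets built on half the test split, routing evaluated on the other
half — is the package's honest companion metric, and the pipeline reports
both.

The printed routing statistic
$\sum_i (F_{test,i}-F_{new,i}) / \sqrt{\sum_i (F_{test,i}-F_{new,i})^2}$
is bounded only by $\pm\sqrt{n}$ (Cauchy–Schwarz), which makes a fixed gate
at 0.999 ill-posed. The package therefore routes and gates with the Pearson
coefficient by default (`correlation_mode = "pearson"`), keeping the printed
form selectable (`"as_printed"`) and unit-tested, with the 0/0 case of
identical vectors pinned to 1.0 in both modes and constant-vector Pearson
pinned to 0.0.

When a query's maximum correlation strictly exceeds 0.999 the query and its
*predicted* label join the training pool (self-training — true labels are
not assumed at inference), and the model is flagged stale until
`ensemble_refit()`. The pool never shrinks.

## Synthetic data

Real LBCE benchmarks are external downloads; the generator supplies
controllable stand-ins. Sequences are drawn i.i.d. from a background residue
frequency (uniform by default); positives receive an explicit number of
planted k-mer copies (`floor(weight)` plus a Bernoulli remainder) written
over random windows — insertion, not frequency reweighting, so the per-
sequence effect size is explicit; labels flip with probability `noise`.
Defaults were fixed once as the study conditions: lengths 15–30 (typical
linear epitope lengths), the `separable` fixture with 500 + 500 sequences
and three copies of the dipeptide `WH` per positive at zero noise, a
signal-free `random` fixture (100 + 100), an `imbalanced` fixture (1:4), and
a `short_seqs` fixture (lengths 1–5) exercising the degenerate window cases.

`run_tss_sweep()` re-runs the pipeline at a series of target test-set
sizes (drawing a fresh synthetic dataset per point by stratified random
sampling, each with a derived seed) and tabulates the union, routed and
confusion-based metrics per size — the structural counterpart of
evaluating one method across small-to-large test sets.

What the generator does *not* emulate: motif positional preference, surface
accessibility, homology between sequences, or realistic residue usage.
Passing tests therefore demonstrate that the machinery recovers planted
compositional signal and behaves at chance without it — not that the method
attains any particular accuracy on real epitope data.

## Problem sizes and runtime choices

The test suite runs the full pipeline at the separable fixture's scale
(1000 sequences, 8420 features) with small search budgets (`Ns` 2–5, `Ni`
2–4), which a single CPU completes in tens of seconds per run; the
published budgets (population 100, 100 iterations, 10 runs) are exposed as
config echoes for users who want them. Sparse-matrix SVM fits and
memoized length scoring are what keep the length search linear in the
number of distinct candidate lengths.

## Known limitations

* Stage-two selection on the test partition is optimistic by construction
  (see `inner_split`).
* Union accuracy is an upper envelope, not a deliverable accuracy.
* Self-augmentation uses predicted labels; under distribution shift it can
  reinforce mistakes.
* The variance fitness of stage one is nearly insensitive to label
  assignment for symmetric, equal-spread classes; it discriminates in the
  skewed count regime of k-mer features.
* Multi-class support is formulaic (the fitness is k-generic) but only the
  binary case is exercised and tested.
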