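---
title: "From taxa to functions: scoring, classification and robust feature selection"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{From taxa to functions: scoring, classification and robust feature selection}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Taxonomic profiles of the gut microbiome are the standard substrate for
disease-versus-control classification, but they hide functional redundancy:
different species carry overlapping repertoires of molecular functions, and
a metabolic capability that matters for the host can be spread thinly over
many individually unremarkable taxa.  `funtaxa` translates a samples × taxa
abundance table into a samples × annotations table of functional scores,
classifies samples on either representation with seeded random-forest
ensembles, and distills repeated runs into consensus shortlists of
discriminant taxa and annotations, together with explicit taxon–annotation
linkage so that every selected function can be traced back to the organisms
carrying it.

## Functional scores

Given the abundance $n_{t,i}$ of taxon $t$ in sample $i$ and the number
$x_{F,t}$ of protein clusters of taxon $t$ annotated with the functional
annotation $F$ (a GO term or EC number, as counted from the per-taxon
annotation tables of a proteome-annotation pipeline such as EsMeCaTa), the
score of $F$ in sample $i$ is

$$\mathrm{score}_{F,i} \;=\; \sum_t n_{t,i}\, x_{F,t},$$

i.e. the abundance-weighted count of the annotation's carriers.  Abundances
are first forced to relative form (percent of the sample total).
Annotations scoring zero in every sample are dropped before any
normalization — their term frequency would be undefined and they carry no
information.

### TF-IGM weighting

The optional TF-IGM normalization boosts annotations concentrated in few
samples.  The term frequency $tf_{f,i}$ divides each score by the sample's
total; for each annotation the frequencies are ranked decreasingly across
the $n$ samples as $T(f)_1 \ge \dots \ge T(f)_n$ and the inverse gravity
moment is

$$igm(f) = \frac{T(f)_1}{\sum_{r=1}^{n} T(f)_r \, r},$$

giving the weighted value $tf_{f,i}\,(1 + \lambda\, igm(f))$.  The
strength $\lambda$ lives in $[5, 9]$ and defaults to 7, the value
recommended in the text-mining literature the scheme comes from.  Two
conventions are worth stating because they affect reproducibility:

* **Ties** in the ranking take consecutive ranks under a stable descending
  sort (no midranks); an all-zero annotation gets $igm = 0$ by convention
  rather than 0/0.
* **Fitting scope**: the gravity moments are fitted on *all* samples,
  including the held-out test set, exactly as the reference protocol does;
  this is a deliberate faithfulness choice and a mild leakage channel.
  A strict mode (`apply_treatment(..., fit_ids = )` for scaling) is
  available for leakage-averse use.

Whenever variable selection shrinks the annotation set, the configured
treatment is re-applied from the raw scores: term-frequency denominators
change with the column subset, so re-normalization is intentionally not a
no-op.

Standard scaling, the alternative treatment, uses the population
(divide-by-$n$) variance so results are bit-comparable with the common
Python convention; zero-variance features map to 0.

## Classification protocol

Each *run* sets aside a test subset (20% of samples, stratified by class)
that is shared by every iteration of the run and by both the taxonomic and
functional profiles.  Within a run, each of the 20 forests draws its own
validation subset (20% of the non-test samples) and is tuned by a grid
search with stratified 5-fold cross-validation on its training split,
optimizing AUC.  Class weights are balanced (inversely proportional to
class frequency), and split quality inside the trees is Gini impurity.
The tuned axes are the number of trees, a tree-size cap (depth, standing
in for a leaf-count cap) and the number of features each split may
consult; the default grid is {50, 100, 200} × {unlimited, 6, 7} ×
{sqrt, log2, 0.5·p} and is fully overridable — the simulation suites in
this package use the single-configuration `small_rf_grid()` (100 trees,
unlimited depth, sqrt mtry), which keeps desk-scale experiments fast
without changing the protocol's structure.

Every random choice derives from `seed(run, forest) = base_seed +
1000·run + forest` (forest 0 is the test draw), so an entire multi-run
analysis is a pure function of the data and one integer.

Per model we record train/validation/test AUC (rank-based, midrank ties —
equal to the Mann–Whitney U statistic over $n_1 n_0$), the selected
hyperparameters, and a probability threshold maximizing Youden's J on the
validation set (reported for confusion-style summaries; it never affects
the AUC).  An SVM ensemble (grid over C, kernel, gamma) is available for
single-iteration performance comparisons; it emits no importance vector
and therefore cannot drive selection.

### Importances

Gini importances are taken from the forest's mean impurity decrease and
normalized to sum to one per model before averaging across the ensemble,
so models with different tree counts contribute comparably.  The
alternative SHAP importance is the mean absolute per-sample attribution
over the model's validation samples, computed by a path-dependent
tree-SHAP implementation written for this package: conditional
expectations follow each tree's own split covers (reconstructed by routing
the training data through the tree).  The implementation is checked in the
test suite against a brute-force Shapley enumeration on small trees and
against the local-accuracy identity $\sum_j \phi_j = f(x) - E[f]$.

## Elbow cutoff and iterative selection

After averaging importances over the ensemble, features are ranked
decreasingly and cut at the elbow of the ranked curve.  Both axes (rank
position, importance) are min-max normalized to $[0,1]$; the elbow is the
point of maximum perpendicular distance *below* the chord joining the
first and last points — the rotation-equivalent form of the kneebow
method, which makes the cutoff invariant to positive rescaling.  Features
strictly above the elbow point are Significant; on the canonical curve
(10, 9, 8, 0.3, 0.2, 0.1) this keeps exactly three.  Degenerate curves
(fewer than three features, constant, or nowhere below the chord) retain
all features with a warning — the method never silently selects nothing.

Iteration 0 trains on the full feature set; each subsequent iteration
restricts the raw table to the previous significant set, re-applies the
treatment, and retrains with the run's fixed test and validation subsets.
The loop runs 5 iterations by default and skips vacuous retraining once
two or fewer features remain.  A one-sided Wilcoxon signed-rank test
(α = 0.05) over the paired per-forest test AUCs warns — never aborts —
when selection significantly degraded performance.

## Consensus across runs

Ten runs (default), each with its own test subset, give ten significant
lists per iteration level.  Per level:

* **Robust** — selected by every run;
* **Confident** — selected by at least 75% of runs, i.e.
  `ceiling(0.75 · n_runs)` (8 of 10);
* **Candidate** — selected at least once.

The optimal iteration level maximizes the median (optionally mean; both
appear in the field and the package exposes the choice) of the runs'
median test AUCs, ties going to the earliest level.  If the best summary
AUC is below 0.6 — strictly — the selection is flagged as potentially
unreliable.  Runs that stopped early carry their last selection and AUC
forward, keeping every level comparable across runs.  Taxonomic and
functional AUC distributions are compared two-sidedly with a Mann–Whitney
U test: the exact U distribution when tie-free, otherwise a normal
approximation without continuity correction (so identical samples give
p = 1 exactly).

## Linkage analytics

For a robust annotation $F$, each linked taxon $M$ (association count
$x_{F,M} > 0$) contributes

$$\mathrm{strength}(M) = \frac{\bar n_M\, x_{F,M}}
 {\sum_{M' \in A(F)} \bar n_{M'}\, x_{F,M'}},$$

with $\bar n_M$ the taxon's mean abundance over *all* samples (the
formula carries no group index; a per-group variant is exposed but
non-default).  Strengths sum to one per annotation.  Each feature is
assigned to the class where its mean is higher; the reported ratio is
mean(control)/mean(unhealthy), negated when unhealthy-dominant, so its
magnitude is at least 1 and ties resolve to control with +1.

Functional redundancy between taxa is screened with Jaccard proximity
over binary annotation support; pairs at or above 0.95 count as
functionally identical neighbors.  Robust annotations are categorized by
their taxon linkage: **Cumulative** first (no robust linked taxon at all
— their signal emerges from summed weak contributions), then the rest by
total linked-taxon count into **Ubiquitous** (top decile), **Specific**
(bottom decile) and **In-between**.  "Decile" is ambiguous between the
value range and the empirical distribution; both modes are implemented
(`decile_mode = "range"` is the default, `"quantile"` the alternative)
and neither is asserted as canonical.

## The synthetic-data generator

`generate_dataset()` emulates the statistical structure the pipeline
assumes, so that every stage is testable without downloads:

* per-taxon log-normal abundances (log-sd 1) closed to per-sample
  relative abundances — the compositional character of MetaPhlAn-style
  input;
* a sparse taxon–annotation association matrix (Bernoulli 10% density ×
  zero-truncated Poisson counts, mean 3), the many-to-many structure of
  real annotation maps;
* 3 planted signal taxa shifted by 2 log-sd between classes;
* one planted *cumulative* annotation linked exclusively to 15 weak taxa
  shifted by 0.6 log-sd each.

Planted taxa get a low baseline (log-mean −2): disease-associated taxa
are typically rare, and keeping them small stops the compositional
closure from distorting the unplanted taxa's relative profiles.  The
cumulative shift of 0.6 log-sd per taxon is chosen so that each weak
taxon is individually sub-threshold (univariate AUC ≈ 0.66, far below
the ≈ 0.92 of the signal taxa and below typical taxonomic elbow
cutoffs) while the 15-taxon aggregate separates the classes at ≈ 1.75 sd
— strong enough that the annotation is reliably robust on the functional
side.  Because all 15 weak taxa sit near the significance boundary, an
occasional lucky draw makes one of them individually robust in a
minority of datasets; that residual variance is inherent to the
construct and is reported, not suppressed.

What the generator does **not** emulate: real phylogenetic correlation
between taxa, over-dispersed zero inflation of rare taxa, annotation
ontology structure (GO parent–child), or batch effects.  Passing tests
on synthetic data therefore demonstrate the pipeline's mechanics and its
statistical behaviour under the planted model, not performance on any
real cohort.

## Problem sizes and numerical choices

The simulation suites run at 100 samples per class, 50 taxa and 200
annotations, with 10 seeds for signal recovery and 10 seeds × 3 runs ×
20 forests for the cumulative-effect study — sizes chosen so the whole
suite completes comfortably on a single core while keeping the planted
effects in the regime the defaults describe.  Grid search in these
suites uses `small_rf_grid()`; the structure of the protocol (dedicated
test and validation subsets, seeded forests, elbow selection, consensus)
is identical at any grid size.

Other numerical conventions, gathered in one place: stable sorts
everywhere ties can occur (importance ranking, gravity-moment ranking);
grid-search ties resolve to the first configuration; optimal-level ties
resolve to the earliest level; the elbow never selects zero features;
orientation of an input table is never guessed without identifier
evidence (ambiguity is an error, not a transposition).

## Known limitations

* TF-IGM and scaling are fitted on all samples by default (faithfulness
  over strictness); use the strict mode when leakage matters more than
  comparability.
* SHAP-based selection is markedly slower than Gini (R-level tree
  traversal) and, as with the reference implementation, tends to produce
  smaller robust sets.
* The consensus categories are counts over a small number of runs;
  with fewer than 4 runs the Confident category collapses onto Robust
  (`ceiling(0.75·n) = n`).
* Multi-class labels are rejected by design; the data model is binary.
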