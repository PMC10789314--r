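---
title: "Methods: geometric enantioselectivity calling and sequence-function modeling"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: geometric enantioselectivity calling and sequence-function modeling}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(stereoscreen)
```

## The problem

Fungal flavin-dependent monooxygenases (FDMOs) such as TropB, AfoD and AzaH
carry out oxidative dearomatization of resorcinol substrates with high
enantioselectivity. Mechanistically, the face of the substrate ring presented
toward the activated FAD cofactor (C4&alpha;-hydroperoxyflavin) receives the
hydroxyl group, so the geometry of a docked substrate pose carries direct
information about the stereochemical outcome (R or S product), and the
position of the substrate relative to the cofactor and the active-site
arginine carries information about whether the enzyme converts the substrate
at all.

`stereoscreen` implements the analysis layer of an in-silico
sequence-structure-function screen, downstream of structure prediction and
docking. Its inputs are receptor structures with the FAD cofactor placed,
docked ligand pose ensembles with per-pose energies, sequence alignments, and
assay annotations; its outputs are per-enzyme stereochemistry and reactivity
calls and a ranking of candidate key residues.

## Stereochemistry from pose geometry

**Ring-plane normal.** Three named atoms on the ligand ring define a plane;
the unit normal is the normalized cross product
$(\mathbf{a}_2-\mathbf{a}_1)\times(\mathbf{a}_3-\mathbf{a}_1)$. The
orientation is fixed by the right-hand rule on the user-supplied atom order,
which is what makes the call chiral: reversing the order maps every angle
$\theta \mapsto 180^\circ - \theta$ and swaps R and S.

**Pose angle.** The angle between the ring normal and the vector from the
mean ligand heavy-atom coordinate to the FAD reference atom (C4&alpha;).
Angles below 90&deg; are S poses, above 90&deg; R poses. The 90&deg; boundary
is geometrically uninformative (the ring plane contains the cofactor
direction), so it is reported as `degenerate` within a small tolerance
(default $10^{-9}$ degrees) rather than silently assigned. The angle is
evaluated with the `atan2` form, which stays fully conditioned at 0&deg; and
180&deg; where `acos` loses half the significant digits.

**Clustering.** Docked poses (500 per pair in the source protocol) are
grouped into mesostates by heavy-atom RMSD in the fixed receptor frame — no
superposition, since the receptor frame is shared by construction. The
published protocol used the MMTSB `kclust` tool (1 Å radius, no
least-squares fit) whose exact assignment rule is not documented; we adopt a
deterministic greedy leader algorithm: poses are visited in ascending-energy
order, each joining the first cluster whose leader lies within the radius,
else founding a new cluster. The visiting order guarantees the leader is the
lowest-energy member, which makes it the cluster representative whose energy
ranks the cluster. Ties in representative energy are broken by lower
representative pose id. This choice is reproducible, order-independent given
the energy ranking, and recovers planted partitions exactly whenever jitter
stays below 0.4&times; the radius and cluster centers are at least
3&times; the radius apart (an analytic consequence of translation-only
jitter; see the generator section).

**Boltzmann weighting.** Each cluster $i$ contributes weight
$g_i e^{-E_i/k_B T}$, with $g_i$ the cluster size and $E_i$ the
representative energy (kcal/mol). The R fraction is

$$
R_{frac} \;=\; \frac{\sum_{i \in R} g_i\, e^{-E_i/k_B T}}{Z},
\qquad Z = \sum_i g_i\, e^{-E_i/k_B T}.
$$

Two numerical/physical choices deserve note. First, the exponent is negative:
lower-energy mesostates must dominate, which is also why clusters are ranked
by their lowest-energy representative. Second, $E_{\min}$ is subtracted
before exponentiation; this is mathematically neutral (the weights are shift
invariant) and prevents overflow for strongly negative docking energies. The
temperature defaults to 300 K with $k_B = 0.0019872$ kcal/(mol K); both are
configurable, and the result's dependence on $T$ interpolates between the
ground-state call ($T \to 0^+$) and the cluster-size fraction
($T \to \infty$). Degenerate (90&deg;) clusters contribute to $Z$ but never
to the numerator — counting unassignable geometry as non-R is the
conservative direction, and a warning is emitted.

**Labels.** $R_{frac} > 0.8$ is called R, $R_{frac} < 0.2$ is called S, and
everything between is racemic (R/S). The cutoff rule is stated with strict
inequalities on all branches, leaving the endpoints unassigned; we map the
endpoints to R/S, the least committal class. The consensus stereochemistry
of an enzyme across its ligand panel is the modal label, with ties going to
R/S.

## Reactivity from docking descriptors

Five descriptors summarize the representative pose of the top-ranked
cluster: the distance from the ligand centroid to C4&alpha; (`fad_distance`,
&#8491;), the top-cluster ring angle (`fad_angle`, degrees), the distance
from the designated anionic ligand oxygen to the CZ atom of the active-site
arginine — R206 in TropB reference numbering — (`anion_distance`, &#8491;),
and two ligand-efficiency terms: docking energy and externally predicted
pK$_d$, each divided by the number of ligand heavy atoms. The source
protocol does not name the ligand atom used for the anion distance; because
the substrates are anionic at a specific phenolate oxygen we default to a
user-designated oxygen atom name (configurable). External affinity
predictors enter only through a scorer contract
(`scorer(receptor, pose, ligand_id) -> pKd`); a table-backed scorer is
provided, and a missing value degrades to a missing descriptor with a
warning rather than a failure.

The classifier is a plain maximum-likelihood logistic regression (binary:
reactive means any non-zero conversion with any panel ligand) with Wald
standard errors and p-values per descriptor, so the descriptor-screening
workflow (e.g. dropping a descriptor non-predictive at p > 0.10 in most
ligand-specific fits) can be applied as a filter. All five descriptors are
kept by default — the published analysis found the FAD distance
non-predictive but is ambiguous about whether it was removed from the final
model, so removal is an option, not the default. Quasi-separation (common at
n = 67 with informative descriptors) is detected from the glm convergence
diagnostics and handled by a small ridge refit (penalty $10^{-4}$ on
non-intercept terms, penalized-information standard errors) with an explicit
flag on the model object. The classification threshold is 0.5; none is
stated in the source.

## Sequence features

Residue coordinates are expressed in reference (TropB-style) numbering: the
k-th non-gap position of the reference row of the alignment is residue k.
Binding-site residues are those with any heavy atom within 4.5 &#8491;
(inclusive — the conventional contact-cutoff reading) of any ligand heavy
atom of any top pose, with the union taken across the ligand panel;
second-shell residues are those within 4.5 &#8491; of any binding-site
residue, excluding the binding site itself (the two sets are treated as
disjoint, matching the "previously unexplored second-shell residues"
reading). The feature matrix keeps alignment columns that are residues of
interest and have at most 10% gaps (strictly more is dropped), one
categorical feature per column with the gap as its own category. Integer
label encoding over a fixed alphabet is used for the tree models — it
preserves one-SHAP-value-per-residue semantics, which one-hot encoding would
fragment across 21 indicator columns.

Stereochemistry training labels are encoded S = -1, R/S = 0, R = +1. The
default is the mode across the ligand panel; a mean-of-per-ligand-codes
variant (sign of the mean; |mean| < 0.25 is racemic) is available behind
`stereo_labels(method = "mean")` because the source describes the label
construction in both ways in different places.

## Sequence-function models and SHAP consensus

Models are trained with seeded stratified k-fold cross-validation (default
5 folds, seed 17; stratification falls back to plain folds with a warning
when a class is smaller than the fold count). Three tree backends run behind
one training/SHAP contract: depth-wise gradient boosting, loss-guided
histogram boosting, and a single-round bagged random forest, all through
xgboost — the one tree library in scope with an exact tree-path SHAP
implementation, which the contract requires for every backend. Backends
degrade gracefully: a failing backend is skipped with a warning as long as
one remains. Backend seeds derive from the algorithm identity rather than
its position in the requested list, so results are invariant to algorithm
ordering.

SHAP values are computed on held-out rows only. Residue importance within a
fold is the mean absolute SHAP value (over rows, and over classes for the
three-class stereochemistry model), min-max normalized to [0, 1] within the
fold; the consensus importance is the mean over all (algorithm, fold) pairs.
Averaging normalized fold importances avoids the selection bias of picking a
single best model. Dependence profiles keep the sign: a residue's held-out
SHAP values for the class of interest are divided by that residue's maximum
absolute fold value (mapping to [-1, 1]) and grouped by the amino acid the
sequence carries at the residue, pooled across folds and models. For the
three-class model the class-specific SHAP matrix of the requested class is
used (e.g. the R class).

Metrics: accuracy, the generalized multiclass Matthews correlation
coefficient (Gorodkin's $R_K$, reducing to the familiar binary formula for
two classes), and macro-averaged F1.

## The synthetic generators

The generators define the study conditions under which the package's claims
are tested; they are first-class, tested code.

* `generate_toy_complex(angle, ...)` builds a planar six-carbon ring whose
  normal makes exactly the requested angle with the centroid-to-C4&alpha;
  vector, decorated with in-plane atoms in symmetric pairs so the heavy-atom
  centroid stays on the ring axis, plus a minimal receptor shell (an
  arginine with CZ at a controlled distance, one contact residue, one
  second-shell residue, one remote residue). A seeded rigid rotation and
  translation is applied to the whole complex, so tests exercise arbitrary
  frames while angles and distances are preserved exactly.
* `generate_pose_ensemble()` plants clusters with known membership, sizes
  and representative energies. Jitter is translation-only, so fixed-frame
  RMSD between members equals the distance between their translation
  offsets; this makes the recovery condition (jitter &le; 0.4 radius,
  centers &ge; 3 radius apart) provable rather than empirical.
* `generate_screen_dataset()` emulates the screen-level mechanism: an F/Y
  stereochemistry switch column and an I/V reactivity switch column planted
  in otherwise label-independent background columns (uniform composition,
  2% gaps), with a configurable label-noise rate. Defaults are 300 enzymes,
  60 columns, noise 0.1 — desk-scale but large enough that the planted
  determinants are recoverable well above chance. Noise at or above 0.5 is
  rejected since the signal must dominate.
* `generate_descriptor_table()` draws standard-normal descriptors and
  Bernoulli labels from a stated logistic model, the simulate-and-refit
  oracle for the classifier.

Every generator is a deterministic function of its seed, and none touches
the global RNG stream.

What the generators do **not** emulate — and hence what passing tests do not
show about real data: docking physics and force-field energies (cluster
energies are planted, not computed), ligand rotamers (jitter is
translational), phylogenetic correlation between sequences (columns are
independent given the labels, whereas real ancestral libraries are strongly
tree-structured, which inflates apparent importances of co-varying
residues), and real family-specific amino-acid composition.

## Problem sizes and numerical choices

The test suite runs the end-to-end screen analysis at 300 enzymes &times;
60 columns with 20 replicates, clustering checks on 200 random ensembles of
up to ~50 poses, the logistic recovery at n = 5000 over 20 seeds, and
metric-oracle comparisons on 200 random confusion matrices — sizes chosen so
the full suite completes in a few minutes on a single core while leaving the
statistical assertions well-powered. Degenerate-geometry guards use a
$10^{-9}$ &#8491;&sup2; cross-product-norm threshold (collinear ring atoms)
and a $10^{-9}$ &#8491; threshold for a FAD reference coinciding with the
ligand centroid.

## Known limitations

* The leader clustering is a documented stand-in for MMTSB `kclust`, whose
  internal assignment rule is unpublished; partitions can differ from the
  original tool near cluster boundaries.
* The temperature entering the Boltzmann weights is not stated in the source
  protocol; 300 K is a convention, and $R_{frac}$ does depend on it.
* On a label-shuffled screen the consensus importance profile is *not* flat:
  the chance association between the best noise column and the shuffled
  labels is a fixed property of the dataset, and cross-validation folds
  share most of their rows, so every fold re-finds the same spurious column.
  Key-residue rankings should therefore always be read against a shuffled
  control run on the same data, not against an assumption of flatness.
* Reference-numbering maps assume the reference sequence is present in the
  alignment and that insertions relative to it are uninformative (unmapped
  columns are dropped from residue-of-interest selection).
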