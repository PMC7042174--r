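---
title: "Shape-descriptor screening with learned scoring models: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Shape-descriptor screening with learned scoring models}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(usrml)
```

This vignette documents the models implemented in `usrml`, the
assumptions behind them, the numerical and design choices that were
genuinely open, and what the synthetic test bed does and does not show
about real screening data.

## Moment descriptors

A conformer with atoms at positions $x_1, \dots, x_n \in \mathbb{R}^3$ is
encoded by the distributions of Euclidean distances from every atom to a
small set of reference points. For USR these are the molecular centroid
(`ctd`), the atom closest to it (`cst`), the atom furthest from it
(`fct`) and the atom furthest from `fct` (`ftf`). Each of the four
distance distributions is condensed to three numbers:

* $m_1$: the mean distance;
* $m_2$: the square root of the population second central moment;
* $m_3$: the *signed* cube root of the population third central moment.

**Moment convention.** The second and third moments are central moments
on the population ($1/n$) convention, normalized by the square and cube
root so that all three values share the length unit of $m_1$ (ångström).
A standardized skewness would be dimensionless and could not be
normalized "onto the scale of the first moment", so the central-moment
reading is the only dimensionally consistent one; the signed cube root
preserves the direction of the asymmetry. A single-atom cloud yields
$(d_1, 0, 0)$.

Concatenating the four triples gives the 12-value USR descriptor. It is
invariant under rotation, translation and atom reordering, covariant
under uniform scaling, and — because all reference points are reflection
equivariant — *blind to chirality*: enantiomeric point clouds produce
identical USR descriptors. The test suite asserts all of these as
properties against an independent loop-based reimplementation.

### Charge- and lipophilicity-augmented descriptors

ElectroShape embeds each atom in 4 or 5 dimensions,
$(x, y, z, Q q_i)$ or $(x, y, z, Q q_i, P \ell_i)$, where $q_i$ is the
partial charge, $\ell_i$ the atomic logP contribution, and $Q, P$ scale
factors that bring the extra dimensions onto a magnitude comparable to
the spatial ones. Both default to 25 Å per unit — the published
ElectroShape choice — and are configuration fields of
`descriptor_scheme()` so their sensitivity can be studied. Distances are
full 4/5-dimensional Euclidean distances.

Five reference points are used: the augmented centroid $c_1$; the cloud
point furthest from $c_1$ ($c_2$); the cloud point furthest from $c_2$
($c_3$); and a chirality-sensitive pair $c_4, c_5$ whose spatial part is
displaced from $c_1$ along the spatial cross product
$s = (c_2 - c_1)_{xyz} \times (c_3 - c_1)_{xyz}$ by half the spatial
length of $(c_2 - c_1)$, and whose 4th coordinates carry the maximum and
minimum scaled charge of the cloud ($c_4$'s and $c_5$'s 5th coordinate,
in 5D, is that of $c_1$). When the spatial parts are collinear the cross
product degenerates and $c_4 = c_5 = c_1$, with a logged message. Because
no external ground truth exists for these constants at desk scale,
correctness is asserted through invariance properties rather than
reference values.

**Tie-breaking.** All selected reference points (`cst`, `fct`, `ftf`,
$c_2$, $c_3$) break distance ties by the lowest atom index, which makes
the computation deterministic and order-stable; on tie-free clouds the
descriptor is fully permutation invariant.

**Hydrogens** are kept in the cloud by default: polar hydrogens carry
the charges that shape the augmented dimensions. Schemes can exclude
them (`include_hydrogens = FALSE`) for pure-shape studies when records
carry element symbols.

## Conformer protocol

Conformers are embedded with ETKDG, whose experimental torsion knowledge
produces geometries that are already effectively energy-minimized; a
single-point MMFF94 energy is then computed *without* further
minimization, deliberately. Ensembles are pruned by an energy window:
a conformer is kept exactly when its energy is *strictly less* than
5 kcal/mol above the molecule's lowest-energy conformer (LEC) — equal or
higher is removed — so the LEC itself always survives and widening the
window never drops a previously kept conformer. Charges default to the
MMFF94 charge model (Gasteiger selectable) and per-atom lipophilicity to
Crippen-type atomic contributions; both are attached at generation time
so descriptor computation never needs molecular perception.

Two knobs have no published value and are configuration with documented
defaults: the per-molecule conformer cap (200, generous for drug-like
flexibility at desk scale) and the embedding retry policy (one reseeded
retry on failure, then exclusion with a warning). Note one deliberate
consequence of skipping RMSD pruning (an explicit non-goal): rigid
molecules yield several numerically distinct but descriptor-equivalent
embeddings rather than a single conformer.

## Classical screening and learned scoring

The baseline screen scores a library molecule against a template set by
the maximum inverse-Manhattan similarity over all conformer pairs, and
against multiple templates by the best template score (standard
group-max screening; the multi-template aggregation is not uniquely
dictated by the literature and is documented here as this package's
baseline). Rankings sort by descending score with ties broken
lexicographically by molecule identifier, so enrichment factors are
reproducible bit for bit.

The learned models replace the similarity metric:

* **Gaussian mixture** (`fit_gmm()`): full-covariance EM with a
  $10^{-6}$ diagonal regularization added at every M step, k-means
  initialization (jittered-row fallback for degenerate data), and a
  tracked, non-decreasing training log-likelihood. The score is the
  mixture log-density. The density is the standard multivariate normal
  mixture $\sum_k c_k \, \mathcal{N}(x;\mu_k,\Sigma_k)$ with its
  $(2\pi)^{-d/2}|\Sigma_k|^{-1/2}$ normalization and $-\tfrac12$
  exponent.
* **Isolation forest** (`fit_isolation_forest()`): random axis-aligned
  splits on subsamples of 256 points, path lengths normalized by the
  usual $c(\psi)$ term; the anomaly score $2^{-E[h]/c(\psi)}$ is negated
  so that *higher = more active-like* across every family. Nodes whose
  points are exactly duplicated are unsplittable and become leaves.
* **Neural network** (`fit_ann()`): one ReLU hidden layer (100 or 500
  nodes in the default grid), one linear output node, trained as a
  regression of active = 1 / decoy = 0 under squared error with
  full-batch Adam, inputs standardized, early stopping on a held-out
  10% of rows, best-epoch weights kept. Ranking uses the raw output.
  Class imbalance can optionally be countered by duplicating active
  rows to a 1:1 ratio; this is off by default because balanced and
  unbalanced training produce comparable rankings at roughly double the
  training cost.

The one-class families (mixture, forest) are fitted on **active
conformer descriptors only** — decoys never reach their training data,
mirroring template-based screening where only actives are known. This
is enforced structurally (the fitting path extracts active rows) and
can be audited at run time through `options(usrml.audit_env = )`,
which records the label vector of every batch handed to a fitting
routine.

## Training protocol

All splits are at **molecule level**: conformers of one molecule are
near-duplicates, and splitting them across folds would leak test
information into training. The protocol is: stratified 80/20 split into
training set L and test set T; stratified 5-fold cross-validation of
every hyperparameter grid point on L (one-class models fit on the
in-fold actives and are validated on the held-out fold's actives *and*
decoys); best mean validation score wins, ties going to the earlier grid
row; refit on all of L; rank T. The selection metric defaults to ROC AUC,
which is stabler than EF 1% on small validation folds; EF 1% is
selectable. Scores of a molecule's conformers aggregate by max, mirroring
the classical rule.

**LEC mode** reduces the *training/template* side to lowest-energy
conformers (ties by lowest conformer id); test and library molecules
are always scored with all their conformers. This matches the classical
design of screening a full-conformer library against LEC templates.

**Fraction sweep.** The split is performed once so the test set is
identical across all 16 cells (8 sizes x 2 modes). Within each cell the
training *actives* are subsampled at random with a per-cell derived
seed; decoys are subsampled proportionally for the supervised network
only, since one-class models never train on them. Cells that retain no
active are reported as unavailable rather than aborting the sweep, and
cells whose cross-validation cannot score any fold fall back to the
first grid point with a note.

## Evaluation

* **Enrichment factor**: the top-$x\%$ window holds
  $c_x = \lceil x/100 \cdot N \rceil$ compounds, never fewer than one, so
  EF at 0.25% is defined even on small test sets; boundary ties resolve
  by the deterministic ranking order. EF is undefined (an error) without
  actives.
* **ROC AUC**: the Mann–Whitney construction with half credit for tied
  scores; equivalent to brute-force pair counting (asserted in tests).
* **Improvement ratio**: $100 \cdot EF_{model} / EF_{baseline}$; a zero
  baseline yields "unavailable" (`NA`) rather than infinity.
* **Wilcoxon rank-sum**: two-sided; exact by exhaustive enumeration of
  all group assignments (midranks for ties) for combined $n \le 10$,
  normal approximation with tie correction above. No multiple-comparison
  adjustment is applied — comparisons are reported as single pairwise
  tests.

Evaluation always consumes one score per molecule (post-aggregation),
matching the ranking of molecules rather than conformers.

## The synthetic test bed

`make_screening_scenario()` generates descriptor-space scenarios
directly: active conformer descriptors are drawn from `active_modes`
Gaussian clusters (one per hypothetical binding mode) whose centers sit
`separation` units from the origin along mutually orthogonal axes, and
decoy descriptors from a broad background Gaussian (sd = 3 x the active
`noise_sd`) centered at the origin, rejected when closer than
`separation` to any active center. Defaults (20 actives in 2 modes,
1000 decoys, 5 conformers per molecule, separation 8, noise 1,
dimension 12) define the standard test conditions used by the
acceptance checks. Each conformer carries a synthetic energy so LEC
reduction is well defined.

Two deliberate choices: the decoy background is Gaussian rather than
uniform so densities stay finite and single-mode AUCs are analytically
predictable; and at `separation = 0` the scenario degenerates to a true
null — decoys are drawn from the *same* distribution as actives, so
labels carry no information and any model must score AUC ≈ 0.5. (Keeping
the broad background at zero separation would leave a variance signal a
density model could exploit, which would make the null scenario
mislabeled.)

Descriptor-space scenarios isolate the learning and evaluation machinery
from conformer-generation variance; point-cloud "molecules"
(`random_point_cloud()`, `mirror_conformer()`, `rigid_transform()`)
cover the descriptor mathematics itself. What passing these tests does
**not** show: that real actives form Gaussian clusters in descriptor
space, that real decoys are property-matched the way curated benchmark
decoys are, or that enrichment levels observed here transfer to any
particular protein target — scenario difficulty is a dial, and the
acceptance conditions use a cleanly separable setting.

## Problem sizes and numerical choices

The test suite and the acceptance script run at desk scale, chosen so
the full suite completes in a few minutes on one CPU: 100 random clouds
(3–30 atoms) for oracle equivalence, 50 clouds x 20 motions for rigid
invariance, 5000 draws x 10 seeds for mixture recovery, a 20-active /
1000-decoy scenario for the end-to-end screens, and a 101-active /
300-decoy redundant scenario for the 16-cell sweep.

Other numerical details, collected: EM stops when the relative
log-likelihood gain falls below $10^{-8}$ (500 iterations cap);
mixture covariances are regularized, never inverted directly
(Cholesky); descriptor tables are written as plain CSV at full
precision and round-trip to at least 12 significant digits; every
random step derives its own child seed from the master seed, so whole
pipelines are reproducible end to end; all randomness goes through
`withr::with_seed`, leaving the caller's RNG state untouched.

## Known limitations

* The chemistry backend requires an external RDKit installation; without
  it the package is a descriptor-space toolkit only.
* The isolation forest and network are reference implementations tuned
  for clarity and desk-scale data, not for million-conformer corpora.
* ElectroShape's $c_4/c_5$ constants follow the published construction
  but cannot be validated against external reference descriptors here.
* Wilcoxon comparisons are unadjusted pairwise tests.
* EF depends on the active/decoy ratio of the dataset; cross-study
  comparisons should rely on AUC, which does not.
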