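---
title: "Conformer-ensemble descriptor aggregation for molecular property prediction"
author: "confagg"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Conformer-ensemble descriptor aggregation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(confagg)
```

## The problem

Most molecules are flexible: rotating single bonds produces an ensemble of
thermally accessible conformers, each with its own 3D geometry and energy.
Any descriptor computed from 3D coordinates is therefore not a property of a
*compound* but of one *conformer*, and a modeller who wants one feature
vector per compound must decide how to collapse the ensemble. `confagg`
implements the full experimental apparatus needed to study that decision:

* multi-conformer SDF input/output and dataset curation,
* conformational diversity statistics (superposed pairwise RMSD) and a
  conformational-dependency statistic for properties,
* per-conformer 3D descriptors (3D-MoRSE, pharmacophore triplets, a
  many-body tensor representation) and 2D baselines (a Morgan-style
  circular fingerprint and topological pharmacophore triplets),
* six aggregation schemes plus a multi-instance "nonaggregation" scheme,
* compound-level cross-validated regression with paired nonparametric
  comparison of pipelines,
* and a synthetic conformer-ensemble generator with a *known* ground-truth
  conformer and a tunable degree of conformational dependency, so that every
  claim the package makes can be tested end-to-end without external data.

## Aggregation schemes

Given per-conformer descriptor vectors $x_1,\dots,x_N$ for one compound, the
package provides:

* **Boltzmann weighting.** Conformer existence probabilities
  $p_i = \exp(-E_i/kT) \,/\, \sum_j \exp(-E_j/kT)$ with
  $k = 0.0019872041$ kcal/(mol K) and $T = 298$ K by default, and
  $x_{\mathrm{Agg}} = \sum_i p_i x_i$. Energies are shifted by their minimum
  before exponentiation so large-magnitude total energies (e.g.
  semiempirical totals) cannot overflow; the weights are invariant to that
  shift.
* **Mean.** $x_{\mathrm{Agg}} = \frac1N \sum_i x_i$.
* **Global minimum.** The row of the lowest-energy conformer.
* **Random.** One uniformly drawn row; the draw is reseeded per
  cross-validation repeat (from the global seed, the repeat index and the
  compound id) so repeats differ but reruns reproduce exactly. This scheme
  is a control.
* **RMSD max / min.** The row of the conformer with the largest (smallest)
  RMSD to the ground-truth conformation, where
  $\mathrm{RMSD}_i = \sqrt{\frac1M \sum_j \delta_j^2}$ over heavy atoms
  after optimal superposition. These are controls that bracket how much the
  choice of conformer matters. An all-atom variant is available via
  `heavy_only = FALSE`.
* **Nonaggregation** (instance-wrapper multi-instance learning). Every
  conformer becomes a training instance carrying the compound's label; at
  prediction time the per-conformer predictions are averaged.

Ties (equal energies or RMSDs) resolve to the lowest conformer index — a
documented choice, since any fixed rule works but reproducibility demands
one.

## Descriptors

**3D-MoRSE.** For scattering parameter $s$ and atomic weights $w$:
$\sum_{i<j} w_i w_j \,\sin(s\,r_{ij})/(s\,r_{ij})$. The classic
160-component vector arises from 32 values of $s$ and five weighting
schemes (unit, atomic mass, van der Waals volume, Sanderson
electronegativity, polarizability, each scaled relative to carbon). The
printed form of the $s$ grid ("1 ... 32 Å") is read here as 32 integer
values in reciprocal ångströms, the standard convention for this
descriptor family; the element constants ship in `element_constants`.

**Pharmacophore triplets.** Vertices are ring centroids (one per 5- or
6-membered ring, labels `R5`/`R6`) plus all other heavy atoms labelled by
element. Every 3-subset of vertices is keyed by its labels and its three
pairwise distances floored to 1 Å bins (bond counts in the topological
variant, where a centroid's distance is the minimum over its ring atoms);
the key is canonicalized by taking the lexicographic minimum over the six
vertex orderings, so the total count is always $\binom{V}{3}$. Because the
vertex rule can be read as "any 5/6-ring" or "aromatic 5/6-ring", both are
implemented (`vertex_rule`), with the inclusive reading as default.

**MBTR.** Per degree $d \in \{1,2,3\}$ and element tuple, a
Gaussian-broadened distribution of a geometry function on a fixed grid:
atom counts over atomic number ($d=1$), inverse pairwise distance over
$[0, 1.1]$ Å$^{-1}$ ($d=2$), and the cosine of the angle at the middle
atom over $[-1, 1]$ ($d=3$). For $n$ elements the tuple counts are $n$,
$n(n+1)/2$ and $n^2(n+1)/2$; with 10 grid points per distribution this
yields 540 components for a four-element system and 950 for five. The
10-point grid is the unique uniform choice consistent with those two
published dimensionalities; the broadening width defaults to one grid-cell
width. These reconstructed settings are deliberate defaults, exposed in
`mbtr_config()`.

**2D baselines.** `circular_fingerprint()` is a native Morgan-style hashed
circular fingerprint (radius 2 — bond diameter 4 — folded to 2048 bits,
bit or count format) over atom invariants (element, heavy degree, attached
hydrogens, formal charge, aromatic membership). `triplet_fingerprint_2d()`
is the topological pharmacophore triplet described above. Both are
conformation-independent by construction.

## The synthetic generator

The generator emulates the situation the pipeline is built for — ensembles
of 2–40 conformers per compound with pairwise all-atom RMSD diversity on
the ångström scale, per-conformer energies, a designated ground-truth
conformation, and property values whose conformational dependency is
tunable — without any external conformer engine:

* **Molecules** are unbranched heavy-atom chains (4–9 atoms by default,
  elements C/N/O, hydrogens completed to standard valence). No rings or
  stereochemistry: conformational flexibility, the object of study, is
  carried entirely by backbone dihedrals.
* **Geometry** is built with fixed 1.54 Å bonds and tetrahedral angles;
  backbone dihedrals are drawn from the staggered states (60/180/300
  degrees) with 12 degrees of Gaussian jitter. Conformers with any
  nonbonded pair closer than 0.9 Å are rejected and resampled.
* **Energies** come from a 12-6 Lennard-Jones sum over atom pairs at least
  four bonds apart, with van der Waals radii and well depths from
  `element_constants`. This reproduces the qualitative feature that
  matters: staggered-state conformers separated by fractions of a kcal/mol
  up to strongly clashed outliers, so Boltzmann weights at 298 K mix a few
  low-energy conformers.
* **Ground truth** is a copy of the toy-energy global minimum perturbed by
  0.1 Å Gaussian noise, so "most stable" and "ground truth" correlate
  without coinciding — the situation a force-field optimum has with
  respect to the conformation that generated a reference property.
* **Properties.** A dipole-like geometric core
  $f_{\mathrm{geo}} = \lVert \sum_j q_j r_j \rVert$ uses fixed per-element
  pseudo-charges (Pauling electronegativities, mean-centred per molecule so
  the quantity is origin-independent), evaluated on the ground-truth
  conformer or Boltzmann-averaged over the ensemble; a compositional term
  $g_{\mathrm{graph}}$ is a weighted atom-type count. The property is
  $\lambda f_{\mathrm{geo}} + (1-\lambda) g_{\mathrm{graph}} +
  \mathcal{N}(0, \sigma)$ with $\sigma = 0.1$ by default. $\lambda = 0$
  gives a property of the chemical graph alone; $\lambda = 1$ with the
  ground-truth mode gives a property determined exactly by one geometry.
  The median IQR-scaled per-compound SD of the per-conformer property — the
  package's conformational-dependency statistic — is nondecreasing in
  $\lambda$ and is about 0.34 at $\lambda = 1$ under the default generator,
  i.e. squarely in the "conformation-dependent property" regime.

What the generator does *not* emulate: ring systems, stereochemistry,
realistic force fields, electronic properties, or the descriptor
correlations of drug-like chemistry. Tests passing on synthetic data
therefore demonstrate that the machinery is correct and that the
aggregation orderings hold *when the data-generating process matches the
assumed one* — not that any particular ordering will hold on a given real
data set.

## Evaluation protocol

Splits are always by compound, so conformers never straddle a fold
boundary, and sparse-descriptor vocabularies are rebuilt from the training
fold only. Repeated k-fold (default 5x3 or 5x5) reports the fold-wise mean
and SD of $R^2$, MAE and RMSE; leave-one-out pools all predictions and
computes the metrics once. All cells of a run share one split plan, which
is what makes the paired Wilcoxon signed-rank comparison of two pipelines
valid: the same folds are compared pairwise. Zero differences are
discarded; up to 25 nonzero pairs the two-sided p-value is exact (computed
by the shift algorithm, which remains exact under midrank ties — the
built-in `wilcox.test` refuses this case), beyond that a normal
approximation with tie and continuity corrections is used. No
multiple-testing correction is applied, deliberately reproducing the
compared protocol; treat the p-values accordingly. One-way ANOVA across
aggregation methods and a Tanimoto-similarity extrapolation curve (MAE
over test compounds whose nearest training neighbour is below a
similarity threshold) complete the toolbox.

Model adapters delegate to established learners: `ranger` random forests
(single-threaded, seeded — bit-for-bit reproducible), `nnet` perceptrons,
`glmnet` elastic net with a seeded internal penalty selection, and ordinary
least squares. Hyperparameters are plain defaults; the tuned per-property
settings of the original study are not public, so no numeric agreement
with its tables is claimed.

## The recovery study (acceptance experiment)

The package's headline self-check generates 200 compounds (seed fixed) and
runs 5x5-fold cross-validation three times:

* $\lambda = 1$, ground-truth mode, MBTR descriptors, random forest:
  modelling the ground-truth conformer's descriptors yields a
  significantly lower per-fold MAE than the rmsd-max control
  (median MAE about 1.02 vs 1.14, exact signed-rank p on the order of
  $10^{-6}$). MBTR is used here because, of the implemented 3D
  descriptors, it is the most sample-efficient carrier of geometric
  information at this data-set size; 3D-MoRSE needs substantially more
  compounds before its high-frequency components stop behaving as noise
  for tree ensembles.
* Boltzmann-average mode, 3D-MoRSE, random forest (150 trees, mtry 40 for
  tractability of the instance-expanded fit): nonaggregation and mean both
  achieve lower median MAE than the random and global-minimum controls,
  and the nonaggregation advantage is individually significant — the
  qualitative ordering the aggregation literature reports.
* $\lambda = 0$ (composition-only), elastic net: the 2D circular
  fingerprint is never significantly worse than any 3D aggregation (it is
  in fact slightly better, sitting essentially at the noise floor). The
  elastic net is the right instrument here because the target is linear in
  substructure counts; a mid-sized forest cannot form that sum and would
  understate every descriptor equally.

Problem sizes (200 compounds, 5x5 CV, the forest sizes above) were chosen
so the full study runs in minutes on one CPU while leaving each comparison
with 25 paired folds. These are the same conditions
`tests/testthat/test-acceptance.R` asserts.

## Numerical choices and degenerate inputs

* Superposition uses the Kabsch algorithm restricted to proper rotations
  (determinant +1); a wholly degenerate point set yields the identity
  rotation and a centroid-aligned RMSD. Correspondence is by atom index —
  conformers of one molecule share atom order — so no graph-automorphism
  search is performed; for externally deposited data with symmetric
  molecules this can bias RMSD slightly high, which is why the deposited
  RMSD check carries a +-0.05 Å tolerance.
* Energies are normalized to kcal/mol at load time from a declared unit
  (kcal/mol, kJ/mol, eV, hartree); SD tag names are configurable and
  auto-detected by the accession checker, which reports what it found.
* The dependency statistic divides by the IQR (linear-interpolation
  quantiles) of the per-compound *means* across the data set; the pooled
  conformer-level population is available behind
  `iqr_population = "all_values"`. A zero IQR makes the statistic
  undefined (`NA` with a warning) rather than infinite.
* Molecular-weight curation is strictly "less than"; top-k selection by
  rotatable bonds breaks ties lexicographically by compound id; curation is
  idempotent.
* Seeds: one user seed fans out through `derive_seed()` (a small
  deterministic string hash) to every stage, so a single integer
  reproduces generation, splits, model fits and random aggregation draws
  byte-for-byte, while stages remain decoupled.
* Stereocenter and cis/trans flags on `Molecule` are consumed by
  `curate()` but must be supplied by an external perception adapter; the
  built-in chain generator produces neither, so the flags default to
  `FALSE`.

## Known limitations

* The Morgan-style fingerprint is a faithful member of the circular-
  fingerprint family but its hashed bit positions do not match any other
  toolkit's, so fingerprints are comparable only within this package.
* Degree-3 MBTR is an O(atoms^3) R loop per conformer; it is the slowest
  descriptor and the practical bottleneck for large ensembles.
* The 2D pharmacophore triplet ignores hydrogens by design; targets that
  depend on hydrogen counts are learnable from it only indirectly.
* The signed-rank comparisons inherit the no-correction policy described
  above; with many descriptor x aggregation cells, some nominally
  significant differences are expected by chance.
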