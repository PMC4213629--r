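---
title: "Methods: comparative cranial biomechanics and craniodental functionspaces"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: comparative cranial biomechanics and craniodental functionspaces}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(craniomech)
```

`craniomech` implements a comparative cranial-biomechanics workflow for
herbivorous dinosaurs (and any taxa with comparable data): estimating jaw and
neck muscle forces from digital reconstructions, comparing skulls under static
biting with a small finite-element (FE) solver, summarising craniodental
function across a clade as a multivariate "functionspace", and projecting a
time-scaled phylogeny into that space. This vignette records the models, the
parameters that matter, the numerical choices, and what the synthetic data
generators do and do not emulate.

## Muscle forces: the dry-skull method

A reconstructed muscle's contractile force is estimated as

$$F = \sigma_{sp} \cdot \mathrm{PCSA}, \qquad \mathrm{PCSA} = V / L,$$

where $V$ is reconstructed muscle volume (mm³), $L$ the straight-line
origin-to-insertion length (mm), and $\sigma_{sp}$ the specific tension of
vertebrate skeletal muscle. The default $\sigma_{sp}$ is 392 kPa, stored in
kPa and converted to N/mm² at use (the package-wide unit system is mm / N /
MPa, so FE stress output is directly comparable to published element-stress
tables in MPa). Total length is only an approximation of fibre length; no
pennation correction is applied, deliberately minimising ad hoc assumptions.
Craniocervical muscles have no usable volume reconstruction, so their
cross-sectional area is taken directly from occipital insertion areas.

Because specific tension in vertebrate muscle spans a wide literature range,
`tension_sweep()` recomputes force tables over a vector of tensions (default
147, 250 and 392 kPa — a bracket drawn once from the published range for
vertebrate skeletal muscle). Force is exactly linear in both PCSA and
tension, so the sweep rescales conclusions rather than changing rankings.

Left/right muscle pairs are computed per table row with no silent doubling:
whether a published table reports unilateral or bilateral totals is often
unstated, and summing is left to the analyst.

## The FE solver

`solve_static()` is a small-strain, linear-elastic solver on 4-node
constant-strain tetrahedra — the element type of large CT-derived cranial
models — with:

* **Muscle loads** (`apply_muscle_load()`): the total force is split equally
  over the origination-set nodes, each share directed from its node towards
  the insertion point. This mirrors preprocessor muscle-loading macros that
  "load multiple nodes along a vector projected towards the insertion". The
  macro's nodal weighting is not documented anywhere we know of; equal split
  is deterministic and stated. Consequently the resultant equals the nominal
  total only when directions are parallel — the enforced contract is the
  per-node magnitude.
* **External loads**: a resultant over a node set, distributed either by
  boundary-triangle tributary area (`"area"`, the default — consistent nodal
  forces, required for uniform-traction fields to be exact) or equally.
* **Constraints**: `per_node` prescribes displacements (zero or given values)
  on selected axes; `distributed_coupling` constrains the *set-average*
  displacement per axis through a Lagrange multiplier. The latter is the
  linear analogue of a distributing coupling constraint (a reference point
  tied to a node set by rigid links), spreading restraint over the set and
  avoiding the artificial stress singularities of point constraints.
  Quadrate sets are constrained in x, y, z and tooth sets along the biting
  axis, which is **global y** by convention (overridable).
* **Bite forces** (`bite_force()`): tooth distributed couplings are swapped
  for single fully fixed nodes and the reaction component along the biting
  axis is summed over the bite nodes — reaction-force extraction exactly as
  practised on cranial models.

Numerics: the sparse symmetric stiffness is assembled from the standard
isotropic formula; the solve is a deterministic sparse direct factorisation
(with an explicit error — not a pseudo-inverse — when rigid-body modes
remain, caught by factorisation failure or a residual check at 1e-6).
Reactions at fixed dofs are $K u - f$; coupling forces are the multipliers
spread with their row weights. Per-axis global equilibrium
($\sum$ reactions $+ \sum$ loads $= 0$) is verified in the tests at 1e-6
relative tolerance on every solved case. Element stress summaries
(min/mean/max von Mises) use an unweighted mean over elements, matching
element-stress table conventions; a volume-weighted mean is available.

Verification battery (all in the test suite): a patch test (affine boundary
displacement reproduced exactly, uniform stress), the axial bar closed form
($\delta = FL/EA$, $\sigma = F/A$, exact for this field), a two-material bar
in series, linearity in loads and inverse scaling with stiffness, and an
Euler–Bernoulli cantilever. Constant-strain tetrahedra are stiff in bending,
so the cantilever converges monotonically from below: the package's
convergence sequence is 2×2×20, 4×4×40 and 6×6×60 cells (12 960 elements at
the finest), reaching the beam-theory tip deflection within 15% (measured
≈ 8%) at the finest refinement, with summary stresses changing < 5% between
the two finest levels. These problem sizes keep the default test run fast
while exercising every code path of the production-scale formulation.

## Ecological vs structural comparisons

`run_comparison()` pairs two models under two standardisation protocols:

* **ecological** — both models at natural size and loads: how the animals
  compare as competitors;
* **structural** — model B's loads rescaled so total applied muscle force
  per unit skull surface area equals model A's: a size-free comparison of
  skull shape, since for geometrically similar bodies stress is invariant
  when load scales with area. "Skull surface area" is the total boundary
  area of the volume mesh.

The juvenile-to-adult case (a skull scaled by 180%) is exposed as a generic
`linear_scale_factor` in `scale_model()`: coordinates scale by the factor and
muscle/external forces by factor², the contract implied by isometry (volume
× factor³ over length × factor). Whether re-measured adult muscle forces
would differ from isometric rescaling is unknowable from outside the original
reconstruction; isometry is the only stated rule and is applied exactly.

The geometric-similarity property — a mesh scaled by $s$ with loads scaled
by $s^2$ reproduces the identical stress field — is verified at $s = 2$ and
is what makes the structural comparison meaningful. Published absolute
element stresses and bite forces for real skulls are *not* reproducible
here: they depend on CT-derived specimen geometry. The package therefore
verifies the solver and protocols on closed-form and similarity oracles
instead, and the box "skull proxy" (`skull_proxy_model()`) is a labelled
synthetic stand-in reproducing the loading/constraint topology of a cranial
biting model, not skull geometry.

## The craniodental functionspace

`z_transform()` standardises each continuous character to mean 0 and sample
(n−1) sd 1 over its scored cells; binary characters enter untouched as 0/1.
Distances (`fs_distance()`) default to Euclidean over the characters both
taxa score, rescaled by $\sqrt{p_{total}/p_{shared}}$ — the standard
pairwise-deletion treatment that keeps sparsely shared pairs from appearing
artificially close. Because the exact distance used in historical PCO runs
of such matrices is usually unstated, plain pairwise Euclidean and a
range-normalised Gower option are provided and the choice is recorded in the
ordination object.

`pco()` double-centres the squared-distance matrix (Gower) and
eigendecomposes it. Axes are ordered by eigenvalue; variance fractions are
taken over positive eigenvalues only; negative eigenvalues (expected for
semi-metric incomplete-data distances) are counted and reported, with no
Lingoes/Cailliez correction by default — corrections change variance
fractions and would silently move replication targets. On complete data the
result equals PCA exactly (verified at 1e-9).

`npmanova()` computes the permutational-MANOVA pseudo-F from Euclidean
distances among score rows (by default the first 18 axes, taken literally
from the reported protocol) with

$$F = \frac{SS_B/(g-1)}{SS_W/(n-g)}, \qquad
p = \frac{\#\{F^* \ge F\} + 1}{n_{perm} + 1},$$

seeded label permutation (default 9999 permutations; p is never reported as
0), and an exhaustive-enumeration mode for small two-group problems. The
univariate case reduces to the classical ANOVA F (verified against `aov`),
and the implementation is cross-checked against `vegan::adonis2`. Pairwise
tables use Bonferroni correction — chosen as the most conservative standard
correction since the original correction method is not stated. Character
loadings are Spearman rank correlations with mid-ranked ties, computed per
character over its scored taxa and skipped below 3 points.

## Phylomorphospace

`time_scale()` re-implements occurrence-based time-scaling: tips are dated
at their first-appearance ages (stage-midpoint by convention when stages are
resolved upstream), a node's age is the oldest age among its descendants
(`basic`), and `mbl` mode pushes node ages rootward minimally so every
branch is at least `mbl` Myr (default 1 Myr) — zero-length branches would
break Brownian ancestral-state weights. `mbl` never lowers any node age
relative to `basic`, and tip ages are never altered.

Ancestral states use branch-length-weighted squared-change parsimony —
internal values minimising $\sum (\Delta x)^2 / \ell$ over branches — which
equals the maximum-likelihood states under Brownian motion. The method
behind published phylomorphospace figures is rarely stated; this is the
field-standard default and is solved here exactly as a sparse linear system
over the tree's weighted Laplacian (verified against brute-force numerical
minimisation and `phytools::fastAnc`, and unbiased at the root over 200
simulated Brownian datasets). Polytomies are treated as hard.
`project_phylomorphospace()` emits one parent-to-child segment per branch
with tips pinned at their observed ordination scores; tips lacking scores
are pruned with a warning.

## Synthetic data: what it emulates, and what it does not

Three seeded generators make every stage testable without any download:

* `make_box_mesh()` / `skull_proxy_model()`: structured boxes split six
  tetrahedra per cell (Kuhn subdivision, chosen over the 5-tet split for
  orientation uniformity; an optional mirrored mode makes the
  tetrahedralisation exactly left/right symmetric so paired bite points see
  identical stiffness). Node sets mark tooth pairs, quadrate patches and
  muscle origination patches; materials can be layered along z.
* `make_two_grade_matrix()`: two functional grades with continuous
  characters offset by ±δ/2 between groups and binary characters with
  group-dependent rates. Study-condition defaults, fixed a priori: 35 taxa,
  20 characters as 17 continuous + 3 binary (the counts reported for such
  matrices are internally inconsistent — a stated total of twenty against
  17 + 4 by kind — and the package keeps the total and the continuous
  count), δ = 2.5 within-group sd (clear grade separation, as observed
  empirically), sd 1, binary rates 0.2/0.8, and a missing fraction of
  0.247 masked as exactly `round(0.247 × 700) = 173` cells so realised
  completeness is deterministically 75.3% (to one decimal). Masks are
  completely-at-random (redrawn deterministically if they would leave a
  taxon pair with no shared characters, or a character with under two
  scored cells; a column-biased mode mimics concentration of missingness in
  poorly preserved taxa).
* `make_bm_tree_data()`: random bifurcating topologies, uniform tip ages on
  145–170 Ma (a Late Jurassic-like window), `mbl` time-scaling, Brownian
  tip values with recorded truth.

What passing tests on these synthetics demonstrate: the arithmetic,
ordination geometry, statistical calibration (type-I error at α = 0.05
within binomial error over 500 null runs) and estimator unbiasedness of the
pipeline. What they do not demonstrate: recovery of any empirical result
that depends on real skull geometry or on the actual character matrix.
In particular, the empirical targets "PC1+PC2 > 50%" emerge naturally from
the study-condition generator, but an individual axis value such as
"PC3 = 7.4%" is a property of the real matrix; without redistributing it,
the package reports the synthetic analogue and documents the gap rather
than simulating agreement.

## Pipeline and provenance

`run_pipeline()` chains the stages (muscle forces → synthetic models → FE
comparison → functionspace → phylomorphospace) under one config whose
`units` tag must read `"mm_N_MPa"`, writes every output with 6 significant
digits, and records a manifest (config hash, seeds, package version, MD5
checksum per output). Reruns with an identical config are bit-identical;
stage failures are recorded in the manifest by stage name and re-raised.

## Known limitations

* Constant-strain tetrahedra require fine meshes for bending-dominated
  problems; the solver targets small verification meshes, not
  million-element production models.
* Distributed couplings constrain set averages (fully linear); true rigid
  distributing couplings add kinematic coupling between the set's nodes.
* The distance choice for incomplete matrices genuinely changes axis
  variance fractions; all options are exposed and labelled.
* Time-scaling implements the basic and minimum-branch-length rules only;
  stochastic calibration methods are out of scope.
* No nonlinear materials, contact, dynamics, or mesh generation from
  imaging data.
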