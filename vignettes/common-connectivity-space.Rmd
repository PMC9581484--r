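---
title: "A common connectivity space: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A common connectivity space: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bxs)
```

## The problem

Brains of different species, and of the same species at different ages,
differ in size, folding, and areal layout, so their cortical locations
cannot be compared coordinate by coordinate. What *can* be compared is how
each cortical location connects to a standard set of named white-matter
bundles: a **connectivity blueprint**, the matrix whose row $i$ holds the
likelihood that vertex $i$ connects through tract $k$, for tracts
$k = 1 \dots T$ reconstructed with the same protocol logic in every brain.
Once two brains are expressed in this shared "tract basis", their
vertices live in one space and can be compared, matched, and embedded
together, regardless of geometry.

`bxs` implements that pipeline end to end at desk scale: standardized
probabilistic tractography under seed/waypoint/exclusion/stop protocol
semantics, population tract atlases, blueprint construction and group
averaging, symmetric Kullback–Leibler (KL) divergence mapping between
brains, spectral-embedding atlas translation, and tract-maturation GLMs.
Because real neonatal/adult/macaque diffusion MRI datasets are out of
reach for automated testing, every analysis runs on synthetic phantoms
with known ground truth; the phantom generators are first-class, tested
code.

## The divergence measure

Rows of normalized blueprints are probability distributions over tracts,
so two vertices $i$ (brain $N$) and $j$ (brain $A$) are compared with the
symmetric KL divergence in bits:

$$D_{ij} \;=\; \sum_k N_{ik} \log_2 \frac{N_{ik}}{A_{jk}}
          \;+\; \sum_k A_{jk} \log_2 \frac{A_{jk}}{N_{ik}}$$

`symmetric_kl()` and `divergence_matrix()` implement this directly.
**Zero handling:** blueprint rows routinely contain exact zeros, which
make the sum infinite. A floor of $10^{-6}$ (configurable, recorded in
outputs) is added to *every* entry of both rows, which are then
re-normalized. Under this rule the divergence is finite, nonnegative,
symmetric, and zero exactly when the rows coincide. The floor perturbs
values by $\mathcal{O}(10^{-5})$ bits for typical rows — negligible
against the 0.1–1-bit scale of real comparisons.

Derived maps:

* `min_divergence_map()` — per vertex of the non-reference brain, the
  minimum of its divergence row over the reference brain, and the argmin
  (the best-matching vertex). Ties break deterministically to the lowest
  index. Direction is a flag; the convention is rows = non-reference,
  columns = reference.
* `parcellate_divergence()` — parcel-wise **median** along rows and
  columns; excluded parcels (poorly represented regions such as an insula
  analogue) never enter. Even-count medians use the midpoint convention.
  `corresponding_parcel_divergence()` takes the diagonal when both brains
  share one parcellation scheme.
* `joint_divergence()` / `xor_divergence()` — fuzzy-logic AND
  ($B \times C$) and exclusive OR ($B + C - 2BC$) of two divergence maps,
  e.g. an ontogeny and a phylogeny dimension. These formulas are only
  meaningful on $[0,1]$, and the source analyses do not state their
  normalization, so this package makes the convention explicit: inputs
  must first pass `rescale_map()` (min–max over valid vertices), and the
  `scaled` flag is enforced as a small state machine rather than assumed.
* `entropy_map()` — Shannon entropy (bits) of each row, a complexity
  measure of connection patterns; zero entries contribute zero.
* `bootstrap_divergence()` — resamples both groups with replacement
  (reference design: 100 iterations at group sizes 20/20/4),
  re-averages, and returns the per-vertex mean and variance of the
  min-divergence map.

## Tracking model

The streamline engine (`propagate_streamline()`, `run_protocol()`)
follows the standardized cross-species configuration: 0.5 mm steps
(0.2 mm macaque preset), a curvature threshold of 80° per step, at most
2000 steps per direction, and subsidiary fibers considered above a 1%
volume fraction. At each step one fiber is drawn from the voxel's
discrete fiber set with probability proportional to its volume fraction
(posterior-sampling crossing-fiber models are out of scope; fractions act
as mixture weights).

Two choices deserve explanation:

* **Per-run sign instead of per-step realignment.** If every sampled
  orientation were re-flipped toward the current heading, no turn could
  ever exceed 90° and the curvature threshold would lose most of its
  meaning. Instead the sign is fixed once per run at the seed (forward =
  the locally dominant fiber; backward = its negation) and applied to all
  sampled orientations, so a genuine 120° kink terminates with reason
  `"curvature"`. This assumes orientation fields are sign-consistent
  along bundles, which the phantoms guarantee; axial (sign-free) fields
  from real crossing-fiber fits would need a realignment mode, a known
  limitation.
* **Binary visitation counting.** Each valid streamline increments a
  voxel at most once, so maps normalized by the valid-streamline count
  read as visitation probabilities in $[0,1]$ — the interpretation the
  downstream 0.1% binarization threshold requires. Whether multiple
  visits should accumulate is left open by the source material; binary
  counting is the stated convention here.

Protocol semantics: a streamline is valid iff it visits every waypoint
mask (in any order — order constraints are not part of the protocol
model); any exclusion-mask visit discards it; stop masks truncate
propagation (the stop voxel itself is recorded). With reverse seeding the
protocol runs a second time with seed and target roles exchanged and the
two *normalized* distributions are summed. A run with zero valid
streamlines returns an explicit `empty` flag, never silent zeros.

## Atlases and reproducibility

`build_atlas()` binarizes each subject's normalized density map at 0.1%
(0.001) and averages across subjects, giving per-voxel population
percentages. "0.1%" is interpreted as a fraction of valid streamlines —
maps are streamline-count-normalized, so the percent sign reads on that
scale; the constant lives in one argument. `atlas_similarity()`
correlates tracts between atlases over the **union** of voxels
suprathreshold (30% population) in either atlas; union support was chosen
over intersection because it avoids asymmetry between the two atlases
(the source is silent on this point, and its printed cross-dataset
correlations are not recomputable without the original cohorts either
way). `intersubject_variability()` enumerates all $n(n-1)/2$ within-group
pairs — 231 at the reference group size $n = 22$ — and, across groups,
draws exactly the same number of distinct cross pairs without
replacement, seeded.

## Blueprints

`surface_connectivity()` seeds streamlines from every mesh vertex (the
white–gray-boundary analogue; 1000 per vertex at full scale, far fewer in
tests) and records vertex-by-voxel visitation counts over a brain mask
with ventricle voxels removed. `build_blueprint()` multiplies this matrix
by the stacked tract density maps — entry $(i,k)$ is the inner product of
vertex $i$'s visitation profile with tract $k$'s map. Rows are normalized
on demand; zero-support rows (medial-wall analogue) carry an explicit
validity flag that propagates into divergence maps, rather than being
padded with a pseudo-uniform distribution. `average_blueprints()`
normalizes subjects **first**, then averages, then re-normalizes; the
alternative (average raw counts) would let streamline-rich subjects
dominate. The chosen order is recorded in output metadata.

## Embedding

`similarity_from_divergence()` inverts parcel divergence
($1/(D+\varepsilon)$, $\varepsilon = 10^{-6}$ guarding self-pairs; a
Gaussian kernel is exposed as an alternative since only "the inverse" is
specified). Parcels of both brains enter one joint similarity graph, and
`spectral_embed()` returns coordinates from the leading nontrivial
eigenvectors of the normalized (random-walk) graph Laplacian — chosen
over the unnormalized Laplacian for scale invariance to overall
similarity magnitude. Two determinism conventions: each mode's sign is
canonicalized (first nonzero loading positive), and coordinates carry
diffusion-map scaling (each mode weighted by its operator eigenvalue
$1-\lambda$), which makes the degenerate all-equal-similarity case
collapse to coincident points instead of arbitrary axes. Disconnected
similarity graphs are refused with component sizes named.
`system_centers()` summarizes each anatomofunctional system by the
coordinate-wise median of its parcels, per brain.

## Maturation statistics

`fit_dti()` does log-linear least-squares tensor estimation restricted to
the $b = 1000$ s/mm² shell plus $b = 0$ volumes, with FA and MD from the
eigenvalue closed forms; non-physical fits (nonpositive eigenvalues) are
flagged, not clipped, for transparency at low SNR.
`tract_median_metric()` extracts tract-wise medians over atlas ROIs
thresholded at 30% population, plus tract volume in mm³ as a confound.
`fit_maturation_glm()` runs one OLS model per tract per metric (metric ~
age + birth weight + head circumference + tract volume + QC score), with
Bonferroni correction across the tract family within a metric at
$\alpha = 0.05$ — the family definition and $\alpha$ are conventions,
recorded in the output attributes, since neither is printed in the source
material. Rank-deficient designs fail loudly, naming the collinear
columns. Registration of atlases to native space is replaced by a
same-grid precondition; warping is out of scope.

## What the phantoms emulate — and what they do not

* `make_fiber_phantom()` builds straight, arc, and 90°-crossing bundles
  with up to three fibers per voxel and per-bundle volume fractions, each
  with a matching protocol (seed at one end, waypoint mid-course, stop at
  the far end, exclusion off-course) and a ground-truth voxel mask.
* `make_synthetic_blueprints()` draws vertex-specific Dirichlet profiles
  shared across groups (ground-truth correspondence = identity) and mixes
  in a group-specific profile with weight `group_shift` — a convex,
  bounded, monotone control of expected between-group divergence, zero in
  expectation at shift 0 (groups exchangeable). Subject rows are
  Dirichlet draws around the shifted profile (default concentration 100,
  i.e. modest subject-to-subject variability). Dirichlet rows were chosen
  because blueprint row distributions are not modeled in the source
  material and Dirichlet gives normalized rows with one interpretable
  concentration parameter.
* `make_dwi_phantom()` produces multi-shell signals
  $S = S_0 e^{-b\,g^\top D g}$ from stated tensors with Gaussian noise at
  a stated SNR (Rician optional; Gaussian is the default because the
  tracker never consumes raw DWI in the main pipeline). The emulated
  shell structures are $b = 400/1000/2600$ and $b = 1000/2000/3000$
  s/mm².

All generators are seed-deterministic. A green test on these phantoms
establishes that the *algorithms* behave as specified — correct counting,
normalization, divergence algebra, recovery of planted structure. It does
not establish anything about real neuroanatomy: the phantoms have no
folding, no partial-volume gradients, no distortion or motion artifacts,
and their bundle geometry is trivially simple. Cohort-scale numbers from
the source analyses (mean divergences of 0.33/0.62/0.68 bits, atlas
correlations of 0.89/0.86) depend on those real datasets and are
deliberately not asserted anywhere in this package.

## Numerical conventions

* KL floor $10^{-6}$ with re-normalization; negative round-off in the
  vectorized divergence matrix clamped at zero.
* Normalized blueprint rows must sum to 1 within $10^{-9}$.
* Voxel indices 0-based, world coordinates mm RAS+; all masks of one
  protocol must share grid and affine exactly.
* Medians: midpoint convention on even counts.
* Argmin ties: lowest index.
* Integer-valued volumes are written as int32 NIfTI (bit-exact round
  trip); doubles as float64.
* Every stochastic entry point takes a seed; the CLI records seed and a
  config hash in a `.provenance.json` sidecar next to each output.

## Known limitations

* The tracker is pure R and desk-scale; it is not a replacement for
  GPU/compiled tractography at cohort scale.
* Directed orientation fields are assumed sign-consistent along bundles;
  axial fields from real data would need a realignment mode.
* The NIfTI/GIFTI readers cover the subset of the formats this pipeline
  writes (plus common encodings) and are not general-purpose libraries.
* Template-space semantics are carried as a free-text tag only;
  registration between spaces is out of scope by design.
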