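# bxs — standardized tractography and common connectivity spaces

`bxs` is an R toolkit for comparing cortical connectivity across brains
that share no geometry — different species, different ages — by
expressing every brain in one shared basis: its pattern of connections to
a standard library of named white-matter tracts.

It is aimed at researchers who want to prototype, teach, or validate the
*logic* of cross-brain connectivity comparison — protocol-constrained
tractography, connectivity blueprints, divergence mapping, atlas
translation — on fully synthetic data with known ground truth, without
downloading any imaging cohort.

## The core model

1. **Standardized tractography.** Each tract is reconstructed by
   probabilistic streamlining under a protocol of masks: a *seed*
   (starting points), *waypoints* (a streamline must visit all of them to
   be valid), an *exclusion* mask (any visit discards the streamline) and
   a *stop* mask (truncates propagation). Valid streamlines are counted
   once per voxel and normalized by the number of valid streamlines.
   Defaults: 0.5 mm steps (0.2 mm small-brain preset), 80° curvature
   threshold, 2000 max steps, 1% subsidiary-fiber volume-fraction
   threshold. The packaged library metadata describes 23 named bundles
   (19 bilateral + 4 commissural) that expand to 42 protocols.

2. **Connectivity blueprints.** Seeding from every vertex of the
   white–gray boundary gives a (cortex × brain-voxels) visitation matrix;
   multiplying by the stacked tract density maps gives the blueprint
   `N` with `N[i, k]` = connection likelihood of vertex `i` through tract
   `k`. Normalized rows are probability distributions over tracts.

3. **Divergence.** Vertices of two brains are compared with the symmetric
   Kullback–Leibler divergence, in bits:

   ```
   D[i, j] = Σ_k N[i,k] log2(N[i,k] / A[j,k]) + Σ_k A[j,k] log2(A[j,k] / N[i,k])
   ```

   Minimum-divergence maps ("how different is the best-matching
   profile"), parcel-median divergence matrices, joint (`B·C`) and
   exclusive-OR (`B + C − 2BC`) map algebra, row entropy, and bootstrap
   dispersion are built on top.

4. **Atlas translation.** Inverse divergence (`1/(D+ε)`) over parcels of
   both brains forms one similarity graph; spectral embedding (normalized
   graph Laplacian, top two modes) places corresponding cortical systems
   near each other, letting atlases be read across brains.

5. **Maturation statistics.** Diffusion-tensor fits (log-linear LS on the
   b = 1000 shell), tract-median FA/MD over population-atlas ROIs (30%
   threshold), and per-tract OLS of metric against age with birth weight,
   head circumference, tract volume and QC score as confounds, Bonferroni
   corrected across the tract family.

Everything runs on built-in phantoms: fiber fields with straight / arc /
crossing bundles plus matching protocols and ground-truth masks, Dirichlet
blueprints with a tunable between-group shift, and closed-form DWI
signals.

## Worked example

```r
library(bxs)

# a straight-bundle phantom with its protocol and ground truth
spec <- phantom_spec(shape = c(30L, 12L, 12L),
  bundles = list(list(kind = "straight", axis = 1, center = c(6, 6),
                      radius = 1.5, fraction = 1)), seed = 7)
ph <- make_fiber_phantom(spec)

# run the protocol: seed -> waypoint -> stop, exclusion off-course
pdm <- run_protocol(ph$field, ph$protocols[[1]],
                    tracking_params(samples = 200, seed = 42))
pdm
#> <path_density_map> 30 x 12 x 12, 200 valid streamline(s), normalized

tv <- ph$truth[[1]]$values
100 * sum(pdm$counts$values >= 0.001 & tv == 1) / sum(tv)
#> [1] 96.66667     # % of ground-truth bundle voxels recovered at the 0.1% threshold

# two synthetic "brains" with controlled divergence, compared via Eq-style
# symmetric KL on group-averaged blueprints
res <- make_synthetic_blueprints(n_vertices = 100, n_tracts = 11,
  n_groups = 2, group_shift = 0.3, n_subjects = 10, seed = 1)
gA <- average_blueprints(res$groups[[1]])
gB <- average_blueprints(res$groups[[2]])
mm <- min_divergence_map(divergence_matrix(gA, gB))
summarize_divergence(mm)
#> $mean   0.2053128     # bits; grows with group_shift
#> $sd     0.07205588
#> $median 0.200953
#> $mad    0.06829071

mean(mm$argmin == seq_len(100))
#> [1] 0.83              # best-match recovery of the identity correspondence
```

The numbers mean: tracking recovered 96.7% of the planted bundle at the
0.1% density threshold; the two synthetic brains (shift 0.3) diverge by
~0.21 bits on average at the best-matching vertex; and with subject noise
present, 83% of vertices still pick their true counterpart as the best
match (at shift 0 with low noise this is 100% — see the acceptance
tests).

## Command line

```sh
Rscript inst/cli/bxs phantom --spec spec.json --seed 3 --out phantom/
Rscript inst/cli/bxs track --field phantom/field.nii.gz \
    --protocol phantom/bundle1/protocol.json --samples 1000 --seed 7 --out density.nii.gz
Rscript inst/cli/bxs divergence --a groupA.tsv --b groupB.tsv --out div/
```

Subcommands: `phantom`, `track`, `atlas`, `blueprint`, `divergence`,
`embed`, `maturation`. Exit codes: 0 success, 1 module error, 2 usage.
Every output gets a `.provenance.json` sidecar (tool version, seed,
config hash).

## Documentation

See `vignettes/common-connectivity-space.Rmd` for the model, parameter
conventions, phantom design, numerical choices, and known limitations.
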