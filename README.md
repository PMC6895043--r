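# cryofit

Rigid-body fitting of multi-domain atomic models into cryo-EM density maps
by Metropolis Monte Carlo, with a per-residue map–model correlation report
for local model validation.

At intermediate cryo-EM resolution (4–8 Å) atomic refinement is
ill-posed, but whole domains can be placed reliably by optimizing only
their global rotations and translations against the map. `cryofit` scores
a pose with

```
E = w1 * (1 - CC(rho_obs, rho_calc))
  + w2 * sum_{i != j} eps_ij [ (r_ij/d_ij)^12 - 2 (r_ij/d_ij)^6 ]
```

where `CC` is the Pearson cross-correlation between the experimental map
and a Gaussian model density simulated from the current pose, and the
second term is a 12-6 steric-clash penalty over inter-body atom pairs with
CHARMM-convention parameters (`r_ij = r_i + r_j`,
`eps_ij = sqrt(eps_i * eps_j)`). Defaults are `w1 = 100`, `w2 = 1`, and a
budget of 50,000 Metropolis moves (random single-body Gaussian
translations and rotations about the body centroid).

Local quality is judged per residue: `CC(R_i)` is the same correlation
restricted to the voxels strictly within 5 Å of residue *i*'s atoms, with
mask-local means and the model density simulated from every atom. A
positive score means the map supports the model locally; consecutive runs
of non-positive residues are flagged.

The package is aimed at structural biologists fitting domain models
(crystal structures, predicted models) into intermediate-resolution maps,
and includes a synthetic fixture generator (idealized poly-Ala helices plus
ground-truth maps) so that the whole pipeline is testable without any
downloads.

## Worked example

Build a two-helix dumbbell, simulate a 6 Å ground-truth map on 2 Å voxels,
displace one helix by 5 Å and 15°, and recover its pose:

```r
library(cryofit)

toy  <- makeToyModel("dumbbell", nRes = 10, offset = 20)
map  <- makeGroundTruthMap(toy$model, resolution = 6, voxel = 2)
pert <- perturbPose(toy$model, toy$partition, "body2",
                    translation = 5, rotation = 15, seed = 42)

fit <- fitModel(pert$model, toy$partition, map,
                mcConfig(nMoves = 50000, resolution = 6, seed = 7))
fit
#> FitResult: 50000 moves, acceptance 54.8%, seed 7
#>   best: EnergyBreakdown: total 1.78561 (cc 0.982144, ccTerm 1.78561, clashTerm 0)

modelRMSD(bestModel(fit), toy$model, bodies(toy$partition)$body2)
#> [1] 0.676965
```

The fit drives the total energy from ~42 (the perturbed pose) down to 1.8:
the map–model correlation recovers to 0.98 and the displaced helix returns
to within 0.7 Å of its true pose. Per-residue validation of the recovered
model:

```r
rep <- perResidueCC(bestModel(fit), map, resolution = 6, radius = 5)
flagPoorRegions(rep)   # zero rows: every residue scores cc > 0
```

A command-line interface wrapping the same functions is installed at
`system.file("cli", "cryofit.R", package = "cryofit")`, with subcommands
`fit`, `score`, `quality`, `simulate` and `make-fixture` (PDB models in,
MRC2014 maps in/out, TSV traces and JSON results out).

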