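---
title: "Rigid-body fitting of atomic models into cryo-EM maps: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Rigid-body fitting of atomic models into cryo-EM maps: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Single-particle cryo-EM frequently resolves a multi-subunit assembly at
intermediate resolution (4--8 Å): good enough to place folded domains, far
too coarse to refine atomic positions freely.  The standard remedy is
rigid-body fitting — each domain keeps its internal geometry from a crystal
structure or a predicted model, and only its global rotation and translation
are optimized against the experimental density.  `cryofit` implements this
as Metropolis Monte Carlo sampling over domain poses, plus a per-residue
map–model correlation report for judging which parts of a fitted model
(e.g. a flexible linker threaded through weak density) the map actually
supports.

## The objective function

A pose is scored by

$$E = w_1\,\bigl(1 - \mathrm{CC}(\rho_o, \rho_c)\bigr)
    \;+\; w_2 \sum_{i}\sum_{j \ne i}
      \varepsilon_{ij}\left[\left(\frac{r_{ij}}{d_{ij}}\right)^{12}
      - 2\left(\frac{r_{ij}}{d_{ij}}\right)^{6}\right]$$

with defaults $w_1 = 100$, $w_2 = 1$.

* **Correlation term.**  $\mathrm{CC}$ is the Pearson correlation between
  the experimental map $\rho_o$ and the model density $\rho_c$ simulated
  from the current pose, evaluated by default over every voxel of the
  experimental map.  A model-proximity mask (`modelMask()`) can restrict the
  domain explicitly; the package never masks silently.  Because CC is
  bounded by 1, the term is non-negative and vanishes exactly at a perfect
  fit.
* **Clash term.**  A 12-6 potential with CHARMM-convention pair parameters:
  $r_{ij} = r_i + r_j$ (sum of van der Waals radii) and
  $\varepsilon_{ij} = \sqrt{\varepsilon_i \varepsilon_j}$.  The minimum is
  $-\varepsilon_{ij}$ at $d = r_{ij}$ and the zero crossing sits at
  $d = 2^{-1/6} r_{ij}$; closer approach is penalized steeply, which is the
  property the fit relies on.

Two scoping decisions deserve emphasis.  First, the pair sum runs over
**inter-body pairs only** (including body vs. fixed atoms).  Atom pairs
inside one rigid body are at constant separation under rigid motion, so
including them would add a large pose-independent offset — often dominated
by covalently bonded neighbours — without changing any energy difference.
Second, the double sum counts each pair in both orders; `orderedPairs =
FALSE` halves the value if the unordered convention is preferred.  Both
choices change only the absolute scale of reported clash energies, never
the sampling behaviour.

The clash cutoff defaults to 8 Å, where the neglected 12-6 tail is below
$10^{-3}\varepsilon$ per pair.  Pairs are found by a plain double loop over
inter-body atom pairs; at the system sizes this package targets (domains of
$10^2$–$10^3$ atoms) this is not a bottleneck, and a neighbour-list scheme
would be the first thing to add for much larger assemblies.

## Model density

No closed-form "true" density exists for a model at finite resolution, so a
convention is required.  Each atom contributes an isotropic Gaussian with

* standard deviation $\sigma = 0.225 \times \text{resolution}$
  (`sigmaFactor`, configurable),
* amplitude proportional to atomic number (`amplitude = "unit"` for flat
  weights),
* truncation at $4\sigma$ (beyond which a contribution is dropped, and an
  atom outside the grid by more than that simply contributes nothing).

The correlation coefficient is insensitive to the exact width convention —
it is invariant under any positive affine rescaling of either map — so this
choice affects absolute densities but hardly the fitted poses.  Simulation
requires `resolution >= 2 * voxel` (Nyquist); violating it is an error, not
a warning.  Voxel positions refer to voxel centres, and a grid's origin is
the centre of voxel (0,0,0).

## Sampling

Each of the `nMoves` iterations (default 50,000, the total across all
bodies) proposes either a translation or a rotation of one uniformly chosen
body, with probability 1/2 each:

* translation: isotropic Gaussian, $\sigma$ = 1 Å (`translationStep`);
* rotation: Gaussian angle, $\sigma$ = 2° (`rotationStep`), about a
  uniformly random axis through the **current body centroid** — pivoting at
  the centroid decouples the rotation channel from the translation channel.

Both channels are symmetric ($q(x \to x') = q(x' \to x)$), so plain
Metropolis acceptance — accept if $\Delta E \le 0$, else with probability
$\exp(-\Delta E / kT)$ — targets the Boltzmann measure of $E$.  The
temperature is not part of the published protocol; the default $kT = 1$ is
chosen so that with $w_1 = 100$ a one-percentage-point change in CC gives
$|\Delta E| = 1$, i.e. acceptance stays meaningful on the scale at which CC
moves.  With the default steps this yields 30–60% acceptance on the bundled
fixtures.  An optional linear `anneal = c(start, end)` schedule is provided
but off by default.  Proposals whose energy overflows (deep steric overlap
can exceed floating-point range) are auto-rejected and counted rather than
aborting the run.

The sampler reports the **best pose seen**, not the final pose: plain
Metropolis at fixed $kT$ does not terminate at the minimum.  Whether moves
should alternate deterministically between translations and rotations was an
open choice; the random 50/50 split keeps the proposal chain memoryless.

### Incremental evaluation

Recomputing the full objective at every move would cost a whole-model
density simulation each time.  `energyState()` caches per-body density
grids, the running correlation sums and the inter-body clash table; a
single-body move then touches only that body's density contribution and its
pair rows.  This is exact, not approximate — the test suite holds it to
$10^{-8}$ against full recomputation over a thousand Metropolis-gated moves
— and the state is re-synchronized from scratch every 500 moves so that
floating-point drift cannot accumulate over long runs (a final audit
compares the cached energy against a fresh evaluation and aborts on
disagreement beyond $10^{-6}$).

## Per-residue quality score

For residue $i$, the mask $R_i$ collects the voxels whose centre lies
**strictly** closer than 5 Å (`radius`) to any atom of the residue, and

$$\mathrm{CC}(R_i) = \frac{\sum_{y \in R_i}(\rho_o(y) - \bar\rho_o)
  (\rho_c(y) - \bar\rho_c)}
  {\sqrt{\sum_{y \in R_i}(\rho_o(y) - \bar\rho_o)^2}
   \sqrt{\sum_{y \in R_i}(\rho_c(y) - \bar\rho_c)^2}}$$

with both means taken over $R_i$ itself, not the whole map, and $\rho_c$
simulated from **every** atom of the model (the 5 Å masking distance is the
whole-model convention; a residue-only $\rho_c$ is available behind
`calcMode = "residue"` for diagnostics).  A positive score indicates that
the model locally explains the density; `flagPoorRegions()` extracts
maximal per-chain runs at or below a threshold (default 0).  Residues whose
mask is empty are reported with `cc = NA` and a warning; residues whose
mask shows no density variation on either side are reported as `cc = 0`
with `degenerate = TRUE` — a deliberate sentinel meaning "no measurable
agreement", chosen so that residues sitting in featureless density rank
below any residue with genuine signal instead of propagating `NA` through
downstream comparisons.

## Synthetic ground truth

The generator builds idealized poly-alanine α-helices: CA atoms on a
2.28 Å-radius helix with 1.5 Å rise and 100°/residue (hence the canonical
3.8 Å CA–CA distance), five heavy atoms per residue placed in the local
cylindrical frame.  The geometry is idealized, not refined — CB points
axially so the body stays within a 2.3 Å radial envelope, which keeps the
two bodies of the default dumbbell (20 Å apart) separated by more than
15 Å.  The default benchmark conditions are a 10-residue-per-body dumbbell,
a 6 Å ground-truth map on 2 Å voxels, and one body perturbed by exactly
5 Å and 15° in a random direction; these sizes keep a full 50,000-move fit
around half a minute on one CPU while leaving the perturbation large enough
that recovery is not trivial.

Optional map noise is i.i.d. Gaussian per voxel, scaled to a fraction of
the clean map RMS.  That exercises the correlation kernel's robustness but
deliberately omits everything that makes real cryo-EM noise structured:
CTF, solvent background, local resolution variation, anisotropy.  Passing
the recovery benchmark therefore demonstrates that the sampler and
objective work as specified on well-posed problems; it does not certify
performance on experimental maps, where the density simulation convention
and local map quality matter far more.

```{r example}
library(cryofit)
toy  <- makeToyModel("dumbbell", nRes = 10, offset = 20)
map  <- makeGroundTruthMap(toy$model, resolution = 6, voxel = 2)
pert <- perturbPose(toy$model, toy$partition, "body2",
                    translation = 5, rotation = 15, seed = 42)
fit  <- fitModel(pert$model, toy$partition, map,
                 mcConfig(nMoves = 50000, resolution = 6, seed = 7))
modelRMSD(bestModel(fit), toy$model, bodies(toy$partition)$body2)
```

## File formats and conventions

* **PDB** (via `bio3d`): fixed-column ATOM/HETATM records; coordinates in
  Å, written to three decimals, so a round trip is exact to $10^{-3}$ Å.
  Alternate locations collapse to the highest-occupancy conformer (ties:
  first encountered).  Hydrogens and waters are dropped by default —
  deposited intermediate-resolution cryo-EM models carry neither, and the
  clash term is defined over heavy atoms.
* **MRC2014**: modes 0/1/2 read, mode 2 written; orthogonal cells only;
  axis order normalized from MAPC/MAPR/MAPS; origin from the ORIGIN record,
  falling back to NSTART × voxel.  Round trips are value-exact at float32.
* **Nonbonded parameters**: a plain-text element-level table
  (`inst/extdata/vdw_default.txt`) with optional per-atom-name overrides;
  the exact parameter set is configurable data, not a constant of the
  package, because published fits rarely state the force-field version they
  used.

## Known limitations

* Bodies are strictly rigid; no internal flexibility, no torsion-space
  moves.  Flexible refinement belongs to downstream tools.
* The clash pair search is $O(n_A n_B)$ per body pair; adequate for
  domain-scale fitting, not for ribosome-scale assemblies.
* No FSC computation, map sharpening, resampling, or non-orthogonal cells.
* A single fixed temperature by default; rugged landscapes (symmetric
  assemblies, many bodies) may need the annealing schedule or multiple
  seeds — the recovery benchmark in the test suite runs ten seeds for
  exactly that reason.
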