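---
title: "Modelling a mitochondria-targeted peroxidation probe in a cardiolipin membrane"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling a mitochondria-targeted peroxidation probe in a cardiolipin membrane}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mitoprobe)
```

## The system and the questions

Cardiolipin (CL), the four-tailed anionic phospholipid of the inner
mitochondrial membrane, is unusually prone to peroxidation because its acyl
chains are predominantly linoleoyl. A ratiometric probe for CL peroxidation
couples a BODIPY 581/591 fluorophore carrying an oxidizable phenyl-butadienyl
(PDT) tail to a triphenylphosphonium cation (TPP⁺) through a flexible
two-amide linker. Whether such a probe reports CL oxidation faithfully
depends on three structural questions this package makes computable:

1. **Depth**: does the probe's oxidizable diene reside at the same depth in
   the bilayer as the CL dienes and the CL hydroperoxides that attack it?
2. **Lateral affinity**: does the cationic probe co-localize laterally with
   the anionic cardiolipin rather than with the zwitterionic bulk lipids?
3. **Flexibility**: how stiff is the conjugated tail, and how floppy the
   linker, at thermal energies?

Alongside the structural model, a kinetics module quantifies the bench
readout: conjugated-diene formation at 234 nm during cytochrome-c-driven
liposome oxidation.

## The coarse generator instead of molecular dynamics

The reference analyses of this kind are run on ~1 µs all-atom membrane
simulations. Those are not reproducible at desk scale, so the package ships
a *generator* that emulates the statistical structure of such trajectories
with one particle per marker site. It is first-class, tested code — every
analysis stage runs identically on generated ensembles and on structures
read from GRO/PDB/XYZ files.

The model membrane mixes PLPC : SLPE : POPC : TLCL in the ratio 7 : 21 : 7 : 8
(the inner-membrane-like composition; SLPE is treated as the ethanolamine
species its abbreviation denotes). A leaflet of `n` lipids receives species
counts by largest-remainder apportionment — deterministic, exact whenever
`n` is a multiple of 43 — so `n = 43` gives exactly 7/21/7/8:

```{r}
cfg <- build_bilayer(n_per_leaflet = 43, seed = 1)
cfg$counts
```

Each lipid contributes marker particles: a phosphate-equivalent "P" for all
species; for cardiolipin additionally the central glycerol carbon "C2" and
the diene carbons "CC"; oxidized variants add the peroxide site "OO". The
probe contributes six markers (TPP phosphorus, two linker beads, two diene
carbons, the PDT tail centroid). Mono-peroxidized cardiolipin comes in
exactly eight species — the four linoleate hydroperoxide isomers (9-EE,
9-EZ, 13-EE, 13-ZE) on either the glycero-1- or glycero-2-acid half — and
`build_bilayer(..., oxidized = 9)` replaces the TLCL population by the four
same-position variants in equal proportion.

**Depths** are drawn from per-group Gaussians along the bilayer normal
(midplane at z = 0, per-leaflet sign). Defaults, all configurable, with a
common sigma of 3 Å: headgroup/TPP 18 Å, CL glycerol C2 16 Å, acyl and dye
dienes 8 Å, linker 14 Å, C9 hydroperoxide 9 Å, C13 hydroperoxide 13 Å. The
values reproduce the qualitative picture the analyses are meant to detect:
an L-shaped probe whose headgroup-region TPP lies outside its acyl-region
diene, and a C9 hydroperoxide band that co-localizes with the probe diene
more closely than the C13 band. They are modelling choices, not measured
constants.

**Lateral structure** is sampled per frame: lipids are placed uniformly with
a 4 Å hard-core minimum distance (dart throwing), and cardiolipin in the
dye-containing leaflet is then resampled by Metropolis Monte Carlo under a
square attraction well of depth ε (in kT) within radius r₀ of the dye,
with 2D periodic minimum image. Independence proposals make the chain mix
essentially immediately; 25 sweeps are used per frame. ε = 0 reduces to
uniform placement, and frames are statistically independent by
construction, which makes Monte-Carlo standard errors honest. The default
well radius r₀ = 7 Å mirrors the first-shell dye–CL distance reported for
the all-atom system; ε defaults to 2 kT.

What the generator deliberately does **not** emulate: solvent, membrane
undulations and curvature, barostat fluctuations, conformational coupling
between lipids, any in-plane correlation beyond the single dye–CL well, and
temporal autocorrelation (frames are independent; a real trajectory's
effective sample size is smaller). Passing the analysis suite on generated
data therefore validates the *statistics pipeline* — binning, normalization,
alignment, clustering, seeding — not the physics of any particular membrane.

## The localization statistics

`depth_density_profile()` histograms marker z-coordinates (recentred on the
per-frame phosphate midplane), averages over frames, and divides by slab
volume. Unit modes follow the display convention of plotting minority
components on comparable scales: mass density in g/cm³ for bulk groups, a
×10 scale for CL dienes, and a ×10 molar scale for the probe groups. The
unscaled profile integrates back to the selection's total mass per unit
area, which the tests assert to 1e-9.

`profile_overlap()` normalizes two same-grid profiles to unit sum and
returns the summed bin-wise minimum — 1 for identical shapes, 0 for disjoint
ones. For two equal-σ Gaussians separated by Δ the closed form is
2Φ(−Δ/(2σ)), which the binned implementation matches to the binning error;
that is the statistic behind "the C9 hydroperoxide overlaps the probe diene
more than C13 does":

```{r}
trj9 <- sample_frames(build_bilayer(n_per_leaflet = 43, seed = 2, oxidized = 9),
                      n_frames = 60, epsilon = 2, r0 = 7, seed = 3)
profile_overlap(depth_density_profile(trj9, group = "dye_diene"),
                depth_density_profile(trj9, group = "CL_peroxide"))
```

`lateral_map()` re-expresses every frame in the dye's own frame: translate
the dye reference point (by default the midpoint of the PDT and TPP
centroids) to the origin, rotate about the normal so the planar projection
of the PDT→TPP vector points along +Y, wrap neighbours by lateral minimum
image, and average per-species areal concentrations on a square grid.
Frames whose alignment vector has a degenerate planar projection are
skipped and counted. The occupancy mask marks cells above 50 % of the
species' own bulk concentration (count over leaflet area). The 50 %
threshold is interpreted per species, matching per-species occupancy plots;
an alternative reading (50 % of total lipid) would only rescale the masks.

`radial_distribution()` is lateral-2D by default: in-plane minimum-image
distances from the TPP phosphorus to a partner marker (CL C2 glycerol
carbon, or SLPE phosphate) within the dye-containing leaflet, normalized
per frame by the ideal-gas annulus expectation n_B/Area × π(r₂²−r₁²), so
g → 1 for unstructured placement. Lipids in a leaflet are quasi-planar and
the reference analyses are leaflet-restricted, which is why 2D is the
default; a 3D mode (spherical shells) exists. Per-bin standard errors come
from the frame-to-frame spread, which is exact here because frames are
independent.

`cluster_conformers()` implements GROMOS (Daura) clustering: pairwise RMSD
after optimal rigid-body superposition (Kabsch; implemented in
`kabsch_rmsd()` and cross-checked against an independent fitted-RMSD
routine in the tests), then iterative extraction of the frame with the most
neighbours within the cutoff. The "0.3" cutoff is read as 0.3 nm, the
GROMOS convention for an unlabelled RMSD cutoff; ties are broken toward the
lowest frame index so the partition is deterministic.

## Torsion parametrization

The probe's force-field gap is the conjugated phenyl-butadienyl tail: the
dihedrals between diene carbons need explicit parametrization against a
reference potential-energy surface (PES), supplied as an angle/energy CSV
(in practice a tabulated quantum-chemical relaxed scan; the quantum
machinery itself is out of scope).

The energy model is the CHARMM periodic form E(φ) = Σ k(1 + cos(nφ − δ)).
Phases are restricted to {0°, 180°}, encoded as signed amplitudes at δ = 0,
which makes fitting **linear**: `fit_dihedral_terms()` solves least squares
in (offset, k₁, …) on cos(nφ) basis functions, reports the RMSE, and can
subtract a molecular background profile first so the terms absorb only
torsional energy. Default multiplicities {1, 2, 3}; the fit refuses grids
with fewer than 2·|multiplicities| + 1 points. On a noiseless
self-generated PES, recovery is exact to numerical precision and the fit is
idempotent.

`relaxed_scan()` reproduces the standard four-step protocol on toy
molecules (harmonic bonds/angles, periodic torsions, 1-4 LJ and Coulomb):
(1) drive the scanned dihedral to a grid value and hold it with a stiff
harmonic restraint (1000 kcal/mol/rad²), (2) minimize everything else, (3)
record the mechanical energy **without** the restraint term, (4) continue
from the relaxed geometry. Numerical choices: BFGS followed by damped
Newton polishing on a numerical Hessian (pseudo-inverse over non-degenerate
modes, so rigid-body null directions are harmless), convergence at
max-gradient 1e-6 kcal/mol/Å with an explicit error naming the failing
angle otherwise; after convergence the scanned dihedral is snapped back to
the exact grid angle before the energy is recorded, which removes the
O(slope/k_restraint) bias the restraint would otherwise leave and makes the
rigid-molecule limit exact. The test suite checks the scan against a
brute-force grid minimization over the free bend angles of a stiff-bond
4-site chain, a regime chosen so the oracle's fixed-bond assumption costs
< 1e-4 kcal/mol while relaxation still moves the profile by ~1 kcal/mol.

`flexibility_range()` reports the width of the contiguous interval around
the PES global minimum with E ≤ threshold, by linear interpolation between
grid points (periodic grids handled by wrapping). The default threshold is
2 kT at 310 K (0.616 kcal/mol); the temperature behind a published "2kT" is
rarely stated, so it is a parameter — a 50-degree-scale range for a
conjugated single bond is the expected order of magnitude.

`assemble_charges()` merges per-fragment RESP-style charge sets (the +1 e
TPP fragment and the neutral PDT-BODIPY fragment): junction atoms take the
fragment mean, the merged total is checked against the declared total
(error beyond 0.01 e), and the residual is spread uniformly so the molecular
charge is restored exactly.

## Oxidation kinetics

Conjugated dienes absorb at 234 nm with molar absorptivity
ε = 27 400 M⁻¹cm⁻¹. `diene_concentration()` inverts Beer–Lambert,
c(t) = (A(t) − A₀)/(ε·l), in µM; the baseline is the first sample (or the
pre-addition mean). `oxidized_fraction()` divides by total CL — per CL
molecule by default, with a `per_chain` switch dividing by the four
linoleoyl chains per CL, since a printed "x % of CL oxidized" does not
disambiguate the two accountings. `rate_segments()` fits ordinary least
squares per inter-addition segment and reports after/before slope ratios,
the antioxidant-inhibition readout (0 = complete inhibition). The bundled
`simulate_oxidation_trace()` emulates the standard assay: 100 µM CL
liposomes, 5-minute sampling, a linear phase of 0.4 µM/min — the rate at
which one fifth of the CL is oxidized over the 50-minute linear window —
and optional additions at 30 minutes. Known spectral caveat handled as
documentation only: a quinone antioxidant with an isosbestic point at
234 nm does not perturb the diene signal, so no correction term exists.

## Reproducibility and the pipeline

`run_pipeline()` drives generator → analyses → report from one validated
YAML config. Per-stage seeds derive from the master seed by a fixed integer
recurrence; the report (JSON) records the package version, an FNV-1a
fingerprint of the config, and the derived seeds, and an identical config
reproduces every artifact byte-identically. Structure I/O: GRO (nm, 3
decimals), PDB (Å, 3 decimals, MODEL per frame, CRYST1 box) and multi-frame
XYZ are written and parsed by the package itself with fixed-column rigour
and line-numbered parse errors; XYZ carries no residue metadata, so reading
it back accepts a topology argument.

Problem sizes used by the tests and the acceptance script — 43 lipids per
leaflet, 60–500 frames per ensemble, 12-point torsion grids, 50-frame
clustering fixtures — were chosen as the smallest sizes at which the
Monte-Carlo error bands in the assertions are comfortably resolved.

## Known limitations

* The generator's square-well affinity produces a first-shell plateau, not
  the peaked RDF of a real liquid; only the location and monotone growth of
  the enrichment are meaningful, not its shape.
* Depth Gaussians are independent per marker; real chains impose
  correlations between the depths of connected sites.
* The toy-molecule engine covers exactly the terms needed for torsion work
  (bonds, angles, torsions, 1-4 pairs); it is not a general force field and
  has no nonbonded machinery beyond 1-4 pairs.
* The kinetics module assumes background-referenced absorbance and constant
  ε; turbidity drift and product absorption are not modelled.
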