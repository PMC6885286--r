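# mitoprobe

Tools for modelling and analysing how a mitochondria-targeted lipid
peroxidation probe behaves in a cardiolipin-rich membrane, and for
quantifying the oxidation kinetics it reports.

The probe in question couples a BODIPY 581/591 fluorophore bearing an
oxidizable phenyl-butadienyl (PDT) tail to a triphenylphosphonium cation
(TPP⁺) through a flexible linker. Whether such a probe is a faithful
cardiolipin (CL) peroxidation sensor is a quantitative question about

* **depth** — the probe's diene must sit at the same bilayer depth as the CL
  dienes/hydroperoxides that oxidize it (density profiles along the normal,
  and their overlap coefficient `Σ min(p̂₁, p̂₂)`);
* **lateral affinity** — the cation should co-localize with anionic CL
  rather than the zwitterionic bulk (dye-aligned lateral occupancy maps at a
  50 %-of-bulk threshold, and the lateral radial distribution function
  `g(r)` between the TPP phosphorus and the CL C2 glycerol carbon);
* **flexibility** — a stiff conjugated tail, a floppy linker (periodic
  dihedral models `E(φ) = Σ k(1 + cos(nφ − δ))` fitted by linear least
  squares to relaxed torsion scans; thermal 2 kT flexibility ranges; GROMOS
  conformer clustering at a 0.3 nm RMSD cutoff);
* **kinetics** — conjugated dienes formed during cytochrome-c-driven
  liposome oxidation, from `A₂₃₄` via Beer–Lambert with
  ε = 27 400 M⁻¹ cm⁻¹, with per-segment rates around antioxidant additions.

Because the reference data for the structural questions are microsecond
all-atom membrane simulations, the package ships a seeded coarse generator
(one particle per marker site, Gaussian depth bands, Metropolis-sampled
dye–CL lateral attraction, 7:21:7:8 PLPC/SLPE/POPC/TLCL composition,
largest-remainder apportionment, all eight mono-hydroperoxy-CL variants)
so that every analysis stage is testable at desk scale. All analyses also
run on structures read from GRO, PDB, or multi-frame XYZ files.

## Worked example

```r
library(mitoprobe)

cfg <- build_bilayer(n_per_leaflet = 43, seed = 1)
cfg$counts
#> PLPC SLPE POPC TLCL
#>    7   21    7    8

trj <- sample_frames(cfg, n_frames = 200, epsilon = 2, r0 = 7, seed = 2)

# depth: TPP in the headgroup band, the oxidizable diene among acyl chains
profile_peak_depth(depth_density_profile(trj, group = "TPP"))        # 18.5 A
profile_peak_depth(depth_density_profile(trj, group = "dye_diene"))  #  8.5 A

# lateral: cardiolipin enriched in the dye's first shell
radial_distribution(trj, "TLCL", bin = 1)
#> rdf_result TPP-P vs TLCL-C2 (lateral): peak g = 4.82 at r = 4.50 A over 200 frames
# ... versus 1.36 for the same seed with epsilon = 0 (no affinity)
```

The 18.5 Å vs 8.5 Å peak depths recover the L-shaped insertion (headgroup
TPP, buried diene); the first-shell g(r) of ~4.8 at ε = 2 kT against ~1.4
at ε = 0 is the lateral cardiolipin enrichment around the cation.

Kinetics, from a bundled synthetic spectrophotometer export (100 µM CL,
antioxidant added at 30 min):

```r
tr <- read_absorbance_csv(
  system.file("extdata/example_absorbance.csv", package = "mitoprobe"),
  system.file("extdata/example_additions.csv", package = "mitoprobe"))
conc <- diene_concentration(tr)                  # uM, Beer-Lambert inverse
rate_segments(tr$time, conc, tr$annotations)$ratios
#>   label time slope_before slope_after      ratio
#> 1  TBHQ   30    0.3995464  0.02109228 0.05279057
oxidized_fraction(conc, 100)[tr$time == 30]      # 0.12 of CL oxidized so far
```

The diene formation rate of ~0.4 µM/min drops 19-fold on antioxidant
addition (ratio 0.053; 0 would be complete inhibition).

Torsion parametrization from a tabulated reference profile:

```r
fit <- fit_dihedral_terms(read_pes(
  system.file("extdata/example_pes.csv", package = "mitoprobe")))
fit
#> dihedral fit (phases fixed at 0 deg; signed amplitudes):
#>   k = +0.350000 kcal/mol  n = 1
#>   k = -2.500000 kcal/mol  n = 2
#>   k = -0.000000 kcal/mol  n = 3
#>   offset 2.850000, RMSE 2.5e-15 kcal/mol
flexibility_range(read_pes(system.file("extdata/example_pes.csv",
                                       package = "mitoprobe")))
#> 58.1   # degrees within 2 kT at 310 K
```

A whole run — generator, depth/overlap/map/RDF/cluster analyses, CSV
artifacts and a seeded, byte-reproducible JSON report — is driven by one
YAML config through `run_pipeline()`, or from a shell via the thin CLI in
`inst/cli/mitoprobe.R` (`run`, `variants`, `version` subcommands).

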