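# icegrowth

Tools for studying ice growth and its inhibition by antifreeze proteins
(AFPs) in molecular simulations.

Insect AFPs adsorb to the prism faces of ice and stop growth below the
melting point. The accepted mechanism is adsorption–inhibition via the
Gibbs–Thomson effect: bound proteins subdivide the growth front into
curved patches, and a surface of curvature radius smaller than the
critical radius

```
R = A_g · M_w · σ · T0 / (L · ρ_i · (T0 − T_r))
```

(`A_g` = 2 spherical / 1 cylindrical, `M_w` molecular weight, `σ`
ice–water interfacial energy, `L` latent heat of fusion, `ρ_i` ice
density, `ΔT = T0 − T_r` supercooling) is in equilibrium with the melt —
growth stalls. This package implements, for simulation studies of that
mechanism:

* **Critical-radius theory** with real-water and TIP4P parameter sets
  (`critical_radius`, `embryo_size`, `compare_gibbs_thomson`);
* **Interface construction**: ice-Iₕ lattices with Bernal–Fowler proton
  disorder (`build_ice_lattice`, `assign_protons`), a prism-face seed
  tilted so that step growth re-enters the periodic box an integer number
  of layers higher (`tilt_seed`, `periodic_consistency`), a constrained
  disordered barrier layer, solvation, and AFP placement over the seed
  (`build_system`, `write_system`);
* **Trajectory analysis**: mobility-based ice/water classification
  (immobile = moved < 0.8 Å over three 100 ps frames), ice fractions and
  equilibration statistics, AFP binding tracks from centre-of-mass
  heights, geometric hydrogen bonds and ordered bridging waters at the
  ice-binding surface, occupancy-averaged front extraction (> 85% water
  occupancy) and cylindrical curvature fits (`classify_ice`,
  `ice_fraction`, `equilibrium_stats`, `track_afp`, `detect_hbonds`,
  `detect_ordered_waters`, `occupancy_map`, `extract_front`,
  `fit_cylinder`);
* **Synthetic trajectories with ground truth** so that every pipeline
  stage is testable without running MD (`generate_growth_trajectory`,
  `generate_binding_track`, `generate_ordered_water_fixture`).

It is aimed at people building or analysing ice/water interface
simulations who need the surrounding computational apparatus — not an MD
engine; the package constructs systems and analyses trajectories produced
elsewhere (multi-frame XYZ dialect, multi-model PDB, DCD + topology).

## Worked example

Critical radii with the two built-in parameter sets:

```r
library(icegrowth)
critical_radius(water_model("real"), supercooling = 1, "spherical")
#> Gibbs-Thomson critical radius (spherical, real water model)
#>   supercooling  1 K
#>   R             5.18e-08 m  (518 Angstrom)
#>   embryo volume 5.83e+08 A^3
#>   molecules     1.8e+07
```

A critical ice embryo at one degree of supercooling holds ~18 million
waters — which is why a specially arranged seeded interface, not direct
nucleation, is the practical simulation route. For the TIP4P water model
at 5 K supercooling the critical *cylindrical* radius (the relevant
geometry for a front pinned between adsorbed AFPs repeating through the
periodic boundary) is:

```r
critical_radius(water_model("tip4p"), supercooling = 5, "cylindrical")
#>   R             4.59e-09 m  (45.9 Angstrom)
```

A synthetic pinned front at exactly that radius, pushed through the full
occupancy → front-extraction → circle-fit pipeline, comes back with the
planted curvature:

```r
scn <- growth_scenario(box = c(12, 80, 60), front = "cylindrical",
                       z0 = 12, radius = 46, pin_spacing = 80,
                       front_noise_sd = 1, n_frames = 60, seed = 5)
g   <- generate_growth_trajectory(scn)
occ <- occupancy_map(g$traj)                      # 1 A voxels, 1.4 A spheres
fit <- fit_cylinder(extract_front(occ, threshold = 0.85, seed_top_z = 1))
fit
#> cylinder fit: radius 46.1 A, centre (y = 40.0, z = -11.6), RMS residual 0.84 A
#>   convex toward liquid: TRUE
compare_gibbs_thomson(fit, water_model("tip4p"), supercooling = 5)
#> Fitted front radius vs Gibbs-Thomson theory
#>   fitted      46.1 A
#>   theoretical 45.9 A (tip4p, cylindrical, dT = 5 K)
#>   ratio       1.003
```

The ratio near 1 is the quantitative statement of the adsorption–
inhibition picture: the steady-state front curvature between pinning
sites matches the Gibbs–Thomson critical radius.

Assembling the full interface system (seed + barrier + solvent + AFP)
and writing it out:

```r
afp <- synthetic_afp_pdb()        # synthetic stand-in; any PDB works
sys <- build_system(box = c(51.5, 126.6, 83.9), afp = afp, seed = 1)
write_system(sys, "interface")    # PDB + constraint CSV + run-settings YAML
```

A thin command-line wrapper is installed under `inst/scripts/icegrowth`
(`gt` and `simulate` subcommands), e.g.
`icegrowth gt --model tip4p --supercooling 5 --geometry cylinder`.

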