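---
title: "Models and methods: ice-growth interfaces and AFP analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods: ice-growth interfaces and AFP analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(icegrowth)
```

# The problem

Antifreeze proteins (AFPs) adsorb to the surfaces of growing ice crystals
and halt growth at temperatures below the melting point, producing thermal
hysteresis. The adsorption--inhibition picture explains this through the
Gibbs--Thomson effect: bound AFPs subdivide the growth front into small
curved patches, and a curved ice surface is only in equilibrium with its
melt at a lower temperature than a flat one. If the curvature forced
between adsorbed proteins exceeds the critical curvature for the ambient
supercooling, the front stops.

This package provides the computational apparatus for studying that
mechanism in molecular simulations of an insect (spruce budworm type) AFP
at an ice/water interface: the critical-radius theory, construction of an
ice-I~h~/water interface system that supports continual step growth under
periodic boundaries, and the trajectory analyses that turn raw coordinates
into the quantities of interest (ice fractions, binding events, ordered
surface waters, time-averaged front shapes). Because the microsecond-scale
molecular dynamics itself requires a cluster and an external MD engine,
everything is validated against a synthetic-trajectory generator with
exact ground truth.

# Gibbs--Thomson critical radius

The equilibrium (critical) radius at supercooling $\Delta T = T_0 - T_r$
is

$$R = \frac{A_g\, M_w\, \sigma\, T_0}{L\, \rho_i\, \Delta T},$$

with $A_g = 2$ for spherical and $1$ for cylindrical geometry, $M_w$ the
molecular weight of water, $\sigma$ the ice--water interfacial energy, $L$
the latent heat of fusion and $\rho_i$ the ice density. Two presets are
built in: experimental water/ice constants ($\sigma = 29.1\times10^{-3}$
J/m^2^, $L = 6.02\times10^{3}$ J/mol, $\rho_i = 917$ kg/m^3^, $T_0 =
273.15$ K) and the TIP4P water model ($\sigma = 23\times10^{-3}$ J/m^2^,
$L = 4.4\times10^{3}$ J/mol, $\rho_i = 944$ kg/m^3^, $T_0 = 230.5$ K).
The grouping of the equation as written above is fixed by requiring that
both built-in parameter sets reproduce their standard worked results
(518 Å for a sphere of real water at 1 K supercooling; 46 Å for a TIP4P
cylinder at 5 K), which resolves any typesetting ambiguity in the source
formula.

```{r}
critical_radius(water_model("real"), supercooling = 1, "spherical")
critical_radius(water_model("tip4p"), supercooling = 5, "cylindrical")
```

The spherical result is the reason direct nucleation simulations are
impractical: an embryo of critical size at 1 K supercooling contains some
$1.8\times10^{7}$ waters. Internally the radius is kept at full
precision; user-facing printing rounds to 3 significant figures, and
comparisons against printed reference values use a 1% relative tolerance
to absorb that rounding. No temperature dependence of $\sigma$ or $L$,
Tolman corrections, or nucleation kinetics are modelled.

# The interface model

## Ice I~h~ lattice and proton disorder

The oxygen sublattice of hexagonal ice is generated from an orthorhombic
cell of dimensions $a \times c \times \sqrt{3}a$ holding 8 molecules
(two 4-molecule hexagonal cells), with the a-axis along x, the c-axis
along y and prism layers stacked along z. Default lattice constants are
the rounded repeats $a = 4.5$ Å and $c = 7.4$ Å; the crystallographic
values (4.497/7.324 Å) can be supplied instead. The block density at the
defaults is 0.92 g/cm^3^.

Protons are assigned by a two-stage Monte Carlo: a random assignment of a
donor to every O--O bond is repaired by defect migration (repeatedly
flipping a bond at an over- or under-donating oxygen) until both
Bernal--Fowler rules hold exactly -- two covalent hydrogens per oxygen, one
proton per hydrogen-bonded pair -- and then directed loops are reversed
(which cannot break the ice rules) until the net dipole per molecule falls
below 0.1 of a single molecular dipole. Exact zero dipole is not sought;
the target is a generic proton-disordered, nearly apolar seed. Bond lists
are image-resolved, so a single periodic unit cell (where one neighbour
pair can be bonded through more than one periodic image) is handled
correctly; this is what makes a brute-force enumeration over all bond
orientations of the 8-molecule cell a usable oracle in the tests.

## Tilted seed, growth step, and y-periodic consistency

The seed slab is cut from the lattice with its prism face tilted by a few
degrees to the long (y) axis of the box, plus an extra partial prism layer
(the growth step). The point of the tilt is that, across the y-periodic
boundary, the prism face reappears an integer number of layers higher:
a step growing across the face re-enters the box one step up, giving
unbounded growth from a finite seed, as with a screw dislocation.

Two geometric facts shape the implementation. First, an arbitrary angle is
not consistent with a fixed box length: the rise across $L_y$ must be an
integer number of prism interlayer spacings $d = \sqrt{3}a/2$. Second, in
ice I~h~ successive prism layers are offset by half a cell along the
a-axis, so exact site-level registry across the boundary needs an *even*
layer offset $n$. The default `"snap"` mode therefore replaces the
requested angle by the nearest commensurate one: it picks the even $n$
closest to the implied rise, chooses the integer count $j$ of c-repeats
with $(j c_\mathrm{eff})^2 + (n d)^2 = L_y^2$, and absorbs the residual
(typically below 1%) into a strain $c_\mathrm{eff}$ of the c repeat. With
the reference box ($L_y = 126.6$ Å) a requested 4.3° snaps to 3.53°
($n = 2$, $j = 17$); the stated 4.3° is not commensurate with a
single-layer rise over that box length, and `mode = "exact"` faithfully
errors beyond a 0.25-layer tolerance. `periodic_consistency()` verifies on
the generated coordinates that translating the seed by one box length
lands every oxygen on an exact lattice site (RMSD below 0.1 Å).

The slab is trimmed in the lattice frame (so its faces are prism planes),
y-trimmed to $[0, L_y)$ -- which partitions lattice sites exactly, leaving
no seam across the y boundary -- and left 2.3 Å short of $L_x$, because
the a-repeat does not divide the reference box width; the small x-seam
keeps the 2.2 Å clash invariant and is irrelevant to growth along y.
Default slab thickness is 8.5 Å, chosen so a paper-scale box yields a
seed count of the observed magnitude (~1700--2200 constrained waters).

## Barrier, solvation, AFP

Below the seed, a 5 Å disordered layer of constrained waters acts as an
ice barrier preventing downward growth. Both the barrier and the free
water are placed by rejection sampling with a hard 2.2 Å oxygen--oxygen
exclusion at a liquid target density of 997 kg/m^3^ (liquid water packs
far below the jamming density of this process, so placement always
terminates; an unreachable density raises an error after a placement
budget). Placement is deterministic under the RNG seed.

The AFP is placed with its centre of mass 20 Å above the topmost seed
oxygen, optionally rotated so the plane of its ice-binding-surface (IBS)
threonine hydroxyl oxygens (residues 7, 23, 39, 54, 69, 84 and 101)
faces the seed with the threonine row along the a-axis. Any user PDB can
be supplied; the package ships no experimental structure. For tests and
examples `synthetic_afp_pdb()` writes a clearly-labelled synthetic
stand-in with the right IBS numbering and geometry. No force-field or
topology assignment is performed, and no MD is run; `write_system()`
encodes restraint flags in the PDB B-factor column, writes a constraint
CSV, and records the intended MD settings in a YAML stub for users who
hand the system to an engine.

# Trajectory analyses

All analyses assume frames captured at a fixed interval (default 100 ps)
and treat the box as periodic in x and y.

**Mobility classification.** A water is ice at frame $t$ if its oxygen
stays within 0.8 Å of its 3-frame mean position over frames
$[t, t+2]$ (200 ps), after unwrapping periodic jumps. The criterion
phrase "moved less than 0.8 Å over three frames" admits two readings;
the deviation-from-window-mean form is the default because it is stable
against single-frame vibrational excursions, and the first-to-last
displacement form is available as `mode = "endpoint"`. Windows overlap
(one per starting frame); labels are undefined for the final two frames.
The classifier is monotone in its threshold, and on synthetic
trajectories at the default amplitudes (ice vibration 0.2 Å SD; liquid
diffusion 0.1 Å^2^/ps, i.e. a 4.5 Å per-frame step) it recovers the
generated labels at or above 99% -- that separability is the acceptance
gate for the generator defaults.

**Ice fraction and equilibration.** The ice fraction is the proportion of
ice-labelled waters above the seed (boundary: the plane through the
topmost constrained seed oxygen, computed once -- the seed is static).
Equilibration over a window is judged by ordinary least squares of
fraction on time: mean ± SD are reported and the window counts as
equilibrated when the slope confidence interval covers zero.

**Binding detection.** The AFP centre-of-mass height is tracked; a
20 ns rolling window is "bound" when its SD is below 1.5 Å *and* its mean
lies within 10 Å of the current front height, and the reported bind time
is the start of the final bound stretch sustained to the end of the
trajectory (so transient arrests followed by detachment do not count).
None of the three thresholds comes from the source study; they were
chosen so that diffusive and pinned synthetic tracks separate cleanly,
and all are exposed as arguments. On 500-frame synthetic tracks the
planted bind time is recovered within one window and never-binding
tracks false-positive below 5%.

**Hydrogen bonds and ordered waters.** The H-bond criterion is the
standard geometric one (donor--acceptor O--O within 3.5 Å,
H--donor--acceptor angle within 30°). Ordered bridging waters are
non-ice waters with at least one bond to an ice-labelled water and one
to an IBS threonine hydroxyl; "fully coordinated" members have two of
each (in the planted fixture geometry: donate one to ice, accept one
from ice, donate one to a threonine, accept one from the adjacent
threonine). The detector reports the member spacing along the a-axis and
each member's distance to the nearest bulk-ice site, since the observed
bridging waters sit at positions distinct from lattice sites.

**Occupancy map and front shape.** Water oxygens are rasterised as
1.4 Å spheres onto a 1 Å voxel grid (a voxel is occupied in a frame when
its cube intersects the sphere -- the usual volumetric-map semantics) and
averaged over frames; the ice front is where occupancy exceeds 0.85.
Front extraction keeps the above-threshold region 3-D-connected to the
seed (26-connectivity, periodic in x and y), which stops isolated
high-occupancy noise from registering and lets internal lattice voids --
real features of ice I~h~ at this resolution -- remain inside the body
without breaking columns. Per-column heights are corrected down by
`r_atom - voxel`: coverage overshoots the outermost oxygen centres by one
rasterisation radius, the discrete top face overshoots by half a voxel
on average, and the topmost site plane sits about half an interlayer
spacing below the nominal boundary (the latter two roughly cancel one
voxel). Columns with no covered voxel are interpolated along y. The
height field retains the corrugation of the discrete lattice termination
(± one layer); the downstream cylinder fit averages over it.

**Curvature comparison.** The cylinder axis is x (the periodic direction
along which adsorbed AFPs repeat), so the fit is a least-squares circle
(Käsa form) to the x-averaged (y, height) profile. A circle is reported
only when it describes the profile clearly better than a straight line
(circle RMS below half the line RMS); otherwise the result is "no finite
curvature", which is a valid verdict, not a failure. On synthetic pinned
fronts of radius 46 Å with 1 Å quenched roughness, the fit recovers
46 ± 3 Å and the ratio to the TIP4P Gibbs--Thomson radius at 5 K is
1.00 ± 0.07.

# The synthetic generator: what it does and does not emulate

`generate_growth_trajectory()` produces waters vibrating about ice-lattice
sites below a front $z(y, t)$ (flat, tilted-advancing, or cylindrical
between pinning sites) and waters diffusing above it, with exact per-water
per-frame labels, plus optional quenched front roughness. Liquid motion is
uncorrelated Gaussian displacement with reflective walls -- there are no
interactions, no momentum, no realistic structure factor, and a freezing
water simply snaps to its site. This suffices for what it is used for:
validating the mobility classifier, occupancy mapping, front extraction
and curvature fitting against known truth. Passing these tests
demonstrates that the pipeline recovers the structures it is designed to
measure; it does not demonstrate anything about real water dynamics, and
the microsecond-scale observables of actual AFP simulations (equilibrated
ice fractions, binding tallies, detachment temperatures) are out of scope
at desk scale -- the pipeline merely ingests such trajectories when
supplied (multi-frame XYZ dialect, multi-model PDB, or DCD with a
topology PDB).

Default scenario sizes used by the test suite were chosen to exercise the
estimators at full fidelity while staying small: classification is checked
on 10^4^ waters over 100 frames; front recovery on a 12 × 80 × 60 Å box
over 60 frames; binding on 500-frame tracks (20 planted, 100 null seeds).

# Numerical and design choices

* Coordinates: x = a-axis, y = c-axis/long axis, z = growth direction;
  half-open box $[0, L)$; minimum-image in periodic dimensions.
* Water placement: rejection sampling, 2.2 Å exclusion, deterministic
  under seed; free-region density within 2% of target by construction.
* Classifier windows overlap; disjoint windows would merely subsample the
  same statistic.
* Degenerate inputs error early and descriptively: non-positive
  supercooling (undefined equilibrium radius), empty analysis regions,
  windows longer than the trajectory, missing hydrogens, empty IBS sets,
  infeasible planted geometry.
* The proton-disorder defect walk has a step budget (2000 steps per
  oxygen) and reports remaining defects on failure; the loop-move stage
  warns if the dipole target is not reached within its budget.
* All stochastic components (proton seed, placement, generators) are
  reproducible bit-for-bit under a fixed seed.

# Known limitations

* The builder produces geometry only -- no force field, minimisation or
  dynamics; restraints are annotations.
* The x-direction of the seed is incommensurate with the reference box
  width (2.3 Å trim seam); growth physics in the model concerns the y
  boundary.
* The synthetic liquid is non-physical by design (see above); H-bond and
  ordered-water analyses on synthetic data are validated on planted
  fixtures, not on realistic liquid structure.
* Front extraction at 1 Å voxels carries half-layer corrugation; radii
  are robust to it, absolute heights are accurate to about one layer.
* DCD reading is a thin wrapper over an external reader and requires a
  matching topology PDB; it is exercised only through that reader's own
  guarantees, as binary fixtures are not distributed with the package.
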