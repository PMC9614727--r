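---
title: "Methods: pressure-driven water permeation and bilayer profiling with poreflux"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: pressure-driven water permeation and bilayer profiling with poreflux}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(poreflux)
```

## The problem

A single water channel — here the bacterial aquaporin AqpZ, carried by a
lipid shell sealed into a solid-state nanopore — conducts water when a
hydrostatic pressure difference $\Delta P$ is applied across the membrane.
Molecular simulations of such systems produce trajectories from which three
families of quantities are extracted:

1. **Transport**: the number of water molecules crossing the channel per unit
   time, the volume flux $J_v$, and from its linear response to $\Delta P$
   the hydraulic permeability $L_P$ and osmotic permeability $P_f$.
2. **Sealing**: the verification that *no* water passes anywhere except
   through the channel (the leakproof contract of the lipid–wall interface).
3. **Structure**: the radial profile of bilayer thickness, axial density
   profiles of water and ions, the axial elongation of the lipid tail chains,
   and the backbone RMSD of the protein.

`poreflux` implements this analysis chain for any trajectory expressed in
its frame model (nm / ns / kJ mol$^{-1}$; orthorhombic boxes; water
represented by its oxygen atom; 1-based particle indices, following R
convention). It also ships a seeded synthetic-trajectory generator with
analytic ground truth, so the entire chain is testable without running a
molecular-dynamics engine.

## The region-based pressure method

Under periodic boundary conditions a pressure difference cannot be imposed
through walls. Instead the water layer is partitioned along $z$ into three
regions, with region III isolated from the two faces of the membrane by
regions I and II. A constant axial force $f$ applied to each of the $n$
water molecules in region III generates

$$\Delta P = \frac{n f}{A} = \frac{f\,d}{v_W},
\qquad n = \frac{A\,d}{v_W}, \qquad \Delta\mu = f\,d = \Delta P\, v_W ,$$

where $A$ is the membrane area, $d$ the thickness of region III, $v_W$ the
average volume of one water molecule, and $\Delta\mu$ the resulting chemical
potential difference of water between regions I and II.

```{r pressure}
# force per molecule for an 80 MPa drop across an 8 nm forced layer
force_for_pressure(80, d = 8)                      # kJ mol^-1 nm^-1
pressure_from_force(0.1813, d = 8, A = 100)        # back to MPa
```

These are exact arithmetic identities and the implementation treats them as
such: `pressure_from_force(f, n, A)` and `pressure_from_force(f, d, v_W, A)`
agree to machine precision, forces are linear in $\Delta P$, and reversing
$f$ reverses $\Delta P$ and $\Delta\mu$ exactly. `apply_scheme()` evaluates
region III membership with half-open intervals $[z_{lo}, z_{hi})$ so the
three regions form a partition with no double counting (boundary handling is
a convention; this one is ours). The module computes forces only — no
dynamics are integrated, which keeps the method's arithmetic separable and
exactly testable. Positional-restraint settings (the spring constants used to
pin a membrane against the net applied force) are carried as configuration
metadata only.

**Defaults.** $v_W = 0.0301\ \mathrm{nm}^3$ (bulk water at 300 K, 1 bar),
configurable; $d = 8$ nm as the reference forced-layer thickness.

## Counting permeation events

`detect_crossings()` runs a per-particle three-state machine
(below / between the planes / above) over an axis-unwrapped trajectory:

* An event requires a **full plane-to-plane traversal**: a particle last
  seen beyond one entry/exit plane next seen beyond the other. Midplane or
  vestibule fluctuations never count.
* Every frame strictly between the planes must be **radially inside** the
  channel; a single excursion beyond the radius voids the event. This strict
  semantics makes the companion `seal_check()` conservative.
* Particles that start between the planes are assigned the side of their
  first exit and complete no event there (a deterministic tie-break).
* Re-crossings are retained individually and cancel in the net count.

A trajectory must be unwrapped along the axis first (`unwrap_axis()`,
minimum-image accumulation); apparent jumps larger than half a box edge are
refused rather than guessed. Two exact symmetries are enforced by tests:
reversing the frame order negates the net count, and the incremental
detector agrees event-for-event with an exhaustive brute-force re-scan.

`seal_check()` reruns the traversal machine over the membrane slab without
the radial requirement and counts traversals whose path was ever radially
*outside* the channel — leaks through the lipid annulus or the lipid–wall
interface. The sealed-membrane contract is a count of exactly zero.

`net_flux()` turns an event list into
$J_W = (N_+ - N_-)/T$ (molecules/ns) and $J_v = J_W v_W / A$ (nm/ns, also
reported in cm/s). Its standard error is block-averaged with 5 blocks by
default. Because 5 block means estimate a standard error with only 4 degrees
of freedom, an alternative `se_method = "counting"`
($\mathrm{Var}(N_+ - N_-) = N_+ + N_-$) is provided; it is exact when
crossing events are independent, which holds for the synthetic generator by
construction and approximately for single-file channel hopping.

## From flux to permeability

The linear transport law $J_v = L_P \Delta P$ has zero intercept — no flux
without a driving force — so `fit_LP()` estimates $L_P$ as the weighted
least-squares slope *through the origin*, with inverse-variance weights when
per-point standard errors are supplied. A free-intercept fit is reported
alongside purely as a linearity diagnostic. The slope error is the
propagated error times the standard scale factor
$\max\!\big(1, \sqrt{\chi^2/(n-1)}\big)$, so understated per-point errors
cannot understate the slope error; a calibration study during development
showed that without this factor, noisy 5-block per-point errors make the
nominal 2-SE interval cover only $\sim$86% instead of $\sim$95%.

An impermeable-solute concentration difference drives the same flux as
$\Delta P = R T \Delta C$, hence hydraulic and osmotic permeability are
related by a constant factor:

$$P_f = L_P\,\frac{R\,T}{V_W},$$

with $V_W$ the molar volume of water (default 18.07 cm$^3$ mol$^{-1}$,
configurable — reported single-channel permeabilities are sensitive to this
convention at the $\sim$10% level). Units mirror the conventions of the
permeation literature: $L_P$ in cm$^5$ N$^{-1}$ s$^{-1}$
($=10^{-10}$ m$^3$ Pa$^{-1}$ s$^{-1}$, a per-channel volume flow per
pressure) and $P_f$ in cm$^3$ s$^{-1}$.

```{r pf}
Pf_from_LP(7.3e-18, T = 300)            # cm^3/s
pressure_concentration_equiv(delta_P = 10)
```

## Structure profiles

* `radial_thickness()` — cylindrical transform of the lipid C2 markers (the
  carbon separating the hydrophilic head from the two hydrophobic tails; the
  marker atom name is configurable because force fields differ), pooled over
  frames and molecules into radial bins: mean axial position per leaflet and
  local thickness $h(\rho)$. Empty bins are flagged, never zero-filled.
* `axial_density()` — per-bin number density $\langle n \rangle/(A\,\Delta z)$
  or mass density (g cm$^{-3}$); the number-density profile satisfies
  $\sum_b \rho_b A \Delta z = $ mean selected count per frame to machine
  precision.
* `chain_elongation()` — $|z_\mathrm{last} - z_\mathrm{first}|$ per tail
  chain per frame, binned by the lipid's C2 radial position. Axial
  elongation is the quantitative proxy for the gauche-to-all-trans
  conformational transition of the tails near a hydrophobic pore wall;
  dihedral statistics are deliberately out of scope.
* `backbone_rmsd()` — Cartesian RMSD against a reference frame, optionally
  after optimal rigid-body (Kabsch) superposition via `bio3d::fit.xyz`; the
  RMSD arithmetic itself is computed at full precision in this package.

Profiles can be recentred per frame on a reference selection (e.g. the
protein backbone centroid), making them invariant under rigid axial
translation of the whole system. Default bins: 0.25 nm radially over
$[0, \rho_\mathrm{max}]$, 0.1 nm axially — fine enough to resolve the
thickness gradient and the exclusion-zone edges at fixture scale.

**Uncertainties.** Profile standard errors are block-decorrelated over
frames (5 blocks) by default. `radial_thickness()` additionally offers
`se_method = "iid"` (per-sample scatter), which is the calibrated choice
when frames are independent — true for the synthetic shell, not for real
trajectories.

## What the synthetic generator does and does not emulate

`synthetic_spec()` fixes the study conditions; the generators are seeded and
bit-reproducible, and every draw records its ground truth.

* `gen_channel_trajectory()` schedules crossings as two Poisson processes —
  forward at $\lambda_0 + g\,\Delta P$, backward at $\lambda_0$ — so the
  expected net rate is **exactly** $g\,\Delta P$ (rejection-free event
  scheduling; ground truth is analytic, not simulated). Scheduled events are
  rendered as smooth plane-to-plane paths radially inside the channel;
  reservoir and annulus waters jitter in bands that never touch the planes,
  so the membrane is sealed except for explicitly planted leak paths.
* `gen_lipid_shell()` imposes
  $h(\rho) = h_\mathrm{bio} + \Delta h\,(\rho/\rho_\mathrm{max})^k$ on the
  leaflet C2 markers (axial Gaussian jitter only, so radial binning is exact
  and the per-bin recovery is unbiased) and a linearly increasing tail
  elongation.
* `gen_density_system()` samples particles from a piecewise axial density —
  zero for $|z| \le 1$ nm, linear ramp to $|z| = 4$ nm, bulk beyond — for
  water and, in the saline variant, ions at a bulk number fraction of
  $\approx 0.022$ (the $\sim$3.5 wt% salinity of seawater).

**Chosen conditions.** Five pressures 10, 25, 50, 75, 100 MPa; crossing-rate
coefficient $g = 0.0243$ events ns$^{-1}$ MPa$^{-1}$, i.e. $L_P/v_W$ for a
channel of hydraulic permeability $7.3\times10^{-18}$ cm$^5$ N$^{-1}$
s$^{-1}$, so the synthetic channel has the permeability measured for AqpZ in
this class of system; channel radius 1 nm with entry/exit planes at
$z=\mp2$ nm (a 4 nm slab); $h_\mathrm{bio} = 2.5$ nm, $\Delta h = 1.5$ nm,
$k = 2$ over a pore of radius 4 nm. Values that no study states were chosen
once at desk scale and not revisited: 20 ns per pressure with a 20 ps output
stride (enough for tens-to-hundreds of events at the upper pressures), an
equilibrium bidirectional hop rate $\lambda_0 = 0.5$ ns$^{-1}$ (real
aquaporin equilibrium hopping is several per ns, but at these shortened
durations a full-rate baseline would drown the net signal at 10 MPa; the
reduced rate preserves the signal-to-noise *structure* of a flux
measurement, not its absolute cost), and a 1 ns traversal time.

**What passing tests show — and don't.** The generator reproduces the
statistical structure the analyses assume (Poisson crossing counts linear in
$\Delta P$, a sealed annulus, an imposed thickness law, piecewise densities,
rigid-body motions). It does not emulate atomistic water structure,
single-file correlations inside the channel, protein flexibility, membrane
undulations, or frame-to-frame correlation of marker positions. Passing the
end-to-end tests therefore validates the *analysis chain* — counting,
unwrapping, binning, fitting, unit handling — not any force field or
sampling protocol.

## Numerical choices and degenerate inputs

* Internal units nm / ns / kJ mol$^{-1}$; permeabilities additionally in
  cm$^5$ N$^{-1}$ s$^{-1}$ and cm$^3$ s$^{-1}$; $R = 8.314462618$ J
  mol$^{-1}$ K$^{-1}$.
* Region membership and bin intervals are half-open; `findInterval`-style
  binning with the rightmost edge closed.
* Zero-duration flux, nonpositive $d$, $v_W$, $A$, $T$, $V_W$, fewer than
  two distinct pressures, mismatched selection sizes, empty leaflet
  selections: domain errors. Empty region III occupancy: a warning
  (pressure undefined that frame), not an error. Empty water selections:
  zero flux / zero leaks / all-zero density, silently.
* Trajectories with wrapped axial jumps are refused with a pointer to
  `unwrap_axis()`; an apparent displacement of exactly half a box edge is
  ambiguous and raises an error advising a denser output stride.
* Triclinic boxes are rejected everywhere (slab systems in rectangular
  boxes are the target geometry).
* XTC input is not supported (no R reader is available); CSV/XYZ text
  dialects and DCD (via `bio3d`) are.

## Problem sizes used in the shipped tests

The test suite and the acceptance script regenerate everything at desk
scale: 50 replicates $\times$ 5 pressures $\times$ 20 ns (about 1000 frames
and 100–200 particles per trajectory) for the permeability recovery; 20
seeds $\times$ 1000 random-walk particles for the detector/oracle
equivalence; 120–240 lipids over 50 frames for the thickness law; a few
thousand particles per frame for densities. These sizes were chosen so the
statistical assertions have comfortable power while the whole suite runs in
about a minute.

## Known limitations

* Only the $+z$ channel axis is supported; tilt a system before analysis.
* The crossing detector assumes planes fixed in the (unwrapped) axial
  coordinate; systems drifting by multiple box lengths should be recentred
  (or analysed with a `center` selection for the profile functions).
* `seal_check()` classifies a traversal as a leak if *any* between-plane
  frame lies radially outside the channel; a genuine channel crossing with a
  momentary radial excursion would be counted conservatively as a leak.
* Flux standard errors from 5 blocks are noisy (4 degrees of freedom); for
  fits across pressures the scale-factor correction in `fit_LP()` absorbs
  most of the resulting miscalibration, but longer trajectories or the
  counting SE are preferable when applicable.
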