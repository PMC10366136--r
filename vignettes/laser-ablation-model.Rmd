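---
title: "Modelling laser coagulation and vaporization with dynamic optics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling laser coagulation and vaporization with dynamic optics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The physical problem

Continuous-wave laser ablation denatures and removes soft tissue through two
photothermal effects: *coagulation* (protein denaturation, visible as
whitening, beginning around 60 °C) and *vaporization* (boiling off of tissue
water at 100 °C, which excavates a crater). Both depend on where in the
tissue the light is absorbed — and that, in turn, changes as the tissue
coagulates, because denatured tissue scatters light several-fold more
strongly than native tissue. A predictive simulation therefore has to close
the loop: light transport → heating → damage → *changed optics* → light
transport. `ablatesim` implements that loop for a collimated Gaussian beam
scanned across a voxelized air/tissue slab.

## Model components

### Damage kinetics and dynamic optics

Irreversible thermal damage is tracked per voxel by the Arrhenius integral

$$\Omega(\mathbf r, t) = A \int_0^t
  \exp\!\left\{-\frac{E_a}{R\,T(\mathbf r, t')}\right\} dt',$$

with the damaged volume fraction $\alpha = 1 - e^{-\Omega}$; $\Omega = 1$
($\alpha = 63\,\%$) is the conventional coagulation threshold, and
$\Omega = 5$ ($\alpha = 99\,\%$) is treated as complete coagulation. Note the
sign of the exponent: damage must *accelerate* with temperature, which is
the standard Henriques form used here. The dynamic optical properties (DOP)
rule linearly mixes native and fully coagulated reduced scattering by
volume fraction,

$$\mu_s'(\alpha) = (1 - \alpha)\,\mu_{s,\mathrm{native}}' +
  \alpha\,\mu_{s,\mathrm{coagulated}}',$$

while $\mu_a$ is held at its native value: at 980 nm the absorption change on
coagulation is small (of order $0.07 \to 0.06\ \mathrm{mm^{-1}}$, which
deepens the optical penetration depth
$\delta = 1/\sqrt{3\mu_a(\mu_a + \mu_s')}$ by only ~8 %) whereas scattering
rises by a factor of ~2.65.

### Light transport

`compute_absorption()` traces photon packets through the voxel lattice:
free paths sampled from the local $\mu_t = \mu_a + \mu_s$, a weight fraction
$\mu_a/\mu_t$ deposited at each interaction, Henyey–Greenstein deflection
with $g = 0.9$, and stochastic unpolarized Fresnel reflection/refraction at
every voxel face where the refractive index changes (the air–tissue surface,
and crater walls once voxels have been removed). The scattering coefficient
is obtained from the similarity relation $\mu_s = \mu_s'/(1-g)$ since the
DOP rule is stated in terms of $\mu_s'$. The tissue index is fixed at 1.44
throughout heating; vaporized voxels revert to $n = 1$.

Packets below weight $10^{-4}$ play Russian roulette (survival probability
0.1, survivors reweighted ×10), which is unbiased in expectation. Because a
stochastic kill/promote step cannot conserve weight *within* a single run,
the kernel tallies the weight roulette creates and destroys; the reported
balance

$$\mathrm{absorbed} + \mathrm{escaped} + \mathrm{specular} =
  \mathrm{launched} + \mathrm{gain} - \mathrm{loss}$$

closes to floating-point precision on every run, and the net roulette term
is zero in expectation. Tests assert both facts.

### Heat transport and phase change

The thermal solver evolves volumetric enthalpy rather than temperature so
the latent-heat plateau of boiling is captured without front tracking:

$$\frac{\partial H}{\partial t} = k\,\nabla^2 T + S, \qquad
T = \begin{cases} H/(\rho c_p) & H < \rho c_p T_v\\
T_v & \rho c_p T_v \le H \le \rho(c_p T_v + L_v)\end{cases}$$

integrated by explicit forward differences with a 7-point Laplacian,
harmonic-mean face conductivity between dissimilar materials (the standard
conservative choice; flux symmetry makes total enthalpy exactly conserved
under the adiabatic boundaries), and the FTCS stability bound
$\Delta t \le \rho c_p \Delta x^2 / (6k)$ enforced at run time. At the
plateau onset $H = \rho c_p T_v$ the two branches agree, so the boundary
case is resolved by continuity. When a voxel's enthalpy reaches

$$H_\mathrm{th} = \rho\,(c_p T_v + L_v)$$

(inclusive comparison, so ties break deterministically) it is removed: its
optics and conductivity become those of air, its enthalpy leaves the system
with the vapor (the new air voxel restarts at the local pre-removal
temperature with air's heat capacity), and its damage state is frozen.
Removal is irreversible. Air conducts with its own constants; convection
and radiation are not modelled.

### The coupling loop

Optics change on the timescale of damage accumulation (seconds), far slower
than heat diffusion across a voxel, so transport is refreshed only every
$t_\mathrm{heat}$ (default 2 ms at 0.1 mm voxels) while the enthalpy/damage
fields advance every $\Delta t$ (default 10 µs). Within each window the
beam is treated as stationary at its window-start position — over one
window the beam moves at most a few µm, far below the voxel size. Window
iteration follows the non-strict bound "continue while
$j\,t_\mathrm{heat} \le t_\mathrm{on}$", so when the scan time is an exact
multiple of the window one extra window is irradiated; the over-delivery is
$t_\mathrm{heat}/t_\mathrm{on} \lesssim 10^{-4}$ of the dose in the
reference settings. After the laser stops, diffusion and damage continue
for $t_\mathrm{laser,off}$: residual heat keeps coagulating tissue well
after irradiation, which the tests verify. Each transport call draws its
own RNG stream seeded from `(seed + 10007 * j) mod (2^31 - 1)`, making runs
bit-reproducible regardless of how windows are executed.

## Parameters and defaults

| parameter | default | units | meaning |
|---|---|---|---|
| $\mu_a$ | 0.07 | 1/mm | tissue absorption at 980 nm |
| $\mu_{s,\mathrm{native}}'$ | 1.0 | 1/mm | native reduced scattering |
| $\mu_{s,\mathrm{coagulated}}'$ | 2.65 | 1/mm | after full coagulation (2.65× native) |
| $g$ | 0.9 | – | scattering anisotropy |
| $n$ | 1.44 | – | tissue refractive index |
| $k$ | 5.1e-4 | W/(mm·K) | conductivity (≈ water) |
| $\rho c_p$ | 3.6e-3 | J/(mm³·K) | volumetric heat capacity (≈ water) |
| $T_v$, $L_v$ | 100, 2257 | °C, J/g | boiling point / latent heat of water |
| $A$, $E_a$ | 7.39e39, 2.577e5 | 1/s, J/mol | Arrhenius kinetics (liver-like) |

All values live in one internal unit system (mm, g, s, J, °C) to avoid the
silent factor-of-ten errors that mixing 1/mm optics with W/(cm·K)
conduction invites; `read_scenario()` converts configs quoted in the usual
literature units. The optical anchors ($\mu_a$, the 2.65× coagulation
factor, $g$, $n$) are values reported for porcine liver at 980 nm; the
thermal and kinetic constants are literature-style placeholders — they are
deliberately *configuration inputs*, not built-in truths, and should be
replaced when modelling a specific tissue. The helper
`bath_time_for_omega()` inverts the kinetics at constant temperature,
$t = \Omega\,e^{E_a/RT_K}/A$ — the design rule for preparing
bath-coagulated calibration samples at prescribed $\Omega$ (hotter baths
need exponentially less time).

## Scenarios and the scaled twins

`make_reference_scenarios()` builds the six reference irradiations — 50 W at
0.5/0.75/1.0 mm/s (coagulation *and* vaporization) and 10 W at
1.0/1.25/1.5 mm/s (coagulation only) — on the full 300 × 300 × 150 lattice
of 0.1 mm voxels with a 20 mm scan and $10^7$ packets per transport call.
Those runs are hours-scale; for routine testing each scenario has a
desk-scale twin on a 48 × 40 × 28 lattice of 0.25 mm voxels (12 × 10 mm
laterally, 1 mm air over 6 mm tissue) with a 4 mm scan, 4000 packets per
call, $\Delta t = 0.4$ ms and $t_\mathrm{heat} = 50$ ms. The twins keep the
*local* physics of the full problem — same power, speed, beam diameter and
material constants, hence the same fluence and dwell time under the beam —
and complete in tens of seconds each.

Scaling choices worth knowing about:

* The stable $\Delta t$ is limited by **air**, whose thermal diffusivity is
  ~150× tissue's; 0.25 mm voxels relax that bound to ~0.48 ms. Coarser
  voxels are the price of a tractable step count; the crater (~1–3 mm) is
  still resolved by 5–12 voxels.
* The twins cannot preserve every dimensionless group at once once the
  pitch changes: tissue optical depth per mm is preserved exactly, the
  thermal window number $k\,t_\mathrm{heat}/(\rho c_p \Delta x^2)$ is not.
  Both are recorded in `scenario$groups` and the stability ratio is
  asserted at construction.
* Cooling times are shortened (6 s / 3 s versus 30 s / 10 s) — enough for
  the peak temperature to relax and post-irradiation coagulation to appear.
* At the slowest high-power speed the coagulation front can reach the
  twin's bottom boundary, where the adiabatic wall slightly inflates the
  lesion. The twins therefore support *qualitative* contrasts (regime map,
  DOP-versus-static signs, speed trends), not absolute lesion dimensions —
  which is exactly how the test suite uses them. Full-scale lesion sizes
  require the full-scale scenarios.

What the twins *do* reproduce, deterministically per seed and consistently
across seeds: 10 W produces coagulation without any vaporization; 50 W
produces both; switching the DOP update off (static native optics,
`dop = FALSE`) lets light diffuse deeper, which grows the coagulation
region and starves the crater — so with DOP the vaporized area is larger
and the coagulated area smaller; and all lesion metrics fall with
increasing scan speed.

## Numerical choices and edge cases

* **Albedo weighting, not analog absorption**: deposition of $w\mu_a/\mu_t$
  per interaction is unbiased with far lower variance; a pure absorber
  ($\mu_s = 0$) deposits its whole weight at the first interaction, which
  makes the Beer–Lambert check exact in distribution.
* **Specular accounting**: a packet that escapes without ever scattering but
  after at least one Fresnel reflection is tallied as specular
  (≈ 3.25 % at normal incidence on $n = 1.44$); everything else that leaves
  the lattice is "escaped". Lattice boundaries are open.
* **Beam footprint checks**: a beam axis entirely outside the lattice
  produces a warning and a zero field rather than an error, since a scan
  may legitimately start outside a cropped region of interest.
* **Damage-rate cutoff**: the Arrhenius exponential is skipped below 42 °C,
  where the liver-like rate is < 1e-3 s⁻¹ — numerically negligible against
  the $\Omega = 1$ contour over any simulated duration, but a large saving
  since most of the lattice sits near room temperature. `step_enthalpy()`
  exposes the cutoff (`omega_T_min = -Inf` evaluates everywhere).
* **Degenerate beams**: `diameter_1e2 → 0` collapses to a pencil beam, used
  by the analytic transport tests.
* **Mid-window overshoot**: enthalpy may pass $H_\mathrm{th}$ between
  removal checks; the temperature stays clamped at $T_v$ until the
  window-end removal, and the user-facing `enthalpy_to_temperature()`
  treats above-threshold enthalpy on a present voxel as an internal
  consistency error.

## What the tests do and do not show

The suite validates each component against an independent route: the
Beer–Lambert closed form and a continuous-space slab Monte Carlo oracle for
transport; exact conservation, the 3D Gaussian heat kernel (pointwise
within 2 % after diffusing ~7 voxel lengths) and the maximum principle for
the solver; closed-form constant-temperature kinetics for damage; and
brute-force mask scans for the lesion metrics. End-to-end, the scaled twins
reproduce the qualitative regime map and the directional effect of the DOP
feedback. None of this certifies absolute accuracy on real tissue: blood
perfusion, carbonization, temperature-dependent thermal properties,
wavelength-dependent $\mu_a$ dynamics and inter-sample variability are all
outside the model, and the shipped thermal/kinetic constants are
placeholders to be replaced by measured values for the tissue at hand.
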