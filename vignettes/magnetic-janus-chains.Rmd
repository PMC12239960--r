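---
title: "Simulating magnetic Janus microrobot chains: model, units and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating magnetic Janus microrobot chains}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The system and the model

`janusim` simulates sub-millimeter Janus microrobots: hydrogel spheres whose
lower spherical cap is loaded with sedimented NdFeB microparticles and
permanently magnetized. Each robot is described by its geometric center
$\mathbf r_c$, a unit symmetry axis $\mathbf u$ pointing from the magnetic
cap toward the hydrogel pole, and a unit dipole direction
$\hat{\boldsymbol\mu} \perp \mathbf u$. The cap's excess mass and the
permanent dipole both live at the cap centroid
$\mathbf r_m = \mathbf r_c - s\,\mathbf u$, with
$s = 3R(1-h)^2/(3-2h)$ the exact centroid of a spherical cap of height
$h\sigma$ ($\sigma = 2R$ the diameter, $h$ the cap fraction of the
diameter). This anisotropic construction is what produces the
characteristic behaviors: upright resting (cap-down pendulum), staggered
"zigzag" chains, and gait-dependent locomotion under programmed fields.

The forces are:

* **Excluded volume** between centers: the purely repulsive
  Weeks–Chandler–Andersen potential,
  $U_\mathrm{WCA}(r) = 4\varepsilon[(\sigma/r)^{12} - (\sigma/r)^6] +
  \varepsilon$ for $r < 2^{1/6}\sigma$, zero beyond. The $+\varepsilon$
  shift makes potential and force vanish continuously at the cutoff (a
  $-\varepsilon$ shift would leave a $2\varepsilon$ jump).
* **Dipole–dipole** interactions between the cap points:
  $U = \varepsilon\,[\,\mathbf m_i\cdot\mathbf m_j/r^3 -
  3(\mathbf m_i\cdot\hat{\mathbf r})(\mathbf m_j\cdot\hat{\mathbf r})/r^3\,]$
  in reduced units, with forces applied at $\mathbf r_m$ and the resulting
  lever-arm torque $(\mathbf r_m-\mathbf r_c)\times\mathbf F$ included
  about the center, so the two reference points are mechanically
  consistent.
* **Field coupling**: Zeeman energy $-\boldsymbol\mu\cdot\mathbf B$, i.e.
  torque $\boldsymbol\mu\times\mathbf B$ and no net force in the (spatially
  uniform) programmed fields. The sign is chosen so dipoles align *with*
  the field; the opposite sign would anti-align them and contradicts every
  observed behavior.
* **Gravity and buoyancy**, split into a center load
  $-(\rho_\mathrm{gel}-\rho_\mathrm{w})V_\mathrm{sphere}\,g\,\hat z$ at
  $\mathbf r_c$ and a cap load
  $-(\rho_\mathrm{mag}-\rho_\mathrm{gel})V_\mathrm{cap}\,g\,\hat z$ at
  $\mathbf r_m$; the two sum exactly to the net buoyant weight, and the cap
  load's torque rights the particle cap-down.
* **Walls** (floor, stairs, inclines, channels, obstacles): planar
  rectangles with closest-feature contact. The normal response is a
  WCA-type repulsion evaluated on $d + \sigma/2$, where $d$ is the
  center-to-surface distance — the interaction with a virtual particle
  half-embedded in the wall. This choice gives surface contact near zero
  gap *and* exactly the particle–particle contact stiffness; a
  half-diameter-width wall potential measured from the center has four
  times that stiffness and is unstable in the explicit-Euler scheme at the
  reference timestep.
* **Coulomb stick–slip friction** for particles that are part of a chain
  (at least one neighbor within the 1.1 $\sigma$ bond cutoff):
  $\lambda_s = 0.5$, $\lambda_d = 0.4$. In overdamped dynamics the
  tangential velocity is proportional to the tangential force, so sticking
  is detected on the force itself: if it does not exceed $\lambda_s N$ the
  contact sticks (friction cancels it exactly), otherwise kinetic friction
  $\lambda_d N$ opposes the slide. Yaw about the contact normal is
  resisted analogously with lever arm $\sigma/2$. Single particles roll
  rather than slide and get no friction at all.

The equations of motion are overdamped (non-thermal, first order):
$\gamma\,\dot{\mathbf r}_c = \sum\mathbf F$ and
$\gamma_r\,\boldsymbol\omega = \sum\mathbf T$, advanced by explicit Euler;
the body frame $(\mathbf u, \hat{\boldsymbol\mu})$ is rotated rigidly by
the exponential map of $\boldsymbol\omega\,\Delta t$ and re-orthonormalized
every step. An inertial reading of the rotational equation ("$\gamma_r
\dot\omega$") would contradict the first-order translational equation and
the non-thermal Brownian framing, so the overdamped reading is
implemented. There is no thermal noise; seeds only affect initial
placements, and runs are bitwise reproducible.

# Reduced units

Quantities are nondimensionalized by an energy unit
$\varepsilon = 4.0694\times10^{-10}$ J, a length unit $\sigma$ (the
particle diameter, reference $600\ \mu$m) and a time unit
$\tau = 1/60$ s. The translational drag is $\gamma = 0.3$ in units of
$\varepsilon\tau/\sigma^2$ — equivalently $5.65\times10^{-6}$ kg/s — and
the rotational drag is $\gamma_r = \gamma/3$ (the $\gamma\sigma^3/3$
convention; with $\sigma = 1$ both dimensional readings of the printed
form give 0.1). Magnetic moments are scaled so the reduced pair potential
carries the physical $\mu_0/4\pi$ prefactor:
$m^* = \mu\sqrt{\mu_0/(4\pi\varepsilon\sigma^3)}$, giving $m^* \approx
1.15$ for the measured $\mu = 1.08\times10^{-6}$ A m². Fields scale as
$B^* = B\sqrt{4\pi\sigma^3/(\mu_0\varepsilon)}$ so that
$\varepsilon\,m^*B^* = \mu B$ exactly.

# Key parameters and defaults

| parameter | default | why |
|---|---|---|
| cap fraction $h$ | 0.33 | reproduces the reference particle mass (0.314 mg) and net buoyant weight (1.97 μN) with the stated densities; 0.32 gives 0.304 mg / 1.87 μN |
| densities | 1.0 / 1.12 / 7.6 g/ml | water, PEGDA hydrogel, NdFeB cap |
| dipole $\mu$ | $1.08\times10^{-6}$ A m² | measured moment of a fabricated robot; the remanent-magnetization value $0.87\times10^{-6}$ is available as the `"remanent"` preset |
| diameter | 600 μm | the size paired with the printed mass/force estimates; `fabricated_particle()` builds the 575 μm / 0.5 mm robots with the dipole scaled by particle volume at fixed ferromagnetic loading |
| $\Delta t$ | $10^{-3}\tau$ | reference step; contact stiffness at the bond equilibrium gives an Euler amplification factor comfortably below 1 |
| bond cutoff | 1.1 σ | just outside the dipole/WCA bond equilibrium (≈1.04–1.06 σ); used for both chain detection and the in-chain friction flag |
| stick threshold | — | stick/slip is decided on the tangential force against $\lambda_s N$ directly (the overdamped analogue of a velocity threshold), which cannot chatter |

# Regularizing the offset point dipoles

The dipole points sit $s \approx 0.29\sigma$ inside each sphere. Two
tumbling particles can bring their cap points to $\approx 0.4\sigma$
separation while their centers still satisfy the excluded-volume contact;
the point-dipole force then grows as $1/r^4$ faster than the center
repulsion can balance, and the pair collapses — a divergence of the point
approximation, not of the physics, since a distributed cap magnetization
gives a large but finite contact force. The kernel distance is therefore
saturated below $r_\mathrm{sat} = 0.85\sigma$ (magnitudes frozen,
directions kept), and for strong moments the saturation radius widens so
the contact force never exceeds $f_\mathrm{dip,max} = 25\,\varepsilon/\sigma$
— the largest force the excluded-volume contact can balance while the
explicit-Euler step remains stable at $\Delta t = 10^{-3}\tau$. Both knobs
are exposed in `simulation_config()`. Consequences worth knowing:

* bonded pairs and chains are unaffected in ordinary configurations
  (bond distances sit near 1.05 σ, outside the saturation radius);
* force–gradient consistency holds outside the saturation radius (and is
  tested there);
* for large cap fractions the widened radius flattens the short-range
  gain from tilting caps together, so the increase of the dimer offset
  angle with $h$ is reproduced only weakly.

# Field programs

`field_static()`, `field_rotating()`, `field_oscillating()` (sinusoidal
sweep between two angular bounds — the sweep waveform is not dictated by
the actuation hardware description, and the sinusoid keeps torques smooth
at the reference timestep), `field_conical()` and `field_schedule()`
compose every protocol. Presets carry the documented working points:
walking (4 mT rotating in yz at 1 Hz), crawling (6 mT, 3 Hz, sweep
$-2\pi/3$ to $\pi/3$), swinging (6 mT, 2 Hz, full $\pm\pi$ sweep with the
plane tilted $-30^\circ$), lateral (6 mT, 3 Hz, $\pm\pi/3$ with a
$6^\circ$ pitch), a precessing assembly field (6 mT, 32 Hz, cone
half-angle $80^\circ$ about vertical — near-horizontal precession
synchronizes upright spinning; the exact cone parameters are not printed
anywhere, so this is a package choice), and the 20 Hz disassembly field.

# What the scenarios demonstrate — and what they do not

The scenario registry reproduces the figure-level experiments at desk
scale. The important honest findings from building them:

**Scale matters for the gaits.** The walking tumble requires the
per-particle lift force ($\sim 3m^{*2}\sin 2\delta / r^4$) to beat the
buoyant weight. For the 600 μm robot with the measured moment this ratio
is ≈1.1 (marginal, stick–slip walking); for the 0.5-mm fabricated robot
with the volume-scaled moment it is ≈1.7 and the dimer walks a clean
end-over-end tumble at $v = 2\sigma f$ — 10.4 mm/s at 10 Hz for the 1-mm
body, against the recorded 9.85 mm/s. Gait and terrain scenarios therefore
use `fabricated_particle()`.

**Long chains do not tumble rigidly in this force set.** Rigid end-over-end
rotation of an $N$-chain needs the field torque, transmitted through the
bonds, to beat a gravitational lift torque that grows as $N^2$, while the
bond orientation stiffness ($\sim 2m^{*2}/r^3 \approx 3\varepsilon$) is
several times smaller than the field coupling
($m^*B^* \approx 10\varepsilon$ at 4 mT). Individual dipoles follow the
field, bonds pass through repulsive phases, and chains of $N \ge 4$ move
by a slower stretch–recollect crawl, shedding and re-absorbing dimers.
This is why the staircase scenario uses risers scaled to the dimer
(0.4 mm, below the body length; 0.5 mm defeats it) rather than the
published 2-mm staircase climbed by long experimental chains, and why the
reassembled population cycles between full connectivity and partial
fragmentation under the 1 Hz rotating field (the reassembly metric reports
the maximum efficiency attained, which does reach 1.0).

**Planar symmetry.** The walking tumble stays in the yz plane only for a
transversely symmetric initial chain; transverse jitter of even
0.02 σ develops the in-plane zigzag offset, after which a dimer approaches
a riser diagonally and stalls against it. Terrain scenarios use the
symmetric reference configuration; treat stair climbing as a demonstration
of the geometric property (ascent requires chain length above the riser),
not as robust to arbitrary perturbation.

**Cap-fraction window.** Sweeping $h$ with the moment scaled by cap volume
reproduces the low-$h$ failure of dimerization cleanly (at $h = 0.05$ the
moment is ~3% of the reference and the pair never reaches contact). The
high-$h$ failure ("cap too heavy to flip") is *not* reproduced: the
righting torque scales as $s\,G_m \propto (1-h)^2 h^2$ and vanishes as
$h \to 1$, so nothing in the implemented force set prevents pairing at
$h = 0.95$. The corresponding assertion is kept in the acceptance suite
and fails, documenting the model boundary.

**Other known limitations.** Drag is linear and isotropic (no
hydrodynamic interactions, no wall lubrication), so gaits that lean on
drag anisotropy are weak: crawling advances at ~0.1 mm/s rather than
mm/s, and the lateral drift is sub-mm/s. The incline scenario ascends at
20° and loses grip by 30° (experimentally up to 35°). The chain-to-ring
reversal protocol mostly makes the body-fixed dipoles rotate in place
instead of curling the chain, so the ring transformation is shipped as a
protocol demonstration without an assertion. Thermal noise is absent by
construction; nothing here speaks to Brownian effects at smaller scales.

# Numerical choices

* Explicit Euler at $\Delta t = 10^{-3}\tau$ (default). Stability of a
  contact is $\Delta t \cdot k/\gamma < 2$ with $k$ the contact stiffness;
  the bond equilibrium sits at $k \approx 300\text{–}500$, hence the force
  bound above. The channel scenario, whose lateral sweep presses chain
  ends hard into walls, runs at $\Delta t = 2.5\times10^{-4}\tau$.
* A displacement of more than $0.5\sigma$ in one step aborts with a
  "timestep too large" diagnostic; a center closer than $0.05\sigma$ to a
  wall surface aborts as a penetration guard. Walls are thin and
  two-sided: the repulsion acts along the closest-feature direction on
  either side, which also makes convex corners continuous except at the
  corner point itself.
* Orientation drift is controlled by re-orthonormalizing
  $(\mathbf u, \hat{\boldsymbol\mu})$ each step; unit norms and
  orthogonality hold to $10^{-9}$ over $10^6$ steps.
* Chain ordering in `detect_chains()` projects onto the component's
  principal axis and breaks ties by particle id, so partitions are
  deterministic and permutation-invariant.
* Mean gait speeds are net centroid displacement over a whole number of
  field periods after a two-period transient (the averaging window is not
  dictated by anything; whole periods remove the within-cycle wobble).

# Problem sizes used by the tests

The suite runs two- to eight-particle scenarios of 0.5–20 s simulated
time (up to $1.2\times10^6$ integrator steps per case), 200-configuration
randomized oracles for chain detection, and dense-grid closest-point
oracles for wall contacts; the whole suite completes in well under a
minute on one core. The acceptance script re-runs the walking dimer
(20 field periods at 10 Hz) and the 8-chain frequency-switch experiment
from scratch.

```{r example}
library(janusim)

# the analytic force budget
force_scale_report()

# a walking dimer at 10 Hz
res <- run_scenario("walking", f_Hz = 10, n_periods = 20, seed = 1)
res$summary$mean_speed_mm_s

# assembly of eight robots into a zigzag chain
asm <- run_scenario("chain_assembly_8", seed = 1)
asm$summary$assembly_efficiency
```
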