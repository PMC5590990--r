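---
title: "Methods: coupled SPH-FE simulation of heart-valve fluid-structure interaction"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: coupled SPH-FE simulation of heart-valve fluid-structure interaction}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

`sphvalve` is a desk-scale simulator for intraventricular hemodynamics
and heart-valve dynamics. Blood is a weakly-compressible smoothed
particle hydrodynamics (SPH) fluid, valve tissue is an
explicit-dynamics finite-element structure, and the two exchange
momentum through node-to-surface penalty contact. This vignette is the
package's own account of the models, the numerical choices, and what
the synthetic benchmark scenes do and do not demonstrate.

## The fluid model

Fields are kernel-weighted sums over particles,
$A(\mathbf r_a) = \sum_b m_b \frac{A_b}{\rho_b} W(\mathbf r_a - \mathbf r_b, h)$,
with a cubic spline kernel of compact support $2h$. Mass conservation
is integrated in rate form,
$\mathrm d\rho_a/\mathrm dt = \sum_b m_b \mathbf v_{ab} \cdot \nabla_a W_{ab}$,
and momentum combines a symmetrized pressure term with a Morris-type
physical viscosity,
$$\frac{\mathrm d\mathbf v_a}{\mathrm dt}
 = -\sum_b m_b \frac{P_a + P_b}{\rho_a \rho_b} \nabla_a W_{ab}
 + \sum_b m_b \frac{(\mu_a + \mu_b)\,\mathbf v_{ab}}{\rho_a \rho_b\, r_{ab}^2}\,
   \mathbf r_{ab}\cdot\nabla_a W_{ab}.$$
Blood carries a reference density of 1056 kg/m^3 and a dynamic
viscosity of 0.0035 Pa s. Because the pairwise contributions are
antisymmetric, the discrete equations conserve linear momentum to
round-off, which the test suite checks directly.

Pressure closes the system through an artificial weakly-compressible
equation of state. The default is linear, $P = c_0^2(\rho - \rho_0)$,
with a Tait form selectable. The artificial sound speed is chosen per
scene at roughly ten times the fastest expected flow speed (or the
equivalent for the imposed pressure scale), keeping density
fluctuations near 1%; the valve scenes use 12-20 m/s. Time integration
is symplectic (semi-implicit) Euler with
$\Delta t = 0.25\, h / (c_0 + v_\max)$, a single rate evaluation per
step; `step_fluid()` rejects steps that violate the acoustic CFL bound.
The smoothing length defaults to $h = 1.3\,\Delta x$ for a lattice
spacing $\Delta x$; the reference full-scale seeding spacing is 0.8 mm,
while the shipped scenes use 1.5-3 mm so each runs in minutes on one
CPU (the vignette's scene sizes: ~1 000 fluid particles in the 2D
tank and channel, ~2 900 in the dam, ~1 500 in the tube valve, ~3 700
in the idealized ventricle).

### Stabilization, in and out of the box

The printed continuity and momentum operators are implemented verbatim
and exposed as `density_rate()` / `momentum_rate()` with every
stabilizer off, because the conservation and benchmark oracles must see
the bare equations. Bare WCSPH is, however, well known to suffer
tensile (clumping) instability and acoustic density noise, and the
scenes enable the standard, config-gated remedies:

* delta-SPH density diffusion (coefficient 0.1) smooths the
  checkerboard density mode;
* Monaghan artificial viscosity (0.05-0.15) damps acoustic collisions;
* free-surface scenes clamp pressure at zero (`p_min` in the equation
  of state) so surface tension states cannot seed particle pairing;
* a Shepard density filter is available but off by default.

### Boundaries

Rigid and prescribed-motion boundaries (tank and channel walls, tube
shells, the moving ventricular wall, piston plates) are layers of
boundary "dummy" particles, three deep so kernels near a wall see full
support. Their pressures are re-extrapolated from the adjacent fluid
with a hydrostatic correction every step (the generalized wall
treatment), which makes walls stiff and the hydrostatic field accurate;
their densities follow from the equation of state. A short-range linear
spring between fluid and boundary particles (engaging only below one
particle spacing, stiffness $m/(4\Delta t^2)$) prevents the slow creep
through the wall lattice's saddle points that sustained pressure
otherwise drives - without it every pressurized scene leaks. Because
walls are kinematically prescribed, this one-sided guard does not
enter the fluid-fluid momentum balance, and the momentum-conservation
tests run on boundary-free systems.

The viscous no-slip at a wall is only approximate with zero-velocity
dummy particles; the channel benchmark sharpens it by extrapolating
wall velocities anti-symmetrically from the adjacent fluid
(`noslip_walls`), and a shear-cell test documents that fluid adjacent
to a tangentially moving plate tracks it within 20% without that
option.

Pistons impose pressure waveforms on the ends of tube extensions. A
piston is a rigid plate of boundary particles whose normal velocity is
set from the acoustic characteristic relation
$v_p = v_f - (P_f - P_\mathrm{target})/(\rho_0 c_0)$, with fluid
pressure and velocity kernel-interpolated one support-length inside the
column: the plate behaves as a massless velocity-controlled boundary
that imposes the target pressure while letting outgoing waves leave.
The raw relation closes an explicit feedback loop through the
interpolation lag, so the velocity is relaxed (factor ~0.15-0.2 per
update) and capped; a sealed-column test verifies the interior settles
at the target pressure within 5%.

## The tissue model

Leaflets are constant-strain membrane triangles carrying the modified
anisotropic Holzapfel-Gasser-Ogden (MHGO) energy
$$W = c_1\{e^{c_2(\bar I_1 - 3)} - 1\}
 + \frac{k_1}{2k_2}\sum_{i=1,2}\left[
   e^{k_2[\kappa \bar I_1 + (1-3\kappa)\bar I_{4i} - 1]^2} - 1\right]
 + \frac{1}{D}(J-1)^2,$$
with two collagen fiber families at $\pm\theta$ about the local
circumferential axis and dispersion $\kappa \in [0, 1/3]$. A family
contributes only while its exponent argument is positive (tension-only
fibers, the standard convention for a law that is silent about
compressed fibers). The calibrated human parameter rows for aortic and
anterior/posterior mitral leaflets ship in
`valve_material_table()` alongside the three Ogden chordae rows, whose
energy $W = \sum_i (2\mu_i/a_i^2)(\bar\lambda_1^{a_i} +
\bar\lambda_2^{a_i} + \bar\lambda_3^{a_i} - 3)$ drives nonlinear truss
elements that are slack in compression by default. The `mhgo_cauchy_stress()`
and `ogden_fiber_tension()` implementations are closed-form derivatives
of these energies; the test suite verifies both against
central-difference differentiation of the printed energies to 1e-5
relative on 100 seeded random tension states per tissue row, and checks
frame indifference to 1e-9.

Incompressibility is enforced by plane stress plus the volumetric
penalty: each membrane element solves its through-thickness stretch so
the normal second Piola-Kirchhoff stress vanishes (a guarded
secant iteration with a bisection fallback). Chordal forces are
reported as force, and the uniaxial truss force $A_0\,\mathrm dW/\mathrm
d\lambda$ is identical under nominal-stress and Cauchy-times-current-area
readings, so the choice is moot for the reported quantity.

Two deliberate simplifications, with consequences:

* Membranes have no bending stiffness (the full model's layered solid
  elements are out of scope at desk scale). A membrane under in-plane
  compression therefore crumples element by element, which is both
  unphysical and numerically fatal for an exponential law. The package
  uses the standard tension-field (wrinkling) treatment: principal
  stretches below one are treated as slack and the stress is projected
  onto the taut principal direction. The smooth, taut regime - where
  the constitutive oracles operate - is untouched.
* Explicit central-difference dynamics with row-sum lumped mass
  (tissue density 1100 kg/m^3, a documented constant) needs the stable
  increment of the stiffest element. Because the fiber exponent
  $k_2 \sim 10^2\text{-}10^3$ makes the tangent modulus grow
  explosively with strain, the coupled runner estimates the current
  tangent each fluid step and substeps the structure adaptively
  (capped), with mass-proportional damping and a generous nodal speed
  guard (10-15 m/s, far above any resolved tissue velocity) against
  start-up transients.

## Coupling

Fluid particles within a contact thickness (0.8 particle spacings by
default) of a membrane face receive a penalty force along the face
normal, `stiffness x penetration`, with the exact opposite reaction
spread over the face nodes by barycentric weights - so coupling
conserves momentum to machine precision, which is asserted per step in
the tests. The stiffness auto-scales as $m/(\beta \Delta t^2)$,
$\beta = 4$, the largest spring stable at the CFL step; a sub-critical
dashpot removes contact chatter, and an optional ghost-pressure term
adds the pressure contribution a contacted particle's truncated kernel
is missing beyond the surface. Projections falling exactly on a shared
edge are assigned to the lowest element index (deterministic
tie-break); degenerate faces are excluded with a warning.

Within a fluid step the structure substeps many times, so contact is
re-evaluated against the moving mesh inside each substep from a
once-per-step candidate list; the fluid receives the substep-averaged
reaction. Freezing the contact force across substeps - the obvious
shortcut - delivers impulses of tens of m/s to milligram leaflet nodes
and was the dominant failure mode during development.

## Prescribed motion and waveforms

Keyframe tracks interpolate per-node displacements with cubic splines;
cardiac tracks are periodic with periodic end conditions (the cycle is
closed, so C2 continuity across the cycle boundary is the natural
choice; the keyframes themselves are reproduced exactly). Chordal
origins travel between their mid-diastolic and mid-systolic
papillary-muscle anchors under a smooth cosine ramp synchronized to the
phase transitions (linear selectable) - the interpolation law between
the two imaged anchor states is not specified by the data, and the
cosine ramp is the choice with continuous velocity. The aortic outlet
waveform is parametric (diastolic 80 mmHg, systolic 120 mmHg over a
0.05-0.35 s ejection window, exponential diastolic decay) and can be
replaced by any time-value table; the atrial side uses a constant
20 mmHg in the cardiac configuration.

## The synthetic scenes and what they show

All geometry is generated in code; no patient data is consumed.

* **Hydrostatic tank** (2D): settled interior pressure versus
  $\rho g h$, within 5% at interior probes (time-averaged over the
  trace tail, since the undamped tank supports percent-level acoustic
  sloshing).
* **Plane Poiseuille channel** (2D, periodic): steady profile versus
  the analytic parabola within 5%. The benchmark fluid is more viscous
  than blood (0.1 Pa s) so the viscous diffusion time fits the run;
  the comparison is in nondimensional profile shape and absolute
  magnitude for that fluid.
* **Elastic gate**: a water column held by a membrane gate clamped at
  its top edge, periodic in the spanwise direction. Walled variants
  measure the dam resultant with O(h/L) corner-kernel errors of
  10-25% that resolution cannot affordably remove; the periodic dam
  isolates the gate and matches $\tfrac12 \rho g H^2 w$ within 5%
  (settled column height from the conserved fluid volume and footprint,
  avoiding an O($\Delta x$) seeding bias). The soft gate's free bottom
  tip deflects downstream, the expected sign.
* **Tube valve**: a rigid tube with a parametric tri-leaflet membrane
  valve bound to the aortic-leaflet material row. The closed,
  coapted configuration is the stress-free reference (watertight up to
  the contact layer, verified by a ray-crossing check); attachment is
  the annulus arc plus the commissure corner points, leaving the side
  edges free as in a native valve. A forward 30 mmHg inlet opens it
  (projected orifice area from ~0 to above 1 cm^2); staging the outlet
  to 45 mmHg reverses the gradient and closes it, with positive
  regurgitant (closing) volume measured by the downstream flux plane.
  The closure driver is the physiological diastolic gradient - an
  inlet-side reduction alone is too weak on this short horizon.
* **Idealized left ventricle**: a truncated ellipsoid (long-to-radial
  axis ratio 1.6) whose radial wall scaling is built from a 10-keyframe
  cavity-volume waveform - end-diastolic 112 ml, end-systolic 47 ml,
  period 0.8 s, so the track encodes a 65 ml stroke volume and 58%
  ejection fraction - with two basal orifices continuing into straight
  tube extensions (about five diameters) closed by pressure pistons.
  Scaling radial coordinates by $s_k = \sqrt{V_k / V_\mathrm{EDV}}$
  makes the cavity volume match every keyframe exactly up to mesh
  discretization (<2%, divergence-theorem oracle). Over the early
  systolic window the cycle-integrated flux through the tube planes
  matches the prescribed chamber volume change within 2%. Getting
  there required three scene-design details worth recording: the
  cavity is seeded as a 3D lattice clipped to a slightly offset
  ellipsoid and then pressurized during settling (slice-wise seeding
  leaves ~20% voids whose filling masquerades as lost flux); the two
  flux disks must not overlap (the tubes are close); and a static
  skirt under the basal plate seals the corner the contracting wall
  vacates.

What passing these fixtures does *not* show: patient-specific
anatomy, cluster-scale resolution (the reference configuration is
~500 000 particles), leaflet bending mechanics, calcification, active
myocardial contraction, or turbulence. The scenes establish that the
governing equations, constitutive laws, coupling and metrics are
implemented correctly at a resolution where closed-form oracles exist.

## Metrics

The post-processing module implements the clinical quantities as pure
functions: stroke volume and ejection fraction from end-diastolic and
end-systolic volumes; effective orifice areas
$\mathrm{EOA}_{AV} = \mathrm{MSF}/(51.6\sqrt{\Delta P})$ and
$\mathrm{EOA}_{MV} = \mathrm{MDF}/(31\sqrt{\Delta P})$ from
root-mean-square systolic/diastolic flow rates (ml/s) and mean
gradients (mmHg); regurgitant volume as the time integral of negative
flow and regurgitant fraction RF = RV/SV; transvalvular pressure drops
from kernel-interpolated probe pairs; axial hydrodynamic force as the
signed projection of contact reactions on the valve axis; E/A as the
ratio of the two largest diastolic inflow peaks in temporal order
(prominence-based detection, 100 ms minimum separation); and rapid
valve opening/closing times as the contiguous high-slope tracts of the
belly radial-velocity curve, with "high" meaning above a configurable
fraction (default 0.2) of the peak slope magnitude. Belly radial
velocity is the belly marker's velocity projected on the instantaneous
radial direction through the marker; a surface-normal alternative is a
one-line change in the scene recorder. Reports round the way clinical
tables do: one decimal for mmHg and cm^2, integers for percent and ms.

## Numerical choices at a glance

| Quantity | Default | Rationale |
|---|---|---|
| Smoothing length | $1.3\,\Delta x$ | standard cubic-spline spacing ratio |
| Sound speed | $\ge 10 \times$ flow scale | ~1% density fluctuation |
| CFL factor | 0.25 | explicit WCSPH practice |
| Contact thickness | $0.8\,\Delta x$ | below a spacing, above a half |
| Contact stiffness | $m/(4\Delta t^2)$ | stable at the CFL step |
| delta-SPH / artificial viscosity | 0.1 / 0.05-0.15 | literature values |
| Tissue density | 1100 kg/m^3 | soft-tissue literature value |
| Plane-stress tolerance | $10^{-7} \times 2/D$ | volumetric-stiffness scaled |
| Slope threshold (RVOT/RVCT) | 0.2 of peak slope | config-exposed |

Determinism: nothing in the solver draws random numbers; seeded jitter
is available for particle seeding but unused by the shipped scenes, so
identical configurations reproduce identical traces bit for bit (a
test asserts this on CSV output).

## Known limitations

Beyond the scope cuts above: the no-slip condition at penalty-coupled
surfaces is only approximate (contact is frictionless in the normal
direction; a velocity-proportional tangential damping is config-gated);
pressure transfer through contact carries discretization error of
order 10% at these resolutions; leaflet-leaflet coaptation is mediated
by the interposed fluid rather than a dedicated self-contact; and the
wrinkling model discards compressive membrane stiffness entirely, so
post-buckling wrinkle wavelengths are not resolved. The projected
orifice area of a nearly-closed valve is a coarse polygon measure: a
functionally sealed valve (zero flux) can still report a few tenths of
a cm^2.
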