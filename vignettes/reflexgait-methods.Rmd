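---
title: "Predictive simulation of walking with reflex-based muscle control"
author: "reflexgait"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predictive simulation of walking with reflex-based muscle control}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(reflexgait)
```

## The model

`reflexgait` synthesizes walking without motion data: a planar
neuromusculoskeletal model is controlled by spinal-reflex-inspired feedback
laws, and the free parameters of those laws (together with the initial state)
are optimized so that the resulting movement is upright, forward-progressing
at a target speed, head-stable, and metabolically cheap. Kinematics, kinetics,
muscle coordination, and energetics then *emerge* from the optimization rather
than being tracked.

### Skeleton

The skeleton has 7 segments — a lumped trunk+head+arms segment (HAT) and a
thigh, shank, and foot per leg — connected by pin joints at the hips, knees,
and ankles, moving in the sagittal plane: 9 degrees of freedom (hip-point x,
y, trunk pitch, and six joint angles). Flexion (hip), flexion (knee), and
dorsiflexion (ankle) are positive; trunk pitch is positive in forward lean.
The equations of motion are formed in minimal coordinates (mass matrix from
segment Jacobians, Christoffel-free velocity-product bias accumulated per
body), so pin joints are satisfied exactly.

Default inertial parameters are an anthropometric reconstruction for an 80 kg,
1.88 m adult (HAT 53.5 kg / 3 kg m$^2$, thigh 8.5 kg / 0.15 kg m$^2$, shank
3.5 kg / 0.05 kg m$^2$, foot 1.25 kg / 0.005 kg m$^2$); the numeric table is
not fixed by the framework and ships as an editable YAML
(`inst/extdata/model_planar.yaml`). The ankle joint is raised 5 cm above the
sole, with the heel and ball contact spheres 6 cm behind and 13 cm ahead of
it. Joint limits are one-sided nonlinear spring-dampers (default 300 N m/rad,
30 N m s/rad) that engage only beyond the limit angle; the instantaneous sum
of squared limit torques is the hyperextension penalty (HPE) used by the
effort objective.

### Contact

Each foot carries two spheres of radius 1 cm. The normal force is a compliant
Hunt–Crossley law
$$\mathrm{GRF}_y = k\,h^{1.5}\,(1 + 1.5\,c\,\dot h),$$
active for penetration $h > 0$ and clamped below at zero — the raw expression
turns adhesive during fast retraction, which we exclude as unphysical.
Defaults: $k = 9.4281\times 10^5$ N m$^{-1.5}$, $c = 2$ (m/s)$^{-1}$.
Friction is $\mathrm{GRF}_x = -\mu(\dot x)\,\mathrm{GRF}_y$ with a smooth, odd
Stribeck blend
$$\mu(\dot x) = \mu_d \tanh(4 \dot x/v_t)
  + (\mu_s-\mu_d)\,\frac{\dot x/v_t}{(0.25 (\dot x/v_t)^2 + 0.75)^2}
  + \mu_v\,\dot x,$$
with $\mu_s = \mu_d = 0.8$, $\mu_v = 0.5$ s/m, $v_t = 0.1$ m/s. The blend
itself is a documented local choice (the static hump vanishes for
$\mu_s = \mu_d$); its large-slip asymptote $(\mu_d + \mu_v |\dot x|)$ and
odd symmetry are pinned by tests against an independently coded oracle.

Contact state for the controller is a per-foot boolean with hysteresis:
a foot is "on the ground" once its total normal force exceeds 20 N and "off"
again below 5 N, which debounces heel-strike detection against contact
chatter.

### Musculotendon units

Eight Hill-type musculotendon units actuate each leg: ILPSO, GMAX, HAMS
(biarticular), RF (biarticular), VAS, GAS (biarticular), SOL, TA. Parameters
(maximum isometric force, optimal fiber length, maximum shortening velocity,
tendon slack length) are reconstructions of the reflex-walking literature's
values, shipped as `inst/extdata/mtu_params.csv`; the RF row is an explicit
assumption, since the source muscle set does not include it. Moment arms are
constant (hip) or cosine-shaped (knee, ankle) and the path length is their
exact integral, so $\partial l_{MTU}/\partial\theta = -r(\theta)$ holds
analytically (tested by finite differences at 100 random poses).

Curve shapes: active force–length is a Gaussian bell
$\exp(-(\tilde l-1)^2/0.45)$; force–velocity is a Hill hyperbola
$(1+\tilde v)/(1-4\tilde v)$ on shortening and a $C^1$-matched saturating
branch $1.5 - 0.5/(1+10\tilde v)$ on lengthening; the passive element is the
usual exponential toe curve reaching 1 at 60 % stretch. The tendon is a
quadratic series spring reaching $F_{max}$ at 4 % strain. Fiber length is a
state variable: each step the required force–velocity value is obtained from
tendon equilibrium and inverted for the fiber velocity (clamped to
$[-v_{max}, v_{max}]$), which the integrator advances. Activation follows a
first-order lag ($\tau = 10$ ms) integrated exactly. A baseline excitation
$u_0 = 0.01$ keeps activations strictly positive.

### Reflex controller

Excitations are sums of a baseline and law outputs, clipped to $[0,1]$:

* force feedback $u^F = G_F\,F_{MTU}(t-D)$,
* stretch feedback $u^L = G_L\,[\,l_{CE}(t-D)-H\,]_+$,
* PD control $u^\theta = [\,K_p(\theta(t-D)-\theta_{des}) +
  K_d\dot\theta(t-D)\,]_+$,

with transmission delays fixed per muscle group ($D = 5$ ms ILPSO, GMAX,
HAMS, RF; 10 ms VAS; 20 ms GAS, SOL, TA). Laws switch with a per-leg
gait-mode machine — STANCE on foot contact, EARLY_SWING on contact loss,
LATE_SWING once the swing ankle passes `d_swing` ahead of the COM — and both
legs share one parameter set (structural left/right symmetry).

The per-muscle, per-mode wiring is declarative (a table, shipped as
`inst/extdata/wiring_default.yaml`) so deviations are visible and testable:
stance couples positive force feedback on SOL/GAS/VAS (VAS with a rectified
knee-overextension inhibition and TA with SOL-force inhibition), TA stretch
feedback, and a shared trunk-orientation PD on GMAX/ILPSO as an antagonist
pair with a scaled HAMS contribution; early swing uses ILPSO stretch feedback
for swing initiation and TA stretch for foot clearance; late swing ("stance
preparation") places the hip and knee with PD pairs while HAMS force feedback
decelerates the limb; each mode also carries small constant offsets. The
trunk-PD target is referenced to the vertical of the simulation frame (on
inclines, the slope normal); this convention is a deliberate choice and is
what makes the two incline representations differ at the *controller* level
while the passive plant is exactly equivalent.

The table defines 55 free controller parameters; with `d_swing` and 18
initial conditions (9 coordinates + 9 velocities) the design vector has
exactly 74 entries, asserted at construction. The optimizer works on the
normalized unit cube; an affine codec maps to physical bounds.

### Objective

A rollout (10 s nominal) is scored by
$$R = w_{fail} J_{fail} + w_{vel} J_{vel} + w_{head} J_{head} +
w_{effort} J_{effort},$$
with $w_{fail} = 5\times10^5$, $w_{vel} = 50$, $w_{head} = 25$,
$w_{effort} = 1$ for every scenario. $J_{fail} = (1/T_{fall})(T - T_{fall})$
uses the first time the COM height (perpendicular to the contact plane) drops
below 0.7 m. $J_{vel}$ averages, over heel-strikes, the deadband penalty
$Q(d,\varepsilon) = d^2\,[|d| > \varepsilon]$ of the previous step's mean
forward COM speed against the 1.5 m/s target ($\varepsilon = 0.05$ m/s); a
"step" is the interval between consecutive heel-strikes of either leg, and
the first strike (no preceding step) is skipped. $J_{head}$ applies
$Q(\cdot, 0.2)$ to the relative forward velocity of the head (top of trunk)
versus the COM over the exact 100 Hz sample grid. $J_{effort}$ is the
mass-normalized mean of total muscle metabolic power plus $0.005\,\mathrm{HPE}$,
normalized by the *carried* mass $M_{body} + M_{back}$.

One addition proved necessary for desk-scale optimization. The velocity term
is defined only on heel-strike intervals, so a model that stands still (or
takes two steps and then stands) pays no velocity penalty and, being
metabolically cheapest, becomes the global optimum — our stabilized plant
*can* balance statically, an attractor the original limit-cycle controller
family never exposed. `make_gait_objective()` therefore charges strike-free
stretches (no steps at all, or gaps longer than 0.8 s at either end of the
rollout) the velocity penalty of their mean COM speed. The exported
`j_vel()` keeps the bare definition (empty set gives 0 with a warning).

### Scenarios

Backpack load is a point mass $M_{back}$ fixed 0.1 m posterior to the trunk
COM with rotational inertia $0.15\,M_{back}$ kg m$^2$. Inclines rotate the
gravity vector while the contact plane stays put — dynamically equivalent to
tilting the plane (verified to $10^{-8}$ over a short passive rollout) — so
reported kinematics and speeds are in the slope frame. The COM-height fall
test then automatically measures perpendicular distance to the slope.

### Integration and determinism

A fixed-step semi-implicit Euler scheme at 0.5 ms advances the skeleton;
the step divides every reflex delay and the 100 Hz objective grid exactly, so
delayed lookups (a ring buffer per leg) and the sample set $S$ carry no
interpolation error. Two velocity-coupled force terms are too stiff for an
explicit step on the 1.25 kg foot segment — joint-limit damping and the slope
of the friction law near zero slip — and are treated implicitly: their
velocity-derivatives enter the mass-matrix solve as a damping matrix, while
reported forces remain the explicit values. Rollouts are deterministic given
identical inputs; CMA-ES is deterministic given its seed.

### Metabolics

Whole-body metabolic power follows the heat-rate tradition: per muscle, an
activation/maintenance rate $m\,(25 + 128 f_{FT})\,a$ W (with muscle mass
$m = F_{max} l_{opt}\rho/\sigma$, $\rho = 1059.7$ kg/m$^3$,
$\sigma = 0.25$ MPa, and $f_{FT}$ the fast-twitch fraction), a shortening
heat rate $0.25\,F\,|v_{CE}|$, and the positive mechanical work rate
$-F\,v_{CE}$ during shortening (eccentric work is not credited). A basal
rate of 1.2 W per kg of unloaded body mass — a standard resting value that
places level-walking cost in the experimentally plausible range — is always
included and reported. All coefficients live in the muscle table and the
model is a single pluggable function, so alternative energetics can be
swapped in.

## The optimizer

CMA-ES (the standard $(\mu/\mu_w, \lambda)$ strategy with cumulative
step-size adaptation and rank-one/rank-$\mu$ covariance updates) searches the
normalized design cube; bounds are enforced by clipping candidates before
evaluation (simple and reproducible). The starting point is evaluated once up
front so a warm start can never be lost. Scenario schedules (increasing load
or incline) are optimized by continuation, each stage starting from the
previous best, with stages that still fall flagged and skipped as warm-start
sources.

Desk-scale defaults are $\lambda = 16$, $\sigma_0 = 0.15$; cluster-scale
reproduction of the full study (thousands of iterations, populations sized
to a 48-node cluster) uses the same code path with different settings.

## Gait analysis

Strides are delimited by heel-strikes of a reference leg; the first two are
discarded so the control excitation cycles can stabilize; the rest are
resampled onto a 101-point 0–100 % gait-cycle grid (the field's convention)
and averaged. Band coverage reports the percentage of grid points within
±1 SD of a reference band, counting the boundary as inside. EMG onset
detection applies the Teager–Kaiser energy operator
$\psi[n] = x[n]^2 - x[n-1]x[n+1]$, rectifies, smooths with a 20 ms moving
average, and thresholds at 6 baseline SDs; the baseline ("off") region is
supplied or auto-selected as the lowest-energy quarter, and detections
shorter than 30 ms are treated as noise (brief gaps are likewise merged).
Metabolic summaries normalize by *unloaded* body mass regardless of carried
load.

`generate_fixtures()` produces deterministic synthetic reference bands, EMG
(Gaussian baseline with amplified bursts at known times), and an analytically
periodic trajectory. These exercise every analysis operation without external
data; they emulate the periodicity, band structure, and burst timing of real
gait data but none of its variability between strides and subjects — passing
the analysis tests therefore validates the *operations*, not the physiology.

## Problem sizes used by the shipped tests

The test suite validates the dynamics against an independent complex-step
Lagrangian oracle (6 random states, relative tolerance $10^{-6}$), energy
conservation over 1 s of passive swing, virtual-work consistency at 100
random poses, CMA-ES on a 10-dimensional sphere ($\lambda = 8$, 200
iterations, target $10^{-8}$), and a closed-loop smoke test that refines the
shipped level-walking warm start for a small number of CMA-ES iterations at
$\lambda = 8$ on 5-s rollouts, checking a non-falling gait of at least 6
strides with mean forward speed in [1.35, 1.55] m/s. These sizes were chosen
so the whole suite runs in minutes on a laptop; the full nine-scenario
continuation study is a separate, longer computation driven by the same
functions (see `inst/cli/optimize.R`).

## Known limitations

* Planar mechanics: no coronal/transverse motion, no separate arms.
* The inertial, muscle, limit, and metabolic coefficient tables are
  literature-style reconstructions, not subject-specific fits.
* The reflex wiring is one member of a family; alternative couplings (e.g.,
  CPG components, double-support-specific laws) are out of scope.
* Predicted absolute metabolic cost depends on the energetics coefficients
  and basal rate; trends across load/incline are more robust than levels.
* The contact model produces sharper heel-strike transients than measured
  force plates, a known artifact of sphere-plane compliant contact.
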