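---
title: "Modelling electrostatic exclusion zones around tubulin assemblies"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling electrostatic exclusion zones around tubulin assemblies}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ezmt)
```

## The physical picture

Hydrophilic, charged surfaces in water expel suspended colloidal particles
from a region near the surface — the *exclusion zone* (EZ). Microtubules are
a natural biological candidate for this effect: the cylinder wall plus the
protruding C-terminal tails carry a large negative charge, and free tubulin
dimers (themselves strongly negative, bare charge about −52 e) are repelled
from it. `ezmt` models this expulsion for three tubulin geometries — the
microtubule cylinder, a single tubulin dimer treated as a sphere, and a flat
tubulin sheet — by combining two classical ingredients:

1. **Screened electrostatics.** The potential outside the surface obeys the
   linearized Poisson–Boltzmann (LPB) equation in a symmetric monovalent
   electrolyte. Its closed-form solutions decay on the Debye length
   $\lambda_D = \sqrt{\varepsilon_0\varepsilon_r k_B T / (2 N_A c_s e^2)}$:
   a $K_0/K_1$ modified-Bessel profile for the cylinder, a screened-Coulomb
   (Yukawa-type) profile for the sphere, and a pure exponential for the
   plane. The diffuse-layer solution applies outside a Stern layer of
   adsorbed counterions, one K⁺ radius (0.33 nm) thick; each solution is
   anchored by the Gauss-law condition at that boundary.

2. **Deterministic overdamped motion.** A tubulin-dimer probe of effective
   charge $Q_\mathrm{eff}$ feels the force $F = Q_\mathrm{eff} E(x)$ and
   Stokes drag $\xi = 6\pi\eta a$; its trajectory follows
   $m\ddot{x} = F(x) - \xi\dot{x}$ from rest. The EZ size is
   *operationalised as the probe displacement* $x(t) - x(0)$, not as a
   threshold crossing of the potential — this matches how EZ growth curves
   are read from time-resolved measurements.

The thermal (stochastic) force is deliberately absent: trajectories are
deterministic, reproducible bit for bit, and represent the mean drift of the
probe rather than any single Brownian realisation.

## Parameters that matter

| Parameter | Default | Units | Why |
|---|---|---|---|
| $\varepsilon_r$ | 78.3 | — | water at 20 °C |
| $T$ | 293.15 | K | 20 °C, standard laboratory temperature |
| $\eta$ | $10^{-3}$ | Pa·s | water viscosity |
| $c_s$ | 10 or 160 | mM KCl | in-vitro-like vs. cytoplasm-like ([K⁺] ≈ 140 mM in cells) |
| $R$ (cylinder) | 12.5 | nm | microtubule outer radius |
| $R$ (sphere), $a$ | 2.71 | nm | volume-equivalent radius of the 2 × 2.5 × 4 nm dimer ellipsoid |
| $d$ | 0.33 | nm | Stern layer, one K⁺ radius, same for all geometries |
| $\sigma$ (cylinder) | −0.102 | C/m² | area-weighted wall + C-termini budget (−25 e wall, −11 e per C-terminus) |
| $\sigma$ (sphere, plane) | −0.090 | C/m² | $Q_\mathrm{bare}/4\pi R^2$ with −52 e |
| $Q_\mathrm{eff}$ | −17 e / −29 e | — | counterion-corrected dimer charge at 10 / 160 mM |
| $m$ | 110 | kDa | dimer mass; irrelevant in the overdamped regime (below) |

Notes on the less obvious choices:

* **−0.102 C/m² is stored as a constant.** The area weights that produce it
  have no unique parameterisation, so `mt_sigma_default` carries the
  canonical value and `mt_charge_budget()` / `mt_surface_charge()` let users
  recompute $\sigma$ from an explicit area model.
* **$Q_\mathrm{eff}$ is a per-concentration constant** (−17 e at 10 mM,
  −29 e at 160 mM), reused unchanged for all three geometries. It is *not*
  interpolated: `tubulin_effective_charge()` refuses other concentrations
  and the configuration layer then requires an explicit value.
* **2.71 nm by volume equivalence.** Among the plausible ellipsoid→sphere
  reductions, equating volumes (the geometric mean of the semi-axes,
  $(2 \cdot 2.5 \cdot 4)^{1/3} = 2.71$ nm) is the one that reproduces the
  canonical radius exactly, so it is the one implemented.
* **T = 20 °C is taken as 293.15 K** throughout.

## Numerical choices

**Bessel evaluation.** Integer-order $K_0, K_1$ come from base R's
`besselK` with exponential scaling, so ratios like
$K_0(r/\lambda_D)/K_1((R+d)/\lambda_D)$ stay finite for $r/\lambda_D$ up to
several hundred (unscaled values underflow beyond $x \approx 700$).
Half-integer orders use their elementary closed forms
$K_{1/2}(z) = \sqrt{\pi/2z}\,e^{-z}$ and
$K_{3/2}(z) = K_{1/2}(z)(1 + 1/z)$, avoiding special-function edge cases.
The spherical profile is written through the half-order Bessel combination
$g(z)$ whose argument is $z$ throughout; with that form
$g(z) = -\tfrac{d}{dz}\left[z^{-1/2}K_{1/2}(z/\lambda_D)\right]$, which is
exactly what the identity $E = -dV/dr$ requires. The test suite enforces
this with a central-difference oracle on every geometry and checks the
spherical solution against an independently derived Yukawa closed form to
$10^{-10}$ relative tolerance.

**Stiffness and the overdamped default.** The inertial time
$m/\xi \approx 3.6$ ps is seven orders of magnitude below the microsecond
horizons of interest, which makes the second-order equation extremely
stiff. The default integration mode therefore solves the first-order
reduction $\dot{x} = F(x)/\xi$ with `deSolve::lsoda` (rtol $10^{-8}$, atol
$10^{-12}$ on positions scaled to nm, times to µs); a `mode = "full"`
second-order path exists for verification. The two agree to better than 1%
once the inertial transient has decayed — in practice beyond roughly 100
inertial times (≪ 1 ns); at 10 inertial times the residual displacement
deficit of order $v_0 m/\xi$ still amounts to ~10% of the (tiny)
displacement, which is the expected constant-force transient behaviour,
not an integration error.

**Output grids.** EZ growth is fast at first (a few µs) and logarithmic
later, so trajectories are sampled on a logarithmic time grid (plus
$t = 0$), 400 points by default. Energy-variation profiles are tabulated on
the trajectory's own coordinates, so energy-vs-distance and EZ-vs-time
tables share support. Summary tables always report the displacement both at
the scenario horizon (50 µs default) and at 10 µs, so curves quoted at
either horizon can be compared without axis ambiguity.

**Linearization validity.** The LPB solution is quantitative only while
$|V|$ stays below the thermal voltage $k_BT/e \approx 25$ mV. The default
tubulin surfaces exceed that at contact (by an order of magnitude at
10 mM), so the linear theory overestimates the near-field voltage at low
salt. Scenario runs log the contact potential and flag the violation; it is
a warning, not an error, because the qualitative screening behaviour —
decay on $\lambda_D$, salt dependence, geometry ordering — is unaffected.

**Force-law fit.** The exponential parameterisation
$F(x)/\xi = K e^{-\kappa x}$ is fitted by linear least squares on
$\log(F/\xi)$ over trajectory samples with $F$ above $10^{-6}$ of its
starting value (dropping the log-of-zero tail and duplicated plateau
coordinates). For the plane the force is exactly exponential and the fit
recovers $\kappa = 1/\lambda_D$ to machine-level residual; for cylinder and
sphere the fit summarises the quasi-exponential Bessel/Yukawa tail and
tracks the true force within ~10% over the first few Debye lengths.

## What the scenario generator emulates — and what it does not

`sample_scenarios()` draws randomized, physically valid parameter sets
spanning and exceeding the tubulin regime: 1–500 mM salt and surface-charge
magnitudes 0.01–0.2 C/m² (both log-uniform, since they span decades), radii,
probe sizes, effective charges, temperature, viscosity and permittivity
uniform over laboratory-plausible ranges. One seed governs all sampling, the
caller's RNG state is restored, and every draw passes the same validation as
hand-built scenarios. Its purpose is property testing — field identities,
screening monotonicity, integrator cross-checks — on inputs nobody
hand-picked.

It does *not* emulate real cytoplasm: no pH-dependent charge, no
multivalent or asymmetric electrolytes, no crowding, no hydrodynamic wall
corrections, and no attempt to reach the micron-scale EZs reported for
synthetic polymer surfaces — the screened-electrostatics mechanism
implemented here saturates on the 10-nm scale at physiological salt. Passing
property tests therefore demonstrates internal consistency of the model, not
fidelity to any particular experiment.

## Known limitations

* The linearized PB closed forms overestimate near-surface voltages at low
  salt (flagged at run time, see above); a nonlinear or ion-size-modified PB
  treatment is out of scope.
* The deterministic trajectory is the noise-free limit; thermal kicks would
  spread an ensemble around it but not shift the mean drift materially in
  the strongly repulsive regime.
* Effective charges are tabulated constants at 10 and 160 mM; other
  concentrations require a user-supplied value.
* Start-rule insensitivity (Stern contact vs. probe-radius contact) holds
  within ~15% at 10 mM on microsecond timescales; at 160 mM the two curves
  keep a constant offset of the order of the start-position gap, which is
  a substantial *relative* difference because the EZ itself is only a few
  Debye lengths there.

## A worked run

```{r run, fig.width = 7, fig.height = 3.5}
scns <- tubulin_scenarios()          # 3 geometries x {10, 160} mM x 2 start rules
res <- run_scenarios(scns, quiet = TRUE)
summary_table(res)[, c("id", "lambda_D_nm", "ez_horizon_nm",
                       "ez_10us_nm", "dU_total_kBT")]
plot_result_set(res[c("cylinder_10mM_stern_contact",
                      "cylinder_160mM_stern_contact")],
                main = "Microtubule EZ")
```

The summary reproduces the headline numbers the test suite asserts: a
~3 nm Debye length at 10 mM (0.75 nm at 160 mM), a microtubule EZ of about
30 nm at 10 mM growing over tens of microseconds, a tubulin–tubulin EZ of
about 20 nm after 10 µs, energy releases from a few to hundreds of
$k_BT$ — mostly within the first 3 nm — and sheet energies about half the
cylinder's at matched conditions.
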