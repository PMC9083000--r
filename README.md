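# ezmt — electrostatic exclusion zones around tubulin assemblies

Charged hydrophilic surfaces in water expel suspended colloidal particles
from an adjacent region, the *exclusion zone* (EZ). Microtubules — hollow
cylinders of tubulin with a strongly negative wall (outer radius 12.5 nm,
surface charge density −0.102 C/m², much of it on the protruding C-terminal
tails) — are a prime biological candidate for this effect, and free tubulin
dimers (bare charge ≈ −52 e) are the natural excluded species. `ezmt` is for
biophysicists and modellers who want quantitative, reproducible estimates of
how far and how fast a tubulin dimer is driven away from a microtubule, from
another dimer, or from a flat tubulin sheet, and how much electrostatic
energy that motion releases.

## The model

Outside a Stern layer of thickness *d* (one K⁺ radius, 0.33 nm), the
potential obeys the linearized Poisson–Boltzmann equation in a symmetric
monovalent electrolyte and decays on the Debye length

$$\lambda_D = \sqrt{\frac{\varepsilon_0\varepsilon_r k_B T}{2 N_A c_s e^2}}$$

(≈ 3 nm at 10 mM KCl, ≈ 0.75 nm at 160 mM). The closed forms per geometry:

* cylinder: $V(r) = \dfrac{\sigma\lambda_D}{\varepsilon_0\varepsilon_r}\,
  \dfrac{R}{R+d}\,\dfrac{K_0(r/\lambda_D)}{K_1((R+d)/\lambda_D)}$
* sphere: the screened-Coulomb (Yukawa) solution fixed by the Gauss
  condition $-dV/dr = \sigma R^2 / \varepsilon_0\varepsilon_r (R+d)^2$ at
  $r = R+d$
* plane: $V(x) = \dfrac{\sigma\lambda_D}{2\varepsilon_0\varepsilon_r}\,
  e^{-(x-d)/\lambda_D}$

A tubulin-dimer probe (sphere of radius *a* = 2.71 nm, effective charge
$Q_\mathrm{eff}$ = −17 e at 10 mM / −29 e at 160 mM, Stokes drag
$\xi = 6\pi\eta a$) then moves deterministically under

$$m\ddot{x} = Q_\mathrm{eff} E(x) - \xi\dot{x}, \qquad x(0)=x_0,\ \dot{x}(0)=0,$$

integrated in its overdamped reduction $\dot{x} = F(x)/\xi$ (the inertial
time $m/\xi \approx 3.6$ ps is negligible on µs horizons; a full
second-order mode is kept for verification). The EZ size is the probe
displacement $x(t) - x(0)$; the energy released is
$\Delta U(x) = Q_\mathrm{eff}[V(x) - V(x_0)]$; and the simulated force law
is summarised by a fit $F(x)/\xi = K e^{-\kappa x}$.

See `vignettes/exclusion-zone-model.Rmd` for assumptions, parameter
rationale and numerical details.

## A worked example

```r
library(ezmt)
scns <- tubulin_scenarios()   # 3 geometries x {10, 160} mM x 2 start rules
res  <- run_scenarios(scns[c("cylinder_10mM_stern_contact",
                             "cylinder_160mM_stern_contact",
                             "sphere_10mM_stern_contact",
                             "plane_10mM_stern_contact")], quiet = TRUE)
summary_table(res)[, c("id", "lambda_D_nm", "ez_horizon_nm",
                       "ez_10us_nm", "dU_total_kBT", "t90_us")]
#>                            id lambda_D_nm ez_horizon_nm ez_10us_nm dU_total_kBT t90_us
#>   cylinder_10mM_stern_contact       3.013          33.4      28.74         -261   15.8
#>  cylinder_160mM_stern_contact       0.753          10.1       8.89         -120   12.8
#>     sphere_10mM_stern_contact       3.013          26.2      21.91         -105   18.7
#>      plane_10mM_stern_contact       3.013          33.0      28.16         -132   16.7
```

Reading the rows: at 10 mM the microtubule drives the dimer ~30 nm away
(28.7 nm by 10 µs, 33.4 nm by the 50 µs horizon — growth is logarithmic by
then), releasing 261 k_BT of electrostatic energy, most of it within the
first 3 nm; at 160 mM stronger screening cuts the EZ to ~10 nm. A single
dimer pushes its neighbour ~22 nm in 10 µs; the flat sheet produces nearly
the cylinder's EZ but about half its energy release. `t90_us` is the time
to 90% of the horizon displacement — tens of microseconds throughout.

Per-scenario trajectory and energy CSVs, a combined summary and quick-look
plots come from `run_scenarios(..., output_dir = )` and
`plot_result_set()`. A thin command-line wrapper with `defaults`, `run`,
`fit-force` and `synth` subcommands lives at
`inst/scripts/ez-pipeline.R`; YAML scenario configs are read and written by
`read_scenario_config()` / `write_scenario_config()`, and
`sample_scenarios()` generates randomized physically valid scenarios for
property testing.

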