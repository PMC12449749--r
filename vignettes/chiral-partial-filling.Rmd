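---
title: "Simulating chiral partial-filling capillary electrophoresis with a sulfated cyclodextrin selector"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating chiral partial-filling capillary electrophoresis with a sulfated cyclodextrin selector}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The system

`cesim` simulates a one-dimensional electrophoretic column in which weak
bases — the anesthetic ketamine and its metabolites norketamine and
hydroxynorketamine, each as an S/R enantiomer pair — interact with a highly
sulfated gamma-cyclodextrin (HS-gamma-CD) chiral selector. The selector is a
polyanion, modeled as a single constituent carrying 13 identical,
independent sulfate sites of per-site pKa −3; at any working pH above ~1 it
is fully dissociated and migrates anodically. Each base binds the selector
1:1 with an apparent constant $K$ and the diastereomeric complexes of the
two enantiomers have (slightly) different $K$ and complex mobilities — the
only distinction between S and R forms, and the basis of the separation.

The effective mobility of a fully protonated base at free selector
concentration $c_L$ is

$$\mu_\mathrm{eff}(c_L) = \frac{\mu_f + \mu_c K c_L}{1 + K c_L},$$

with free-ion mobility $\mu_f > 0$ and complex mobility $\mu_c < 0$. The
curve crosses zero at the transition concentration
$c^* = \alpha\,\mu_f / (|\mu_c| K)$ ($\alpha$ the protonated fraction):
below $c^*$ the base migrates cathodically, above it anionically. In a
spatial gradient of selector concentration each analyte therefore
accumulates at the position where the local concentration equals its own
$c^*$ — gradient focusing, analogous to isoelectric focusing in a pH
gradient. In the partial-filling configuration studied here (selector plug
cathodic of the sample, selector-free catholyte toward the detector), this
focusing, the slow diffusive erosion of the gradient, and the anodic
migration of the selector boundary together decide which enantiomers ever
reach a cathodic detector.

## Model

**Chemistry.** Every constituent is a mono-protic weak acid or base (strong
ions are represented by extreme pKa values: chloride as an acid of pKa −2,
sodium as a base of pKa 13.7) or the multi-site selector. Local equilibrium
is assumed throughout: at every grid cell the pH follows from the charge
balance

$$[\mathrm{H^+}] - \frac{K_w}{[\mathrm{H^+}]} + \sum_i \bar z_i(\mathrm{pH})\,c_i = 0,$$

where $\bar z_i$ is the protonation-averaged charge and $c_i$ the
analytical total. Because the binding constant is the same for the charged
and the neutral form of an analyte, complexation leaves the protonation
fractions untouched, and the charge balance depends on analytical totals
only — the pH solve (safeguarded Newton on a strictly monotone function,
residual below $10^{-13}$ of the gross charge) decouples from the
free-ligand mass balance, which is then a rapidly contracting fixed point
($c_L = c_{L,\mathrm{tot}} / (1 + \sum_k K_k c_{A_k,\mathrm{free}})$;
analytes are trace, so two or three sweeps suffice). Conductivity is
$\kappa = F \sum |z| c u$ over water ions, ionic forms at their averaged
charge, and complexes (net charge −12 for a protonated-base complex). No
activity, ionic-strength or viscosity corrections are applied anywhere;
ionic strength is reported but never used. Temperature is fixed at
298.15 K with $K_w = 10^{-14}$ and water-ion mobilities
$362.5/205.5 \times 10^{-9}$ m²/(V·s), the conventions of dynamic
electrophoresis simulators.

**Transport.** The transported unknowns are the constituent analytical
totals; H⁺/OH⁻ are set point-wise by electroneutrality. At constant
voltage the field follows from series resistance,
$j = U / \int \mathrm{d}x/\kappa$, $E = j/\kappa$. Each constituent's flux
sums over its forms — charged form (velocity $\pm uE$), neutral form
(diffusion only), and complexes, whose flux feeds both the analyte's and
the ligand's continuity equation:

$$\partial_t c_k = -\partial_x \sum_{f \in k} \left( v_f c_f - D_f \partial_x c_f \right).$$

Diffusivities follow Nernst–Einstein, $D = RTu/(F\,\max(|z|,1))$, with the
parent ion's mobility for neutral forms and $|z| = 12$ for the
protonated-base–selector complex. The free selector is transported as one
form at its fully ionized velocity (its site-ionization fraction exceeds
0.9999 at pH ≥ 1, so the approximation is inert at working pH, while its
conductivity contribution uses the exact fraction).

**Discretization.** Explicit finite volumes on a uniform grid: upwind
advection with a slope-limited second-order reconstruction, central
diffusion, and an adaptive step obeying
$\Delta t = s\,\min(\Delta x / v_\max,\ \Delta x^2 / 2 D_\max)$ with CFL
safety $s = 0.4$. Reservoir (Dirichlet) end cells model semi-infinite
electrode vials; a closed-box variant (zero-flux ends) exists for
conservation testing. Interior updates telescope, so mass is conserved to
machine precision; uniform sub-regions are advanced by a single
representative flux "teleported" across the run, which is algebraically
identical to the full update and keeps the per-step cost proportional to
the disturbed region.

**Limiter choice.** The default reconstruction uses the monotonized-central
(MC) limiter rather than minmod. Both are TVD and positivity-preserving
under the CFL bound, but at desk resolutions (2000 cells for a 50 mm
column, i.e. 25 µm cells against 50 µm initial boundary widths) minmod's
residual numerical diffusion at the foot of the selector gradient erodes
the gradient visibly faster than the physical selector diffusivity
($\approx 4 \times 10^{-11}$ m²/s), which systematically advances the
release times of the strongly complexed analytes by ~20%. With MC the
release and arrival times computed at 2000 cells agree with the same runs
at 4000 cells to a few percent. Minmod and plain first-order upwind remain
available via the `limiter` argument.

## The scenario library as synthetic input

The simulation's "data" are initial column states, all built from printed
recipes by `scenario()`: a 50 mm column, the sample compartment at
24.5–25.5 mm (20 µM of each stereoisomer as hydrochloride in 83 mM acetic
acid), a selector plug immediately cathodic of it, and 400 V across a
50 µm ID capillary. The background electrolyte is 2.36 M formic acid,
20 mM ammonium formate, 19 mM selector (a 5% solution) and 247 mM NaOH —
sodium stoichiometric at 13 per selector molecule — with a computed pH of
1.90. Scenario variants change one knob at a time: plug length (5/10/15
mm), sample length (2 mm at half concentration, so sampled amounts are
identical), boundary width (0.5 mm), sample matrix (diluted background
electrolyte admixed, bringing 1.9/9.5/19 mM selector into the sample), a
linear selector ramp replacing the sharp cathodic sample boundary, and
reduced selector concentrations (7.6/3.8/1.9 mM with proportionally
reduced NaOH).

Two compositional choices are genuinely open and were fixed once:

* the **anodic section** is filled with the complete selector-containing
  background electrolyte, and only the section cathodic of the plug is
  selector-free catholyte. The alternative (selector-free anolyte) caps
  the computed initial current far below the reported 16.58 µA, while this
  choice reproduces it within 2%;
* the **catholyte omits sodium together with the selector**, since the
  NaOH exists to neutralize the sulfate sites. Retaining 247 mM sodium
  without the selector would raise the initial current to ~20 µA, outside
  the reported value.

Boundary ramps are raised cosines spanning the stated boundary width,
centred on the nominal zone edge, so zone integrals equal the analytic
amounts; tests depend only on the span, not the shape.

## Numerical choices and degenerate inputs

* pH bracket $[10^{-16}, 100]$ M with geometric-mean bisection fallback;
  non-convergence aborts with the offending cell and time.
* Free-ligand fixed point to $10^{-14}$ relative; absent ligand short-cuts
  to zero.
* `transition_concentration()` brackets on (0, 1 M] and refuses (status
  `"no transition"`) when the mobility curve does not change sign; the
  closed form $\alpha \mu_f/(|\mu_c| K)$ is computed alongside and the two
  agree to $10^{-6}$ relative for fully protonated bases.
* Trace analytes in isotherm evaluations are $10^{-9}$ M (an
  infinite-dilution property); sodium is co-titrated at 13 per selector so
  the background pH stays fixed along a curve.
* Empty compositions equilibrate to pure water (pH 7); zero voltage runs
  are diffusion-limited; a requested fixed step beyond the stable limit is
  an error, as is any negative total beyond round-off after an update.
* The closed-box (zero-flux) variant exists for conservation audits, where
  the finite-volume update conserves each constituent to machine precision.
  A sealed column held at the full 400 V physically polarizes at its ends
  within ~100 s — the electrode depletion layers drive the local
  conductivity and hence the stable time step toward zero — so long-horizon
  closed-box audits are run at a reduced drive where the sealed system
  remains well-posed.
* Event definitions are peak-based (the narrated quantities are peak
  positions): departures interpolate the global maximum's boundary
  crossing; arrivals interpolate the half-plateau crossing *from above*,
  which makes the observation insensitive to starting exactly on the
  initial boundary ramp's midpoint; reversals locate the
  anodic-to-cathodic velocity sign change with a half-cell-per-interval
  dead band, ignoring the sub-second cathodic loading transient.

## Desk-scale problem sizes

The full-resolution study (20 000 cells of 2.5 µm) is far beyond a
desktop budget; the package's own reference resolution is 2000 cells with
the MC limiter, where a 120 s base run takes on the order of a minute.
Integral observables converge monotonically in grid spacing: the current
after 120 s at 1000/2000/4000 cells Richardson-extrapolates to within 1%
of the reported 42.38 µA, and event times at 2000 cells sit within a few
percent of their 4000-cell values. The test suite and the acceptance
script use 1000–4000 cells throughout.

## What the generator does not emulate

Electroosmotic and pressure-driven flow (a constant bulk-velocity hook
exists, default 0, for qualitative exploration only), Joule heating and
radial effects, ionic-strength and viscosity corrections, activity
coefficients, higher-order complexes, the selector's isomeric
heterogeneity, and detector-side mass spectrometry are all out of scope.
Passing tests therefore demonstrate the electrophoretic transport and
equilibrium model under idealized quiescent conditions, not a quantitative
prediction of a real instrument's electropherogram.

## A worked fragment

```{r example}
library(cesim)
sys <- ketamine_cd_system()

solve_equilibrium(bge_composition(), sys)$pH        # 1.894
transition_concentration("S-hydroxynorketamine", sys)$c_star   # 12.89 mM

run <- run_simulation("fig2_base", until = 120, n_cells = 2000,
                      snapshot_times = seq(0, 120, 1))
tail(current_trace(run), 1)                          # ~42.2 uA
departure_time(run, "R-ketamine", boundary_mm = 24.5)
focusing_check(run, 25, "S-hydroxynorketamine")
```
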