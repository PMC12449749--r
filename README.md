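# cesim

Dynamic one-dimensional simulation of chiral capillary electrophoresis with
a highly sulfated cyclodextrin selector in partial-filling mode.

## The problem

Enantioselective CE–MS assays for ketamine and its metabolites
(norketamine, hydroxynorketamine) use a polyanionic chiral selector,
highly sulfated γ-cyclodextrin (HS-γ-CD), at concentrations where all six
stereoisomers bind so strongly that they migrate *anionically* — away from
the cathodic detector. The assays work anyway, because only part of the
column is filled with selector. `cesim` is for separation scientists who
want to understand and optimize such systems: it simulates the coupled
electromigration–diffusion dynamics of every buffer constituent and
analyte, resolving the selector gradient that forms at the sample's
cathodic edge, the transient *focusing* of each enantiomer at the position
where its effective mobility vanishes, and the eventual release of weakly
complexed analytes toward the detector.

## The model in brief

Each weak base binds the selector 1:1; its effective mobility at free
selector concentration $c_L$ is

$$\mu_\mathrm{eff} = \frac{\mu_f + \mu_c K c_L}{1 + K c_L},$$

which crosses zero at $c^* = \alpha\mu_f/(|\mu_c| K)$. In a spatial
selector gradient an analyte accumulates where $c_L = c^*$ (gradient
focusing). The transported unknowns are constituent analytical totals;
every grid cell is kept at acid–base + complexation equilibrium under
electroneutrality (charge-balance pH solve, free-ligand fixed point), the
electric field follows from series resistance at constant voltage, and
fluxes sum electromigration (upwind, slope-limited second order) and
Nernst–Einstein diffusion for every form — free ion, neutral form, and
complex, the latter feeding both the analyte's and the ligand's continuity
equation. See the vignette (`vignettes/chiral-partial-filling.Rmd`) for
assumptions, parameter defaults, and numerical choices.

## Worked example

```r
library(cesim)
sys <- ketamine_cd_system()     # packaged mobility/pKa/K parameter table

# the selector background electrolyte: 2.36 M formic acid, 20 mM ammonium
# formate, 19 mM selector, 247 mM NaOH
solve_equilibrium(bge_composition(), sys)$pH
#> [1] 1.894636

# selector concentration at which S-hydroxynorketamine stands still
transition_concentration("S-hydroxynorketamine", sys)$c_star
#> [1] 12.88637      # mM; R enantiomer: 16.15 mM

# the base partial-filling run: 50 mm column, sample at 24.5-25.5 mm,
# 15 mm selector plug, 400 V
run <- run_simulation("fig2_base", until = 120, n_cells = 2000,
                      snapshot_times = seq(0, 120, 1))
range(current_trace(run)$I_uA)
#> [1] 16.33328 42.21025    # the current climbs as the sample zone clears

departure_time(run, "R-ketamine", boundary_mm = 24.5)
#> <ce_event> departure of R-ketamine at 45.1 s (24.5 mm): ...

focusing_check(run, 25, "S-hydroxynorketamine")
#> $position_mm  25.49
#> $local_selector_mM 13.28   # within 3% of this enantiomer's c* = 12.89
```

The numbers mean: the initial current (16.3 µA) is set by the low-
conductivity sample zone; it rises to ~42 µA as chloride and the sample
matrix clear. Ketamine, the strongest binder, is released from the
focusing gradient toward the anode at ~45 s and is lost for cathodic
detection, while the hydroxynorketamine enantiomers stay focused at their
transition concentrations inside the selector gradient until the selector
boundary itself reaches the sample compartment.

A thin command-line front end wraps the same functions:

```sh
Rscript inst/cli/cesim scenarios list
Rscript inst/cli/cesim simulate fig2_base --cells 2000 --until 120 --out out/
Rscript inst/cli/cesim isotherm --analyte S-hydroxynorketamine --out iso.csv
```

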