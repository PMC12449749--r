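# Packaged partial-filling scenario library. All scenarios share a 50 mm
# column at 400 V in a 50 um ID capillary, with the sample compartment
# centred at 25 mm and a selector plug immediately cathodic of it, the
# anodic section filled with the selector-containing BGE and the section
# cathodic of the plug with selector-free catholyte. Fields not given
# inherit the defaults.
defaults:
  cd_mM: 19.0          # selector concentration in the BGE / plug
  naoh_mM: null        # null -> stoichiometric 13 x cd
  plug_mm: 15.0        # selector plug length cathodic of the sample
  sample_mm: 1.0       # sample compartment length
  analyte_uM: 20.0     # per stereoisomer, as hydrochloride
  acetic_mM: 83.0
  sample_bge_fraction: 0.0
  boundary_mm: 0.05    # sample-BGE boundary width
  other_boundary_mm: 0.05
  gradient_mm: 0.0     # linear selector ramp span at the cathodic sample edge
  voltage: 400.0
  diameter_um: 50.0
  column_mm: 50.0
  duration_s: 120.0
scenarios:
  fig2_base:
    description: base configuration, 15 mm selector plug
  cd_plug_5mm:
    plug_mm: 5.0
    duration_s: 120.0
    description: 5 mm selector plug
  cd_plug_10mm:
    plug_mm: 10.0
    duration_s: 100.0
    description: 10 mm selector plug
  sample_2mm:
    sample_mm: 2.0
    analyte_uM: 10.0
    duration_s: 180.0
    description: 2 mm sample at half analyte concentration (equal amounts)
  shallow_gradient:
    gradient_mm: 4.0
    duration_s: 180.0
    description: shallow selector gradient at the cathodic sample edge
  wide_boundaries_0p5mm:
    boundary_mm: 0.5
    duration_s: 60.0
    description: 0.5 mm sample-BGE boundary widths
  matrix_bge_1to10:
    sample_bge_fraction: 0.1
    duration_s: 60.0
    description: sample in ten-fold diluted BGE (1.9 mM selector)
  matrix_bge_1to2:
    sample_bge_fraction: 0.5
    duration_s: 60.0
    description: sample in two-fold diluted BGE (9.5 mM selector)
  matrix_bge_full:
    sample_bge_fraction: 1.0
    duration_s: 60.0
    description: sample in undiluted BGE (19 mM selector)
  cd_2pct:
    cd_mM: 7.6
    naoh_mM: 98.8
    duration_s: 130.0
    description: 2% selector solution
  cd_1pct:
    cd_mM: 3.8
    naoh_mM: 49.4
    duration_s: 120.0
    description: 1% selector solution
  cd_0p5pct:
    cd_mM: 1.9
    naoh_mM: 24.7
    duration_s: 120.0
    description: 0.5% selector solution
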