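# Constituent and 1:1 complexation parameters for the ketamine /
# HS-gamma-CD partial-filling system. Mobilities in 1e-8 m2/(V s)
# (magnitudes; the fully charged form for the selector), pKa in log10
# units (per site for the selector), K in 1/M, complex mobilities signed.
constants:
  temperature: 298.15
  water_ion_product: 1.0e-14
  h_mobility: 3.625e-7
  oh_mobility: 2.055e-7
constituents:
- name: formic
  kind: weak-acid
  mobility_e8: 5.66
  pKa: 3.75
- name: acetic
  kind: weak-acid
  mobility_e8: 4.42
  pKa: 4.76
- name: sodium
  kind: weak-base
  mobility_e8: 5.19
  pKa: 13.70
- name: chloride
  kind: weak-acid
  mobility_e8: 7.91
  pKa: -2.00
- name: ammonia
  kind: weak-base
  mobility_e8: 7.62
  pKa: 9.25
- name: hs-g-cd
  kind: multi-site-anion
  mobility_e8: 2.00
  pKa: -3.00
  site_count: 13
- name: S-ketamine
  kind: weak-base
  mobility_e8: 2.50
  pKa: 7.50
- name: R-ketamine
  kind: weak-base
  mobility_e8: 2.50
  pKa: 7.50
- name: S-norketamine
  kind: weak-base
  mobility_e8: 2.50
  pKa: 6.65
- name: R-norketamine
  kind: weak-base
  mobility_e8: 2.50
  pKa: 6.65
- name: S-hydroxynorketamine
  kind: weak-base
  mobility_e8: 2.50
  pKa: 6.65
- name: R-hydroxynorketamine
  kind: weak-base
  mobility_e8: 2.50
  pKa: 6.65
complexation:
- {analyte: S-ketamine,           ligand: hs-g-cd, K: 579.0, complex_mobility_e8: -1.34}
- {analyte: R-ketamine,           ligand: hs-g-cd, K: 554.3, complex_mobility_e8: -1.26}
- {analyte: S-norketamine,        ligand: hs-g-cd, K: 482.7, complex_mobility_e8: -0.97}
- {analyte: R-norketamine,        ligand: hs-g-cd, K: 467.6, complex_mobility_e8: -0.86}
- {analyte: S-hydroxynorketamine, ligand: hs-g-cd, K: 200.0, complex_mobility_e8: -0.97}
- {analyte: R-hydroxynorketamine, ligand: hs-g-cd, K: 180.0, complex_mobility_e8: -0.86}
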