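# Default perturbation scenarios for the Medicago S/G lignin screen.
# Values tagged provenance: placeholder are shipped defaults only; replace
# them with the observed values from your transgenic dataset for literal
# reproduction of a screen against real data.
rho_wt: 0.5
rho_provenance: placeholder
scenarios:
  CCoAOMT_down:
    multipliers:
      CCoAOMT: 0.24    # activity reduced ~4.2-fold
    observed_sg: 0.75
    provenance: placeholder
  COMT_down:
    multipliers:
      COMT: 0.1
    observed_sg: 0.05
    provenance: placeholder
  ccr1_ko:
    multipliers:
      CCR1: 0.05       # knockout as small residual activity
    direction: down
    provenance: literature
  ccr2_ko:
    multipliers:
      CCR2: 0.05
    hierarchical_multipliers:
      CCR1: 1.5
      CCoAOMT: 1.5
    direction: up
    provenance: literature
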