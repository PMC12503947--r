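# Reduced-scale two-type competition: a stiff mutant colony embedded in
# wild-type tissue.  Per-type blocks use reference units (areas in mean
# sizer areas, times in mean timer periods); everything omitted takes the
# package defaults.
domain: 300
horizon_tau0: 24
colony_radius: 105
mode: central_colony
A0: 1300
seed: 1
potts:
  kT: 10
  nneigh: 8
types:
  A:
    lam: 2.0
contact_energies:
  JAA: 2.39e-4
  JBB: 1.15e-4
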