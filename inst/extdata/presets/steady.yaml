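# Stable pre-oscillation operation at feed 88 g/L, dilution 0.048 1/h:
# near-complete glycerol consumption, 1,3-PDO 40.66 g/L, butyrate
# 10.02 g/L, other byproducts low. All channels constant (zero amplitude).
name: steady
D: 0.048
D_G: 0.3
S_f: 88
period_h: 52
damping_rate: 0
noise_cv: 0.02
seed: 7
ref_channel: X
t_grid: {from: 0, to: 90, by: 3}
channels:
  X:        {kind: biomass,   unit: g/L,    level_min: 3.0,   level_max: 3.0}
  glycerol: {kind: substrate, unit: g/L,    level_min: 0.8,   level_max: 0.8}
  PDO:      {kind: product,   unit: g/L,    level_min: 40.66, level_max: 40.66}
  butyrate: {kind: product,   unit: g/L,    level_min: 10.02, level_max: 10.02}
  acetate:  {kind: product,   unit: g/L,    level_min: 1.8,   level_max: 1.8}
  lactate:  {kind: product,   unit: g/L,    level_min: 4.26,  level_max: 4.26}
  formate:  {kind: product,   unit: g/L,    level_min: 2.60,  level_max: 2.60}
  H2:       {kind: gas,       unit: mmol/L, level_min: 1.0,   level_max: 1.0}
  CO2:      {kind: gas,       unit: mmol/L, level_min: 10.0,  level_max: 10.0}
  ORP:      {kind: direct,    unit: mV,     level_min: -400,  level_max: -400}
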