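# Non-oscillatory operation at the doubled dilution rate (0.096 1/h, feed
# 88 g/L): most glycerol still consumed but no oscillation develops. All
# channels constant.
name: no_oscillation
D: 0.096
D_G: 0.3
S_f: 88
period_h: 52
damping_rate: 0
noise_cv: 0.02
seed: 7
ref_channel: X
t_grid: {from: 0, to: 200, by: 3}
channels:
  X:        {kind: biomass,   unit: g/L,    level_min: 2.8,  level_max: 2.8}
  glycerol: {kind: substrate, unit: g/L,    level_min: 1.5,  level_max: 1.5}
  PDO:      {kind: product,   unit: g/L,    level_min: 38.0, level_max: 38.0}
  butyrate: {kind: product,   unit: g/L,    level_min: 9.0,  level_max: 9.0}
  acetate:  {kind: product,   unit: g/L,    level_min: 2.0,  level_max: 2.0}
  lactate:  {kind: product,   unit: g/L,    level_min: 5.0,  level_max: 5.0}
  formate:  {kind: product,   unit: g/L,    level_min: 2.0,  level_max: 2.0}
  H2:       {kind: gas,       unit: mmol/L, level_min: 1.0,  level_max: 1.0}
  CO2:      {kind: gas,       unit: mmol/L, level_min: 12.0, level_max: 12.0}
  ORP:      {kind: direct,    unit: mV,     level_min: -420, level_max: -420}
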