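# Damped oscillation at the reduced feed concentration (44 g/L, dilution
# 0.048 1/h): the oscillation triggers but cannot sustain; the amplitude
# envelope decays at 0.012 1/h (half-life ~58 h, about 1.1 cycles) toward
# the channel midlines. Same cycle geometry as the sustained preset at
# roughly half the amplitude.
name: damped
D: 0.048
D_G: 0.3
S_f: 44
period_h: 52
damping_rate: 0.012
noise_cv: 0.02
seed: 7
ref_channel: X
t_grid: {from: 0, to: 260, by: 3}
channels:
  X:        {kind: biomass,   unit: g/L,    level_min: 0.3,  level_max: 2.0,
             rise_h: 20, phase_offset_h: 0}
  glycerol: {kind: substrate, unit: g/L,    level_min: 2.0,  level_max: 28.0,
             rise_h: 32, phase_offset_h: -20}
  PDO:      {kind: product,   unit: g/L,    level_min: 10.0, level_max: 24.0,
             rise_h: 20, phase_offset_h: 0}
  butyrate: {kind: product,   unit: g/L,    level_min: 2.5,  level_max: 7.0,
             rise_h: 20, phase_offset_h: 0}
  acetate:  {kind: product,   unit: g/L,    level_min: 0.8,  level_max: 2.5,
             rise_h: 20, phase_offset_h: 0}
  lactate:  {kind: product,   unit: g/L,    level_min: 0.5,  level_max: 4.0,
             rise_h: 28, phase_offset_h: 16}
  formate:  {kind: product,   unit: g/L,    level_min: 0.5,  level_max: 3.0,
             rise_h: 28, phase_offset_h: 16}
  H2:       {kind: gas,       unit: mmol/L, level_min: 0.05, level_max: 1.3,
             rise_h: 26, phase_offset_h: 16}
  CO2:      {kind: gas,       unit: mmol/L, level_min: 1.5,  level_max: 11.0,
             rise_h: 10, phase_offset_h: -10}
  ORP:      {kind: direct,    unit: mV,     level_min: -550, level_max: -320,
             rise_h: 40, phase_offset_h: -10}
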