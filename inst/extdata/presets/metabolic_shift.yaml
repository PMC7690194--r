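# Pre-oscillation metabolic shift (119-146 h of the reference run): while
# residual glycerol stays low, lactate more than doubles from 4.26 to a
# peak of 9.07 g/L and formate rises from 2.60 to 3.34 g/L, while biomass,
# 1,3-PDO, butyrate and acetate decline somewhat. Modelled as one 27-h
# half-cycle: rising channels climb their flank over the window, declining
# channels descend theirs.
name: metabolic_shift
D: 0.048
D_G: 0.3
S_f: 88
period_h: 54
damping_rate: 0
noise_cv: 0.02
seed: 7
ref_channel: X
t_grid: {from: 119, to: 146, by: 3}
channels:
  X:        {kind: biomass,   unit: g/L,    level_min: 2.6,   level_max: 3.0,
             rise_h: 27, phase_offset_h: -27}
  glycerol: {kind: substrate, unit: g/L,    level_min: 0.8,   level_max: 0.8}
  PDO:      {kind: product,   unit: g/L,    level_min: 36.0,  level_max: 40.66,
             rise_h: 27, phase_offset_h: -27}
  butyrate: {kind: product,   unit: g/L,    level_min: 8.5,   level_max: 10.02,
             rise_h: 27, phase_offset_h: -27}
  acetate:  {kind: product,   unit: g/L,    level_min: 1.5,   level_max: 1.8,
             rise_h: 27, phase_offset_h: -27}
  lactate:  {kind: product,   unit: g/L,    level_min: 4.26,  level_max: 9.07,
             rise_h: 27, phase_offset_h: 0}
  formate:  {kind: product,   unit: g/L,    level_min: 2.60,  level_max: 3.34,
             rise_h: 27, phase_offset_h: 0}
  H2:       {kind: gas,       unit: mmol/L, level_min: 1.0,   level_max: 1.0}
  CO2:      {kind: gas,       unit: mmol/L, level_min: 10.0,  level_max: 10.0}
  ORP:      {kind: direct,    unit: mV,     level_min: -400,  level_max: -400}
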