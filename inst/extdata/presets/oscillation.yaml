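# Sustained limit-cycle oscillation at the reference operating point
# (glycerol feed 88 g/L, dilution rate 0.048 1/h). Cycle geometry: 52-h
# period split into a 20-h rising stage (stage I) and a 32-h falling stage
# (stage II); lactate, formate and H2 peak mid stage II (+16 h after the
# biomass peak), CO2 and ORP lead (peak mid stage I), glycerol mirrors
# biomass. Gas extrema: H2 2.47 / 0.07 mmol/L, CO2 maximum 21.98 mmol/L;
# ORP swings between -271 and -568 mV. The gas-phase dilution rate is an
# assumption (never reported) and must always be explicit.
name: oscillation
D: 0.048        # 1/h
D_G: 0.3        # 1/h, assumed
S_f: 88         # g/L
period_h: 52
damping_rate: 0
noise_cv: 0.02
seed: 42
ref_channel: X
t_grid: {from: 0, to: 290, by: 3}
channels:
  X:        {kind: biomass,   unit: g/L,    level_min: 0.4,  level_max: 3.6,
             rise_h: 20, phase_offset_h: 0}
  glycerol: {kind: substrate, unit: g/L,    level_min: 3.0,  level_max: 55.0,
             rise_h: 32, phase_offset_h: -20}
  PDO:      {kind: product,   unit: g/L,    level_min: 20.0, level_max: 50.0,
             rise_h: 20, phase_offset_h: 0}
  butyrate: {kind: product,   unit: g/L,    level_min: 5.0,  level_max: 13.0,
             rise_h: 20, phase_offset_h: 0}
  acetate:  {kind: product,   unit: g/L,    level_min: 1.2,  level_max: 4.0,
             rise_h: 20, phase_offset_h: 0}
  lactate:  {kind: product,   unit: g/L,    level_min: 1.0,  level_max: 6.0,
             rise_h: 28, phase_offset_h: 16}
  formate:  {kind: product,   unit: g/L,    level_min: 0.5,  level_max: 3.4,
             rise_h: 28, phase_offset_h: 16}
  H2:       {kind: gas,       unit: mmol/L, level_min: 0.07, level_max: 2.47,
             rise_h: 26, phase_offset_h: 16}
  CO2:      {kind: gas,       unit: mmol/L, level_min: 2.0,  level_max: 21.98,
             rise_h: 10, phase_offset_h: -10}
  ORP:      {kind: direct,    unit: mV,     level_min: -568, level_max: -271,
             rise_h: 40, phase_offset_h: -10}
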