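# chemosc

Analysis toolkit for spontaneous metabolic oscillations of *Clostridium
butyricum* during long-term continuous fermentation of glycerol to
1,3-propanediol (1,3-PDO). Under glycerol-limited operation at low dilution
rates the culture oscillates with a period of about two days: biomass,
residual glycerol, every product, the dissolved gases H₂/CO₂ and the redox
state of the broth all swing together, with lactate, formate and H₂ lagging
the rest of the metabolism and CO₂ leading it. `chemosc` is for
fermentation scientists and bioprocess engineers who need to quantify such
behaviour from bioreactor time series — and to know how well their
estimators work, which a built-in, mass-balance-consistent synthetic data
generator with retained ground truth makes testable.

## What it computes

**Chemostat kinetics.** Specific rates from the constant-volume chemostat
mass balances, with local-polynomial derivative estimation on noisy
(possibly irregular) grids:

```
mu    = (1/X) dX/dt + D
q_s   = (1/X) (D*S_f - D*C_S - dC_S/dt)        [g/(g h)]
q_P   = (1/X) (dC_P/dt + D*C_P)                [g/(g h)]
q_gas = (1/X) (dC_gas/dt + D_G*C_gas)          [mmol/(g h)]
```

**Oscillation geometry.** Prominence-filtered extrema; peak-to-peak period
with an autocorrelation cross-check; biomass-defined cycle segmentation
into the growth rising stage (stage I) and falling stage (stage II);
per-cycle extrema with phase positions; circular phase lags between
channels; peaks-per-cycle counts for bimodal rate waveforms; and
sustained / damped / none regime classification via an amplitude half-life
criterion.

**Redox.** Linear calibration of the NAD⁺/NADH enzymatic cycling assay
(slope vs 0.01–0.05 mM standards), sample quantification with QC flags,
NAD⁺/NADH ratio series, formate dehydrogenase activity from A340 slopes,
and ORP summaries through the same cycle statistics as the metabolites.

**Expression.** TPM quantification, trimmed-mean-of-M-values (TMM)
normalisation, pseudocounted fold changes, a differential filter at the
study thresholds (adjusted p < 0.001, |log2FC| ≥ 1), and classification of
genes into the two opposite oscillation-phase patterns (type I: maximum in
the rising stage; type II: the mirror).

**Genome.** Assembly summaries from FASTA: scaffold count, total length,
N50 (first-cumulative-≥-half convention) and GC content.

## Worked example

```r
library(chemosc)
report <- run_full_pipeline("oscillation", seed = 42, noise_cv = 0.02)
print(report$oscillation)
```

```
oscillation_summary: regime 'sustained' (reference X)
  mean period 52.0 h over 4 cycle(s)
  X         max    3.652 +/- 0.060  min    0.405 +/- 0.013  lag +0.0 h
  glycerol  max   54.234 +/- 0.525  min    3.099 +/- 0.132  lag -20.2 h
  PDO       max   50.420 +/- 0.400  min   20.139 +/- 0.552  lag -0.7 h
  butyrate  max   13.036 +/- 0.150  min    4.972 +/- 0.121  lag -1.5 h
  acetate   max    3.970 +/- 0.109  min    1.211 +/- 0.023  lag -0.7 h
  lactate   max    6.100 +/- 0.136  min    1.003 +/- 0.026  lag +15.0 h
  formate   max    3.425 +/- 0.069  min    0.513 +/- 0.002  lag +16.5 h
  H2        max    2.467 +/- 0.057  min    0.076 +/- 0.005  lag +14.3 h
  CO2       max   21.641 +/- 0.557  min    2.122 +/- 0.140  lag -10.5 h
  ORP       max -266.691 +/- 4.386  min -572.975 +/- 11.378  lag -10.5 h
```

Reading this: the simulated culture oscillates in a sustained limit cycle
with a 52-h mean period over 4 analysed cycles. Biomass (X) is the phase
reference. 1,3-PDO, butyrate and acetate peak with biomass; lactate,
formate and H₂ peak ~15–16 h later (mid stage II); glycerol mirrors
biomass, and CO₂ and the ORP probe lead by ~10 h (peaking mid stage I).
Per-cycle H₂ extrema average 2.47 and 0.08 mmol/L, the CO₂ maximum
21.6 mmol/L, and ORP swings between about −267 and −573 mV — the broth
moving from an oxidised state in the growth rising stage to a reduced
state as growth collapses.

The numbered scripts under `analysis/` walk the same pipeline step by
step (simulation → kinetics → oscillation → redox → expression → genome
statistics) and write their tables under `results/`.

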