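---
title: "Analysing metabolic oscillations in continuous glycerol fermentation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Analysing metabolic oscillations in continuous glycerol fermentation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

*Clostridium butyricum* converts glycerol to 1,3-propanediol (1,3-PDO) in
continuous culture. Under glycerol-limited operation at low dilution rates
the culture can fall into spontaneous, sustained metabolic oscillations:
biomass, residual glycerol, every product, the dissolved gases and the
redox state of the broth all swing with a period of roughly two days.
`chemosc` packages the quantitative analyses such a dataset needs —
specific-rate kinetics, oscillation geometry, redox quantification,
oscillation-phase expression patterns, assembly statistics — together with
a synthetic data generator that emulates the bioreactor so every estimator
can be validated against retained ground truth.

## The chemostat balances

All kinetics derive from the standard constant-volume chemostat mass
balances. With dilution rate $D$ (h$^{-1}$), gas-phase dilution rate $D_G$
(h$^{-1}$) and feed concentration $S_f$ (g/L):

$$\mu = \frac{1}{X}\frac{dX}{dt} + D, \qquad
  q_s = \frac{1}{X}\left(D S_f - D C_S - \frac{dC_S}{dt}\right),$$
$$q_P = \frac{1}{X}\left(\frac{dC_P}{dt} + D C_P\right), \qquad
  q_{gas} = \frac{1}{X}\left(\frac{dC_{gas}}{dt} + D_G C_{gas}\right).$$

Units: $\mu$ in h$^{-1}$, $q_s$ and $q_P$ in g/(g·h), $q_{gas}$ in
mmol/(g·h). At steady state these reduce to the identities $\mu = D$,
$q_P = D C_P / X$ and $q_s = D (S_f - C_S)/X$, which the test suite checks
exactly. The substrate balance is occasionally printed elsewhere with a
$(dX/dt)\,C_S$ term; that term has units g$^2$/(L$^2$·h) and cannot be
added to $D S_f$, so `specific_substrate_uptake()` implements the
dimensionally consistent form above (reading the stray term as a slip for
$D C_S$).

Two practical notes. $D_G$ is a property of the off-gas measurement setup
and is rarely reported; it has no package default and must always be
supplied. And the derivative terms need an estimation scheme the source
data never dictates: `estimate_derivative()` fits a local degree-2
polynomial over a moving window of the nearest samples *in time* (so
irregular grids are handled naturally), defaulting to a 5-sample window;
on a uniform grid with a 3-sample window it reduces to central
differences. Points where biomass falls below `x_min` (default $10^{-3}$
g/L) are masked rather than divided by.

## Oscillation geometry

Cycles are defined on the biomass channel, matching the growth-centric
stage convention: stage I is the rising flank (trough to peak), stage II
the falling flank (peak to trough), and the two durations sum to the
trough-to-trough interval by construction. On top of that:

* `detect_extrema()` finds alternating peaks/troughs with a prominence
  floor, default 20% of the channel range; equal-height ties resolve to
  the earliest time.
* `detect_period()` averages peak-to-peak intervals (peak times refined
  off-grid by a local parabola), excludes cycles deviating more than 30%
  from the running median — irregular stretches occur in real runs and
  the reported mean period excludes them; the exact exclusion rule being
  unstated, the 30% rule is this package's choice — and cross-checks
  against the first autocorrelation maximum, warning at >20% disagreement.
* `cycle_statistics()` reports per-cycle extrema with phase positions in
  $[0,1)$ from the stage-I trough; the stage boundary sits at
  stage-I-duration/period.
* `phase_lag()` takes the circular mean of per-cycle peak-time differences,
  folded into $(-T/2, T/2]$.
* `classify_regime()` labels a channel `none`, `damped` or `sustained`.
  The damped/sustained cut is an amplitude half-life of 3 mean periods,
  fitted by regressing log peak amplitude on peak time: damped bioreactor
  runs lose their oscillation within a few cycles, and no quantitative
  criterion is reported, so the threshold is a package design choice
  (tests exercise both sides of the boundary). A relative-amplitude floor
  (range below 20% of the median level) keeps measurement noise on a flat
  channel from being read as oscillation; a genuine oscillation that small
  around a large offset would be missed, which we accept.

## The synthetic generator

The generator is the package's study-condition encoding, not a dial. Each
channel is parametrized as a smooth periodic waveform at the
*concentration* level: a rising flank over `rise_fraction` of the period
and a falling flank over the remainder, between `level_min` and
`level_max`, peaking `phase_offset_h` hours after the biomass peak. The
specific-rate ground truth is then *derived analytically* by inverting the
balances above, and those rates force a real `deSolve` integration
(`lsoda`, relative tolerance $10^{-8}$) whose solution reproduces the
configured concentrations. This inversion — rather than hand-tuning rate
waveforms until the concentrations look right — is what makes the
generator mass-balance consistent by construction and the printed
concentration extrema directly configurable.

The flanks are quintic Hermite segments with zero slope and *matched
curvature* at both extrema, making the waveform C$^2$ across the whole
cycle. The smoothness matters: a curvature jump at the biomass trough
(as a raised-cosine template would have) biases any finite-difference
derivative by $O(h)$ exactly where $X$ is smallest, and would defeat the
sub-1% rate-recovery validation. A side benefit is plateau-like shoulders
on the slow flank, similar to the short platform stages real rate curves
show after their peaks.

Presets live as YAML files under `inst/extdata/presets/` so every
study-facing number is version-controlled data, not code:

* **oscillation** — feed 88 g/L, $D = 0.048$ h$^{-1}$. Period 52 h with a
  20 h stage I and 32 h stage II. The reported stage durations (20–22 h
  and 32–41 h) sum to at least 52 h and therefore cannot coexist with the
  reported 51-h mean period; 52 h with a 20/32 split keeps both stages
  inside their reported ranges while staying within 2% of the reported
  mean. Lactate, formate and H$_2$ peak 16 h after biomass (mid stage
  II); CO$_2$ and the ORP probe lead (peaks mid stage I); glycerol
  mirrors biomass (60 → 3 g/L scale). Gas extrema encode the reported
  2.47/0.07 mmol/L (H$_2$) and 21.98 mmol/L (CO$_2$); ORP swings between
  −271 and −568 mV.
* **steady** — the stable pre-oscillation phase: constant channels at
  1,3-PDO 40.66 g/L, butyrate 10.02 g/L.
* **damped** — feed 44 g/L; amplitude envelope $e^{-0.012 t}$ (half-life
  ≈ 58 h ≈ 1.1 cycles, safely inside the 3-period damping criterion).
* **no_oscillation** — $D = 0.096$ h$^{-1}$, constant channels.
* **metabolic_shift** — the 27-h pre-oscillation upshift: lactate climbs
  4.26 → 9.07 g/L, formate 2.60 → 3.34 g/L, biomass and the main products
  decline mildly.

Assumptions worth stating: the sampling interval (3 h) and the biomass
levels (0.4–3.6 g/L) are not reported and are this package's realistic
choices; $D_G = 0.3$ h$^{-1}$ is likewise an assumption. Measurement
noise is multiplicative with a configurable CV (default 0.02; replicate
draws of a point reproduce the CV, which a Monte-Carlo test checks).

Because $\mu(t)$ is prescribed, the biomass equation is homogeneous: a
biomass offset in the initial state never decays (it permanently rescales
the biomass trajectory), while product offsets wash out at rate $D$. The
default initial state is therefore the on-cycle state at the first grid
point; batch-style starts can be passed explicitly via `state0`, and the
first simulated cycle is excluded from all recovery statistics as a
transient by convention (`post_transient_window()`).

What the generator deliberately does not emulate: mechanistic feedback
(the oscillation's cause), so the phase structure is imposed rather than
emergent; drifting cycle periods and the mid-run irregular stretches;
channel-correlated measurement error; negative specific rates are allowed
where the configured concentration geometry implies net consumption.
Passing recovery tests therefore show that the *estimators* are unbiased
and noise-robust on data with the reported geometry — not that the
biological mechanism is understood.

## Redox quantification

The enzymatic cycling assay reads NAD$^+$/NADH out as an absorbance slope
(ΔA570/min); `fit_calibration()` fits the slope against standards
(0.01–0.05 mM) by ordinary least squares, retaining the intercept because
the assay has a reagent blank, and `quantify_samples()` inverts it,
clipping and flagging below-blank concentrations and flagging
extrapolation beyond 1.5× the top standard. `nad_ratio()` masks NADH
below $10^{-3}$ mM rather than dividing by a vanishing denominator.
`fdh_activity()` converts an A340 slope into enzyme units with the NADH
extinction coefficient defaulting to 6.22 mM$^{-1}$cm$^{-1}$
(configurable; the assay description leaves it implicit). The unit
definition follows the study's wording (1 mmol NADH per minute).
Per-biomass normalisation of the cofactor pools is deliberately out of
scope: only extract-basis values are reported.

## Expression patterns

`tpm()` is plain transcripts-per-million on annotated gene lengths
(bacterial, unspliced; no effective-length correction). `tmm_factors()`
implements the published trimmed-mean-of-M-values recipe (30% trim on M,
5% on A, inverse-variance weights, factors rescaled to geometric mean 1);
the test suite verifies it against an independent reference
implementation. The differential filter keeps the study's thresholds
(adjusted $p < 0.001$, $|\log_2 FC| \ge 1$) but replaces the original
tool's internal MA-plot statistic — external software, out of scope —
with an exact binomial test of each gene's count split against the
proportion implied by effective library sizes, BH-adjusted; a null
simulation confirms the false-positive rate stays at the alpha level.
Fold changes use a pseudocount of 0.5 (finite fold changes are reported
for near-silent genes without a stated convention, so one is needed).

`classify_pattern()` renormalises each sample column (so calls are
invariant to per-sample rescaling) and labels a gene type I when its
maximum falls in a rising-stage sample and its minimum in a falling-stage
sample with at least `min_fold = 2` between them — the "over two-fold"
phrasing used for the clearest marker genes motivates the default — and
type II for the mirror image. `simulate_counts()` generates the matching
five-sample negative-binomial design (time points 528–567 h, three
falling- and two rising-stage samples) with retained per-gene truth;
recovery exceeds 95% at low dispersion.

## Assembly statistics

`assembly_stats()` reads FASTA via Biostrings and reports scaffold count,
total length, N50 and GC. N50 uses the "first cumulative ≥ half on the
descending sort" convention (assemblers differ on ties; a brute-force
enumeration oracle checks equivalence property-style). Ambiguity codes
count toward total length but are excluded from the GC denominator by
default (`gc_all_bases = TRUE` switches to an all-bases denominator, since
the reporting convention used for the published 28.56% is unstated).
`simulate_assembly()` constructs a synthetic stand-in with exactly
prescribed statistics for validation; it is labelled synthetic throughout
and is not a deposited genome record, which cannot be redistributed here.

## Numerical choices and problem sizes

* ODE integration: `lsoda`, rtol $10^{-8}$, atol $10^{-10}$; states more
  negative than $10^{-6}$ of the initial scale abort with an error.
* Derivatives: window 5, degree 2 by default; validation of the sub-1%
  rate round-trip uses a 0.25-h grid and window 3 (on the 3-h grid the
  finite-difference truncation error, not the estimator, dominates).
* Recovery runs: 5.5 simulated cycles at 3-h sampling, first cycle
  dropped, 3–4 analysed cycles; noise CV 0.02–0.03; seeds fixed in the
  tests. Each run takes well under a minute.
* Expression simulations: 600–3000 genes, five samples, depth 2–3 million.
* Tie-breaks: equal-height extrema take the earliest time; pattern-call
  ties take the first sample.

## Limitations

The generator is phenomenological: it reproduces the reported geometry of
the oscillation, not its cause, so it cannot be used to test mechanistic
hypotheses (pyruvate-node disorder, acetaldehyde accumulation) — only the
measurement pipeline. Period estimation assumes at least two clean peaks;
heavily damped or short series fall back to regime labels without a
period. The DEG filter is a two-library exact test without biological
replication, as in the original design — its p-values describe counting
noise, not biological variance.
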