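# conflictlba

Analysis pipeline for approach–avoid decision-making under motivational
conflict on a linear track, for behavioral neuroscientists working with
tracking data, choice response times, and fiber photometry.

Animals running a track toward a reward that is also dangerous do not
commit to a single policy: they oscillate between the start and the
goal, and the oscillations are punctuated by brief pauses. Each pause
ends in one of two ways — the animal resumes toward the goal
(*approach*) or reverses toward the start (*avoid*) — so each pause is
a discrete, timed decision. This package turns raw tracking traces into
those decisions, models them, and links them to simultaneously recorded
Ca²⁺ signals.

## What it computes

**Microstructure.** Tracking dropouts are repaired by linear
interpolation; each frame is classified as moving toward the goal,
toward the start, or paused (no movement ≥ 90 ms followed by ≥ 1.5 cm
of uninterrupted movement). Pauses on the track proper (0–88 cm, Start
and Goal boxes excluded) become decision events with a location,
duration (RT), and outcome. Pauses collated into 5 cm bins are
clustered (k-means on median location, count, median duration,
% approach; silhouette-scored) into decision zones; defaults place the
boundaries at 15 and 83 cm (start / mid / goal).

**Decision model.** The linear ballistic accumulator (LBA): for each
response option *i*, evidence starts at a point drawn uniformly on
[0, A] and grows linearly at a rate drawn from N(v_i, s), s ≡ 1; the
first accumulator to reach the threshold b = k + A wins, and the
observed RT adds a nondecision time t0. The drift rates are read as
reward salience (approach) and danger salience (avoid); **response
caution** is b − A/2, the average evidence a decision requires.
Densities, defective CDFs, choice probabilities, and a race sampler are
exact and tested against Monte-Carlo, quadrature, and
finite-difference oracles.

**Bayesian estimation.** Per subject × zone, by Hamiltonian Monte
Carlo written for this model (analytic gradients in C++, dual-averaging
step size targeting δ = 0.8, dense mass matrix learned in warmup):
3 chains, warmup 1000 of 2000 iterations, thinning 1. Priors: v ~
TN(2, 1, 0+), A ~ TN(0.5, 1, 0+), k ~ TN(0.5, 1, 0+), t0 ~ U(0, 1).
Convergence is gated on split Gelman–Rubin R̂ < 1.1 and effective
sample size Neff > 100 for every parameter.

**Photometry.** dF/F = (Ca − fitted isosbestic)/fitted isosbestic,
where the fitted isosbestic is the OLS projection of the 405 nm channel
onto the 465 nm channel. Peri-event kernels (−5…+5 s, baselined to
−5…−2.5 s) are bootstrapped across subject means (1000 resamples,
percentile CIs expanded by √(n/(n−1))); a significant transient is a
CI excursion from 0 lasting ≥ 1/3 s.

**Linkage.** Mean pause dF/F per subject × zone is joined with the LBA
estimates; the package reports per-parameter correlations and a
standardized regression of dF/F on the approach and avoid drifts.

A ground-truth-labeled synthetic cohort generator (`simulate_cohort`)
stands in for raw data: bistable track oscillations with LBA-resolved
pauses, and two-channel photometry sharing a multiplicative artifact
with goal-locked transients (PVT-like) or a spatial ramp (vSub-like).

## Worked example

```r
library(conflictlba)
report <- run_pipeline(cohort_config(seed = 11),
                       sampler = sampler_config(seed = 12))
```

Output of this exact call:

```
stage simulate: 8 subjects x 20 trials (seed 11)
stage microstructure: 1609 pauses across 8 subjects
stage lba: 24 fits, 0 skipped
stage photometry: 24 (subject, zone) dF/F aggregates
stage linkage: 24 rows; regression adj R2 = 0.838
```

What the report contains (same run):

- Zone boundaries recovered at 14.1 and 80.6 cm (generative regime
  changes at 15 and 83 cm); mean silhouette 0.49.
- Zone-mean caution: goal 1.02 > start 0.90 > mid 0.82 — more evidence
  is demanded where danger is close, so goal-zone decisions are the
  slowest.
- Mean RT: avoid 0.529 s vs approach 0.405 s — the speed–safety
  trade-off, pooled across the track.
- Standardized regression of pause dF/F on the drifts:
  β(approach) = −0.58, β(avoid) = +0.45, adj R² = 0.84 — goal-locked
  Ca²⁺ activity is high exactly where reward salience collapses and
  danger salience rises.

Each number is recomputed from scratch by the pipeline; seeds make the
run exactly reproducible.

## Command line

```sh
inst/cli/conflictlba simulate --seed 9 --out data/
inst/cli/conflictlba segment --input 'data/tracking_s*.csv' --out out/
inst/cli/conflictlba fit-lba --pauses out/pauses.csv --out out/
inst/cli/conflictlba run-all --seed 9 --out out/
```

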