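---
title: "Models and methods: pause-resolved approach–avoid decisions, LBA inference, and photometry"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's own account of its science: the models
and their assumptions, the tunable constants and why they have the
defaults they do, what the synthetic generator does and does not
emulate, and the numerical choices a maintainer would want written
down. It states no empirical result that the test suite and
`scripts/acceptance.R` do not themselves compute.

## 1. The behavioral model of the task

The apparatus is a 120 cm runway: a 22 cm Start box, 88 cm of track
proper, and a 10 cm Goal box. All analysis uses a one-dimensional
track coordinate with 0 at the Start-box door and increasing toward
the goal; the Start box occupies negative coordinates, the Goal box
coordinates above 88 cm. Only the x-coordinate of the tracked body
center is analyzed; y is carried through but unused.

Under motivational conflict (reward and punishment co-located at the
goal), locomotion is bistable: runs toward the goal alternate with
retreats, interrupted by pauses. The package treats each pause as one
approach–avoid decision:

- **Pause**: no movement for at least 90 ms, followed by at least
  1.5 cm of uninterrupted movement. "No movement" cannot mean zero
  displacement at 30 fps with centroid jitter, so a per-frame
  displacement below 0.2 cm counts as still — well below plausible
  tracking jitter and an order of magnitude below the 1.5 cm movement
  criterion. Configurable (`still_tol`).
- **Uninterrupted movement**: cumulative same-direction displacement
  with no still step; movement runs totaling under 1.5 cm are treated
  as jitter and folded back into the surrounding pause.
- **Outcome**: approach if the resolving movement heads toward the
  goal, avoid if toward the start.
- **RT**: the pause duration, onset to the first frame of the
  resolving movement. Whether a fixed onset component should be
  subtracted is genuinely open; the package equates RT with pause
  duration and leaves any such component to the LBA's nondecision
  time, which absorbs exactly that kind of constant.

Pauses whose median still-phase location falls in the Start or Goal
box are excluded: box dwells include reward consumption and trial
staging, not track decisions.

### Zones

Pauses are collated into 5 cm bins; each non-empty bin contributes
median location, pause count, median duration, and % approach. The
features are z-scored (they live on incommensurate scales) and
clustered by k-means with 50 restarts and a fixed seed; per-bin
silhouette values score the partition. Boundaries are midpoints
between adjacent bins assigned to different clusters; a
non-contiguous solution is reported with a warning rather than
silently reordered. With the defaults the generative cohort yields
three contiguous zones with boundaries near 15 and 83 cm — start,
mid, and goal zones.

## 2. The decision model

The linear ballistic accumulator: for response option $i$ (here
1 = approach, 2 = avoid), evidence starts at $U(0, A)$ and grows
linearly at rate $d_i \sim N(v_i, s)$ until the first accumulator
reaches $b = k + A$; the observed RT adds a nondecision time $t_0$.
$s$ is the scale-fixing constant, 1: multiplying $(v, s, A, k)$ by any
$c > 0$ changes nothing observable (a property the test suite asserts),
so one parameter must be pinned.

Single-accumulator distribution functions have the standard closed
forms in $\Phi$ and $\phi$; the winner-takes-all ("defective") density
of an observed $(c, \mathrm{rt})$ pair is
$f_c(\mathrm{rt}-t_0)\prod_{j \ne c}(1 - F_j(\mathrm{rt}-t_0))$.
**Response caution** is $b - A/2$: threshold minus mean starting
evidence, the average evidence a decision requires.

Numerical choices:

- Arguments of $\Phi, \phi$ are clipped to $\pm 38$; densities are
  floored at $10^{-290}$ before logs.
- $A = 0$ is a separate branch (point start):
  $F(t) = \Phi((v - b/t)/s)$, $f(t) = (b/(s t^2))\,\phi((b/t - v)/s)$,
  avoiding $1/A$ cancellation. For $A$ between 0 and $\sim 10^{-9}$
  the generic formulas remain accurate to about $10^{-6}$ absolute,
  which the tests cover.
- Races in which every drift is negative never terminate. The sampler
  resamples such trials, i.e. it draws from the race *conditioned on
  termination*.

**Conditioning the likelihood.** The common convention leaves the
likelihood as the bare defective density, because real datasets
contain only terminated trials and the correction
$1 - \prod_i \Phi(-v_i/s)$ is negligible when drifts are comfortably
positive. Here the correction is applied (each trial's density is
divided by the termination probability), for a concrete reason: the
validation and acceptance suites draw generating parameters from the
priors, where drifts near zero make the non-termination mass reach
several percent; with the unnormalized likelihood that mismatch is a
real bias and measurably degrades credible-interval coverage. With the
conditioned likelihood the model is exactly the process the sampler
implements, and coverage is calibrated. `sample_posterior(...,
normalize = FALSE)` restores the bare-density convention.

## 3. Bayesian estimation

Priors: $v_i \sim \mathrm{TN}(2, 1, 0^+)$ per option,
$A \sim \mathrm{TN}(0.5, 1, 0^+)$, $k \sim \mathrm{TN}(0.5, 1, 0^+)$,
$t_0 \sim U(0, 1)$ s. Sampler settings: 3 chains, warmup 1000,
iterations 2000, thinning 1, target acceptance $\delta = 0.8$.
Convergence gates: split Gelman–Rubin $\hat R < 1.1$ and
autocorrelation-based $N_\mathrm{eff} > 100$ per parameter, both
implemented in-package (split-half $\hat R$; Geyer initial monotone
positive sequence for $N_\mathrm{eff}$) and cross-checked against an
independent implementation (coda) in the tests.

No MCMC engine is available in the target environment, so the sampler
is part of the package: Hamiltonian Monte Carlo with analytic
gradients of the log posterior (C++), on an unconstrained scale —
$\log v_i$, $\log A$, $\log k$, and a scaled logit for $t_0$ — with
Jacobian corrections. Design details that took iteration to get right:

- **$t_0$ truncation.** The likelihood is degenerate for
  $t_0 \ge \min(\mathrm{rt})$, so $t_0$ is transformed to
  $(0, \min(1, \min \mathrm{rt}))$. A harder truncation at
  $0.9 \times \min(\mathrm{rt})$ was considered and rejected: with
  true $t_0$ drawn from $U(0,1)$, that bound frequently excludes the
  truth (whenever $t_0 \gtrsim 0.2$ and decision times are short),
  making honest coverage impossible. The logit transform already
  keeps draws strictly below the bound, so no safety margin is
  needed.
- **Dense mass matrix.** The $A$–$k$ posterior trades off strongly
  (their sum $b$ is well identified; each alone is not). A diagonal
  metric left the slow ridge direction with effective sample sizes
  below 100 on some prior-drawn datasets; the chain therefore
  estimates a full covariance from the middle of warmup (shrunk
  toward its diagonal, Cholesky-factored) and re-adapts the step size
  against it.
- **Trajectory length.** Leapfrog path length is jittered uniformly in
  $[L/2, 3L/2]$ with $L = 32$; shorter paths ($L = 16$) mixed the
  ridge too slowly on hard datasets.
- **Initialization.** All chains start from a short BFGS ascent of the
  log posterior (plus per-chain jitter, SD 0.1). Dispersed inits can
  leave one chain adapting its step size in a region it later leaves,
  then rejecting persistently; mode-centered inits make the adapted
  geometry consistent across chains. Fits remain deterministic given
  the seed.
- Divergent transitions (non-finite energy or $\Delta H > 1000$) are
  counted and reported; they reject the proposal.

Fits are independent per subject × zone with a minimum of 20 pauses
per cell (cells below it are skipped and logged); point estimates are
posterior means. Whether zones should share $t_0$ within an animal is
unknowable from the available description; independent fits are the
weaker assumption and are flagged as such.

## 4. Photometry

dF/F uses the fitted-isosbestic convention: the isosbestic channel is
the predictor in an OLS fit of the Ca²⁺ channel, and
$\mathrm{dF/F} = (\mathrm{Ca} - \widehat{\mathrm{iso}})/\widehat{\mathrm{iso}}$,
a fraction internally (×100 only for display). The regression
direction matters: predicting Ca from iso yields a fitted artifact
reference in Ca-channel units.

Peri-event kernels: dF/F is linearly resampled onto a uniform 20 Hz
axis over −5…+5 s (the acquisition chain is 3 Hz low-passed, so 20 Hz
oversamples safely) and each event waveform is baselined to the mean
of −5…−2.5 s. Events with incomplete windows are dropped. Bootstrap:
subject mean waveforms are resampled with replacement 1000 times; the
2.5/97.5 percentiles of the resampled across-subject mean, expanded
about the bootstrap mean by $\sqrt{n/(n-1)}$, form the band; a
significant transient is a band excursion from zero lasting at least
1/3 s, implemented as ≥ 7 consecutive samples at 20 Hz. Whether the
band itself should additionally be low-pass filtered is ambiguous in
the source description; persistence-only is implemented.

## 5. The synthetic cohort: what it emulates, what it does not

`simulate_cohort` generates the world the pipeline assumes, with full
ground truth. Defaults state that world once:

- 8 subjects × 20 trials at 30 fps; 2 min trial timeout; run speed
  $N(20, 3)$ cm/s per run; positional jitter SD 0.03 cm (below the
  0.2 cm stillness tolerance, so detection is near-exact at default
  noise).
- Pause placement: inhomogeneous spatial Poisson hazard, bimodal with
  peaks near both track ends (the observed pause spatial profile); the
  downstream stages estimate, never assume, this profile.
- Per-zone LBA parameters encode the target structure: approach drift
  dominates in start (3.0 vs 1.6) and mid (3.5 vs 1.2) zones; the
  advantage reverses at the goal (2.0 vs 2.6); goal caution is 1.5×
  mid caution (1.125 vs 0.75, via k = 0.875 vs 0.5 at A = 0.5);
  $t_0 = 0.15$ s everywhere. Per-subject log-normal jitter (SD 0.08)
  individuates animals.
- Pause durations *are* the drawn race RTs (rounded to the frame grid
  in the trajectory; the exact draw is recorded in the ground truth),
  and a 2 cm refractory run after each pause keeps consecutive
  decisions separated by at least one detectable movement — without
  it, two pauses closer than the 1.5 cm movement criterion are one
  event by definition and recall is ill-posed.
- Photometry: both channels share a multiplicative artifact (two slow
  sinusoids plus a motion-coupled term, scaled by `artifact_gain`);
  the Ca channel multiplies in the signal — goal-locked double-
  exponential transients (rise 0.1 s, decay 0.5 s, peak 5% dF/F) at
  goal-zone pause onsets, or a linear spatial ramp. Broadband channel
  noise (SD 0.5% of baseline) passes through the acquisition chain's
  3 Hz low-pass (two-pass exponential smoother). The filter is not
  cosmetic: white noise in the isosbestic predictor attenuates the
  OLS slope (errors-in-variables) and leaks artifact into dF/F at
  about $|r| \approx 0.07$; band-limited noise keeps the leak near
  0.03, inside the correction's stated operating characteristic.

**One directional claim needs care.** In a two-option LBA with shared
$s, A, b, t_0$, the locally dominant option is conditionally *faster*
— simulation across a wide grid of parameterizations at fixed caution
found no regime where the more probable response is slower. So at the
goal, where avoidance dominates, avoid decisions cannot be locally
slower than approach decisions in this generative family. The
slower-avoid phenomenon is a *pooled* contrast: avoid decisions
concentrate where caution is high (goal) and are the slow minority
where approach dominates (start, mid). The pipeline therefore asserts
avoid RT > approach RT pooled across the track, which the default
cohort satisfies for every subject, and reports zone-resolved RTs so
the local structure is visible.

What a green test does **not** establish: the generator does not
emulate tracking outliers or identity swaps, reward-consumption
artifacts, photobleaching beyond the shared multiplicative artifact,
hemodynamic contamination, session-to-session drift, or any learning
across trials; zone parameters are stationary within a session.
Passing recovery on this world validates the estimators' correctness,
not their robustness to pathologies the world lacks.

## 6. Linkage

LBA estimates and pause dF/F aggregates join on (subject, zone);
missing cells drop (no imputation). Standardized regression z-scores
predictors *and* response, making coefficients unit-free standardized
betas; the default model uses the two drifts, with caution available
as an optional third predictor (the two-drift model is the one whose
coefficients are reported in the source analysis this mirrors).
Per-parameter correlations carry unadjusted p plus Benjamini–Hochberg
q across the three parameters, labeled as such. Per-subject
coefficients are computed over that subject's three zone points and
are descriptive only — three points cannot support inference.

## 7. Known limitations

- The HMC sampler is model-specific; it is not a general-purpose
  engine, and `target_accept` maps to dual-averaging acceptance, not
  to any particular off-the-shelf sampler's semantics.
- Zones with heavy choice imbalance (e.g. mid-zone avoid fractions of
  a few percent) identify the minority drift mostly through the
  survivor term; its posterior leans on the prior accordingly.
- The bootstrap's false-positive behavior is characterized for 8
  subjects and i.i.d. null waveforms; heavy cross-subject correlation
  would change it.
- `cluster_zones` assumes the decision regimes differ in at least one
  collated feature; regimes differing only in RT *shape* at equal
  medians would not separate.
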