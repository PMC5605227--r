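---
title: "Step-response entrainment: models, estimators and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Step-response entrainment: models, estimators and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(stepclock)
```

`stepclock` models how a circadian oscillator entrains to light-dark
cycles through instantaneous phase shifts at dawn and dusk. This vignette
explains the models and estimators, the conventions and tunable
parameters, what the synthetic-data generators do and do not emulate, and
the numerical choices made where the design was genuinely open.

## The phase-oscillator model

The clock is reduced to a single phase θ̂, measured in cycles
(1 cycle = 2π rad). Our convention fixes θ̂ = 0 at the trough of the
rhythm (circadian time CT 0, with CT labelled at 24 h per cycle
regardless of the condition-specific free-running periods) and θ̂ = 0.5 at
the peak. The oscillator advances at frequency ω_L = 1/T_day in the light
and ω_D = 1/T_night in the dark, and responds to the two environmental
transitions with instantaneous, phase-dependent shifts: L̂(θ̂) at dawn and
D̂(θ̂) at dusk. One driving cycle of period T with day length τ maps the
dawn phase forward as

θ̂_dusk = θ̂_dawn + L̂(θ̂_dawn mod 1) + τ ω_L,
θ̂_dawn' = θ̂_dusk + D̂(θ̂_dusk mod 1) + (T − τ) ω_D.

`iterate_diurnal_map()` implements this map; `simulate_continuous()` is
the equivalent explicit-time version (default step 0.01 h), used when the
schedule contains dark pulses. Phase is stored unwrapped and wrapped only
at shift evaluation and reporting, which avoids branch ambiguity. The two
simulators agree cycle-by-cycle to 10⁻¹⁰, which the test suite asserts.
A dark pulse in constant light is decomposed as a dusk step at pulse
start followed by a dawn step at pulse end.

Entrainment is judged by circular statistics: stable if the circular SD
of the dawn phases of the last five cycles is below 0.01 cycles
(`detect_stable_entrainment()`), with the approach speed measured by the
first window at which the three-cycle sliding circular variance drops
below 0.01 (`cycles_to_entrain()`). Circular estimators matter: phases
straddling the 0/1 wrap would fail a naive SD criterion.

## Step-response functions and their estimation

L and D are measured by step-perturbation experiments: replicate
reactions are switched between "day" and "night" conditions at a grid of
times, and each perturbed reaction is compared with an unperturbed
control. Because a step changes *both* the phase and the period, the
shift is defined as the difference between the perturbed reaction's
apparent phase (fit with the post-step period) and the control's phase,
both evaluated at the step time (`step_phase_shift()`). Data inside a
16 h window after the step are excluded as transient (tunable in
`step_experiment_set()`). Periods are shared across all reactions in a
buffer condition (`fit_sinusoids_shared_period()`), as replicate
reactions of one preparation have one period.

Measured (θ, Δθ) pairs are assembled into a piecewise-linear,
1-cycle-periodic function (`assemble_step_response()`), with shifts
wrapped to (−0.5, 0.5] — the winding-0 convention that a single step
never shifts the clock by more than one cycle. `linearize_step_response()`
fits a line to the nodes inside the phase window the oscillator actually
visits during diurnal entrainment (defaults: CT 18–34 for L, CT 6–22 for
D, both spanning 16 CT hours) and extends it periodically with one
compensating one-cycle jump at a breakpoint. The stored slopes are the
positive coefficients of L(θ) = −l(θ − θ_L), D(θ) = −d(θ − θ_D); the
breakpoint defaults to the phase diametrically opposite the midpoint of
the linearization window, where the oscillator rarely sits during
entrainment, and is overridable.

Uncertainty is propagated by non-parametric bootstrap
(`bootstrap_master_dataset()`): whole trajectories are resampled with
replacement from the pooled master dataset — rather than per-reaction —
so that the correlated uncertainty in shared periods and control phases
flows into every downstream quantity. Resamples missing a control in
either condition, or with fewer than three usable step phases in a
direction or a linearization window, are redrawn and counted.
`bootstrap_slopes()` additionally resamples the nodes within the
linearization window (500 retained resamples per function by default,
each required to contain at least three unique points).

## Linear theory

With linear L and D the composed map is affine with contraction factor
(1 − l)(1 − d); it has a unique stable fixed point whenever
|(1 − l)(1 − d)| < 1 and d + l − ld ≠ 0. `entrained_fixed_point()`
evaluates the closed form and verifies the winding branch by one
application of the wrapped map. Differentiating the entrained peak time
with respect to day length gives

m(l, d) = 1 − (1 − (1 − l)·ω_D/ω_L) / (d + l − ld),

which is implemented in `slope_m()`. At ω_D/ω_L = 1 it reduces to
d(1 − l)/(d + l − ld): l = 1 pins the clock to dawn (m = 0), l = 0,
d = 1 pins it to dusk (m = 1), and intermediate slopes produce
intermediate tracking; with the measured slopes l ≈ 0.34, d ≈ 0.38 and a
frequency ratio of 0.93, m ≈ 0.35 — near-midday tracking. The general
form was re-derived from the fixed point because no clean closed form was
available, and is validated two independent ways in the tests: against
numerical differentiation of the fixed point over random parameter draws,
and against the regression slope of simulated entrained peak times (to
10⁻⁶ when the dawn and dusk phases stay inside the linear regions).

The same linear regime predicts that phase-resetting (PRC), wedge and
seasonal-entrainment experiments share two dimensionless slopes β₁, β₂:

Δt_pk = θ̂_t/(ω_L β₂) + δ(1 + β₁/β₂) + C₁ (resetting, pulse length δ),
t_pk = τ(1 − β₁ − β₂) + T β₁ + C₂ (entrainment).

`predict_prc()`/`predict_seasonal()` evaluate these forms and
`fit_beta_model()` fits all datasets at once by minimizing
χ² = Σ((yᵢ − fitᵢ)/σᵢ)² over six parameters: β₁, β₂ and one intercept per
linear segment (PRC left and right of its breakpoint, wedge, seasonal).
For fixed slopes the intercepts are weighted means of the residuals, so
the optimization is a profiled two-dimensional search from multiple
starts; 95% intervals come from the curvature of χ² at the optimum
(covariance 2H⁻¹). The β and (l, d) parameterizations are kept distinct —
no conversion between them is asserted — but the package's simulations
connect them empirically: the test suite extracts β₂ from the simulated
PRC slope and β₁ from the simulated wedge slope and confirms that the
simulated seasonal slope equals 1 − β₁ − β₂ to 10⁻⁸.

The PRC breakpoint position is a configurable phase. An experimentalist
would place it by inspecting where the measured PRC wraps; the global fit
takes it as given.

`allocation_bias()` quantifies the downstream consequence of a tracking
slope m for daytime resource allocation between dawn-peaking and
dusk-peaking transcript classes: each class is an idealized 24 h
sinusoid, rectified at zero, whose phase relative to dawn shifts by
m·(τ − 12) as the day length changes; the bias is the normalized
difference of the integrals over the lit interval [0, τ]. Idealized
sinusoids replace fitted microarray waveforms here; the fit of those
waveforms is out of scope, and the profile phases are parameters.

## Limit-cycle geometry

The geometric model asks what kind of dynamical system *produces*
linear-looking step responses. Day and night are two circular limit
cycles — the day orbit of radius 1 at the origin, the night orbit of
radius R displaced by X along +y (the axis choice is unobservable by
rotational symmetry) — traversed at 2π/24 rad/h. In the
strong-attraction idealization a dusk or dawn transition projects the
state radially onto the other orbit: the new phase is the angle, about
the new centre, of the nearest point of the new circle (`radial_jump()`;
verified against brute-force nearest-point search). The induced dusk and
dawn response functions follow purely from geometry
(`step_response_from_geometry()`); when the source orbit does not
enclose the target centre the jump map has winding 0 and the tabulated
response carries a genuine discontinuity, the geometric origin of the
breakpoint. A source point landing exactly on the target centre (possible
on the R = X diagonal) has no defined image; `radial_jump()` refuses it,
and tabulation drops that node.

`slope_over_grid()` maps the entrained slope m over (R, X): small night
orbits give dawn tracking (m ≈ 0, the dawn jump erases day-length
information), R ≫ X gives dusk tracking (m ≈ 1), and midday tracking
needs displacement comparable to the radii. Entrainment requires the
final two cycles to agree within π/180 rad and two initial phases (π/4,
5π/4; 30 cycles) to converge to within the same tolerance; a cell is
additionally masked as non-linear when the mean absolute residual of the
phase-versus-τ line exceeds 10% of the phase excursion.

Three relaxed variants drop the idealizations: exponential radial
attraction ṙ = −a(r − R_orb) with t₁/₂ = ln 2/a (10 cycles, initial
phases 0 and π, entrainment judged on peak times with an extra 0.5 h
residual tolerance), elliptical orbits (minor axis along x; the radial
drive −a·d_ellipse is signed and corrected by the ellipse's own ṙ(θ) so
that an on-ellipse state stays on the ellipse; the nearest-point distance
is found by bounded 1-D minimization over the parameter angle, bracketed
by the polar angle ± π/2, tolerance 10⁻¹⁰), and sinusoidally modulated
angular velocity θ̇ = ω(1 + (ε/ω) sin ωt), which preserves the 24 h
period exactly. Integration is fixed-step RK4, default dt = 0.01 h, with
convergence under step halving asserted in the tests. Whether the
velocity-modulation clock resets at dawn or runs from simulation start is
not determined by the physics described; it defaults to dawn-reset and is
exposed as `velocity_phase`. After the final dawn the oscillator relaxes
until its radius is within 1% of the day orbit and the peak time is the
additional time to reach θ = π/2 (`peak_time_dynamic()`).

## Rhythm estimation choices

Sinusoidal fits minimize Σ[yᵢ − (A sin(2πxᵢ/T − φ) + bxᵢ + C)]² with the
period constrained to bounds (default 23–25 h for free-running reporter
rhythms). At fixed T the model is linear in (A cos φ, −A sin φ, b, C), so
the inner minimization is exact linear least squares and only T is
profiled (201-point grid plus golden-section polish). This replaces the
usual multi-start heuristics with a global optimum; fits report φ in
(−π, π]. Trajectories are first normalized to zero mean and unit SD over
the retained samples, after excluding all dark samples and the first
2.5 h after every dark-to-light transition, where luciferase reporters
show clock-independent (masking) transients. Fits whose squared error
exceeds 10 (normalized units; configurable) are rejected as outliers —
on a 96-well plate this typically removes a handful of dead or noisy
wells.

Parabolic peak estimation fits quadratics to 6 h windows around local
maxima of a 3-sample moving median (minimum peak separation 12 h,
candidates restricted to values above the series median); vertices
outside their window or from non-concave fits are rejected with a
warning. Parabolic and sinusoidal estimates genuinely differ on
asymmetric waveforms — for a fast-rise/slow-fall shape the parabolic peak
precedes the sinusoid peak — which is why both are provided and callers
must choose explicitly (`fitter` in the pipeline configuration).

Waveform similarity between driven days and the post-release rhythm uses
Kendall's tie-adjusted τ (ties occur in counts data) on samples paired by
exactly equal times-after-dawn; offsets present in only one window (the
masked 2.5 h after a mid-experiment dawn, say) are dropped, and
mismatched cadences are an error rather than an interpolation.

Dark-pulse phase shifts are measured from replicate-averaged peak times,
each replicate wrapped to within half a period of a common reference
before averaging, with fits restricted to a 36–48 h window after pulse
end. The clock phase at the pulse is computed from the mean control phase
and period as θ̂_t = t/T̄ − (φ̄ − π/2)/(2π) mod 1, the form consistent
with our trough-at-zero convention (the constant offset in this
conversion is immaterial downstream: the global fit absorbs it into C₁).

## Synthetic data: what it emulates and what it does not

The generators produce ~24 h sinusoidal rhythms (signal = −cos 2πθ̂) with
additive Gaussian noise on the normalized scale, replicate series, dark
samples flagged for exclusion, a decaying post-dawn masking transient
(amplitude 2, time constant 0.8 h) to exercise the exclusion logic, and
distinct free-running periods in day and night conditions (defaults
23.7 h and 25.7 h). Step experiments mirror the in vitro protocol: one
control per buffer condition, steps every 2 h over 24 h, 15 min
sampling cadence, with a second out-of-phase replicate set available by
starting at θ̂₀ + 0.5. Defaults of four replicate series, σ = 0.1
normalized units and 30 min reporter cadence match plate-scale
experiments.

Real waveforms are not sinusoids (a skew option exists, default off, to
exercise the parabolic-versus-sinusoid difference), counts-level noise is
not modelled (noise is additive on the normalized scale), and phase
diffusion between transitions is absent. Passing recovery tests therefore
demonstrates correctness of the estimators under the stated noise model,
not robustness to waveform misspecification. One concrete small-sample
effect is documented by the tests: when SEMs are re-estimated from four
replicates instead of known noise, the nominal 95% CI coverage of the
global β fit degrades — a property of plug-in SEMs, not of the fitter —
so the calibration checks use exact SEMs.

## Problem sizes and reproducibility

The test-suite and acceptance computations use deliberately modest
problem sizes chosen to make every check a from-scratch computation: 10
driving cycles and a 0.1 h day-length grid for the entrainment census,
1000 draws for slope propagation, 60 bootstrap resamples for ensemble
coverage (the estimation default is 1000), 20 seeded repetitions for
parameter recovery, a 12×12 (R, X) grid for the geometry phenomenology,
and 100–300 cycle tails for period scans (the scan default is 1000
cycles/950 recorded, matching the long-tail protocol). Every stochastic
stage takes an explicit seed, and all pipelines are bit-reproducible
given a configuration; run logs record the seed, thresholds and phase
conventions.

## Known limitations

Amplitude dynamics, stochastic phase diffusion and multi-oscillator
coupling are out of scope (the geometry module covers amplitude only
through the relaxation variants). The β↔(l, d) conversion is not
implemented; the two parameterizations are linked only through
simulation. Breakpoint placement is a parameter, not an inference. The
entrained fixed point is reported only when a winding branch verifies
under the wrapped map; maps whose jumps create periodic orbits instead of
fixed points are reported as not found rather than approximated.
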