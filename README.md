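# stepclock

Circadian clocks stay useful across the seasons only if they keep a stable
relationship to the light-dark cycle as the day length changes. For the
cyanobacterial KaiABC clock, driven rhythms track the *middle* of the day:
the peak time of clock output shifts by about half an hour for every hour
of extra daylight. `stepclock` implements the modelling framework behind
that observation: the entrained behaviour of the clock is reduced to two
*step-response functions* — the instantaneous phase shift L(θ) caused by a
dark-to-light (dawn) step and D(θ) caused by a light-to-dark (dusk) step,
each as a function of the clock phase θ at which the step lands — plus the
free-running frequencies in light and dark.

The package provides, end to end:

* **Rhythm analysis** — normalization and masking of driven reporter time
  series, sinusoidal regression (single or shared period, with the period
  profiled exactly), local parabolic peak estimation, outlier rejection,
  Kendall waveform similarity, dark-pulse phase shifts, and weighted linear
  regression with known errors.
* **Step-response estimation** — phase shifts of step-perturbed reactions
  measured against controls at the step time (disentangling the shift from
  the period change), assembly into 1-cycle-periodic interpolated
  functions, linearization over the phase ranges used during entrainment,
  and non-parametric bootstrap propagation of the full pipeline.
* **Phase-oscillator simulation** — the iterated dawn/dusk map
  θ̂(dusk) = θ̂(dawn) + L̂(θ̂) + τ/T_day,
  θ̂(dawn') = θ̂(dusk) + D̂(θ̂) + (T−τ)/T_night,
  a continuous-time variant for dark pulses, stable-entrainment detection
  by circular statistics, PRC/wedge simulation, and driving-period scans.
* **Linear theory** — the closed-form entrained fixed point and the slope
  of peak time versus day length,
  m(l, d) = 1 − (1 − (1−l)·ω_D/ω_L)/(d + l − ld),
  which reduces to d(1−l)/(d+l−ld) at equal frequencies; plus the
  two-parameter (β₁, β₂) linear-response model for phase-resetting, wedge
  and seasonal data, and daytime resource-allocation bias.
* **Global fitting** — simultaneous χ² fit of β₁, β₂ and per-dataset
  intercepts to PRC, wedge and seasonal observation sets, with profiled
  intercepts and curvature-based confidence intervals.
* **Limit-cycle geometry** — day/night orbits as displaced circles with
  instantaneous radial resetting, the step-response functions this
  geometry implies, entrainment maps over (R, X) grids, and relaxed
  variants (finite attraction, elliptical orbits, modulated angular
  velocity).
* **Synthetic data** — seeded generators for every dataset shape the
  pipelines consume, with known ground truth, so each estimation stage is
  verified by parameter recovery.

## Worked example

Recover step-response slopes from a synthetic step experiment and predict
seasonal entrainment:

```r
library(stepclock)

params <- oscillator_params(T_day = 23.7, T_night = 25.7)
model  <- linear_entrainment_model(l = 0.34, d = 0.38,
                                   theta_L = 26/24 - 1, theta_D = 14/24,
                                   params = params)
sf  <- as_step_functions(model)

set <- generate_step_experiment(params, sf$L, sf$D, sigma = 0.1, seed = 42)
est <- estimate_step_response(set)
est$L_lin$slope; est$D_lin$slope        # 0.334, 0.381
est$T_day; est$T_night                  # 23.70 h, 25.75 h

slope_m(est$L_lin$slope, est$D_lin$slope, est$T_day / est$T_night)
# 0.341  -- near-midday tracking

run <- iterate_diurnal_map(0, params, est$L_lin, est$D_lin,
                           driving_schedule(24, 12, 10))
head(as.data.frame(run), 3)
#   cycle dawn_phase dawn_phase_pre dusk_phase  tpk_h tpk_in_day
# 1     1     0.0261         0.0000     0.5324 11.231       TRUE
# 2     2     0.0413         0.0228     0.5476 10.871       TRUE
# 3     3     0.0475         0.0322     0.5539 10.723       TRUE
attr(run, "entrained")        # TRUE
```

The recovered slopes sit within a few percent of the generating values
(l = 0.34, d = 0.38); plugging them into the frequency-corrected formula
predicts that the entrained peak time advances by ≈ 0.34 h per hour of
day length, and the simulated oscillator locks to LD 12:12 within a few
cycles with dawn phase ≈ 0.05 cycles.

Phases are in cycles throughout (1 cycle = 2π rad), with θ̂ = 0 at the
rhythm trough (CT 0) and θ̂ = 0.5 at the peak; CT hours use 24 h/cycle.

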