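# shared fixtures built in code

default_params <- function() oscillator_params(23.7, 25.7)

# linear model with anchors centred in the canonical linearization windows
# (L: 18-34 CT, D: 6-22 CT) and breakpoints diametrically opposite
default_model <- function(l = 0.34, d = 0.38, params = default_params()) {
  linear_entrainment_model(l, d, theta_L = 26 / 24 - 1, theta_D = 14 / 24,
                           params = params)
}

noiseless_sine_traj <- function(T = 24, phi = 1, A = 1, C = 0, b = 0,
                                times = seq(0, 72, 0.5), id = "sine") {
  clock_trajectory(times, A * sin(2 * pi * times / T - phi) + b * times + C,
                   light = 1, series_id = id)
}
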