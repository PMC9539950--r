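# Shared fixtures: the chamber's reference logistic parameters, small beam
# grids, and a closed-form logistic oracle independent of the package's
# evaluate_logistic().

ref_model_1us <- function() logistic_ice_model(0.76, 0.61, 5.12, 1)
ref_model_3us <- function() logistic_ice_model(0.97, 0.35, 3.28, 3)

# direct transcription of the closed form, used as the oracle
logistic_oracle <- function(dpp, alpha, beta, gamma) {
  (1 + (dpp / gamma)^alpha)^(-beta)
}

# a single low-DPP condition at the reference SSD (saturation anchor)
anchor_config <- function(dpp = 0.02, w = 3, n_pulses = 1) {
  beam_config(ssd = 2, grid_tension = 150, pulse_duration = w,
              n_pulses = n_pulses, dpp_true = dpp)
}

# small mixed grid: a few conditions per SSD, both pulse durations
small_grid <- function() replica_grid(n_tensions = 4)

zero_truth <- function(seed = 7) {
  ground_truth(noise = zero_noise(), seed = seed)
}

default_truth <- function(seed = 7) {
  ground_truth(noise = noise_spec(), seed = seed)
}
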