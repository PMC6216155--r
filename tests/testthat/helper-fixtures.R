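# Small shared fixtures built in code at test time.

# A quick low-cost trial: fewer cycles, shorter record, fixed durations
# unless noise in the cycle model is wanted.
quick_sim <- function(seed = 1, n_cycles = 10, noise_sd = 0,
                      fixed_cycles = TRUE, carrier = "bandlimited", r = 4) {
  cm <- if (fixed_cycles) {
    list(contact_mean = 0.288, contact_sd = 0,
         swing_mean = 0.452, swing_sd = 0)
  } else {
    list(contact_mean = 0.288, contact_sd = 0.042,
         swing_mean = 0.452, swing_sd = 0.045)
  }
  gt <- make_ground_truth(r = r, seed = seed, noise_sd = noise_sd,
                          cycle_model = cm)
  synthesize_trial(gt, n_cycles = n_cycles, seed = seed,
                   duration = n_cycles * 0.8 + 1, carrier = carrier)
}
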