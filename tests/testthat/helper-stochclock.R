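# Shared helpers: small experiment wrapper used by several test files.

## quick bulk or methylation experiment at reduced scale
small_experiment <- function(pipeline = "bulk", n_features = 200,
                             sd = 0.03, mode = "clamped",
                             e_m = 0.999, max_age = 50, n_sets = 4,
                             n_cells = 200, seed = 1, ...) {
  if (pipeline == "bulk") {
    clock_experiment("bulk", n_features = n_features,
                     cfg = noise_config(sd, mode = mode),
                     max_age = max_age, n_sets = n_sets,
                     train_sets = seq_len(n_sets / 2), seed = seed, ...)
  } else {
    clock_experiment("methylation", n_features = n_features,
                     rates = maintenance_rates(e_m, 1 - e_m),
                     max_age = max_age, n_sets = n_sets,
                     n_cells = n_cells,
                     train_sets = seq_len(n_sets / 2), seed = seed, ...)
  }
}
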