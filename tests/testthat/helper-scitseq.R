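# Shared fixtures: small cohorts built in code, and the compact model
# configurations used throughout the suite (sized for quick training).

tiny_cohort <- function(n = 6L, seed = 42L, grid = time_grid()) {
  gt <- generate_cohort(generator_config(n_patients = n, seed = seed,
                                         grid = grid))
  gt$cohort
}

# a hand-built 2-patient cohort with known values
two_patient_tables <- function() {
  grid <- time_grid()
  visits <- expand.grid(step = 1:6, patient_id = c("A", "B"),
                        stringsAsFactors = FALSE)[, 2:1]
  visits$month <- grid$months[visits$step]
  for (k in 1:10) visits[[sprintf("s%02d", k)]] <- round(
    5 + sin(seq_len(nrow(visits)) + k), 2)
  visits$med_score <- rep(c(3, 3, 2, 2, 1, 1), 2)
  visits$adherence <- rep(c(1, 1, 1, 0, 0, NA), 2)
  visits$action <- visits$adherence
  statics <- data.frame(patient_id = c("A", "B"))
  for (k in 1:14) statics[[sprintf("f%02d", k)]] <- c(k / 2, k / 3)
  list(visits = visits, statics = statics, grid = grid)
}

quick_slvm_config <- function(epochs = 40L, seed = 1L, ...) {
  slvm_config(latent_dim = 4L, hidden_width = 16L, epochs = epochs,
              learning_rate = 1e-2, n_latent_samples = 20L, seed = seed, ...)
}

quick_lstm_config <- function(epochs = 40L, seed = 1L, ...) {
  lstm_config(hidden_size = 16L, epochs = epochs, learning_rate = 1e-2,
              seed = seed, ...)
}

# benchmark-scale configurations (synthetic-benchmark experiments)
bench_slvm_config <- function(epochs = 100L, seed = 1L) {
  slvm_config(latent_dim = 8L, hidden_width = 32L, epochs = epochs,
              learning_rate = 1e-2, n_latent_samples = 30L, seed = seed)
}

bench_lstm_config <- function(epochs = 100L, seed = 1L) {
  lstm_config(hidden_size = 32L, epochs = epochs, learning_rate = 1e-2,
              seed = seed)
}
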