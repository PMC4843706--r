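# Scene factories shared across tests. Sizes are kept small where the
# property under test allows it; the planted-effect scenes mirror the
# generator defaults (750 ms epochs, alpha-band source).

strong_scene <- function(seed, n_channels = 16, n_epochs = 300,
                         comodulation_r = 0.9, noise_power = 0.1,
                         center_freq = 10, bandwidth = 4) {
  pat <- with_test_seed(seed + 1000, stats::rnorm(n_channels))
  sc <- synthetic_scene(
    n_channels = n_channels, n_epochs = n_epochs, seed = seed,
    sources = list(source_spec(pat, center_freq, bandwidth,
                               comodulation_r = comodulation_r)),
    noise_power = noise_power)
  generate_scene(sc)
}

null_scene <- function(seed, n_channels = 8, n_epochs = 200) {
  sc <- synthetic_scene(n_channels = n_channels, n_epochs = n_epochs,
                        seed = seed, sources = list(), noise_power = 1)
  generate_scene(sc)
}

trend_scene <- function(seed, n_channels = 8, n_epochs = 300,
                        trend_weight = 0.6) {
  pat <- with_test_seed(seed + 2000, stats::rnorm(n_channels))
  sc <- synthetic_scene(
    n_channels = n_channels, n_epochs = n_epochs, seed = seed,
    sources = list(source_spec(pat, 10, 4, comodulation_r = 0.9)),
    noise_power = 0.1, trend_weight = trend_weight,
    comodulation_driver = "trend")
  generate_scene(sc)
}

with_test_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  force(code)
}

cosine_sim <- function(a, b) abs(sum(a * b)) / sqrt(sum(a^2) * sum(b^2))
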