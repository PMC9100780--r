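# Shared fixtures for the small-scale continual-learning benchmark:
# a 5-task synthetic permuted stream, the reference Active Dendrites
# Network (2 x 256 hidden, 5 segments, 5% activation density, 50%
# weight sparsity) and its parameter-matched dense ReLU MLP.  Trained
# runs are memoized so multiple tests can share one training.

bench_cache <- new.env(parent = emptyenv())

bench_adn_spec <- function() {
  network_spec(64, c(256L, 256L), 10L, context_dim = 64L,
               weight_sparsity = 0.5, activation_density = 0.05,
               num_segments = 5L, segment_dim = 64L,
               modulated_layers = c(1L, 2L))
}

bench_stream <- function(seed = 0L) {
  key <- paste0("stream-", seed)
  if (is.null(bench_cache[[key]]))
    bench_cache[[key]] <- generate_synthetic_stream(n_tasks = 5L,
                                                    seed = seed)
  bench_cache[[key]]
}

bench_config <- function(seed = 0L) {
  train_config("prototype_given", epochs_per_task = 20L,
               learning_rate = 3e-3, seed = seed, eval_history = TRUE)
}

bench_run <- function(model = c("adn", "mlp"), seed = 0L) {
  model <- match.arg(model)
  key <- paste0(model, "-", seed)
  if (is.null(bench_cache[[key]])) {
    spec <- if (model == "adn") bench_adn_spec()
    else matched_mlp_spec(bench_adn_spec())
    bench_cache[[key]] <- train_continual(spec, bench_stream(seed),
                                          bench_config(seed))
  }
  bench_cache[[key]]
}

# initialization seed the trainer derives from a master seed, so an
# untrained copy matches a trained run's starting point exactly
derive_seeds_like_trainer <- function(seed) {
  adnet:::derive_seeds(seed, 2L)[1L]
}

# tiny spec used by fast unit tests
tiny_spec <- function(...) {
  network_spec(12, c(16L, 14L), 4L, context_dim = 12L,
               weight_sparsity = 0.25, activation_density = 0.25,
               num_segments = 3L, segment_dim = 12L,
               modulated_layers = c(1L, 2L), ...)
}
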