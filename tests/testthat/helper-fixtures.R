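# Shared fixtures. Heavy objects (a converged toy classifier and its
# autoencoder) are built once per test run and cached in this environment.

.fixture_cache <- new.env(parent = emptyenv())

toy_sim_config <- function() {
  sim_config(n_archetypes = 2L, families_per_archetype = 2L,
             seqs_per_family = 50L, insertion_rate = 1, noise_rate = 0.03,
             novel_archetypes = 1L, max_len = 192L, seed = 101L)
}

toy_model_config <- function() {
  model_config(L_max = 192L, block1_filters = c(8L, 16L, 16L),
               block2_filters = c(16L, 16L, 16L), attention_reduction = 4L,
               batch_size = 16L, max_epochs = 15L, patience = 15L,
               lr = 3e-3, seed = 31L)
}

# Converged toy classifier on a 2-archetype, 4-family grammar with
# family-specific insertions (families separable, folds trivially so).
get_toy <- function() {
  if (!is.null(.fixture_cache$toy)) return(.fixture_cache$toy)
  d <- sample_dataset(toy_sim_config())
  idx <- withr::with_seed(9L, sample(nrow(d$train), 40L))
  model <- build_model(toy_model_config(),
                       folds = unique(d$train$fold),
                       families = unique(d$train$family))
  model <- train_classifier(model, d$train[-idx, ], d$train[idx, ])
  .fixture_cache$toy <- list(data = d, model = model, val_idx = idx)
  .fixture_cache$toy
}

# Main autoencoder for the toy classifier (decoder only is trained).
get_toy_ae <- function() {
  if (!is.null(.fixture_cache$toy_ae)) return(.fixture_cache$toy_ae)
  toy <- get_toy()
  ae <- train_autoencoder(toy$model, toy$data$train[-toy$val_idx, ],
                          decoder_filters = c(24L, 16L, 12L),
                          epochs = 10L, lr = 3e-3, seed = 41L)
  .fixture_cache$toy_ae <- ae
  ae
}
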