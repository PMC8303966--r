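# Expensive shared fixtures, built lazily once per session. All seeds and
# training recipes are fixed so every run of the suite exercises the same
# study conditions.

.fixtures <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (is.null(.fixtures[[name]])) .fixtures[[name]] <- builder()
  .fixtures[[name]]
}

tiny_spec <- function() frame_spec(12, 12, levels = 2)
tiny_params <- function() dot_params(uniform_radius = 1.5)

# 12x12 binary uniform-dot bundle, N = {1,2,3}, 1500/300/300.
tiny_bundle <- function() fixture("tiny_bundle", function() {
  build_dataset("uniform", 1:3, c(1500, 300, 300), seed = 101,
                spec = tiny_spec(), params = tiny_params())
})

# The scaled-down behavioral model: tiny preset trained to the validation
# plateau (~0.03 nats/px).
tiny_fit <- function() fixture("tiny_fit", function() {
  model <- init_model(tiny_model_config(), seed = 202)
  train(model, tiny_bundle(),
        train_config(epochs = 20, batch_size = 32, lr = 1e-3,
                     lr_decay = 0.1, seed = 303))
})

tiny_area_counter <- function() fixture("tiny_area_counter", function() {
  fit_area_counter(tiny_bundle()$validation, tiny_spec())
})

# Interpolation regime: numerosity 2 held out, model trained on {1, 3}.
holdout_bundle <- function() fixture("holdout_bundle", function() {
  build_dataset("uniform", c(1, 3), c(1500, 300, 300), seed = 111,
                spec = tiny_spec(), params = tiny_params())
})

holdout_fit <- function() fixture("holdout_fit", function() {
  model <- init_model(tiny_model_config(numerosities = c(1, 3)), seed = 222)
  train(model, holdout_bundle(),
        train_config(epochs = 20, batch_size = 32, lr = 1e-3,
                     lr_decay = 0.1, seed = 333))
})

# Full-scale uniform-dot dataset at the default study conditions.
full_uniform_bundle <- function() fixture("full_uniform_bundle", function() {
  build_dataset("uniform", 1:8, c(16000, 3200, 3200), seed = 7)
})

# The supervised counter: 22,000 non-uniform frames, labels 0..10,
# stratified 20,000/2,000.
cnn_counter_full <- function() fixture("cnn_counter_full", function() {
  train_classifier_counter(counting_dataset(22000, 0:10, seed = 42),
                           classifier_config(), n_train = 20000)
})

# Quickly trainable micro bundle (8x8 binary frames, N = {1,2}).
micro_bundle <- function() fixture("micro_bundle", function() {
  build_dataset("uniform", 1:2, c(200, 60, 60), seed = 5,
                spec = micro_spec(), params = micro_params())
})
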