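# Small shared fixtures, all generated in code at test time.

tiny_set <- function(n_classes = 4, per_class = 10, size = c(16, 16),
                     noise = 0, seed = 1) {
  make_dataset(dataset_spec(n_classes = n_classes, images_per_class = per_class,
                            image_size = size, noise_level = noise, seed = seed))
}

tiny_model <- function(n_classes = 4, input = c(16, 16), seed = 1) {
  build_model(model_spec("tiny_cnn", n_classes = n_classes,
                         input_size = input, init_seed = seed))
}

# a weight_vector with arbitrary values over the tiny model's layout
rand_weight_vector <- function(model, seed) {
  set.seed(seed)
  w <- get_weights(model)
  w$values <- rnorm(length(w$values))
  w
}

# minimal stand-in for a client update, for aggregation tests
fake_update <- function(weights, n_samples) {
  list(weights = weights, n_samples = n_samples)
}
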