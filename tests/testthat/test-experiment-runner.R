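small_base <- function(seed = 3) {
  fed_config(
    dataset = dataset_spec(n_classes = 4, images_per_class = 12,
                           image_size = c(16, 16), noise_level = 0.1, seed = seed),
    n_clients = 2, rounds = 2, local_epochs = 1, batch_size = 8,
    learning_rate = 0.01, test_fraction = 0.25, base_seed = seed
  )
}

test_that("configurations validate their fields and map every protocol symbol", {
  cfg <- fed_config()
  expect_named(cfg[c("n_clients", "rounds", "local_epochs", "batch_size",
                     "learning_rate")],
               c("n_clients", "rounds", "local_epochs", "batch_size",
                 "learning_rate"))
  expect_error(fed_config(n_clients = 0), "n_clients")
  expect_error(fed_config(rounds = 0), "rounds")
  expect_error(fed_config(learning_rate = 0), "learning_rate")
  expect_error(fed_config(test_fraction = 1), "test_fraction")
  expect_error(fed_config(averaging = "weighted"), "arg")
  expect_error(sweep_spec(small_base(), "n_clients", c()), "non-empty")
  expect_error(sweep_spec(small_base(), "noise", c(1)), "arg")
})

test_that("an end-to-end experiment run produces a complete result bundle", {
  res <- run_experiment(small_base())
  expect_s3_class(res, "fed_result")
  expect_equal(max(res$rounds$round), 2)
  expect_s3_class(res$channel_stats, "channel_stats")
  # summary values recomputable from persisted per-round records
  fin <- fed_final_metrics(res)
  pooled <- res$rounds[res$rounds$client == "POOLED" & res$rounds$round == 2, ]
  expect_equal(fin[["f1"]], pooled$f1)
})

test_that("sweeps run one experiment per axis value with all else held fixed", {
  sw <- sweep_spec(small_base(), "n_clients", c(2, 3))
  results <- run_sweep(sw)
  expect_length(results, 2)
  expect_true(all(vapply(results, inherits, TRUE, "fed_result")))
  expect_equal(results[[1]]$config$n_clients, 2)
  expect_equal(results[[2]]$config$n_clients, 3)
  # every run keeps the base round count => base.rounds RoundRecords each
  for (r in results) expect_equal(max(r$rounds$round), 2)

  sw_r <- sweep_spec(small_base(), "rounds", c(1, 3))
  res_r <- run_sweep(sw_r)
  expect_equal(vapply(res_r, function(r) max(r$rounds$round), numeric(1)), c(1, 3))

  # a failing run is recorded and the sweep continues
  bad_base <- small_base()
  sw_bad <- sweep_spec(bad_base, "n_clients", c(2, 10000))
  res_bad <- run_sweep(sw_bad)
  expect_s3_class(res_bad[[2]], "fed_failure")
  expect_s3_class(res_bad[[1]], "fed_result")
})

test_that("sweep summaries render percents, sort by axis value and round-trip
           through CSV", {
  sw <- sweep_spec(small_base(), "n_clients", c(3, 2))
  results <- run_sweep(sw)
  summ <- summarize_sweep(results)
  expect_equal(summ$run, c("n_clients=2", "n_clients=3")) # ascending axis order
  expect_true(all(summ$final_accuracy_pct >= 0 & summ$final_accuracy_pct <= 100))

  # a run whose final pooled accuracy is 0.95 renders as "95.00"
  fake <- results[1]
  fake[[1]]$rounds[fake[[1]]$rounds$client == "POOLED", "accuracy"] <- 0.95
  attr(fake, "labels") <- "fixed"
  out <- capture.output(print(summarize_sweep(fake)))
  expect_true(any(grepl("95.00", out, fixed = TRUE)))

  path <- tempfile(fileext = ".csv")
  utils::write.csv(as.data.frame(summ), path, row.names = FALSE)
  back <- utils::read.csv(path)
  expect_equal(back$final_accuracy_pct, summ$final_accuracy_pct)
  expect_equal(back$run, summ$run)
})

test_that("round metrics persist as CSV and reproduce the in-memory records", {
  res <- run_experiment(small_base())
  path <- tempfile(fileext = ".csv")
  write_round_metrics(res, path)
  back <- utils::read.csv(path)
  expect_equal(nrow(back), nrow(res$rounds))
  expect_equal(back$accuracy, res$rounds$accuracy)
  expect_equal(back$client, res$rounds$client)
})

test_that("round-curve plots carry one series per run and reject unknown
           metrics", {
  sw <- sweep_spec(small_base(), "n_clients", c(2, 3))
  results <- run_sweep(sw)
  p <- plot_round_curves(results, "f1")
  expect_s3_class(p, "ggplot")
  expect_equal(nrow(p$data), 4) # 2 runs x 2 rounds
  pooled1 <- results[[1]]$rounds[results[[1]]$rounds$client == "POOLED", "f1"]
  expect_equal(p$data$value[p$data$run == "n_clients=2"], pooled1)

  f <- tempfile(fileext = ".png")
  plot_round_curves(results, "accuracy", file = f)
  expect_true(file.exists(f) && file.size(f) > 0)

  expect_error(plot_round_curves(results, "auc"), "valid options")
})

test_that("re-running a sweep with the same spec reproduces every record", {
  sw <- sweep_spec(small_base(), "local_epochs", c(1, 2))
  r1 <- run_sweep(sw)
  r2 <- run_sweep(sw)
  for (i in seq_along(r1)) expect_identical(r1[[i]]$rounds, r2[[i]]$rounds)
})

test_that("configs and sweeps read back from flat YAML files", {
  path <- tempfile(fileext = ".yml")
  writeLines(c(
    "dataset_spec:",
    "  n_classes: 3",
    "  images_per_class: 6",
    "  image_size: [16, 16]",
    "  noise_level: 0.2",
    "  seed: 4",
    "n_clients: 2",
    "rounds: 3",
    "local_epochs: 1",
    "batch_size: 8",
    "learning_rate: 0.01",
    "base_seed: 4"
  ), path)
  cfg <- read_fed_config(path)
  expect_s3_class(cfg, "fed_config")
  expect_equal(cfg$rounds, 3)
  expect_equal(cfg$dataset$n_classes, 3)

  writeLines(c("n_clients: 2", "rounds: 2", "axis: n_clients", "values: [2, 3]"),
             path)
  sw <- read_fed_config(path)
  expect_s3_class(sw, "sweep_spec")
  expect_equal(sw$values, c(2, 3))
})

test_that("weight checkpoints round-trip through the text format", {
  m <- tiny_model(seed = 12)
  w <- get_weights(m)
  path <- tempfile(fileext = ".txt")
  write_weights(w, path)
  back <- read_weights(path)
  expect_equal(back$values, w$values, tolerance = 1e-15)
  expect_equal(back$layout, lapply(w$layout, as.integer))
})
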