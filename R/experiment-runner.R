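#' Configuration of one federated experiment
#'
#' Bundles the fixed parameters of the federated protocol — number of clients
#' `C`, communication rounds `R`, local epochs per round `E_c`, local batch
#' size `B_c`, local learning rate `L_R` — with the dataset, model, split and
#' seed choices. Defaults follow the reference parameter grid (batch 16,
#' learning rate 0.01) at desk scale.
#'
#' @param dataset A [dataset_spec()], a preset name accepted by
#'   [dataset_preset()], or a path to a class-per-directory image tree.
#' @param model A [model_spec()], or `NULL` to derive a `tiny_cnn` spec from
#'   the dataset (class count and image size) seeded by `base_seed`.
#' @param n_clients Number of federated clients `C`.
#' @param rounds Communication rounds `R`.
#' @param local_epochs Full local passes per round `E_c`.
#' @param batch_size Local mini-batch size `B_c`.
#' @param learning_rate Local SGD learning rate `L_R`, > 0.
#' @param test_fraction Fraction of each class held out for testing.
#' @param base_seed Master seed; every other stream (split, partitions,
#'   per-round per-client shuffles) is derived from it.
#' @param averaging Multiclass metric averaging, `"macro"` or `"micro"`.
#' @param stats_source `"computed"` standardizes with statistics of the
#'   training split; `"preset"` uses the canonical pretrained-backbone
#'   constants (mean 0.485/0.456/0.406, sd 0.229/0.224/0.225).
#' @return An object of class `fed_config`.
#' @export
fed_config <- function(dataset = dataset_preset("grape"), model = NULL,
                       n_clients = 3L, rounds = 10L, local_epochs = 1L,
                       batch_size = 16L, learning_rate = 0.01,
                       test_fraction = 0.2, base_seed = 1L,
                       averaging = c("macro", "micro"),
                       stats_source = c("computed", "preset")) {
  n_clients <- .check_count(n_clients, "n_clients")
  rounds <- .check_count(rounds, "rounds")
  local_epochs <- .check_count(local_epochs, "local_epochs")
  batch_size <- .check_count(batch_size, "batch_size")
  if (!is.numeric(learning_rate) || length(learning_rate) != 1L ||
      is.na(learning_rate) || learning_rate <= 0) {
    .fl_stop("`learning_rate` must be a single positive number")
  }
  test_fraction <- .check_fraction(test_fraction, "test_fraction")
  base_seed <- .check_count(base_seed, "base_seed", min = 0L)
  averaging <- match.arg(averaging)
  stats_source <- match.arg(stats_source)
  if (!is.null(model) && !inherits(model, "fl_model_spec")) {
    .fl_stop("`model` must be NULL or a model_spec()")
  }
  structure(
    list(dataset = dataset, model = model, n_clients = n_clients,
         rounds = rounds, local_epochs = local_epochs,
         batch_size = batch_size, learning_rate = learning_rate,
         test_fraction = test_fraction, base_seed = base_seed,
         averaging = averaging, stats_source = stats_source),
    class = "fed_config"
  )
}

#' @export
print.fed_config <- function(x, ...) {
  ds <- if (inherits(x$dataset, "leaf_dataset_spec")) x$dataset$name else as.character(x$dataset)
  cat(sprintf(
    "<fed_config> dataset=%s clients=%d rounds=%d epochs=%d batch=%d lr=%g seed=%d\n",
    ds, x$n_clients, x$rounds, x$local_epochs, x$batch_size,
    x$learning_rate, x$base_seed))
  invisible(x)
}

# resolve the config's dataset field into an in-memory image set
.resolve_dataset <- function(dataset) {
  if (inherits(dataset, "leaf_image_set")) return(dataset)
  if (inherits(dataset, "leaf_dataset_spec")) return(make_dataset(dataset))
  if (is.character(dataset) && length(dataset) == 1L) {
    if (dir.exists(dataset)) return(read_dataset(dataset))
    return(make_dataset(dataset_preset(dataset)))
  }
  .fl_stop("`dataset` must be a dataset_spec, image set, preset name, or directory")
}

.PRESET_STATS <- structure(
  list(mean = c(0.485, 0.456, 0.406), sd = c(0.229, 0.224, 0.225)),
  class = "channel_stats"
)

#' Run one complete federated experiment from a configuration
#'
#' The full pipeline: materialize the dataset, stratified train/test split,
#' resize to the model's input size if needed, standardize both subsets with
#' channel statistics computed on the training split (or preset constants),
#' then execute the federated round loop of [run_federated_training()].
#'
#' @param config A [fed_config()].
#' @return A `fed_result` (see [run_federated_training()]) whose
#'   `channel_stats` field records the standardization used.
#' @examples
#' \donttest{
#' cfg <- fed_config(dataset = dataset_spec(images_per_class = 20, seed = 5),
#'                   rounds = 2, base_seed = 5)
#' res <- run_experiment(cfg)
#' fed_final_metrics(res)
#' }
#' @export
run_experiment <- function(config) {
  stopifnot(inherits(config, "fed_config"))
  data <- .resolve_dataset(config$dataset)
  mspec <- config$model
  if (is.null(mspec)) {
    mspec <- model_spec(architecture = "tiny_cnn",
                        n_classes = length(data$class_names),
                        input_size = dim(data$images[[1]])[1:2],
                        init_seed = derive_seed(config$base_seed, 7))
  }
  config$model <- mspec

  split <- stratified_split(data, config$test_fraction,
                            seed = derive_seed(config$base_seed, 11))
  train <- resize_images(split$train, mspec$input_size)
  test <- resize_images(split$test, mspec$input_size)

  stats <- if (config$stats_source == "computed") {
    compute_channel_stats(train)
  } else {
    .PRESET_STATS
  }
  train <- normalize_images(train, stats)
  test <- normalize_images(test, stats)

  run_federated_training(config, train, test, channel_stats = stats)
}

#' Specification of a parameter sweep
#'
#' One experiment per value of a single axis — number of clients,
#' communication rounds, local epochs, or dataset — with all other parameters
#' held at the base configuration. These are the four experimental scenarios
#' the runner reproduces.
#'
#' @param base A [fed_config()].
#' @param axis One of `"n_clients"`, `"rounds"`, `"local_epochs"`,
#'   `"dataset"`.
#' @param values Non-empty vector (or list, for dataset specs) of axis values.
#' @return An object of class `sweep_spec`.
#' @export
sweep_spec <- function(base, axis = c("n_clients", "rounds", "local_epochs", "dataset"),
                       values) {
  stopifnot(inherits(base, "fed_config"))
  axis <- match.arg(axis)
  if (missing(values) || length(values) == 0L) {
    .fl_stop("`values` must be a non-empty vector of axis values")
  }
  structure(list(base = base, axis = axis, values = values),
            class = "sweep_spec")
}

.axis_label <- function(axis, value) {
  if (inherits(value, "leaf_dataset_spec")) return(value$name)
  paste0(axis, "=", as.character(value))
}

#' Run every experiment of a sweep
#'
#' Executes one federated run per axis value. Per-run seeds are derived
#' deterministically from the base seed and the axis position, so the sweep is
#' reproducible as a whole. A failing run is recorded (with its error message)
#' and the remaining runs continue; when `out_dir` is given, each run's
#' per-round metrics CSV is written as it completes.
#'
#' @param sweep A [sweep_spec()].
#' @param out_dir Optional directory for per-run round-metrics CSV files.
#' @return A list of `fed_result` objects (failed runs hold a `fed_failure`
#'   object instead), with attributes `axis` and `labels`.
#' @export
run_sweep <- function(sweep, out_dir = NULL) {
  stopifnot(inherits(sweep, "sweep_spec"))
  values <- if (is.list(sweep$values)) sweep$values else as.list(sweep$values)
  labels <- vapply(seq_along(values), function(i) {
    .axis_label(sweep$axis, values[[i]])
  }, character(1))
  if (!is.null(out_dir)) dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

  results <- vector("list", length(values))
  for (i in seq_along(values)) {
    cfg <- sweep$base
    cfg[[sweep$axis]] <- values[[i]]
    cfg$base_seed <- derive_seed(sweep$base$base_seed, i)
    results[[i]] <- tryCatch(run_experiment(cfg), error = function(e) {
      structure(list(label = labels[i], message = conditionMessage(e)),
                class = "fed_failure")
    })
    if (!is.null(out_dir) && inherits(results[[i]], "fed_result")) {
      write_round_metrics(results[[i]],
                          file.path(out_dir, paste0("rounds_", gsub("=", "_", labels[i]), ".csv")))
    }
  }
  attr(results, "axis") <- sweep$axis
  attr(results, "labels") <- labels
  results
}

#' Write a run's per-round metrics as CSV
#'
#' Columns: `round`, `client` (client id, `"MEAN"` or `"POOLED"`),
#' `accuracy`, `precision`, `recall`, `f1`, `train_loss`.
#'
#' @param result A `fed_result`.
#' @param path Output CSV path.
#' @return Invisibly, `path`.
#' @export
write_round_metrics <- function(result, path) {
  stopifnot(inherits(result, "fed_result"))
  utils::write.csv(result$rounds, path, row.names = FALSE)
  invisible(path)
}

#' Summary table of a sweep
#'
#' One row per run: the axis value, the final-round pooled accuracy and F1
#' (percent, rounded to 2 decimals), the best round and its values, and the
#' runtime. Rows are sorted by axis value (ascending for numeric axes). Failed
#' runs appear with `NA` metrics and the error message.
#'
#' @param results The list returned by [run_sweep()] (or a list of
#'   `fed_result` objects).
#' @return A data frame of class `fed_summary`.
#' @export
summarize_sweep <- function(results) {
  if (!is.list(results) || length(results) == 0L) {
    .fl_stop("`results` must be a non-empty list of fed_result objects")
  }
  labels <- attr(results, "labels")
  if (is.null(labels)) labels <- as.character(seq_along(results))
  rows <- lapply(seq_along(results), function(i) {
    r <- results[[i]]
    if (inherits(r, "fed_failure")) {
      return(data.frame(run = labels[i], final_round = NA_integer_,
                        final_accuracy_pct = NA_real_, final_f1_pct = NA_real_,
                        best_round = NA_integer_, best_accuracy_pct = NA_real_,
                        best_f1_pct = NA_real_, runtime_sec = NA_real_,
                        error = r$message))
    }
    fin <- fed_final_metrics(r, "final")
    best <- fed_final_metrics(r, "best")
    data.frame(run = labels[i], final_round = as.integer(fin[["round"]]),
               final_accuracy_pct = round(100 * fin[["accuracy"]], 2),
               final_f1_pct = round(100 * fin[["f1"]], 2),
               best_round = as.integer(best[["round"]]),
               best_accuracy_pct = round(100 * best[["accuracy"]], 2),
               best_f1_pct = round(100 * best[["f1"]], 2),
               runtime_sec = round(r$runtime_sec, 2),
               error = NA_character_)
  })
  out <- do.call(rbind, rows)
  num <- suppressWarnings(as.numeric(sub("^[a-z_]+=", "", out$run)))
  out <- if (!anyNA(num)) out[order(num), , drop = FALSE] else out[order(out$run), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("fed_summary", "data.frame")
  out
}

#' @export
print.fed_summary <- function(x, ...) {
  y <- as.data.frame(x)
  for (cl in c("final_accuracy_pct", "final_f1_pct", "best_accuracy_pct", "best_f1_pct")) {
    y[[cl]] <- ifelse(is.na(y[[cl]]), NA, sprintf("%.2f", y[[cl]]))
  }
  print(y, row.names = FALSE)
  invisible(x)
}

#' Plot pooled metric trajectories over communication rounds
#'
#' One line per run: x = round index, y = the pooled value of the chosen
#' metric after aggregation in that round.
#'
#' @param results List of `fed_result` objects (failures are skipped).
#' @param metric One of `"accuracy"`, `"f1"`, `"precision"`, `"recall"`.
#' @param file Optional path; when given the figure is written there (PNG by
#'   extension) and the path returned, otherwise the ggplot object is
#'   returned.
#' @return A ggplot object, or `file` invisibly.
#' @export
plot_round_curves <- function(results, metric = "accuracy", file = NULL) {
  valid <- c("accuracy", "f1", "precision", "recall")
  if (!is.character(metric) || length(metric) != 1L || !(metric %in% valid)) {
    .fl_stop("unknown metric '", as.character(metric)[1],
             "'; valid options: ", paste(valid, collapse = ", "))
  }
  if (inherits(results, "fed_result")) results <- list(results)
  labels <- attr(results, "labels")
  if (is.null(labels)) labels <- paste0("run_", seq_along(results))
  keep <- vapply(results, inherits, TRUE, "fed_result")
  if (!any(keep)) .fl_stop("no successful runs to plot")
  df <- do.call(rbind, lapply(which(keep), function(i) {
    pooled <- results[[i]]$rounds[results[[i]]$rounds$client == "POOLED", ]
    data.frame(run = labels[i], round = pooled$round, value = pooled[[metric]])
  }))
  p <- ggplot2::ggplot(df, ggplot2::aes(x = round, y = value, colour = run)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 1) +
    ggplot2::labs(x = "Communication round", y = paste("Pooled", metric),
                  colour = NULL) +
    ggplot2::theme_minimal()
  if (is.null(file)) return(p)
  ggplot2::ggsave(file, p, width = 7, height = 4.5, dpi = 150)
  invisible(file)
}
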