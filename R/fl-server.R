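#' Federated averaging of client updates
#'
#' Aggregates client weight vectors by the sample-size-weighted element-wise
#' average: update k with `n_k` training samples receives weight
#' `n_k / sum_j n_j`. With equal partition sizes this reduces to the
#' arithmetic mean; a single update is returned unchanged.
#'
#' @param updates Non-empty list of [client_update()] results (or any objects
#'   with fields `weights` (a `weight_vector`) and `n_samples`), all with
#'   identical layouts.
#' @return The aggregated `weight_vector`.
#' @examples
#' \dontrun{
#' global <- fedavg(list(upd1, upd2, upd3))
#' }
#' @export
fedavg <- function(updates) {
  if (!is.list(updates) || length(updates) == 0L) {
    .fl_stop("`updates` must be a non-empty list of client updates")
  }
  for (u in updates) {
    if (is.null(u$weights) || !inherits(u$weights, "weight_vector") ||
        is.null(u$n_samples) || u$n_samples < 1) {
      .fl_stop("every update needs a `weights` weight_vector and `n_samples` >= 1")
    }
  }
  ref <- updates[[1]]$weights
  for (u in updates[-1]) .check_layout(ref$layout, u$weights$layout)
  n <- vapply(updates, function(u) as.numeric(u$n_samples), numeric(1))
  w <- n / sum(n)
  values <- updates[[1]]$weights$values * w[1]
  for (i in seq_along(updates)[-1]) {
    values <- values + updates[[i]]$weights$values * w[i]
  }
  structure(list(values = values, layout = ref$layout), class = "weight_vector")
}

#' Run the full federated training loop
#'
#' Orchestrates the server role over `R` communication rounds: build the
#' initial global model, deal the training pool into `C` equal random client
#' partitions (and the test set into `C` private client shards by the same
#' rule), then per round broadcast the global weights, collect every client's
#' local SGD update, aggregate by [fedavg()], and have each client evaluate
#' the new global model on its own test shard. Per round both the mean of the
#' per-client metrics and the pooled metrics (computed on the summed
#' confusion matrix) are recorded; pooled values are the headline numbers.
#' The whole run is reproducible from `config$base_seed`.
#'
#' @param config A [fed_config()].
#' @param train Preprocessed training [image_set()] with at least
#'   `config$n_clients` images.
#' @param test Preprocessed test [image_set()] with at least
#'   `config$n_clients` images.
#' @param channel_stats Optional [compute_channel_stats()] result recorded in
#'   the result bundle for reproducibility.
#' @return An object of class `fed_result`: list with `config`, `rounds` (a
#'   data frame with one row per round and client plus `MEAN` and `POOLED`
#'   rows), `final_weights`, `channel_stats` and `runtime_sec`.
#' @export
run_federated_training <- function(config, train, test, channel_stats = NULL) {
  stopifnot(inherits(config, "fed_config"),
            inherits(train, "leaf_image_set"), inherits(test, "leaf_image_set"))
  C <- config$n_clients
  if (length(train$images) < C) .fl_stop("fewer training images than clients")
  if (length(test$images) < C) .fl_stop("fewer test images than clients")
  t0 <- proc.time()[["elapsed"]]

  model <- build_model(config$model)
  global_w <- get_weights(model)
  train_parts <- iid_partition(length(train$images), C,
                               seed = derive_seed(config$base_seed, 71))
  test_parts <- iid_partition(length(test$images), C,
                              seed = derive_seed(config$base_seed, 72))
  client_train <- lapply(train_parts, function(p) subset_images(train, p$indices))
  client_test <- lapply(test_parts, function(p) subset_images(test, p$indices))

  rows <- vector("list", config$rounds)
  for (r in seq_len(config$rounds)) {
    updates <- vector("list", C)
    for (k in seq_len(C)) {
      updates[[k]] <- tryCatch(
        client_update(model, global_w, client_train[[k]],
                      epochs = config$local_epochs,
                      batch_size = config$batch_size,
                      lr = config$learning_rate,
                      seed = derive_seed(config$base_seed, r, k),
                      client_id = k),
        error = function(e) {
          .fl_stop(sprintf("round %d, client %d failed: %s", r, k, conditionMessage(e)))
        })
    }
    global_w <- fedavg(updates)

    cms <- lapply(seq_len(C), function(k) {
      client_evaluate(model, global_w, client_test[[k]])
    })
    per_client <- t(vapply(seq_len(C), function(k) {
      cm_metrics(cms[[k]], average = config$averaging)
    }, numeric(4)))
    pooled_cm <- Reduce(`+`, lapply(cms, unclass))
    pooled <- cm_metrics(pooled_cm, average = config$averaging)
    mean_m <- colMeans(per_client)
    mean_loss <- vapply(updates, function(u) mean(u$epoch_losses), numeric(1))

    rows[[r]] <- data.frame(
      round = r,
      client = c(as.character(seq_len(C)), "MEAN", "POOLED"),
      accuracy = c(per_client[, "accuracy"], mean_m[["accuracy"]], pooled[["accuracy"]]),
      precision = c(per_client[, "precision"], mean_m[["precision"]], pooled[["precision"]]),
      recall = c(per_client[, "recall"], mean_m[["recall"]], pooled[["recall"]]),
      f1 = c(per_client[, "f1"], mean_m[["f1"]], pooled[["f1"]]),
      train_loss = c(mean_loss, NA_real_, NA_real_)
    )
  }

  structure(
    list(config = config, rounds = do.call(rbind, rows),
         final_weights = global_w, channel_stats = channel_stats,
         runtime_sec = proc.time()[["elapsed"]] - t0),
    class = "fed_result"
  )
}

#' @export
print.fed_result <- function(x, ...) {
  fin <- fed_final_metrics(x)
  cat(sprintf("<fed_result> %d clients, %d rounds, %d local epoch(s)\n",
              x$config$n_clients, x$config$rounds, x$config$local_epochs))
  cat(sprintf("  final pooled: accuracy %.4f, precision %.4f, recall %.4f, f1 %.4f\n",
              fin[["accuracy"]], fin[["precision"]], fin[["recall"]], fin[["f1"]]))
  invisible(x)
}

#' Pooled metrics of the final (or best) communication round
#'
#' @param result A `fed_result`.
#' @param which `"final"` (default, last round) or `"best"` (round with
#'   highest pooled accuracy).
#' @return Named numeric vector `round`, `accuracy`, `precision`, `recall`,
#'   `f1`.
#' @export
fed_final_metrics <- function(result, which = c("final", "best")) {
  which <- match.arg(which)
  stopifnot(inherits(result, "fed_result"))
  pooled <- result$rounds[result$rounds$client == "POOLED", , drop = FALSE]
  row <- if (which == "final") {
    pooled[which.max(pooled$round), ]
  } else {
    pooled[which.max(pooled$accuracy), ]
  }
  c(round = row$round, accuracy = row$accuracy, precision = row$precision,
    recall = row$recall, f1 = row$f1)
}
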