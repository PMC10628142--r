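#' One client's local update of the global model
#'
#' The client role of a communication round: receive the global weights, load
#' them into a local copy of the model, train on the client's private
#' partition, and return only the updated weights, the partition size and the
#' training losses — never the raw data. The observable output is a pure
#' function of the declared inputs.
#'
#' @param model A built `fl_model` defining the architecture (its current
#'   weights are irrelevant; `global_weights` replaces them).
#' @param global_weights The broadcast `weight_vector`; layout must match the
#'   model's.
#' @param partition_data Non-empty [image_set()]: the client's training
#'   partition.
#' @param epochs,batch_size,lr Local training hyperparameters, as in
#'   [local_train()].
#' @param seed Integer seed for the local batch shuffles.
#' @param client_id Integer identifier recorded in the result.
#' @return An object of class `client_update_result`: list with `client_id`,
#'   `weights` (post-training `weight_vector`), `n_samples` and
#'   `epoch_losses`.
#' @export
client_update <- function(model, global_weights, partition_data,
                          epochs = 1L, batch_size = 16L, lr = 0.01,
                          seed = 1L, client_id = 1L) {
  stopifnot(inherits(model, "fl_model"), inherits(global_weights, "weight_vector"),
            inherits(partition_data, "leaf_image_set"))
  if (!length(partition_data$images)) .fl_stop("client partition is empty")
  model <- set_weights(model, global_weights)
  fit <- local_train(model, partition_data, epochs = epochs,
                     batch_size = batch_size, lr = lr, seed = seed)
  structure(
    list(client_id = as.integer(client_id), weights = fit$weights,
         n_samples = length(partition_data$images),
         epoch_losses = fit$epoch_losses),
    class = "client_update_result"
  )
}

#' Evaluate global weights on a client's private test data
#'
#' Loads the global weights, predicts the argmax class for every test image
#' and accumulates the results into a confusion matrix whose total equals the
#' number of test images.
#'
#' @param model A built `fl_model`.
#' @param global_weights The `weight_vector` to evaluate.
#' @param test_data Non-empty [image_set()].
#' @return An `fl_confusion` matrix (see [confusion_matrix()]).
#' @export
client_evaluate <- function(model, global_weights, test_data) {
  stopifnot(inherits(model, "fl_model"), inherits(global_weights, "weight_vector"),
            inherits(test_data, "leaf_image_set"))
  if (!length(test_data$images)) .fl_stop("test data is empty")
  if (any(test_data$labels > model$spec$n_classes)) {
    .fl_stop("test labels exceed the model's class count")
  }
  model <- set_weights(model, global_weights)
  pred <- predict(model, test_data)
  K <- model$spec$n_classes
  cls <- if (length(test_data$class_names) == K) {
    test_data$class_names
  } else {
    paste0("class_", seq_len(K))
  }
  confusion_matrix(test_data$labels, pred, cls)
}
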