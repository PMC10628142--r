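# Independent oracles, deliberately written as naive brute-force computations
# so they share no code path with the implementation they check.

# nearest-class-template rule: mean image per class from a training subset,
# classify by smallest Euclidean pixel distance to a class template
nearest_template_accuracy <- function(data, n_train_per_class) {
  K <- length(data$class_names)
  train_idx <- integer(0)
  for (k in seq_len(K)) {
    train_idx <- c(train_idx, which(data$labels == k)[seq_len(n_train_per_class)])
  }
  test_idx <- setdiff(seq_along(data$labels), train_idx)
  templates <- lapply(seq_len(K), function(k) {
    ims <- data$images[intersect(train_idx, which(data$labels == k))]
    Reduce(`+`, ims) / length(ims)
  })
  correct <- 0L
  for (i in test_idx) {
    d <- vapply(templates, function(tp) sum((data$images[[i]] - tp)^2), numeric(1))
    if (which.min(d) == data$labels[i]) correct <- correct + 1L
  }
  correct / length(test_idx)
}

# naive per-pair recount of the four measures from raw labels
brute_force_metrics <- function(true, pred, K) {
  acc <- sum(true == pred) / length(true)
  prec <- rec <- f1 <- numeric(K)
  for (k in seq_len(K)) {
    tp <- 0; fp <- 0; fn <- 0
    for (i in seq_along(true)) {
      if (pred[i] == k && true[i] == k) tp <- tp + 1
      if (pred[i] == k && true[i] != k) fp <- fp + 1
      if (pred[i] != k && true[i] == k) fn <- fn + 1
    }
    prec[k] <- if (tp + fp > 0) tp / (tp + fp) else 0
    rec[k] <- if (tp + fn > 0) tp / (tp + fn) else 0
    f1[k] <- if (prec[k] + rec[k] > 0) 2 * prec[k] * rec[k] / (prec[k] + rec[k]) else 0
  }
  c(accuracy = acc, precision = mean(prec), recall = mean(rec), f1 = mean(f1))
}

# per-coordinate weighted mean, the definition of federated averaging
weighted_mean_oracle <- function(value_list, n) {
  out <- numeric(length(value_list[[1]]))
  for (j in seq_along(out)) {
    num <- 0
    for (i in seq_along(value_list)) num <- num + value_list[[i]][j] * n[i]
    out[j] <- num / sum(n)
  }
  out
}
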