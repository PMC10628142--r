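utils::globalVariables(c("round", "value", "run"))

#' Write a weight vector checkpoint as plain text
#'
#' Layout manifest (parameter names and shapes) followed by the raw values at
#' full double precision; the round-trip through [read_weights()] is exact to
#' 17 significant digits.
#'
#' @param weights A `weight_vector`.
#' @param path Output file path.
#' @return Invisibly, `path`.
#' @export
write_weights <- function(weights, path) {
  stopifnot(inherits(weights, "weight_vector"))
  header <- vapply(names(weights$layout), function(nm) {
    paste0(nm, ":", paste(weights$layout[[nm]], collapse = "x"))
  }, character(1))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(paste("fedleaf-weights", length(header)), header), con)
  writeLines(sprintf("%.17g", weights$values), con)
  invisible(path)
}

#' Read a weight vector checkpoint written by [write_weights()]
#'
#' @param path Checkpoint file path.
#' @return A `weight_vector`.
#' @export
read_weights <- function(path) {
  lines <- readLines(path)
  head_parts <- strsplit(lines[1], " ", fixed = TRUE)[[1]]
  if (head_parts[1] != "fedleaf-weights") .fl_stop("not a fedleaf weight checkpoint")
  n_par <- as.integer(head_parts[2])
  layout <- list()
  for (i in seq_len(n_par)) {
    kv <- strsplit(lines[1L + i], ":", fixed = TRUE)[[1]]
    layout[[kv[1]]] <- as.integer(strsplit(kv[2], "x", fixed = TRUE)[[1]])
  }
  values <- as.numeric(lines[(n_par + 2L):length(lines)])
  if (length(values) != sum(vapply(layout, prod, 1))) {
    .fl_stop("checkpoint value count does not match its layout")
  }
  structure(list(values = values, layout = layout), class = "weight_vector")
}

#' Read an experiment or sweep configuration from a YAML key/value file
#'
#' Flat key/value fields matching the arguments of [fed_config()] (and, for
#' sweeps, `axis` and `values`). A `dataset` key may be a preset name or a
#' directory path; a nested `dataset_spec` block is passed to
#' [dataset_spec()], and a nested `model` block to [model_spec()].
#'
#' @param path YAML file path.
#' @return A [fed_config()] or, when `axis`/`values` are present, a
#'   [sweep_spec()].
#' @export
read_fed_config <- function(path) {
  raw <- yaml::read_yaml(path)
  dataset <- raw$dataset
  if (!is.null(raw$dataset_spec)) {
    dataset <- do.call(dataset_spec, raw$dataset_spec)
  }
  model <- NULL
  if (!is.null(raw$model)) model <- do.call(model_spec, raw$model)
  cfg_keys <- c("n_clients", "rounds", "local_epochs", "batch_size",
                "learning_rate", "test_fraction", "base_seed", "averaging",
                "stats_source")
  args <- raw[intersect(names(raw), cfg_keys)]
  if (!is.null(dataset)) args$dataset <- dataset
  args$model <- model
  cfg <- do.call(fed_config, args)
  if (!is.null(raw$axis)) {
    return(sweep_spec(cfg, axis = raw$axis, values = raw$values))
  }
  cfg
}
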