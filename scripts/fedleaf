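#!/usr/bin/env Rscript
# Thin command-line wrapper over the fedleaf package.
#
#   fedleaf generate --config spec.yml --out data_dir [--seed N]
#   fedleaf run      --config run.yml  --out results_dir [--seed N]
#   fedleaf sweep    --config sweep.yml --out results_dir [--seed N]
#   fedleaf report   --config sweep.yml --out results_dir [--seed N]
#
# Config files are flat YAML key/value documents matching the arguments of
# fedleaf::fed_config() / sweep_spec() (see ?read_fed_config); `generate`
# expects a `dataset_spec:` block.

suppressMessages(library(fedleaf))

argv <- commandArgs(trailingOnly = TRUE)
if (length(argv) < 1) stop("usage: fedleaf <generate|run|sweep|report> --config FILE --out DIR [--seed N]")
cmd <- argv[1]
get_arg <- function(flag, default = NULL) {
  i <- which(argv == flag)
  if (length(i) && i[1] < length(argv)) argv[i[1] + 1] else default
}
config_path <- get_arg("--config")
out <- get_arg("--out", "fedleaf_out")
seed <- get_arg("--seed")
if (is.null(config_path)) stop("--config FILE is required")

override_seed <- function(obj) {
  if (is.null(seed)) return(obj)
  s <- as.integer(seed)
  if (inherits(obj, "fed_config")) obj$base_seed <- s
  if (inherits(obj, "sweep_spec")) obj$base$base_seed <- s
  if (inherits(obj, "leaf_dataset_spec")) obj$seed <- s
  obj
}

if (cmd == "generate") {
  raw <- yaml::read_yaml(config_path)
  spec_args <- if (!is.null(raw$dataset_spec)) raw$dataset_spec else raw
  spec <- override_seed(do.call(dataset_spec, spec_args))
  write_dataset(make_dataset(spec), out)
  cat("wrote dataset to", out, "\n")
} else if (cmd == "run") {
  cfg <- override_seed(read_fed_config(config_path))
  if (!inherits(cfg, "fed_config")) stop("config describes a sweep; use `fedleaf sweep`")
  res <- run_experiment(cfg)
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  write_round_metrics(res, file.path(out, "rounds.csv"))
  write_weights(res$final_weights, file.path(out, "final_weights.txt"))
  utils::write.csv(data.frame(channel = 1:3, mean = res$channel_stats$mean,
                              sd = res$channel_stats$sd),
                   file.path(out, "channel_stats.csv"), row.names = FALSE)
  print(res)
} else if (cmd %in% c("sweep", "report")) {
  sw <- override_seed(read_fed_config(config_path))
  if (!inherits(sw, "sweep_spec")) stop("config lacks `axis`/`values`; use `fedleaf run`")
  results <- run_sweep(sw, out_dir = out)
  summ <- summarize_sweep(results)
  utils::write.csv(as.data.frame(summ), file.path(out, "summary.csv"), row.names = FALSE)
  for (metric in c("accuracy", "f1")) {
    try(plot_round_curves(results, metric,
                          file = file.path(out, paste0("rounds_", metric, ".png"))),
        silent = TRUE)
  }
  print(summ)
} else {
  stop("unknown command '", cmd, "'; expected generate, run, sweep or report")
}
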