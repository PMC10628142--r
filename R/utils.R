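#' Derive a reproducible child seed from a base seed and context integers
#'
#' Streams of randomness in a federated run (per-round, per-client, per-epoch)
#' must be reproducible from one base seed yet mutually decorrelated. This
#' mixes the base seed with any number of context integers (round index,
#' client id, epoch index, ...) through a Lehmer-style modular recurrence and
#' returns an integer seed in `[0, 2^31 - 2]`.
#'
#' @param ... Integers: the base seed followed by context values.
#' @return A single integer seed.
#' @examples
#' derive_seed(42, 3, 1) # round 3, client 1
#' @export
derive_seed <- function(...) {
  parts <- as.numeric(c(...))
  stopifnot(length(parts) >= 1, all(is.finite(parts)))
  m <- 2147483647 # 2^31 - 1, keeps products below 2^53 in double arithmetic
  s <- 17
  for (v in parts) {
    s <- (s * 69621 + (v %% m) + 1) %% m
  }
  as.integer(s)
}

# stop() with the calling function's name stripped, consistent message style
.fl_stop <- function(...) stop(..., call. = FALSE)

.check_count <- function(x, name, min = 1L) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x != as.integer(x) || x < min) {
    .fl_stop(sprintf("`%s` must be a single integer >= %d (got %s)",
                     name, min, paste(format(x), collapse = ", ")))
  }
  as.integer(x)
}

.check_fraction <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x <= 0 || x >= 1) {
    .fl_stop(sprintf("`%s` must be a single number in (0, 1)", name))
  }
  as.numeric(x)
}
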