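#' Equal random (IID) partition of training items across clients
#'
#' Deals a seeded uniform shuffle of `1..n_items` contiguously to `n_clients`
#' clients, so partitions are disjoint, cover every index, and differ in size
#' by at most one item — the equal-and-random split of one shared training
#' pool among federated clients. When `n_clients` does not divide `n_items`,
#' the first `n_items %% n_clients` clients receive the extra item.
#'
#' @param n_items Number of training items, >= `n_clients`.
#' @param n_clients Number of clients, >= 1.
#' @param seed Integer seed; the assignment is deterministic per seed.
#' @return A list of `n_clients` objects of class `client_partition`, each
#'   with fields `client_id` (1-based) and `indices` (sorted integer vector).
#' @examples
#' sizes <- vapply(iid_partition(10, 3, seed = 1), function(p) length(p$indices), 1L)
#' sizes # 4 3 3
#' @export
iid_partition <- function(n_items, n_clients, seed = 1L) {
  n_items <- .check_count(n_items, "n_items")
  n_clients <- .check_count(n_clients, "n_clients")
  seed <- .check_count(seed, "seed", min = 0L)
  if (n_items < n_clients) {
    .fl_stop(sprintf("n_items (%d) must be >= n_clients (%d)", n_items, n_clients))
  }
  set.seed(seed)
  shuffled <- sample.int(n_items)
  base <- n_items %/% n_clients
  extra <- n_items %% n_clients
  sizes <- rep(base, n_clients) + c(rep(1L, extra), rep(0L, n_clients - extra))
  ends <- cumsum(sizes)
  starts <- c(1L, utils::head(ends, -1L) + 1L)
  lapply(seq_len(n_clients), function(k) {
    structure(
      list(client_id = k, indices = sort(shuffled[starts[k]:ends[k]])),
      class = "client_partition"
    )
  })
}

#' Export a partition assignment as a two-column table
#'
#' @param partitions Result of [iid_partition()].
#' @return A data frame with columns `index` and `client_id`, sorted by
#'   `index`, suitable for auditing which client owns which item.
#' @export
partition_table <- function(partitions) {
  stopifnot(length(partitions) >= 1,
            all(vapply(partitions, inherits, TRUE, "client_partition")))
  df <- do.call(rbind, lapply(partitions, function(p) {
    data.frame(index = p$indices, client_id = p$client_id)
  }))
  df[order(df$index), , drop = FALSE]
}
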